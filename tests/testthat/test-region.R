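FWD <- PRIMER_515FY
REV <- PRIMER_926R

test_that("IUPAC window matching follows the subset rule", {
  # Y expands T, M expands A: a concrete realization of the primer matches
  expect_equal(iupac_mismatch_count("GTGTCAGCAGCCGCGGTAA", FWD), 0L)
  expect_equal(iupac_mismatch_count(FWD, FWD), 0L)
  # N in the window matches everything
  expect_equal(iupac_mismatch_count("NTGTCAGCAGCCGCGGTAA", FWD), 0L)
  # window ambiguity matches iff its expansion is a subset of the primer's
  expect_equal(iupac_mismatch_count("RTGTCAGCAGCCGCGGTAA", FWD), 1L)  # R !subset G
  expect_equal(substr(FWD, 4, 4), "Y")
  w <- FWD; substr(w, 4, 4) <- "C"   # C subset of Y
  expect_equal(iupac_mismatch_count(w, FWD), 0L)
  expect_error(iupac_mismatch_count("ACG", FWD), "length")
})

test_that("IUPAC matching agrees with the brute-force expansion oracle", {
  set.seed(11)
  codes <- names(IUPAC_EXPANSION)
  for (i in 1:300) {
    window <- paste(sample(codes, nchar(FWD), replace = TRUE,
                           prob = c(rep(10, 4), rep(1, 11))), collapse = "")
    expect_equal(iupac_mismatch_count(window, FWD),
                 oracle_mismatch_count(window, FWD))
  }
})

test_that("find_primer returns the leftmost admissible window", {
  set.seed(5)
  for (i in 1:50) {
    flank <- random_dna(sample(5:30, 1))
    site <- "GTGTCAGCAGCCGCGGTAA"   # concrete 515F-Y site
    seq <- paste0(flank, site, random_dna(20))
    expect_equal(find_primer(seq, FWD), nchar(flank) + 1L)
  }
  expect_true(is.na(find_primer(random_dna(200), FWD)))
  expect_true(is.na(find_primer("ACG", FWD)))  # shorter than primer
})

test_that("find_primer agrees with an exhaustive scan", {
  set.seed(17)
  for (i in 1:200) {
    seq <- random_dna(sample(30:120, 1))
    mm_tol <- sample(0:3, 1)
    nw <- nchar(seq) - nchar(FWD) + 1L
    exhaustive <- NA_integer_
    for (p in seq_len(nw)) {
      if (oracle_mismatch_count(substr(seq, p, p + nchar(FWD) - 1L),
                                FWD) <= mm_tol) {
        exhaustive <- p
        break
      }
    }
    expect_identical(find_primer(seq, FWD, mm_tol), exhaustive)
  }
})

test_that("region extraction cuts strictly between primer sites", {
  set.seed(23)
  fwd_site <- "GTGTCAGCAGCCGCGGTAA"
  rev_site <- reverse_complement("CCGTCAATTCATTTAAGTTT")  # concrete 926R
  x <- random_dna(373)
  seq <- c(iso = paste0(random_dna(25), fwd_site, x, rev_site, random_dna(25)))
  r <- extract_regions(seq, primer_pair())
  expect_equal(r$region, x)
  expect_true(r$fwd_found && r$rev_found)
  expect_equal(r$orientation, "PLUS")
  expect_false(r$too_short)

  # strand symmetry: reverse-complemented input gives the same region
  r2 <- extract_regions(c(iso = reverse_complement(unname(seq))), primer_pair())
  expect_equal(r2$region, x)
  expect_equal(r2$orientation, "MINUS")

  # forward found, reverse absent: region runs to the sequence end
  seq3 <- c(iso = paste0(random_dna(10), fwd_site, x))
  r3 <- extract_regions(seq3, primer_pair())
  expect_equal(r3$region, x)
  expect_true(r3$fwd_found)
  expect_false(r3$rev_found)

  # neither primer: whole sequence, flags false
  plain <- c(iso = random_dna(300))
  r4 <- extract_regions(plain, primer_pair())
  expect_equal(r4$region, unname(plain))
  expect_false(r4$fwd_found || r4$rev_found)
})

test_that("extraction is idempotent via the fallback branch", {
  set.seed(29)
  fwd_site <- "GTGTCAGCAGCCGCGGTAA"
  rev_site <- reverse_complement("CCGTCAATTCATTTAAGTTT")
  for (i in 1:20) {
    x <- random_dna(sample(150:400, 1))
    seq <- c(iso = paste0(random_dna(30), fwd_site, x, rev_site, random_dna(30)))
    r1 <- extract_regions(seq, primer_pair())
    r2 <- extract_regions(stats::setNames(r1$region, "iso"), primer_pair())
    expect_equal(r2$region, r1$region)
    expect_false(r2$fwd_found)
  }
})

test_that("short regions are flagged too_short", {
  fwd_site <- "GTGTCAGCAGCCGCGGTAA"
  rev_site <- reverse_complement("CCGTCAATTCATTTAAGTTT")
  set.seed(3)
  seq <- c(iso = paste0(random_dna(10), fwd_site, random_dna(40), rev_site))
  expect_message(r <- extract_regions(seq, primer_pair(), min_len = 100),
                 "too_short")
  expect_true(r$too_short)
  expect_equal(r$region_length, 40L)
})

test_that("mismatch profile reports the best window over both strands", {
  set.seed(41)
  site <- "GTGTCAGCAGCCGCGGTAA"
  seq1 <- paste0(random_dna(30), site, random_dna(30))
  seq2 <- reverse_complement(seq1)
  seqs <- c(a = seq1, b = seq2, c = random_dna(80))
  prof <- primer_mismatch_profile(seqs)
  expect_equal(prof$fwd_min_mismatch[1:2], c(0L, 0L))
  expect_gt(prof$fwd_min_mismatch[3], 0L)
})

test_that("reverse complement handles ambiguity codes and is an involution", {
  expect_equal(reverse_complement("ACGTRYSWKMBDHVN"), "NBDHVKMWSRYACGT")
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(names(IUPAC_EXPANSION), 50, replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})
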
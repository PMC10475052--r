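test_that("index answers planted containment and empty-set queries", {
  idx <- build_asv_index(c(A1 = "ACGTACGT"))
  ms <- match_isolates(c(i1 = "TTACGTACGTTT"), idx)
  expect_equal(ms$pairs$asv_id, "A1")
  expect_equal(ms$pairs$offset, 3L)

  # identity: region equal to the ASV matches
  ms2 <- match_isolates(c(i1 = "ACGTACGT"), idx)
  expect_equal(nrow(ms2$pairs), 1L)

  # one substitution breaks the 100% identity contract
  ms3 <- match_isolates(c(i1 = "TTACGAACGTTT"), idx)
  expect_equal(nrow(ms3$pairs), 0L)

  # region shorter than every ASV is reported, never matched
  ms4 <- match_isolates(c(i1 = "ACGT"), idx)
  expect_equal(nrow(ms4$pairs), 0L)
  expect_equal(ms4$short_regions, "i1")
})

test_that("duplicate ASV sequences are rejected at index build", {
  expect_error(build_asv_index(c(A1 = "ACGTAC", A2 = "ACGTAC")),
               "duplicate ASV sequence.*A1.*A2")
})

test_that("indexed matcher equals the naive scan on random instances", {
  set.seed(47)
  for (i in 1:60) {
    n_asv <- sample(5:60, 1)
    n_reg <- sample(3:15, 1)
    asv_len <- sample(30:60, 1)
    asvs <- named_seqs(n_asv, asv_len, prefix = "A")
    while (anyDuplicated(asvs)) asvs <- named_seqs(n_asv, asv_len, "A")
    regions <- named_seqs(n_reg, sample(80:200, 1), prefix = "R")
    # plant some containments and 1-mismatch decoys
    for (j in seq_len(min(3L, n_reg))) {
      a <- asvs[[sample(n_asv, 1)]]
      planted <- if (j %% 2L == 0L) a else mutate1(a)
      r <- regions[[j]]
      pos <- sample.int(nchar(r) - nchar(a) + 1L, 1L)
      substr(r, pos, pos + nchar(a) - 1L) <- planted
      regions[j] <- r
    }
    ms <- match_isolates(regions, build_asv_index(asvs))
    expect_identical(match_set_keys(ms), naive_match_keys(regions, asvs))
  }
})

test_that("matching is monotone in ASVs and antitone in region length", {
  set.seed(53)
  asvs <- named_seqs(30, 40, prefix = "A")
  regions <- named_seqs(10, 150, prefix = "R")
  for (j in 1:6) {
    a <- asvs[[sample(30, 1)]]
    r <- regions[[j]]
    pos <- sample.int(nchar(r) - nchar(a) + 1L, 1L)
    substr(r, pos, pos + nchar(a) - 1L) <- a
    regions[j] <- r
  }
  ms_all <- match_set_keys(match_isolates(regions, build_asv_index(asvs)))
  # adding an ASV never removes pairs
  ms_sub <- match_set_keys(match_isolates(regions,
                                          build_asv_index(asvs[1:20])))
  expect_true(all(ms_sub %in% ms_all))
  # truncating regions never adds pairs
  trunc <- substr(regions, 1, 100)
  names(trunc) <- names(regions)
  ms_tr <- match_set_keys(match_isolates(trunc, build_asv_index(asvs)))
  expect_true(all(ms_tr %in% ms_all))
})

test_that("STRICT matches are a subset of EXPAND matches", {
  set.seed(59)
  asvs <- named_seqs(20, 30, prefix = "A")
  regions <- named_seqs(8, 100, prefix = "R")
  amb <- c("R", "Y", "N", "S", "W")
  for (j in 1:8) {
    a <- asvs[[sample(20, 1)]]
    r <- regions[[j]]
    pos <- sample.int(nchar(r) - nchar(a) + 1L, 1L)
    substr(r, pos, pos + nchar(a) - 1L) <- a
    # degrade some planted copies with ambiguity codes
    if (j <= 4) {
      p2 <- pos + sample.int(nchar(a), 1L) - 1L
      substr(r, p2, p2) <- sample(amb, 1)
    }
    regions[j] <- r
  }
  strict <- match_set_keys(match_isolates(regions, build_asv_index(asvs),
                                          policy = "STRICT"))
  expand <- match_set_keys(match_isolates(regions, build_asv_index(asvs),
                                          policy = "EXPAND"))
  expect_true(all(strict %in% expand))
})

test_that("EXPAND matches iff the ASV base lies in the region's expansion", {
  idx <- build_asv_index(c(A1 = "ACGTACGTACGT"))
  # R = {A,G} contains the required A at that position
  reg <- c(i1 = "TTRCGTACGTACGTTT")
  expect_equal(nrow(match_isolates(reg, idx, policy = "EXPAND")$pairs), 1L)
  expect_equal(nrow(match_isolates(reg, idx, policy = "STRICT")$pairs), 0L)
  # Y = {C,T} does not contain A
  reg2 <- c(i1 = "TTYCGTACGTACGTTT")
  expect_equal(nrow(match_isolates(reg2, idx, policy = "EXPAND")$pairs), 0L)
})

test_that("multi-hit report ranks hits and measures extra-hit read share", {
  # 3 ASVs, one sample; iso1 hits A and B, iso2 hits A only
  counts <- matrix(c(50L, 30L, 20L), 1, 3,
                   dimnames = list("S1", c("A", "B", "C")))
  ms <- structure(list(
    pairs = data.frame(isolate_id = c("iso1", "iso1", "iso2"),
                       asv_id = c("A", "B", "A"),
                       asv_length = c(5L, 5L, 5L), offset = 1L),
    isolates_attempted = c("iso1", "iso2", "iso3"),
    short_regions = character(0), policy = "STRICT"), class = "match_set")
  rep <- multi_hit_report(ms, counts)
  # all hits recruit A+B = 80%; top hits only (A for both isolates) = 50%
  expect_equal(rep$pct_reads_all_hits, 80)
  expect_equal(rep$pct_reads_top_hits, 50)
  expect_equal(rep$extra_hit_read_share, 30)
  expect_equal(rep$per_isolate$n_hits, c(2L, 1L, 0L))
  expect_equal(rep$per_isolate$top_asv[1:2], c("A", "A"))

  # two isolates sharing one ASV: union counting, zero extra share
  ms2 <- structure(list(
    pairs = data.frame(isolate_id = c("iso1", "iso2"), asv_id = "A",
                       asv_length = 5L, offset = 1L),
    isolates_attempted = c("iso1", "iso2"),
    short_regions = character(0), policy = "STRICT"), class = "match_set")
  rep2 <- multi_hit_report(ms2, counts)
  expect_equal(rep2$extra_hit_read_share, 0)
  expect_equal(rep2$pct_reads_all_hits, 50)
})
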
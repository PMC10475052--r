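test_that("community simulation is deterministic and long-tailed", {
  cfg <- sim_config(n_taxa = 100, seed = 139)
  c1 <- simulate_community(cfg)
  c2 <- simulate_community(cfg)
  expect_identical(c1, c2)
  expect_false(anyDuplicated(c1$asv_seqs) > 0)
  expect_true(all(nchar(c1$asv_seqs) == cfg$region_length))
  expect_equal(unname(rowSums(c1$abundance)), rep(1, nrow(c1$abundance)))
  # lognormal tail shape at sdlog 2 (bounds from direct simulation of the
  # abundance model): at least one abundant taxon, a substantial sub-0.1%
  # tail, and a non-empty rare class
  for (seed in c(7, 19, 57)) {
    set.seed(seed)
    a <- stats::setNames(rlnorm(100, 0, 2), paste0("t", 1:100))
    r <- a / sum(a)
    expect_gte(sum(r > 0.01), 1)
    expect_gte(sum(r < 0.001), 20)
  }
  mra <- colMeans(c1$abundance)
  expect_gte(sum(classify_biosphere(mra) == "RARE"), 1)
})

test_that("sdlog 0 degenerates to near-uniform abundances", {
  cfg <- sim_config(n_taxa = 50, sdlog = 0, layers = "SRF",
                    size_fractions = "0.2-0.8", seed = 149)
  comm <- simulate_community(cfg)
  # jitter only (sdlog 0.3 within stratum); base abundances equal
  base <- comm$abundance[1, !colnames(comm$abundance) %in% comm$culturable]
  expect_lt(max(base) / min(base), 10)
  cfg2 <- sim_config(n_taxa = 50, sdlog = 0.01, seed = 151)
  a <- rlnorm(50, 0, 0.01)
  expect_lt(max(a) / min(a), 1.5)
})

test_that("planted culturable read fraction is exact in expectation", {
  cfg <- sim_config(n_taxa = 60, layers = "BATHY", size_fractions = "0.2-0.8",
                    culturable_read_fraction = c(BATHY = 0.2),
                    copy_number_model = "none", n_culturable = 10, seed = 157)
  comm <- simulate_community(cfg)
  in_c <- colnames(comm$abundance) %in% comm$culturable
  expect_equal(unname(sum(comm$abundance[1, in_c])), 0.2)
})

test_that("multinomial counts conserve depth and respect copy-number inflation", {
  cfg <- sim_config(n_taxa = 40, layers = "SRF", size_fractions = "0.2-0.8",
                    n_samples_per_stratum = 30, reads_per_sample = 20000,
                    reads_jitter = 0, copy_number_model = "none",
                    culturable_read_fraction = c(SRF = 0.3),
                    n_culturable = 8, seed = 163)
  comm <- simulate_community(cfg)
  cnt <- simulate_counts(comm, cfg)
  expect_true(all(rowSums(cnt$counts) == 20000L))
  # copy numbers all 1: read fraction estimates cell abundance
  in_c <- colnames(cnt$counts) %in% comm$culturable
  frac <- rowSums(cnt$counts[, in_c, drop = FALSE]) / rowSums(cnt$counts)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.3), 3 * se)

  # a 10x copy-number taxon is ~10x inflated at equal cell abundance
  comm2 <- comm
  comm2$abundance[1, ] <- 1 / cfg$n_taxa
  comm2$copy_numbers$copy_number <- c(10, rep(1, cfg$n_taxa - 1L))
  cnt2 <- simulate_counts(comm2, cfg)
  shares <- colMeans(cnt2$counts / rowSums(cnt2$counts))
  ratio <- shares[1] / mean(shares[-1])
  expect_gt(ratio, 8)
  expect_lt(ratio, 12)
})

test_that("isolate construction plants matchable and unmatchable isolates", {
  cfg0 <- sim_config(n_taxa = 50, nonmatch_fraction = 0, isolate_count = 30,
                     n_culturable = 10, seed = 167)
  st <- simulate_study(cfg0)
  regions <- extract_regions(st$isolate_seqs, primer_pair())
  expect_true(all(regions$fwd_found & regions$rev_found))
  ms <- match_isolates(regions, build_asv_index(st$asv_seqs))
  hits <- hits_per_isolate(ms)
  expect_true(all(hits >= 1L))
  # each isolate matches its own source taxon
  src <- st$truth$source_taxon
  own <- paste(names(src), src, sep = "\r")
  expect_true(all(own %in% match_set_keys(ms)))
  # coverage guarantee: every culturable taxon isolated at least once
  expect_setequal(unique(src), st$truth$culturable)

  cfg1 <- sim_config(n_taxa = 50, nonmatch_fraction = 1, isolate_count = 20,
                     n_culturable = 10, seed = 173)
  st1 <- simulate_study(cfg1)
  ms1 <- match_isolates(extract_regions(st1$isolate_seqs, primer_pair()),
                        build_asv_index(st1$asv_seqs))
  expect_equal(nrow(ms1$pairs), 0L)
})

test_that("planted unmatched fraction is recovered", {
  cfg <- sim_config(n_taxa = 80, nonmatch_fraction = 0.25, isolate_count = 100,
                    n_culturable = 20, seed = 179)
  st <- simulate_study(cfg)
  ms <- match_isolates(extract_regions(st$isolate_seqs, primer_pair()),
                       build_asv_index(st$asv_seqs))
  u <- unmatched_isolate_fraction(ms)$overall
  expect_equal(u, 25)   # substitutions make matching impossible by design
})

test_that("full study generation is reproducible per seed", {
  cfg <- sim_config(n_taxa = 60, seed = 181)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$isolate_seqs, s2$isolate_seqs)
  expect_identical(s1$station_counts, s2$station_counts)
  s3 <- simulate_study(sim_config(n_taxa = 60, seed = 182))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("station simulation records its planted cultivability", {
  st <- simulate_station_counts(sim_config(seed = 191))
  truth <- attr(st, "truth")
  expect_equal(st$cfu_per_ml / st$cells_per_ml,
               unname(truth[st$station_id]))
  expect_true(all(st$cells_per_ml > 0))
})
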
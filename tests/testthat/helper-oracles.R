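# Shared oracles and fixture builders. Oracles are deliberately naive and
# independent of the package's own algorithms.

# Naive containment scan: every (region, asv) pair checked with fixed
# substring search. Returns a sorted "isolate\rasv" key vector.
naive_match_keys <- function(regions, asv_seqs) {
  keys <- character(0L)
  for (i in seq_along(regions)) {
    hit <- vapply(asv_seqs, function(a) {
      grepl(a, regions[[i]], fixed = TRUE)
    }, logical(1L))
    if (any(hit)) {
      keys <- c(keys, paste(names(regions)[i], names(asv_seqs)[hit],
                            sep = "\r"))
    }
  }
  sort(keys)
}

match_set_keys <- function(ms) {
  sort(paste(ms$pairs$isolate_id, ms$pairs$asv_id, sep = "\r"))
}

# IUPAC expansions for the brute-force primer-matching oracle.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Position-by-position set-membership scan (the spec'd matching rule,
# written the slow obvious way).
oracle_mismatch_count <- function(window, primer) {
  w <- strsplit(window, "")[[1L]]
  p <- strsplit(primer, "")[[1L]]
  mm <- 0L
  for (i in seq_along(p)) {
    we <- IUPAC_EXPANSION[[w[i]]]
    pe <- IUPAC_EXPANSION[[p[i]]]
    ok <- w[i] == "N" || all(we %in% pe)
    if (!ok) mm <- mm + 1L
  }
  mm
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

named_seqs <- function(n, len, prefix = "s") {
  out <- vapply(seq_len(n), function(i) random_dna(len), character(1L))
  names(out) <- sprintf("%s%03d", prefix, seq_len(n))
  out
}

# One substitution at a random position.
mutate1 <- function(seq) {
  pos <- sample.int(nchar(seq), 1L)
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  seq
}

# A small default synthetic study for reuse across test files.
tiny_study <- function(seed = 101, ...) {
  simulate_study(sim_config(n_taxa = 80, n_samples_per_stratum = 2,
                            reads_per_sample = 3000, isolate_count = 40,
                            n_culturable = 15,
                            layers = c("SRF", "BATHY"),
                            size_fractions = "0.2-0.8",
                            seed = seed, ...))
}
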
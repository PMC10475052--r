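# Permutation rarefaction and collector curves.
#
# Rarefaction draws reads without replacement (multivariate
# hypergeometric): a sample with counts (c_1, ..., c_T) rarefied to depth d
# is a uniform draw of d reads from the pooled c_1 + ... + c_T. The draw is
# realized by the exact sequential-conditional scheme
#   x_1 ~ Hypergeometric(d; c_1, C - c_1),
#   x_i | x_1..x_{i-1} ~ Hypergeometric(d - sum(x); c_i, remaining pool),
# vectorized over permutations, so each single draw sums exactly to depth.

# n_draws x n_taxa matrix of independent without-replacement draws.
.hyper_draws <- function(x, depth, n_draws) {
  stopifnot(all(x >= 0), depth >= 0)
  out <- matrix(0L, nrow = n_draws, ncol = length(x))
  rem <- sum(x)
  k <- rep.int(depth, n_draws)
  for (i in seq_along(x)) {
    rem <- rem - x[i]
    xi <- if (x[i] == 0L) integer(n_draws)
          else as.integer(stats::rhyper(n_draws, m = x[i], n = rem, k = k))
    k <- k - xi
    out[, i] <- xi
  }
  out
}

#' Rarefy one sample once
#'
#' A single multivariate-hypergeometric draw: \code{depth} reads sampled
#' without replacement from the sample's read pool. The result sums exactly
#' to \code{depth} and zeros stay zero.
#'
#' @param x Integer count vector for one sample.
#' @param depth Number of reads to draw; must not exceed \code{sum(x)}.
#' @param sample_id Label used in error messages.
#' @return Integer vector of the same length as \code{x}.
#' @export
rarefy_once <- function(x, depth, sample_id = "sample") {
  x <- as.integer(x)
  if (depth > sum(x)) {
    stop(sprintf("rarefaction depth %d exceeds total reads %d in %s",
                 as.integer(depth), sum(x), sample_id))
  }
  drop(.hyper_draws(x, as.integer(depth), 1L))
}

#' Permutation rarefaction of a count table
#'
#' Every retained sample is rarefied \code{n_perm} times to a common depth;
#' the reported cell value is the round-half-even of the mean over
#' permutations (unrounded means are kept for downstream ranking). Samples
#' with fewer reads than \code{depth} are dropped with a warning before
#' rarefying. Reproducibility: sample i uses the substream seed
#' \code{seed + 1009 * i}, so results do not depend on evaluation order.
#'
#' @param counts Samples x ASVs integer matrix.
#' @param depth Target depth; default the minimum sample total (the lowest
#'   sampling effort).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed (required for reproducibility).
#' @return A \code{rarefied_table}: list with \code{counts} (rounded
#'   integer matrix), \code{means} (unrounded permutation means),
#'   \code{depth}, \code{n_perm}, \code{seed}, \code{dropped}.
#' @export
rarefy_permuted <- function(counts, depth = NULL, n_perm = 1000L, seed) {
  stopifnot(is.matrix(counts), !missing(seed))
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1L) stop("rarefaction depth must be >= 1")
  drop_idx <- which(totals < depth)
  if (length(drop_idx)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[drop_idx], collapse = ", "))
    counts <- counts[-drop_idx, , drop = FALSE]
  }
  if (!nrow(counts)) stop("no samples left after dropping below-depth samples")
  means <- matrix(0, nrow = nrow(counts), ncol = ncol(counts),
                  dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    set.seed(seed + 1009L * i)
    draws <- .hyper_draws(as.integer(counts[i, ]), depth, as.integer(n_perm))
    means[i, ] <- colMeans(draws)
  }
  rounded <- round(means)   # round half to even
  storage.mode(rounded) <- "integer"
  structure(list(counts = rounded, means = means, depth = depth,
                 n_perm = as.integer(n_perm), seed = seed,
                 dropped_samples = names(totals)[drop_idx]),
            class = "rarefied_table")
}

#' @export
print.rarefied_table <- function(x, ...) {
  cat(sprintf(
    "rarefied_table: %d samples x %d ASVs, depth %d, %d permutations (seed %s)\n",
    nrow(x$counts), ncol(x$counts), x$depth, x$n_perm, format(x$seed)))
  if (length(x$dropped_samples)) {
    cat("  dropped below depth:", paste(x$dropped_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

# Accept either a plain matrix or a rarefied_table downstream.
.counts_of <- function(x) {
  if (inherits(x, "rarefied_table")) x$counts else x
}
.means_of <- function(x) {
  if (inherits(x, "rarefied_table")) x$means else x
}

#' Dereplicate isolates into 100%-identity OTUs
#'
#' Two isolates share an OTU iff their extracted region sequences are
#' character-identical; the OTU id is the lexicographically smallest member
#' isolate id.
#'
#' @param regions Named character vector of region sequences (names are
#'   isolate ids).
#' @return data.frame with columns isolate_id and otu_id.
#' @export
dereplicate_isolates <- function(regions) {
  stopifnot(!is.null(names(regions)))
  g <- match(unname(regions), unique(unname(regions)))
  otu_ids <- vapply(split(names(regions), g), min, character(1L))
  data.frame(isolate_id = names(regions),
             otu_id = unname(otu_ids[as.character(g)]),
             stringsAsFactors = FALSE)
}

#' Collector (accumulation) curve over permuted sample orderings
#'
#' For k = 1..n samples, the mean and standard deviation over \code{n_perm}
#' random sample orderings of the cumulative number of distinct units
#' (ASVs or isolate OTUs) observed. At k = n the mean equals total richness
#' exactly and the sd is 0.
#'
#' @param incidence Units x samples logical/0-1 matrix (unit present in
#'   sample).
#' @param n_perm Number of permuted orderings.
#' @param seed Seed.
#' @return data.frame with columns k, mean, sd.
#' @export
collector_curve <- function(incidence, n_perm = 100L, seed = 1L) {
  m <- (as.matrix(incidence) > 0) * 1L
  ns <- ncol(m)
  set.seed(seed)
  rich <- matrix(0L, nrow = n_perm, ncol = ns)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(ns)
    seen <- m[, ord, drop = FALSE]
    if (ns > 1L) {
      seen <- t(apply(seen, 1L, cummax))
    }
    rich[p, ] <- colSums(seen)
  }
  data.frame(k = seq_len(ns),
             mean = colMeans(rich),
             sd = apply(rich, 2L, stats::sd))
}
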
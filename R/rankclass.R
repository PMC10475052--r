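# Rank-abundance structure and occurrence categories.
#
# Marine communities show a characteristic long-tailed rank-abundance
# curve: few abundant taxa (> 1% mean relative abundance), relatively few
# mid-abundant ones, and a long rare tail (< 0.01%). Classifying matched
# ASVs by these classes tells whether cultivation recovers abundant
# community members or only the rare biosphere.

#' Mean relative abundance of each ASV across samples
#'
#' Per-sample relative abundances (each summing to 1) averaged unweighted
#' over samples.
#'
#' @param counts Samples x ASVs matrix or \code{rarefied_table} (unrounded
#'   permutation means are used when available, so downstream ranking is
#'   free of rounding ties).
#' @return Named numeric vector in [0, 1].
#' @export
mean_relative_abundance <- function(counts) {
  mat <- .means_of(counts)
  totals <- rowSums(mat)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total: ",
         paste(rownames(mat)[totals <= 0], collapse = ", "))
  }
  colMeans(mat / totals)
}

#' Classify ASVs into biosphere classes
#'
#' ABUNDANT: mean relative abundance > 1\%; RARE: < 0.01\%; MID otherwise.
#' Boundary values (exactly 1\% or exactly 0.01\%) fall in MID: the class
#' definitions use strict inequalities on both sides of MID's neighbours,
#' leaving the boundaries to the middle class.
#'
#' @param mean_rel_abund Named numeric vector from
#'   \code{\link{mean_relative_abundance}} (proportions, not percent).
#' @return Factor with levels ABUNDANT, MID, RARE.
#' @export
classify_biosphere <- function(mean_rel_abund) {
  cls <- ifelse(mean_rel_abund > 0.01, "ABUNDANT",
                ifelse(mean_rel_abund < 1e-4, "RARE", "MID"))
  factor(cls, levels = c("ABUNDANT", "MID", "RARE"))
}

#' Rank-abundance table with match flags
#'
#' ASVs sorted by descending mean relative abundance (ties broken
#' lexicographically by ASV id), flagged when 100\% identical to at least
#' one isolate, with their biosphere class. The output is a permutation of
#' the input ASV set.
#'
#' @param mean_rel_abund Named numeric vector.
#' @param matched A \code{match_set} or character vector of matched ASV ids.
#' @return data.frame: rank, asv_id, mean_rel_abundance, matched, class.
#' @export
rank_abundance_table <- function(mean_rel_abund, matched = character(0L)) {
  if (inherits(matched, "match_set")) matched <- matched_asvs(matched)
  ids <- names(mean_rel_abund)
  ord <- order(-mean_rel_abund, ids)
  data.frame(
    rank = seq_along(ids),
    asv_id = ids[ord],
    mean_rel_abundance = unname(mean_rel_abund[ord]),
    matched = ids[ord] %in% matched,
    class = classify_biosphere(unname(mean_rel_abund[ord])),
    stringsAsFactors = FALSE
  )
}

#' Rank-abundance plot
#'
#' Log-scale rank plot; ASVs identical to isolates are highlighted.
#'
#' @param rank_table data.frame from \code{\link{rank_abundance_table}}.
#' @param main Plot title.
#' @return Invisibly, \code{rank_table}.
#' @export
plot_rank_abundance <- function(rank_table, main = "Rank abundance") {
  ra <- pmax(rank_table$mean_rel_abundance, .Machine$double.xmin)
  graphics::plot(rank_table$rank, 100 * ra, log = "y", pch = 16, cex = 0.5,
                 col = ifelse(rank_table$matched, "darkorange", "grey60"),
                 xlab = "ASV rank", ylab = "Mean relative abundance (%)",
                 main = main)
  graphics::abline(h = c(1, 0.01), lty = 3, col = "grey40")
  graphics::legend("topright", pch = 16, col = c("darkorange", "grey60"),
                   legend = c("matched by isolate", "unmatched"), bty = "n")
  invisible(rank_table)
}

#' Classify genera by station occurrence
#'
#' The fraction of stations with at least one isolate of the genus decides
#' the category: UBIQUITOUS (> 80\% of stations), WIDESPREAD (>= 50\%),
#' REGIONAL (> 25\%), LOCAL (<= 25\%). The station set is the distinct
#' station ids among the isolates. Threshold arguments expose the boundary
#' policy.
#'
#' @param isolate_meta data.frame with columns \code{genus} and
#'   \code{station_id}; isolates with NA genus are ignored.
#' @param ubiquitous,widespread,regional Fraction thresholds (strict >,
#'   inclusive >=, strict > respectively).
#' @return data.frame: genus, n_stations, n_stations_total, fraction,
#'   category (factor UBIQUITOUS/WIDESPREAD/REGIONAL/LOCAL).
#' @export
occurrence_classify <- function(isolate_meta, ubiquitous = 0.8,
                                widespread = 0.5, regional = 0.25) {
  stopifnot(all(c("genus", "station_id") %in% colnames(isolate_meta)))
  df <- isolate_meta[!is.na(isolate_meta$genus), , drop = FALSE]
  n_total <- length(unique(isolate_meta$station_id))
  n_st <- tapply(df$station_id, df$genus, function(s) length(unique(s)))
  frac <- as.numeric(n_st) / n_total
  cat_of <- ifelse(frac > ubiquitous, "UBIQUITOUS",
                   ifelse(frac >= widespread, "WIDESPREAD",
                          ifelse(frac > regional, "REGIONAL", "LOCAL")))
  out <- data.frame(
    genus = names(n_st),
    n_stations = as.integer(n_st),
    n_stations_total = n_total,
    fraction = frac,
    category = factor(cat_of,
                      levels = c("UBIQUITOUS", "WIDESPREAD", "REGIONAL", "LOCAL")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$fraction, out$genus), ]
}
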
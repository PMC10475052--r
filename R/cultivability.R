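# The "great plate count anomaly" statistic: the percentage of
# heterotrophic prokaryotic cells (flow cytometry, cells/ml, phototrophs
# already excluded by the caller) recoverable as colonies (cfu/ml).

#' Cultivability percentage from plate and cytometry counts
#'
#' \code{100 * cfu_per_ml / cells_per_ml}. Values above 100\% are allowed
#' with a warning (replicate plating can exceed cytometry on pathological
#' inputs). \code{cells_per_ml} must already exclude photosynthetic
#' Cyanobacteria, which plating on heterotroph media does not target.
#'
#' @param cfu_per_ml Colony-forming units per ml (>= 0).
#' @param cells_per_ml Total heterotrophic prokaryote cells per ml (> 0).
#' @return Numeric vector of percentages.
#' @export
cultivability_percent <- function(cfu_per_ml, cells_per_ml) {
  if (any(cells_per_ml <= 0)) stop("cells_per_ml must be > 0")
  if (any(cfu_per_ml < 0)) stop("cfu_per_ml must be >= 0")
  pct <- 100 * cfu_per_ml / cells_per_ml
  if (any(pct > 100)) {
    warning("cultivability above 100% for ", sum(pct > 100), " record(s)")
  }
  pct
}

#' Cultivability per station
#'
#' @param stations data.frame from \code{\link{read_station_counts}} (or
#'   with the same columns).
#' @return Same data.frame with a \code{pct_cultivable} column.
#' @export
cultivability_table <- function(stations) {
  stopifnot(all(c("station_id", "layer", "cfu_per_ml", "cells_per_ml")
                %in% colnames(stations)))
  stations$pct_cultivable <- cultivability_percent(stations$cfu_per_ml,
                                                   stations$cells_per_ml)
  stations
}

#' Per-layer summary of cultivability percentages
#'
#' Mean, minimum and maximum of \code{pct_cultivable} per depth layer;
#' layers with no records are omitted.
#'
#' @param records data.frame with columns \code{layer} and
#'   \code{pct_cultivable} (see \code{\link{cultivability_table}}).
#' @return data.frame: layer, n, mean, min, max.
#' @export
cultivability_layer_summary <- function(records) {
  stopifnot(all(c("layer", "pct_cultivable") %in% colnames(records)))
  idx <- split(seq_len(nrow(records)), records$layer)
  out <- do.call(rbind, lapply(names(idx), function(l) {
    v <- records$pct_cultivable[idx[[l]]]
    data.frame(layer = l, n = length(v), mean = mean(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
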
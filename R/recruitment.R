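# The headline statistics: per-sample and per-stratum percentages of ASVs
# (diversity) and reads (abundance) 100% identical to cultured isolates,
# with taxon exclusion and rRNA operon copy-number correction.

.RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus")

#' Remove ASVs by taxonomy label
#'
#' Excluded labels are rank-qualified, e.g. \code{"domain:Archaea"} or
#' \code{"phylum:Cyanobacteria"}; a bare label matches any rank field.
#' Taxonomy strings are semicolon-separated ordered ranks
#' (domain;phylum;class;order;family;genus), unassigned ranks empty.
#' Samples left empty after filtering are dropped with a warning.
#'
#' @param counts Samples x ASVs matrix.
#' @param taxonomy Named character vector, ASV id -> taxonomy string.
#' @param exclude Character vector of labels; empty means identity.
#' @return Filtered matrix with attribute \code{removed_asvs}.
#' @export
filter_taxa <- function(counts, taxonomy, exclude = character(0L)) {
  stopifnot(is.matrix(counts))
  if (!length(exclude)) {
    attr(counts, "removed_asvs") <- character(0L)
    return(counts)
  }
  tax <- taxonomy[colnames(counts)]
  fields <- strsplit(ifelse(is.na(tax), "", tax), ";", fixed = TRUE)
  hit <- rep(FALSE, ncol(counts))
  for (lab in exclude) {
    parts <- strsplit(lab, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[1L] %in% .RANK_NAMES) {
      ri <- match(parts[1L], .RANK_NAMES)
      hit <- hit | vapply(fields, function(f) {
        length(f) >= ri && f[ri] == parts[2L]
      }, logical(1L))
    } else {
      needle <- parts[length(parts)]
      hit <- hit | vapply(fields, function(f) needle %in% f, logical(1L))
    }
  }
  removed <- colnames(counts)[hit]
  out <- counts[, !hit, drop = FALSE]
  empty <- rowSums(out) == 0
  if (any(empty)) {
    warning("dropping sample(s) emptied by taxon filtering: ",
            paste(rownames(out)[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  attr(out, "removed_asvs") <- removed
  out
}

#' Per-sample recruitment percentages
#'
#' An ASV is present in a sample iff its (rarefied) count is positive.
#' \code{pct_asvs} is the percentage of the sample's richness matched by at
#' least one isolate; \code{pct_reads} the percentage of the sample's reads
#' carried by matched ASVs. The matched set is the union over isolates, so
#' an ASV hit by several isolates is counted once.
#'
#' @param counts Samples x ASVs matrix or \code{rarefied_table}.
#' @param matched A \code{match_set} or character vector of matched ASV ids.
#' @param copy_median Optional median rRNA operon copy number; when given,
#'   \code{pct_reads_corrected = pct_reads / copy_median} is added.
#' @return data.frame, one row per sample: sample_id, n_asvs_present,
#'   n_asvs_matched, pct_asvs, reads_total, reads_matched, pct_reads
#'   (+ pct_reads_corrected).
#' @export
recruitment_per_sample <- function(counts, matched, copy_median = NULL) {
  mat <- .counts_of(counts)
  if (inherits(matched, "match_set")) matched <- matched_asvs(matched)
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads reached recruitment (exclude upstream): ",
         paste(rownames(mat)[totals == 0], collapse = ", "))
  }
  is_matched <- colnames(mat) %in% matched
  present <- mat > 0
  n_present <- rowSums(present)
  n_matched <- rowSums(present[, is_matched, drop = FALSE])
  reads_matched <- rowSums(mat[, is_matched, drop = FALSE])
  out <- data.frame(
    sample_id = rownames(mat),
    n_asvs_present = as.integer(n_present),
    n_asvs_matched = as.integer(n_matched),
    pct_asvs = 100 * n_matched / n_present,
    reads_total = as.numeric(totals),
    reads_matched = as.numeric(reads_matched),
    pct_reads = 100 * reads_matched / totals,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(copy_median)) {
    out$pct_reads_corrected <- copy_number_correct(out$pct_reads, copy_median)
  }
  out
}

#' Correct a read percentage for rRNA operon copy number
#'
#' PCR-based read counts overestimate taxa with many rRNA operon copies;
#' dividing the recruited-read percentage by the median copy number of the
#' isolated genera removes the bulk of that inflation.
#'
#' @param pct_reads Numeric vector of percentages.
#' @param copy_median Median copy number (>= 1).
#' @return Corrected percentages (same scale). Use
#'   \code{\link{format_percent}} for the one-decimal reporting rule.
#' @export
copy_number_correct <- function(pct_reads, copy_median) {
  stopifnot(is.numeric(copy_median), length(copy_median) == 1L,
            copy_median >= 1)
  pct_reads / copy_median
}

#' Format a percentage at reporting precision
#'
#' One decimal place, with a trailing zero decimal collapsed to an integer
#' (7.97 -> "8", 0.46 -> "0.5").
#'
#' @param x Numeric vector of percentages.
#' @return Character vector.
#' @export
format_percent <- function(x) {
  s <- formatC(round(x, 1L), format = "f", digits = 1L)
  sub("\\.0$", "", s)
}

#' Per-stratum means of recruitment percentages
#'
#' Unweighted arithmetic mean and sample standard deviation over the
#' samples in each stratum; a stratum with a single sample reports sd as
#' NA, not zero.
#'
#' @param per_sample data.frame from \code{\link{recruitment_per_sample}}.
#' @param meta Sample metadata with \code{sample_id} and the grouping
#'   columns.
#' @param keys Metadata columns defining the strata.
#' @return data.frame with one row per stratum: keys, n_samples, and
#'   mean/sd of each percentage column.
#' @export
stratum_means <- function(per_sample, meta, keys = c("dataset", "layer")) {
  stopifnot(all(keys %in% colnames(meta)))
  m <- merge(per_sample, meta[, c("sample_id", keys), drop = FALSE],
             by = "sample_id")
  if (nrow(m) < nrow(per_sample)) {
    stop("sample(s) without metadata: ",
         paste(setdiff(per_sample$sample_id, meta$sample_id), collapse = ", "))
  }
  pct_cols <- intersect(c("pct_asvs", "pct_reads", "pct_reads_corrected"),
                        colnames(per_sample))
  g <- interaction(m[, keys, drop = FALSE], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(m)), g)
  rows <- lapply(idx, function(ii) {
    base <- m[ii[1L], keys, drop = FALSE]
    base$n_samples <- length(ii)
    for (col in pct_cols) {
      v <- m[[col]][ii]
      base[[paste0("mean_", col)]] <- mean(v)
      base[[paste0("sd_", col)]] <- if (length(ii) > 1L) stats::sd(v) else NA_real_
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of isolates with no ASV hit
#'
#' Computed over isolates attempted in matching (too-short regions are
#' excluded upstream). With metadata and a grouping column, per-stratum
#' percentages are also returned.
#'
#' @param match_set A \code{\link{match_isolates}} result.
#' @param isolate_meta Optional isolate metadata (isolate_id + grouping
#'   column).
#' @param by Optional metadata column to stratify by (e.g. "layer").
#' @return List with \code{overall} (scalar percentage) and optionally
#'   \code{by_stratum} (data.frame).
#' @export
unmatched_isolate_fraction <- function(match_set, isolate_meta = NULL,
                                       by = NULL) {
  hits <- hits_per_isolate(match_set)
  res <- list(overall = 100 * mean(hits == 0))
  if (!is.null(isolate_meta) && !is.null(by)) {
    stopifnot(by %in% colnames(isolate_meta))
    grp <- isolate_meta[[by]][match(names(hits), isolate_meta$isolate_id)]
    tab <- tapply(hits == 0, grp, mean)
    res$by_stratum <- data.frame(stratum = names(tab),
                                 pct_unmatched = 100 * as.numeric(tab),
                                 stringsAsFactors = FALSE)
  }
  res
}
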
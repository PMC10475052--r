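# End-to-end orchestration: region extraction -> containment matching ->
# rarefaction -> recruitment summaries -> rank/occurrence classification.

#' Run the full recruitment analysis
#'
#' Orchestrates every stage on in-memory inputs and returns a single
#' classed result. Steps: extract the V4-V5 common region from each
#' isolate, match regions against the ASVs by exact containment, optionally
#' exclude taxa (e.g. Archaea, Cyanobacteria), rarefy the count table by
#' permutation to the lowest sampling effort, compute per-sample and
#' per-stratum recruitment percentages (copy-number corrected when a copy
#' table is supplied), rank ASVs into biosphere classes, and classify genus
#' occurrence across stations.
#'
#' @param asv_seqs Named character vector of ASV sequences.
#' @param counts Samples x ASVs integer matrix (see
#'   \code{\link{read_count_table}}).
#' @param sample_meta Sample metadata data.frame (see
#'   \code{\link{read_sample_metadata}}).
#' @param isolate_seqs Named character vector of isolate 16S sequences.
#' @param isolate_meta Optional isolate metadata (enables occurrence
#'   classification and per-stratum unmatched fractions).
#' @param taxonomy Optional named taxonomy strings (needed for
#'   \code{exclude_taxa}).
#' @param copy_numbers Optional genus copy-number data.frame; the median
#'   over the isolated genera corrects read percentages.
#' @param primers A \code{\link{primer_pair}}.
#' @param exclude_taxa Labels passed to \code{\link{filter_taxa}}.
#' @param min_region_len Minimum usable region length.
#' @param policy Matching ambiguity policy (STRICT default).
#' @param n_perm Rarefaction permutations.
#' @param rarefy Set FALSE to compute on raw counts (sensitivity mode).
#' @param seed Seed for the rarefaction permutations.
#' @return A \code{recruitment_study} object.
#' @export
recruitment_study <- function(asv_seqs, counts, sample_meta, isolate_seqs,
                              isolate_meta = NULL, taxonomy = NULL,
                              copy_numbers = NULL,
                              primers = primer_pair(),
                              exclude_taxa = character(0L),
                              min_region_len = 100L,
                              policy = "STRICT",
                              n_perm = 1000L, rarefy = TRUE, seed = 1L) {
  stopifnot(is.matrix(counts))
  validate_sample_coverage(counts, sample_meta)
  if (length(exclude_taxa) && is.null(taxonomy)) {
    stop("exclude_taxa requires taxonomy")
  }

  regions <- extract_regions(isolate_seqs, primers, min_len = min_region_len)
  index <- build_asv_index(asv_seqs)
  match_set <- match_isolates(regions, index, policy = policy)

  if (length(exclude_taxa)) {
    counts <- filter_taxa(counts, taxonomy, exclude_taxa)
  }
  used <- if (rarefy) {
    rarefy_permuted(counts, n_perm = n_perm, seed = seed)
  } else {
    counts
  }

  copy_median <- NULL
  if (!is.null(copy_numbers)) {
    genera <- if (!is.null(isolate_meta)) unique(isolate_meta$genus) else NULL
    copy_median <- copy_number_median(copy_numbers, genera)
  }

  per_sample <- recruitment_per_sample(used, match_set, copy_median)
  by_layer <- stratum_means(per_sample, sample_meta,
                            keys = c("dataset", "layer"))
  by_stratum <- if (!all(is.na(sample_meta$size_fraction))) {
    stratum_means(per_sample, sample_meta,
                  keys = c("dataset", "layer", "size_fraction"))
  } else {
    NULL
  }

  mra <- mean_relative_abundance(used)
  rank_table <- rank_abundance_table(mra, match_set)

  unmatched <- unmatched_isolate_fraction(
    match_set, isolate_meta,
    by = if (!is.null(isolate_meta)) "layer" else NULL)

  occurrence <- if (!is.null(isolate_meta) &&
                    any(!is.na(isolate_meta$genus))) {
    occurrence_classify(isolate_meta)
  } else {
    NULL
  }

  # omnibus test across layers on both percentages (when testable)
  layer_of <- sample_meta$layer[match(per_sample$sample_id,
                                      sample_meta$sample_id)]
  tests <- NULL
  if (length(unique(layer_of)) >= 2L) {
    g_reads <- split(per_sample$pct_reads, layer_of)
    g_asvs <- split(per_sample$pct_asvs, layer_of)
    tests <- list(
      pct_reads = list(omnibus = kruskal_wallis(g_reads),
                       pairwise = pairwise_wilcoxon(g_reads)),
      pct_asvs = list(omnibus = kruskal_wallis(g_asvs),
                      pairwise = pairwise_wilcoxon(g_asvs)))
  }

  structure(list(regions = regions, match = match_set,
                 rarefied = if (rarefy) used else NULL,
                 per_sample = per_sample, by_layer = by_layer,
                 by_stratum = by_stratum, rank_table = rank_table,
                 unmatched = unmatched, occurrence = occurrence,
                 copy_median = copy_median, tests = tests,
                 call = match.call()),
            class = "recruitment_study")
}

#' @export
print.recruitment_study <- function(x, ...) {
  cat("Recruitment of cultured isolates in amplicon communities\n")
  cat(sprintf("  isolates attempted: %d (%d matched, %.1f%% unmatched)\n",
              length(x$match$isolates_attempted),
              length(unique(x$match$pairs$isolate_id)),
              x$unmatched$overall))
  cat(sprintf("  ASVs matched: %d of %d\n",
              sum(x$rank_table$matched), nrow(x$rank_table)))
  if (!is.null(x$copy_median)) {
    cat(sprintf("  copy-number median divisor: %.2f\n", x$copy_median))
  }
  cat("  mean recruitment by dataset/layer:\n")
  bl <- x$by_layer
  for (i in seq_len(nrow(bl))) {
    line <- sprintf("    %-10s %-6s  %%ASVs %5s  %%reads %5s", bl$dataset[i],
                    bl$layer[i], format_percent(bl$mean_pct_asvs[i]),
                    format_percent(bl$mean_pct_reads[i]))
    if ("mean_pct_reads_corrected" %in% colnames(bl)) {
      line <- paste0(line, sprintf("  %%reads(corr) %5s",
                                   format_percent(bl$mean_pct_reads_corrected[i])))
    }
    cat(line, "\n")
  }
  if (!is.null(x$tests)) {
    cat(sprintf("  Kruskal-Wallis across layers: reads p = %.3g, ASVs p = %.3g\n",
                x$tests$pct_reads$omnibus$p_value,
                x$tests$pct_asvs$omnibus$p_value))
  }
  invisible(x)
}

#' @export
#' @method summary recruitment_study
summary.recruitment_study <- function(object, ...) {
  print(object)
  cat("\nBiosphere classes among matched ASVs:\n")
  tab <- table(object$rank_table$class, object$rank_table$matched)
  print(tab)
  if (!is.null(object$occurrence)) {
    cat("\nGenus occurrence categories:\n")
    print(table(object$occurrence$category))
  }
  invisible(object)
}

#' @export
#' @method plot recruitment_study
plot.recruitment_study <- function(x, type = c("recruitment", "rank"), ...) {
  type <- match.arg(type)
  if (type == "rank") {
    plot_rank_abundance(x$rank_table, ...)
  } else {
    bl <- x$by_layer
    graphics::barplot(rbind(bl$mean_pct_asvs, bl$mean_pct_reads),
                      beside = TRUE,
                      names.arg = paste(bl$dataset, bl$layer),
                      col = c("steelblue", "darkorange"),
                      ylab = "Mean percentage matched",
                      legend.text = c("% ASVs", "% reads"), ...)
  }
  invisible(x)
}
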
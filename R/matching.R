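# Exact-containment matching of isolate regions against ASVs.
#
# An (isolate, ASV) pair is reported iff the ASV sequence occurs as an
# exact, gap-free, contiguous substring of the isolate's extracted region.
# This encodes the 100% identity / 100% ASV coverage filter: the ASV must
# be covered over its full length, the isolate may extend beyond it. The
# k-mer seed index is only an accelerator; its semantics are defined by the
# naive substring scan.

#' Build an exact-containment index over ASV sequences
#'
#' Seeds on the leading k-mer of every ASV (k shrinks to the shortest ASV
#' if needed); every candidate hit is verified by full string comparison,
#' so results are identical to a naive scan. Duplicate ASV sequences within
#' one dataset violate ASV uniqueness and are a hard error.
#'
#' @param asv_seqs Named character vector of unambiguous ASV sequences.
#' @param k Seed length (default 31).
#' @return An \code{asv_index} object.
#' @export
build_asv_index <- function(asv_seqs, k = 31L) {
  stopifnot(!is.null(names(asv_seqs)), all(nzchar(names(asv_seqs))))
  validate_dna(asv_seqs, ambiguity = FALSE)
  if (anyDuplicated(names(asv_seqs))) {
    stop("duplicate ASV id(s): ",
         paste(unique(names(asv_seqs)[duplicated(names(asv_seqs))]), collapse = ", "))
  }
  if (anyDuplicated(asv_seqs)) {
    dup <- names(asv_seqs)[duplicated(asv_seqs) | duplicated(asv_seqs, fromLast = TRUE)]
    stop("duplicate ASV sequence(s) within the dataset (ids: ",
         paste(dup, collapse = ", "), ")")
  }
  k_eff <- as.integer(min(k, min(nchar(asv_seqs))))
  lead <- substr(asv_seqs, 1L, k_eff)
  groups <- split(seq_along(asv_seqs), lead)
  structure(list(kmers = names(groups), groups = unname(groups),
                 asv_ids = names(asv_seqs), asv_seqs = unname(asv_seqs),
                 asv_len = nchar(asv_seqs), k = k_eff),
            class = "asv_index")
}

#' @export
print.asv_index <- function(x, ...) {
  cat(sprintf("ASV containment index: %d ASVs (%d-%d nt), seed k = %d\n",
              length(x$asv_ids), min(x$asv_len), max(x$asv_len), x$k))
  invisible(x)
}

# All (asv, offset) containments of indexed ASVs in one region (STRICT).
.query_region <- function(index, region) {
  L <- nchar(region)
  k <- index$k
  if (L < k) {
    return(data.frame(asv = integer(0L), offset = integer(0L)))
  }
  starts <- seq_len(L - k + 1L)
  kmers <- substring(region, starts, starts + k - 1L)
  m <- match(kmers, index$kmers)
  hit <- which(!is.na(m))
  if (!length(hit)) {
    return(data.frame(asv = integer(0L), offset = integer(0L)))
  }
  grp <- index$groups[m[hit]]
  cand_asv <- unlist(grp, use.names = FALSE)
  cand_pos <- rep.int(starts[hit], lengths(grp))
  lens <- index$asv_len[cand_asv]
  ok <- cand_pos + lens - 1L <= L &
    substring(region, cand_pos, cand_pos + lens - 1L) == index$asv_seqs[cand_asv]
  res <- data.frame(asv = cand_asv[ok], offset = cand_pos[ok])
  # keep the leftmost offset per ASV
  res <- res[order(res$asv, res$offset), , drop = FALSE]
  res[!duplicated(res$asv), , drop = FALSE]
}

# Leftmost EXPAND-policy containment offset of one ASV in one region mask.
.expand_offset <- function(rmask, amask) {
  nw <- length(rmask) - length(amask) + 1L
  if (nw < 1L) return(NA_integer_)
  alive <- seq_len(nw)
  for (j in seq_along(amask)) {
    alive <- alive[bitwAnd(rmask[alive + j - 1L], amask[j]) == amask[j]]
    if (!length(alive)) return(NA_integer_)
  }
  alive[1L]
}

#' Match isolate regions against an ASV index
#'
#' Reports every (isolate, ASV) pair where the ASV occurs as a contiguous,
#' gap-free substring of the isolate's extracted region. All hits per
#' isolate are retained (no best-hit selection). Regions flagged
#' \code{too_short} are excluded from the attempt.
#'
#' Ambiguity policy: under \code{STRICT} (default) an ambiguity code in the
#' isolate region never matches, so matching is plain substring equality
#' and cannot create false positives. Under \code{EXPAND} an isolate
#' ambiguity code matches iff the ASV base lies in its IUPAC expansion;
#' every STRICT pair is also an EXPAND pair.
#'
#' @param regions data.frame from \code{\link{extract_regions}}, or a named
#'   character vector of region sequences.
#' @param index An \code{\link{build_asv_index}} result.
#' @param policy \code{"STRICT"} or \code{"EXPAND"}.
#' @return A \code{match_set}: list with \code{pairs} (data.frame
#'   isolate_id, asv_id, asv_length, offset), \code{isolates_attempted},
#'   \code{short_regions} (isolates whose region is shorter than every
#'   ASV, reported but never matched) and \code{policy}.
#' @export
match_isolates <- function(regions, index, policy = c("STRICT", "EXPAND")) {
  policy <- match.arg(policy)
  stopifnot(inherits(index, "asv_index"))
  if (is.data.frame(regions)) {
    keep <- !regions$too_short
    seqs <- regions$region[keep]
    names(seqs) <- regions$isolate_id[keep]
  } else {
    stopifnot(!is.null(names(regions)))
    seqs <- regions
  }
  min_asv <- min(index$asv_len)
  short <- names(seqs)[nchar(seqs) < min_asv]
  pair_list <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (policy == "STRICT") {
      res <- .query_region(index, seqs[[i]])
    } else {
      rmask <- .seq_mask(seqs[[i]])
      offs <- vapply(index$asv_seqs, function(a) {
        .expand_offset(rmask, .seq_mask(a))
      }, integer(1L), USE.NAMES = FALSE)
      res <- data.frame(asv = which(!is.na(offs)),
                        offset = offs[!is.na(offs)])
    }
    if (nrow(res)) {
      pair_list[[i]] <- data.frame(
        isolate_id = names(seqs)[i],
        asv_id = index$asv_ids[res$asv],
        asv_length = index$asv_len[res$asv],
        offset = res$offset,
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, c(pair_list[!vapply(pair_list, is.null, logical(1L))],
                            list(data.frame(isolate_id = character(0L),
                                            asv_id = character(0L),
                                            asv_length = integer(0L),
                                            offset = integer(0L)))))
  structure(list(pairs = pairs,
                 isolates_attempted = names(seqs),
                 short_regions = short,
                 policy = policy),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf(
    "match_set (%s): %d pairs; %d/%d isolates with >= 1 hit; %d distinct ASVs matched\n",
    x$policy, nrow(x$pairs),
    length(unique(x$pairs$isolate_id)), length(x$isolates_attempted),
    length(unique(x$pairs$asv_id))))
  if (length(x$short_regions)) {
    cat(sprintf("  %d region(s) shorter than every ASV (cannot match)\n",
                length(x$short_regions)))
  }
  invisible(x)
}

#' Distinct ASVs matched by at least one isolate
#'
#' @param match_set A \code{\link{match_isolates}} result.
#' @return Character vector of ASV ids (an ASV matched by several isolates
#'   appears once).
#' @export
matched_asvs <- function(match_set) {
  unique(match_set$pairs$asv_id)
}

#' Hit count per attempted isolate
#'
#' @param match_set A \code{\link{match_isolates}} result.
#' @return Named integer vector over all attempted isolates (zeros kept).
#' @export
hits_per_isolate <- function(match_set) {
  n <- table(factor(match_set$pairs$isolate_id,
                    levels = match_set$isolates_attempted))
  stats::setNames(as.integer(n), names(n))
}

#' Multi-hit report: read share attributable to non-primary hits
#'
#' Some isolates match more than one ASV. Per isolate, hits are ranked by
#' descending mean relative abundance of the matched ASV (ties broken
#' lexicographically by ASV id). The extra-hit read share is the recruited
#' read percentage counting all hits minus the percentage counting only
#' each isolate's top hit, both on union ASV sets (an ASV shared between
#' isolates is never double counted) and averaged over samples.
#'
#' @param match_set A \code{\link{match_isolates}} result.
#' @param counts Samples x ASVs matrix or \code{rarefied_table}.
#' @return List with \code{per_isolate} (data.frame isolate_id, n_hits,
#'   top_asv), \code{extra_hit_read_share} (percentage points) and the two
#'   underlying percentages.
#' @export
multi_hit_report <- function(match_set, counts) {
  mat <- .counts_of(counts)
  pairs <- match_set$pairs
  mra <- mean_relative_abundance(counts)
  pct_reads_of <- function(asvs) {
    sel <- intersect(asvs, colnames(mat))
    share <- if (length(sel)) {
      rowSums(mat[, sel, drop = FALSE]) / rowSums(mat)
    } else {
      rep(0, nrow(mat))
    }
    100 * mean(share)
  }
  if (nrow(pairs)) {
    ord <- order(pairs$isolate_id,
                 -mra[match(pairs$asv_id, names(mra))],
                 pairs$asv_id)
    pairs <- pairs[ord, , drop = FALSE]
    top <- pairs[!duplicated(pairs$isolate_id), c("isolate_id", "asv_id")]
  } else {
    top <- data.frame(isolate_id = character(0L), asv_id = character(0L))
  }
  n_hits <- hits_per_isolate(match_set)
  per_isolate <- data.frame(
    isolate_id = names(n_hits),
    n_hits = as.integer(n_hits),
    top_asv = top$asv_id[match(names(n_hits), top$isolate_id)],
    stringsAsFactors = FALSE
  )
  pct_all <- pct_reads_of(unique(pairs$asv_id))
  pct_top <- pct_reads_of(unique(top$asv_id))
  list(per_isolate = per_isolate,
       pct_reads_all_hits = pct_all,
       pct_reads_top_hits = pct_top,
       extra_hit_read_share = pct_all - pct_top)
}
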
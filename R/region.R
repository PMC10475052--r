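# Degenerate primer location and extraction of the V4-V5 common region.
#
# Isolates were Sanger-sequenced with primers different from the amplicon
# primer pair, so isolate and amplicon sequences are only comparable over
# the span both amplify. We locate the amplicon primers (515F-Y / 926R) in
# each isolate sequence by Hamming-window search under IUPAC semantics and
# cut out the region strictly between them.

# 4-bit encoding of IUPAC nucleotide codes (A=1, C=2, G=4, T=8).
.IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

.seq_mask <- function(s) {
  v <- .IUPAC_MASK[strsplit(s, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop("sequence contains non-IUPAC characters: ", s, call. = FALSE)
  unname(v)
}

#' Amplicon primer sequences (V4-V5, 16S rRNA)
#'
#' The 515F-Y forward and 926R reverse primers used for the amplicon
#' datasets, written 5'-3' in IUPAC code.
#'
#' @format Character scalars.
#' @name primers
NULL

#' @rdname primers
#' @export
PRIMER_515FY <- "GTGYCAGCMGCCGCGGTAA"

#' @rdname primers
#' @export
PRIMER_926R <- "CCGYCAATTYMTTTRAGTTT"

#' Define a primer pair
#'
#' @param forward,reverse IUPAC primer sequences, 5'-3'.
#' @param max_mismatches Mismatches tolerated when locating a primer site
#'   (default 0: extraction is conservative).
#' @return A \code{primer_pair} object.
#' @export
primer_pair <- function(forward = PRIMER_515FY, reverse = PRIMER_926R,
                        max_mismatches = 0L) {
  stopifnot(nzchar(forward), nzchar(reverse), max_mismatches >= 0)
  .seq_mask(forward); .seq_mask(reverse)   # validate alphabet
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_pair")
}

#' Reverse-complement DNA, IUPAC-aware
#'
#' @param seqs Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seqs) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seqs))
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Count mismatches between a window and a degenerate primer
#'
#' Position i matches iff the window base's IUPAC expansion is a subset of
#' the primer code's expansion; N in the window matches everything. Window
#' and primer must be the same length.
#'
#' @param window DNA string (may contain ambiguity codes).
#' @param primer IUPAC primer string of equal length.
#' @return Integer mismatch count.
#' @export
iupac_mismatch_count <- function(window, primer) {
  w <- .seq_mask(window)
  p <- .seq_mask(primer)
  if (length(w) != length(p)) {
    stop(sprintf("window length %d != primer length %d", length(w), length(p)))
  }
  sum(!(w == 15L | bitwAnd(w, p) == w))
}

#' Find the leftmost primer site in a sequence
#'
#' Scans the plus strand with a Hamming window under the IUPAC matching
#' rule of \code{\link{iupac_mismatch_count}}. Absence is a value, not an
#' error.
#'
#' @param seq DNA string.
#' @param primer IUPAC primer string.
#' @param max_mismatches Mismatch tolerance.
#' @return 1-based start position of the leftmost hit, or \code{NA_integer_}.
#' @export
find_primer <- function(seq, primer, max_mismatches = 0L) {
  s <- .seq_mask(seq)
  p <- .seq_mask(primer)
  lp <- length(p)
  nw <- length(s) - lp + 1L
  if (nw < 1L) return(NA_integer_)
  mm <- integer(nw)
  for (j in seq_len(lp)) {
    wj <- s[j:(j + nw - 1L)]
    mm <- mm + !(wj == 15L | bitwAnd(wj, p[j]) == wj)
  }
  hit <- which(mm <= max_mismatches)
  if (length(hit)) hit[1L] else NA_integer_
}

# Extract the common region from one oriented isolate sequence.
.extract_one <- function(seq, primers) {
  fwd <- find_primer(seq, primers$forward, primers$max_mismatches)
  orientation <- "PLUS"
  if (is.na(fwd)) {
    rc <- reverse_complement(seq)
    fwd_rc <- find_primer(rc, primers$forward, primers$max_mismatches)
    if (!is.na(fwd_rc)) {
      seq <- rc
      fwd <- fwd_rc
      orientation <- "MINUS"
    }
  }
  if (is.na(fwd)) {
    return(list(region = seq, fwd_found = FALSE, rev_found = FALSE,
                orientation = orientation))
  }
  after_fwd <- fwd + nchar(primers$forward)
  rev_site <- reverse_complement(primers$reverse)
  tail_seq <- substr(seq, after_fwd, nchar(seq))
  rev_hit <- find_primer(tail_seq, rev_site, primers$max_mismatches)
  if (is.na(rev_hit)) {
    region <- tail_seq
    rev_found <- FALSE
  } else {
    region <- substr(tail_seq, 1L, rev_hit - 1L)
    rev_found <- TRUE
  }
  list(region = region, fwd_found = TRUE, rev_found = rev_found,
       orientation = orientation)
}

#' Extract the V4-V5 common region from isolate sequences
#'
#' For each sequence: (1) search the forward primer on the plus strand; if
#' absent, reverse-complement and retry (orientation MINUS). (2) Search the
#' reverse-complemented reverse primer downstream of the forward site.
#' (3) The region is the span strictly between the primer sites (primer
#' spans excluded). If only the forward primer is found the region runs to
#' the sequence end; if neither is found the whole (oriented) sequence is
#' returned with both flags FALSE — partial Sanger reads often start inside
#' the amplified region, and the downstream containment matcher still
#' enforces full ASV coverage.
#'
#' Regions shorter than \code{min_len} are flagged \code{too_short} and
#' should be excluded from matching.
#'
#' @param seqs Named character vector of isolate sequences.
#' @param primers A \code{\link{primer_pair}}.
#' @param min_len Minimum usable region length in nt.
#' @return data.frame with columns isolate_id, region, fwd_found,
#'   rev_found, orientation, region_length, too_short.
#' @export
extract_regions <- function(seqs, primers = primer_pair(), min_len = 100L) {
  stopifnot(inherits(primers, "primer_pair"), !is.null(names(seqs)))
  validate_dna(seqs, ambiguity = TRUE)
  res <- lapply(unname(seqs), .extract_one, primers = primers)
  out <- data.frame(
    isolate_id = names(seqs),
    region = vapply(res, `[[`, character(1L), "region"),
    fwd_found = vapply(res, `[[`, logical(1L), "fwd_found"),
    rev_found = vapply(res, `[[`, logical(1L), "rev_found"),
    orientation = vapply(res, `[[`, character(1L), "orientation"),
    stringsAsFactors = FALSE
  )
  out$region_length <- nchar(out$region)
  out$too_short <- out$region_length < min_len
  if (any(out$too_short)) {
    message(sum(out$too_short), " isolate(s) with region < ", min_len,
            " nt flagged too_short: ",
            paste(out$isolate_id[out$too_short], collapse = ", "))
  }
  out
}

#' Minimum achievable primer mismatch per isolate (diagnostic)
#'
#' Reports, per sequence and primer, the smallest Hamming mismatch count
#' over all windows on both strands. This answers whether the amplicon
#' primers could in principle capture an organism whose isolate sequence
#' never matched any ASV.
#'
#' @param seqs Named character vector of isolate sequences.
#' @param primers A \code{\link{primer_pair}}.
#' @return data.frame with columns isolate_id, fwd_min_mismatch,
#'   rev_min_mismatch (NA when the sequence is shorter than the primer).
#' @export
primer_mismatch_profile <- function(seqs, primers = primer_pair()) {
  min_mm <- function(seq, primer) {
    best <- integer(0L)
    for (s in c(seq, reverse_complement(seq))) {
      sm <- .seq_mask(s); p <- .seq_mask(primer)
      nw <- length(sm) - length(p) + 1L
      if (nw < 1L) next
      mm <- integer(nw)
      for (j in seq_along(p)) {
        wj <- sm[j:(j + nw - 1L)]
        mm <- mm + !(wj == 15L | bitwAnd(wj, p[j]) == wj)
      }
      best <- c(best, min(mm))
    }
    if (length(best)) min(best) else NA_integer_
  }
  data.frame(
    isolate_id = names(seqs),
    fwd_min_mismatch = vapply(seqs, min_mm, integer(1L), primers$forward,
                              USE.NAMES = FALSE),
    rev_min_mismatch = vapply(seqs, min_mm, integer(1L), primers$reverse,
                              USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
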
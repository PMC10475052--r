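# Readers and writers for the external formats plus the shared vocabularies.
# All readers reject malformed input rather than repairing it, and every
# error names the offending record.

#' Controlled vocabularies for sample and isolate metadata
#'
#' Amplicon samples are labelled with one of four depth layers (SRF surface,
#' DCM deep chlorophyll maximum, MESO mesopelagic, BATHY bathypelagic) and
#' optionally a plankton size fraction in micrometres. Isolates use a
#' three-level layer vocabulary (PHOTIC collapses SRF and DCM).
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
SAMPLE_LAYERS <- c("SRF", "DCM", "MESO", "BATHY")

#' @rdname vocabularies
#' @export
ISOLATE_LAYERS <- c("PHOTIC", "MESO", "BATHY")

#' @rdname vocabularies
#' @export
SIZE_FRACTIONS <- c("0.2-0.8", "0.8-3", "3-5", "5-20", "20-200", "0.8-20")

.check_vocab <- function(x, allowed, what, allow_na = FALSE) {
  bad <- !(x %in% allowed)
  if (allow_na) bad <- bad & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop(sprintf("unknown %s label(s): %s (allowed: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' The id of each record is the header token before the first whitespace;
#' sequences are uppercased and U is normalized to T. Duplicate ids and
#' empty sequences are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids),
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(empty <- !nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[empty], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate a DNA alphabet
#'
#' @param seqs Named character vector.
#' @param ambiguity Allow IUPAC ambiguity codes (TRUE for isolates, FALSE
#'   for ASVs, which must be unambiguous).
#' @return Invisibly, \code{seqs}.
#' @export
validate_dna <- function(seqs, ambiguity = TRUE) {
  pat <- if (ambiguity) "^[ACGTRYSWKMBDHVN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop(sprintf("invalid %s sequence for id(s): %s",
                 if (ambiguity) "IUPAC DNA" else "unambiguous DNA",
                 paste(names(seqs)[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(seqs)
}

#' Read an ASV-by-sample count table
#'
#' Tab-delimited with a header; the first column holds row ids. The
#' orientation is declared, never guessed: with \code{asv_rows = TRUE}
#' (default) rows are ASVs and columns samples. Returned matrix is always
#' samples x ASVs. Non-integer, missing or negative cells and duplicated
#' ids are hard errors.
#'
#' @param path Path to a tab-delimited file.
#' @param asv_rows Declared orientation of the file.
#' @return Integer matrix, samples in rows, ASVs in columns.
#' @export
read_count_table <- function(path, asv_rows = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("count table needs an id column plus data columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated row id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(df)[-1L])) {
    stop("duplicated column id(s): ",
         paste(unique(colnames(df)[-1L][duplicated(colnames(df)[-1L])]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim(raw), dimnames(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric count at row '%s', column '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]))
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]))
  }
  mat <- round(num)
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  if (asv_rows) mat <- t(mat)
  mat
}

#' Write a count table
#'
#' @param counts Samples x ASVs integer matrix.
#' @param path Output path.
#' @param asv_rows Write ASVs as rows (default, mirroring
#'   \code{\link{read_count_table}}).
#' @return Invisibly, \code{path}.
#' @export
write_count_table <- function(counts, path, asv_rows = TRUE) {
  m <- if (asv_rows) t(counts) else counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- if (asv_rows) "asv_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_table_with <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read per-sample metadata
#'
#' Requires columns \code{sample_id, dataset, layer, size_fraction,
#' station_id}. \code{layer} must come from \code{\link{SAMPLE_LAYERS}} and
#' \code{size_fraction} from \code{\link{SIZE_FRACTIONS}} (or be empty).
#'
#' @param path Path to a tab-delimited file.
#' @param counts Optional count matrix; if given, every sample in it must
#'   have exactly one metadata row.
#' @return data.frame of validated sample metadata.
#' @export
read_sample_metadata <- function(path, counts = NULL) {
  df <- .read_table_with(path, c("sample_id", "dataset", "layer",
                                 "size_fraction", "station_id"))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  .check_vocab(df$layer, SAMPLE_LAYERS, "layer")
  .check_vocab(df$size_fraction, SIZE_FRACTIONS, "size_fraction", allow_na = TRUE)
  df$size_fraction[!nzchar(df$size_fraction)] <- NA_character_
  if (!is.null(counts)) validate_sample_coverage(counts, df)
  df
}

#' Check that every sample in a count table has metadata
#'
#' @param counts Samples x ASVs matrix.
#' @param meta Sample metadata data.frame.
#' @return Invisibly TRUE.
#' @export
validate_sample_coverage <- function(counts, meta) {
  absent <- setdiff(rownames(counts), meta$sample_id)
  if (length(absent)) {
    stop("sample(s) present in counts but absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read per-isolate metadata
#'
#' Requires columns \code{isolate_id, station_id, layer}; \code{genus} and
#' \code{medium} are optional (empty fields become NA). \code{layer} uses
#' \code{\link{ISOLATE_LAYERS}}.
#'
#' @param path Path to a tab-delimited file.
#' @return data.frame of isolate metadata.
#' @export
read_isolate_metadata <- function(path) {
  df <- .read_table_with(path, c("isolate_id", "station_id", "layer"))
  if (anyDuplicated(df$isolate_id)) {
    stop("duplicated isolate_id(s): ",
         paste(unique(df$isolate_id[duplicated(df$isolate_id)]), collapse = ", "))
  }
  .check_vocab(df$layer, ISOLATE_LAYERS, "layer")
  for (col in c("genus", "medium")) {
    if (!col %in% colnames(df)) df[[col]] <- NA_character_
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  df
}

#' Read per-station colony and cell counts
#'
#' Requires columns \code{station_id, layer, cfu_per_ml, cells_per_ml}:
#' colony-forming units per ml from plating and total heterotrophic
#' prokaryote cells per ml from flow cytometry.
#'
#' @param path Path to a tab-delimited file.
#' @return data.frame with numeric count columns.
#' @export
read_station_counts <- function(path) {
  df <- .read_table_with(path, c("station_id", "layer", "cfu_per_ml",
                                 "cells_per_ml"))
  .check_vocab(df$layer, ISOLATE_LAYERS, "layer")
  df$cfu_per_ml <- as.numeric(df$cfu_per_ml)
  df$cells_per_ml <- as.numeric(df$cells_per_ml)
  if (anyNA(df$cfu_per_ml) || anyNA(df$cells_per_ml)) {
    bad <- df$station_id[is.na(df$cfu_per_ml) | is.na(df$cells_per_ml)]
    stop("non-numeric cfu/cells for station(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$cfu_per_ml < 0)) {
    stop("negative cfu_per_ml for station(s): ",
         paste(df$station_id[df$cfu_per_ml < 0], collapse = ", "))
  }
  if (any(df$cells_per_ml <= 0)) {
    stop("cells_per_ml must be positive; offending station(s): ",
         paste(df$station_id[df$cells_per_ml <= 0], collapse = ", "))
  }
  df
}

#' Read a genus-to-copy-number table
#'
#' Requires columns \code{genus, copy_number} (rRNA operon copies per
#' genome, >= 1).
#'
#' @param path Path to a tab-delimited file.
#' @return data.frame with columns genus and copy_number.
#' @export
read_copy_number_table <- function(path) {
  df <- .read_table_with(path, c("genus", "copy_number"))
  if (anyDuplicated(df$genus)) {
    stop("duplicated genus entries: ",
         paste(unique(df$genus[duplicated(df$genus)]), collapse = ", "))
  }
  df$copy_number <- as.numeric(df$copy_number)
  if (anyNA(df$copy_number) || any(df$copy_number < 1)) {
    stop("copy_number must be numeric and >= 1; offending genus: ",
         paste(df$genus[is.na(df$copy_number) | df$copy_number < 1],
               collapse = ", "))
  }
  df
}

#' Median rRNA operon copy number over a set of genera
#'
#' Uses the standard midpoint rule for even counts. Genera absent from the
#' table are ignored with a warning.
#'
#' @param copy_table data.frame from \code{\link{read_copy_number_table}}
#'   (or with the same columns).
#' @param genera Optional character vector restricting the median to these
#'   genera (e.g. the genera represented among isolates). Default: all.
#' @return Scalar median copy number.
#' @export
copy_number_median <- function(copy_table, genera = NULL) {
  stopifnot(all(c("genus", "copy_number") %in% colnames(copy_table)))
  if (!is.null(genera)) {
    genera <- unique(genera[!is.na(genera)])
    absent <- setdiff(genera, copy_table$genus)
    if (length(absent)) {
      warning("no copy number recorded for genus: ",
              paste(absent, collapse = ", "))
    }
    copy_table <- copy_table[copy_table$genus %in% genera, , drop = FALSE]
  }
  if (!nrow(copy_table)) stop("no genera left to take a median over")
  stats::median(copy_table$copy_number)
}

#' Write a generic tab-delimited table
#'
#' @param df data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
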
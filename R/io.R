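ta_locations <- function() {
  c("PO", "MITO", "ER", "PO_MITO", "PO_MITO_ER", "MITO_ER")
}

#' Read protein records from a FASTA file
#'
#' Wrapped sequence lines are concatenated and record order is preserved.
#' Sequences are upper-case folded and validated against the 20-letter
#' alphabet; an empty sequence or an ambiguity code is an error naming the
#' offending record.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` (first word of the header),
#'   `description` (remainder of the header, possibly `""`) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) abort(paste0("no records in FASTA file: ", path))
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq <- as.character(aa)
  seq <- validate_seq(seq, id = id)
  tibble(id = id, description = description, seq = unname(seq))
}

#' Write protein records to a FASTA file
#'
#' @param data Data frame with `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60) {
  if (nrow(data) == 0) abort("no records to write")
  desc <- if ("description" %in% names(data)) data$description else ""
  header <- ifelse(nzchar(desc), paste(data$id, desc), data$id)
  lines <- unlist(purrr::map2(header, data$seq, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled TA-protein dataset table
#'
#' Tab-delimited with a header row and `#` comment lines. Required
#' columns: `id`, `name`, `location`, `cterm_seq`; optional columns:
#' `organism`, `tmd_start`, `tmd_end`, `source` (any further columns are
#' kept). Location labels must come from the closed vocabulary `PO`,
#' `MITO`, `ER`, `PO_MITO`, `PO_MITO_ER`, `MITO_ER`; TMD coordinates, when
#' present, are validated as 1-based inclusive spans within `cterm_seq`.
#' This reader accepts a user-supplied copy of the original curated
#' training table in the same schema.
#'
#' @param path TSV file path.
#' @return Tibble of validated entries.
#' @export
read_ta_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("dataset file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("id", "name", "location", "cterm_seq")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(df$location), ta_locations())
  if (length(bad) > 0) {
    abort(paste0("unknown location label(s): ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(ta_locations(), collapse = ", "), ")"))
  }
  df$cterm_seq <- validate_seq(df$cterm_seq, id = df$id)
  if (!"tmd_start" %in% names(df)) df$tmd_start <- NA_integer_
  if (!"tmd_end" %in% names(df)) df$tmd_end <- NA_integer_
  df$tmd_start <- as.integer(df$tmd_start)
  df$tmd_end <- as.integer(df$tmd_end)
  for (k in seq_len(nrow(df))) {
    s <- df$tmd_start[[k]]; e <- df$tmd_end[[k]]
    if (is.na(s) != is.na(e)) {
      abort(paste0("entry '", df$id[[k]], "': tmd_start and tmd_end must be ",
                   "given together"))
    }
    if (!is.na(s) && (s < 1 || s >= e || e > nchar(df$cterm_seq[[k]]))) {
      abort(paste0("entry '", df$id[[k]], "': TMD coordinates [", s, ", ", e,
                   "] invalid for a C-terminal sequence of length ",
                   nchar(df$cterm_seq[[k]])))
    }
  }
  as_tibble(df)
}

ta_feature_cols <- function() {
  c("id", "tmd_start", "tmd_end", "tmd_gravy", "tail_charge", "tail_length",
    "upstream_charge", "upstream_gravy", "label")
}

#' Write a feature table to TSV
#'
#' Fixed column order (`id`, `tmd_start`, `tmd_end`, `tmd_gravy`,
#' `tail_charge`, `tail_length`, `upstream_charge`, `upstream_gravy`,
#' `label`), floating-point values formatted with 3 decimals. A missing
#' `label` column is written as `NA`. Round-trips through
#' [read_ta_features()] to 3 decimals.
#'
#' @param data Feature table (e.g. from [compute_ta_features()]); must be
#'   non-empty and contain `id` plus the feature columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ta_features <- function(data, path) {
  if (nrow(data) == 0) abort("no feature rows to write")
  if (!"label" %in% names(data)) {
    data$label <- if ("location" %in% names(data)) data$location else NA_character_
  }
  missing <- setdiff(setdiff(ta_feature_cols(), "label"), names(data))
  if (length(missing) > 0) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- data[, ta_feature_cols()]
  num <- c("tmd_gravy", "tail_charge", "upstream_charge", "upstream_gravy")
  for (col in num) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.3f", out[[col]]))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_ta_features()]
#'
#' @param path TSV file path.
#' @return Tibble with the fixed feature columns; numeric columns parsed
#'   back to numbers.
#' @export
read_ta_features <- function(path) {
  if (!file.exists(path)) abort(paste0("feature file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          id = readr::col_character(),
                          tmd_start = readr::col_integer(),
                          tmd_end = readr::col_integer(),
                          tmd_gravy = readr::col_double(),
                          tail_charge = readr::col_double(),
                          tail_length = readr::col_integer(),
                          upstream_charge = readr::col_double(),
                          upstream_gravy = readr::col_double(),
                          label = readr::col_character()
                        ))
  as_tibble(df)
}
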
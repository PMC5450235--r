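#' Locate a candidate transmembrane domain near the C-terminus
#'
#' Sliding-window surrogate for a transmembrane-helix predictor: among all
#' windows of length `min_len`..`max_len` whose last residue lies within
#' `max_tail_len` residues of the C-terminus, the window maximising mean
#' Kyte-Doolittle hydropathy is returned, provided that maximum reaches
#' `min_score`. Exact score ties (within 1e-9) are broken in favour of the
#' longer window, then the more C-terminal start, so results are
#' reproducible across platforms.
#'
#' @param seq Single amino-acid sequence, length at least `min_len`.
#' @param min_len,max_len Window length bounds (residues). The defaults
#'   17-25 cover the span of a single membrane-crossing helix.
#' @param max_tail_len Maximum number of residues allowed after the window
#'   (the "close to the C-terminus" constraint defining a TA protein).
#' @param min_score Minimum mean hydropathy for a window to qualify.
#' @param scale Hydropathy scale, default [kyte_doolittle()].
#' @return Tibble with columns `tmd_start`, `tmd_end`, `tmd_score`
#'   (1-based inclusive coordinates); zero rows when no window qualifies.
#' @examples
#' find_cterm_tmd(paste0(strrep("S", 30), strrep("L", 21), "QRRRRKLN"))
#' @export
find_cterm_tmd <- function(seq, min_len = 17, max_len = 25,
                           max_tail_len = 30, min_score = 1.6,
                           scale = kyte_doolittle()) {
  if (length(seq) != 1) abort("find_cterm_tmd() takes a single sequence")
  seq <- validate_seq(seq)
  n <- nchar(seq)
  if (n < min_len) {
    abort(paste0("sequence shorter than the minimum window length (",
                 n, " < ", min_len, ")"))
  }
  vals <- unname(scale[strsplit(seq, "", fixed = TRUE)[[1]]])
  cs <- c(0, cumsum(vals))
  tol <- 1e-9
  best <- NULL
  for (len in seq(min_len, min(max_len, n))) {
    e_min <- max(len, n - max_tail_len)
    if (e_min > n) next
    for (e in seq(e_min, n)) {
      s <- e - len + 1
      sc <- (cs[e + 1] - cs[s]) / len
      if (is.null(best) ||
          sc > best$score + tol ||
          (abs(sc - best$score) <= tol &&
           (len > best$len || (len == best$len && s > best$start)))) {
        best <- list(start = s, end = e, len = len, score = sc)
      }
    }
  }
  if (is.null(best) || best$score < min_score) {
    return(tibble(tmd_start = integer(), tmd_end = integer(),
                  tmd_score = numeric()))
  }
  tibble(tmd_start = as.integer(best$start), tmd_end = as.integer(best$end),
         tmd_score = best$score)
}

#' Split a sequence into upstream / TMD / tail regions
#'
#' @param seq Single amino-acid sequence.
#' @param tmd_start,tmd_end 1-based inclusive TMD coordinates within `seq`.
#' @param upstream_len Number of residues immediately N-terminal of the
#'   TMD to report as the upstream region (truncated at the start of the
#'   sequence).
#' @return One-row tibble with columns `context_seq` (everything before
#'   the upstream region), `upstream_seq`, `tmd_seq` and `tail_seq`
#'   (everything after the TMD; possibly empty). Concatenating the four
#'   columns reconstructs `seq`.
#' @examples
#' segment_regions("SSSSLLLLLLLLLLLLLLLLLQRR", 5, 21)
#' @export
segment_regions <- function(seq, tmd_start, tmd_end, upstream_len = 10) {
  if (length(seq) != 1) abort("segment_regions() takes a single sequence")
  seq <- validate_seq(seq)
  n <- nchar(seq)
  if (is.na(tmd_start) || is.na(tmd_end) ||
      tmd_start < 1 || tmd_end < tmd_start || tmd_end > n) {
    abort(paste0("TMD span [", tmd_start, ", ", tmd_end,
                 "] out of bounds for a sequence of length ", n))
  }
  up_start <- max(1, tmd_start - upstream_len)
  tibble(
    context_seq = substr(seq, 1, up_start - 1),
    upstream_seq = substr(seq, up_start, tmd_start - 1),
    tmd_seq = substr(seq, tmd_start, tmd_end),
    tail_seq = if (tmd_end < n) substr(seq, tmd_end + 1, n) else ""
  )
}

#' Locate TMDs for a table of sequences
#'
#' Data-frame verb over [find_cterm_tmd()]. Rows that already carry
#' non-missing `tmd_start`/`tmd_end` values (e.g. curated coordinates from
#' a dataset table, or a command-line override) are passed through
#' untouched with `status = "supplied"`; coordinates always take
#' precedence over detection. Other rows get detected coordinates
#' (`status = "detected"`) or `NA` (`status = "no_tmd"`).
#'
#' @param data Data frame with a sequence column named `seq` or
#'   `cterm_seq` (override with `seq_col`).
#' @param seq_col Name of the sequence column; guessed when `NULL`.
#' @inheritParams find_cterm_tmd
#' @return Tibble: `data` plus `tmd_start`, `tmd_end`, `tmd_score` and
#'   `status` columns.
#' @export
locate_tmd <- function(data, seq_col = NULL, min_len = 17, max_len = 25,
                       max_tail_len = 30, min_score = 1.6,
                       scale = kyte_doolittle()) {
  data <- as_tibble(data)
  seq_col <- seq_col %||%
    intersect(c("seq", "cterm_seq"), names(data))[1]
  if (is.na(seq_col) || is.null(seq_col) || !seq_col %in% names(data)) {
    abort("no sequence column found (expected 'seq' or 'cterm_seq')")
  }
  has_coords <- all(c("tmd_start", "tmd_end") %in% names(data))
  n <- nrow(data)
  start <- end <- rep(NA_integer_, n)
  score <- rep(NA_real_, n)
  status <- rep("no_tmd", n)
  for (k in seq_len(n)) {
    if (has_coords && !is.na(data$tmd_start[[k]]) && !is.na(data$tmd_end[[k]])) {
      s <- as.integer(data$tmd_start[[k]])
      e <- as.integer(data$tmd_end[[k]])
      L <- nchar(data[[seq_col]][[k]])
      if (s < 1 || e <= s || e > L) {
        abort(paste0("row ", k, ": supplied TMD span [", s, ", ", e,
                     "] invalid for sequence of length ", L))
      }
      start[[k]] <- s
      end[[k]] <- e
      score[[k]] <- gravy(substr(data[[seq_col]][[k]], s, e), scale = scale)
      status[[k]] <- "supplied"
    } else {
      hit <- find_cterm_tmd(data[[seq_col]][[k]], min_len = min_len,
                            max_len = max_len, max_tail_len = max_tail_len,
                            min_score = min_score, scale = scale)
      if (nrow(hit) == 1) {
        start[[k]] <- hit$tmd_start
        end[[k]] <- hit$tmd_end
        score[[k]] <- hit$tmd_score
        status[[k]] <- "detected"
      }
    }
  }
  out <- data
  out$tmd_start <- start
  out$tmd_end <- end
  out$tmd_score <- score
  out$status <- status
  attr(out, "ta_seq_col") <- seq_col
  out
}
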
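#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over a sequence. TA-protein TMDs
#' typically score well above 1; fully polar stretches score below 0.
#'
#' @param seq Character vector of amino-acid sequences (upper or lower
#'   case; the 20 standard letters only).
#' @param scale Named hydropathy scale, default [kyte_doolittle()].
#' @return Numeric vector of mean hydropathies.
#' @examples
#' gravy("LLLLL") # 3.8
#' @export
gravy <- function(seq, scale = kyte_doolittle()) {
  seq <- validate_seq(seq)
  vapply(seq, function(s) {
    mean(scale[strsplit(s, "", fixed = TRUE)[[1]]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the ionisable groups of the sequence:
#' each basic group (R, K, H side chains; free N-terminus) contributes
#' `+1 / (1 + 10^(pH - pKa))` and each acidic group (D, E, C, Y side
#' chains; free C-terminus) contributes `-1 / (1 + 10^(pKa - pH))`.
#' Tail fragments of TA proteins are treated as free peptides, i.e. both
#' termini ionisable, which is the convention needed to reproduce reported
#' tail charges; turn the termini off for internal fragments.
#'
#' @param seq Character vector of sequences.
#' @param pH pH at which to evaluate the charge (default 7.0).
#' @param free_nterm,free_cterm Include the free terminal groups?
#' @param pka pKa table as returned by [ta_pka_table()].
#' @return Numeric vector of net charges in elementary charge units (full
#'   precision; round to 1 decimal for presentation).
#' @examples
#' round(net_charge("QRRRRKLN"), 1) # +4.9
#' @export
net_charge <- function(seq, pH = 7.0, free_nterm = TRUE, free_cterm = TRUE,
                       pka = ta_pka_table()) {
  if (!is.numeric(pH) || length(pH) != 1 || is.na(pH) || pH <= 0 || pH >= 14) {
    abort("pH must be a single number in (0, 14)")
  }
  seq <- validate_seq(seq)
  basic_contrib <- function(pKa) 1 / (1 + 10^(pH - pKa))
  acid_contrib <- function(pKa) -1 / (1 + 10^(pKa - pH))
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    q <- 0
    for (res in c("R", "K", "H")) {
      q <- q + sum(ch == res) * basic_contrib(pka$basic[[res]])
    }
    for (res in c("D", "E", "C", "Y")) {
      q <- q + sum(ch == res) * acid_contrib(pka$acidic[[res]])
    }
    if (free_nterm) q <- q + basic_contrib(pka$basic[["Nterm"]])
    if (free_cterm) q <- q + acid_contrib(pka$acidic[["Cterm"]])
    q
  }, numeric(1), USE.NAMES = FALSE)
}

#' Feature vector for one segmented C-terminus
#'
#' Computes the physicochemical features consumed by the group statistics
#' and the classifier: TMD GRAVY, net tail charge, tail length, and the
#' charge/GRAVY of the region immediately upstream of the TMD. Empty tail
#' or upstream regions contribute a charge of 0 and an `NA` GRAVY.
#'
#' @param tmd_seq TMD sequence (non-empty).
#' @param tail_seq Residues C-terminal of the TMD (may be `""`).
#' @param upstream_seq Residues immediately N-terminal of the TMD (may be
#'   `""`).
#' @param pH pH for the charge calculations.
#' @param pka pKa table, see [ta_pka_table()].
#' @return One-row tibble with columns `tmd_gravy`, `tail_charge`,
#'   `tail_length`, `upstream_charge`, `upstream_gravy`.
#' @examples
#' compute_features(strrep("L", 21), "QRRRRKLN")
#' @export
compute_features <- function(tmd_seq, tail_seq = "", upstream_seq = "",
                             pH = 7.0, pka = ta_pka_table()) {
  if (is.na(tmd_seq) || nchar(tmd_seq) == 0) abort("TMD sequence is empty")
  tail_seq <- tail_seq %||% ""
  upstream_seq <- upstream_seq %||% ""
  tibble(
    tmd_gravy = gravy(tmd_seq),
    tail_charge = if (nchar(tail_seq) > 0) {
      net_charge(tail_seq, pH = pH, pka = pka)
    } else 0.0,
    tail_length = nchar(tail_seq),
    upstream_charge = if (nchar(upstream_seq) > 0) {
      net_charge(upstream_seq, pH = pH, pka = pka)
    } else 0.0,
    upstream_gravy = if (nchar(upstream_seq) > 0) {
      gravy(upstream_seq)
    } else NA_real_
  )
}

#' Compute TA-targeting features for a table of sequences
#'
#' Data-frame-first pipeline wrapper: locates the C-terminal TMD of each
#' record (unless coordinates are already present, see [locate_tmd()]),
#' splits the sequence into upstream / TMD / tail regions and computes the
#' feature vector for every record with a TMD. Records without a
#' detectable TMD are kept with `status = "no_tmd"` and `NA` features.
#'
#' @param data Data frame with an `id` column and a sequence column
#'   (`seq` or `cterm_seq`); optional `tmd_start`/`tmd_end` columns are
#'   used as supplied coordinates.
#' @param pH pH for charge calculations.
#' @param upstream_len Length of the upstream region (residues before the
#'   TMD) used for the upstream features.
#' @param pka pKa table.
#' @param ... Detector parameters passed on to [locate_tmd()].
#' @return Tibble: input columns plus `tmd_start`, `tmd_end`, `tmd_score`,
#'   `status`, and the feature columns of [compute_features()].
#' @examples
#' tibble::tibble(id = "x", seq = paste0(strrep("S", 30), strrep("L", 21),
#'   "QRRRRKLN")) |> compute_ta_features()
#' @export
compute_ta_features <- function(data, pH = 7.0, upstream_len = 10,
                                pka = ta_pka_table(), ...) {
  located <- locate_tmd(data, ...)
  seq_col <- attr(located, "ta_seq_col")
  feats <- purrr::pmap(
    list(located[[seq_col]], located$tmd_start, located$tmd_end),
    function(s, a, b) {
      if (is.na(a)) {
        return(tibble(tmd_gravy = NA_real_, tail_charge = NA_real_,
                      tail_length = NA_integer_, upstream_charge = NA_real_,
                      upstream_gravy = NA_real_))
      }
      seg <- segment_regions(s, a, b, upstream_len = upstream_len)
      compute_features(seg$tmd_seq, seg$tail_seq, seg$upstream_seq,
                       pH = pH, pka = pka)
    }
  )
  out <- dplyr::bind_cols(located, dplyr::bind_rows(feats))
  out$tail_length <- as.integer(out$tail_length)
  attr(out, "ta_seq_col") <- NULL
  as_tibble(out)
}
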
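#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes accepted throughout the package. Ambiguity codes
#' (B, Z, X) and the rare residues U/O are rejected rather than guessed,
#' because neither hydropathy nor ionisation is defined for them.
#'
#' @return Character vector of 20 single letters.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used for GRAVY (grand average of
#' hydropathicity) and for the sliding-window TMD scan. Positive values are
#' hydrophobic.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @examples
#' kyte_doolittle()[["I"]] # 4.5
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Default pKa table for peptide net charge
#'
#' Sillero-type pKa values for the ionisable groups of a free peptide:
#' side chains of D, E, C, Y (acidic) and H, K, R (basic) plus the free
#' alpha-amino and alpha-carboxy termini. With this table a free-peptide
#' Henderson-Hasselbalch sum reproduces the tail-charge convention of common
#' online protein calculators at pH 7 (e.g. an Arg contributes almost
#' exactly +1, the free N-terminus about +0.91 and the free C-terminus
#' about -1.0).
#'
#' @return List with numeric vectors `acidic` (names `Cterm`, `D`, `E`,
#'   `C`, `Y`) and `basic` (names `Nterm`, `H`, `K`, `R`).
#' @seealso [net_charge()], [read_scale_config()]
#' @export
ta_pka_table <- function() {
  list(
    acidic = c(Cterm = 3.1, D = 4.4, E = 4.4, C = 8.5, Y = 10.0),
    basic  = c(Nterm = 8.0, H = 6.5, K = 10.0, R = 12.0)
  )
}

#' Read a hydropathy scale or pKa table from a key=value config file
#'
#' One `key=value` pair per line; `#` starts a comment. For a hydropathy
#' scale the keys are the 20 residue letters. For a pKa table the keys are
#' residue letters plus `Nterm`/`Cterm`; acidic groups (D, E, C, Y, Cterm)
#' and basic groups (H, K, R, Nterm) are split automatically.
#'
#' @param path File path.
#' @param type `"hydropathy"` or `"pka"`.
#' @return Named numeric vector (`"hydropathy"`) or a list as returned by
#'   [ta_pka_table()] (`"pka"`).
#' @export
read_scale_config <- function(path, type = c("hydropathy", "pka")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (anyNA(vals)) abort("non-numeric value in config file")
  x <- setNames(vals, keys)
  if (type == "hydropathy") {
    missing <- setdiff(amino_acids(), names(x))
    if (length(missing) > 0) {
      abort(paste0("hydropathy scale missing residues: ",
                   paste(missing, collapse = ", ")))
    }
    return(x[amino_acids()])
  }
  acid_keys <- c("Cterm", "D", "E", "C", "Y")
  base_keys <- c("Nterm", "H", "K", "R")
  missing <- setdiff(c(acid_keys, base_keys), names(x))
  if (length(missing) > 0) {
    abort(paste0("pKa table missing groups: ", paste(missing, collapse = ", ")))
  }
  if (any(x[c(acid_keys, base_keys)] <= 0)) abort("pKa values must be positive")
  list(acidic = x[acid_keys], basic = x[base_keys])
}

#' Reference AGADIR helical-propensity values for the GDAP1 TMD series
#'
#' Externally computed helical-propensity values for the GDAP1 TMD variants
#' discussed as a possible additional targeting parameter. They are stored
#' as reference constants only; the package does not compute helicity.
#'
#' @return Tibble with columns `construct` and `agadir`.
#' @export
gdap1_agadir_reference <- function() {
  tibble(
    construct = c("MUT3", "MUT4", "WT", "MUT5"),
    agadir = c(1.05, 0.73, 0.57, 0.48)
  )
}

# Validate sequences over the 20-letter alphabet after upper-case folding.
# Returns the normalised sequences; errors name the record and the first
# offending character.
validate_seq <- function(seq, id = NULL, allow_empty = FALSE) {
  seq <- toupper(seq)
  id <- id %||% paste0("seq", seq_along(seq))
  for (k in seq_along(seq)) {
    s <- seq[[k]]
    if (is.na(s) || (!allow_empty && nchar(s) == 0)) {
      abort(paste0("record '", id[[k]], "' has an empty sequence"))
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), amino_acids())
    if (length(bad) > 0) {
      abort(paste0("record '", id[[k]], "' contains illegal residue '",
                   bad[[1]], "'"))
    }
  }
  seq
}
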
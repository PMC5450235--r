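# Independent oracles used to cross-check the package implementations.

# Brute-force TMD search: plain enumeration of every admissible window,
# means computed by direct summation. Mirrors the published contract, not
# the package's cumulative-sum implementation.
oracle_tmd <- function(seq, min_len = 17, max_len = 25, max_tail_len = 30,
                       min_score = 1.6) {
  vals <- kyte_doolittle()[strsplit(toupper(seq), "")[[1]]]
  n <- length(vals)
  best <- NULL
  tol <- 1e-9
  for (s in seq_len(n)) {
    for (e in seq_len(n)) {
      len <- e - s + 1
      if (len < min_len || len > max_len) next
      if (n - e > max_tail_len) next
      sc <- sum(vals[s:e]) / len
      if (is.null(best) || sc > best$score + tol ||
          (abs(sc - best$score) <= tol &&
           (len > best$len || (len == best$len && s > best$start)))) {
        best <- list(start = s, end = e, len = len, score = sc)
      }
    }
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  best
}

# Per-group Henderson-Hasselbalch summation, one ionisable group at a
# time (no vectorisation, no counting shortcuts).
oracle_charge <- function(seq, pH = 7, free_nterm = TRUE, free_cterm = TRUE) {
  pka <- ta_pka_table()
  q <- 0
  for (ch in strsplit(toupper(seq), "")[[1]]) {
    if (ch %in% names(pka$basic)) {
      q <- q + 1 / (1 + 10^(pH - pka$basic[[ch]]))
    } else if (ch %in% names(pka$acidic)) {
      q <- q - 1 / (1 + 10^(pka$acidic[[ch]] - pH))
    }
  }
  if (free_nterm) q <- q + 1 / (1 + 10^(pH - pka$basic[["Nterm"]]))
  if (free_cterm) q <- q - 1 / (1 + 10^(pka$acidic[["Cterm"]] - pH))
  q
}

random_peptide <- function(len, letters = amino_acids()) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Well-separated three-class feature set centred at the published group
# means (PO / MITO / ER tail charges), with per-class GRAVY offsets.
separated_blobs <- function(n_per_class = 10, sd = 0.05, seed = 1) {
  specs <- ta_class_specs()[ta_class_specs()$label %in% c("PO", "MITO", "ER"), ]
  specs$n <- as.integer(n_per_class)
  specs$charge_sd <- sd
  specs$gravy_sd <- sd
  synth_feature_dataset(specs, seed = seed)
}

write_tmp_dataset <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}
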
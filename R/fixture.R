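TA_FIXTURE_VERSION <- "1.0"

#' Bundled fixture dataset of TA-protein C-termini
#'
#' A deterministic, versioned table of tail-anchored proteins spanning the
#' four main localisation groups (PO, shared PO/MITO, MITO, ER), bundled
#' so that every analysis stage can be exercised without downloads. It is
#' a synthetic reconstruction: the ACBD5 entry carries the C-terminal
#' TMD-tail peptide from the primary literature (with the terminal Asn
#' restored) and is marked `verified = TRUE`; every other entry pairs a
#' protein name from the TA-protein literature with a generated C-terminal sequence whose
#' tail charge and TMD GRAVY are drawn from the published group
#' statistics, and is marked `verified = FALSE` with a provenance note in
#' `source`. Entries are therefore suitable for testing the pipeline and
#' for qualitative group structure, not for per-protein sequence analysis;
#' supply the original curated table via [read_ta_dataset()] for that.
#'
#' @return Tibble of dataset entries (columns `id`, `name`, `organism`,
#'   `location`, `cterm_seq`, `tmd_start`, `tmd_end`, `source`,
#'   `verified`), with the fixture version in attribute `"version"`.
#' @examples
#' fx <- ta_fixture_dataset()
#' table(fx$location)
#' @export
ta_fixture_dataset <- function() {
  path <- system.file("extdata", "ta_fixture_synthetic_v1.tsv",
                      package = "tatarget", mustWork = TRUE)
  out <- read_ta_dataset(path)
  attr(out, "version") <- TA_FIXTURE_VERSION
  out
}
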
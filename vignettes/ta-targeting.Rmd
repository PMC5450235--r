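---
title: "Methods: physicochemical prediction of TA-protein targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical prediction of TA-protein targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatarget)
```

## The model

Tail-anchored (TA) proteins expose their N-terminal domain to the cytosol
and are held in a membrane by a single transmembrane domain (TMD) near
the C-terminus. Because the TMD emerges from the ribosome only after
translation terminates, targeting is post-translational and is read from
the C-terminal region itself. This package operationalises the two
physicochemical signals that summarise that region:

* **TMD GRAVY** — the mean Kyte–Doolittle hydropathy of the TMD window.
  Hydrophobic TMDs favour capture by the GET/TRC40 chaperone route to the
  ER; less hydrophobic TMDs are poor GET substrates.
* **Net tail charge** — the Henderson–Hasselbalch charge of the residues
  C-terminal of the TMD, evaluated at pH 7.0 as a free peptide. A highly
  positive tail both promotes binding of the peroxisomal import receptor
  PEX19 and penalises ER membrane insertion.

A 3-class probabilistic support vector machine on these two features
assigns each protein calibrated probabilities of peroxisomal (PO),
mitochondrial (MITO) and ER targeting. The package's claim is not that
two features capture all targeting biology — tail residue positioning and
TMD helicity are known further candidates (the package stores externally
computed helicity reference values for the GDAP1 mutant series in
`gdap1_agadir_reference()`, but never computes helicity) — but that they
carry enough signal to make useful probabilistic calls.

## TMD detection: a transparent surrogate

Published TA-protein datasets typically locate TMDs with external HMM
servers whose models cannot be re-derived from their output. We instead
use a deliberately simple, fully specified detector
(`find_cterm_tmd()`): among all windows of length `min_len`–`max_len`
(default 17–25 residues, the span of a single membrane-crossing helix)
whose last residue lies within `max_tail_len` (default 30) residues of
the C-terminus — the "close to the C-terminus" constraint that defines a
TA protein — return the window with maximal mean Kyte–Doolittle
hydropathy, provided it reaches `min_score` (default 1.6). The threshold
was chosen so that the bundled fixture TMDs are detected while fully
polar sequences are not; all four parameters are arguments.

Numerical choices:

* **Ties.** Scores within `1e-9` of each other are treated as tied (mean
  hydropathies of distinct windows can differ by one ulp depending on
  summation order); ties are resolved in favour of the longer window,
  then the more C-terminal start. This makes results identical across
  platforms and makes the detector exactly equal to a brute-force
  enumeration oracle, which the test suite checks on 1,000 random
  sequences.
* **Passthrough.** Curated coordinates in a dataset table (or a `--tmd`
  command-line override) always take precedence over detection
  (`locate_tmd()` reports `status = "supplied"`). This keeps the
  surrogate honest: wherever authoritative coordinates exist, they win.
* **No-TMD records** are reported with `status = "no_tmd"` and missing
  features rather than dropped, so pipelines can account for them.

A consequence of defining the detector over *admissible windows only*
(windows ending near the C-terminus) is that a hydrophobic run far from
the C-terminus can still yield a qualifying, polar-diluted window that
straddles its tail end. We consider this the correct reading of the
window-maximisation contract; the detector is a TMD *locator*, not a
TA-protein classifier, and callers who need "is this a TA protein"
semantics should inspect the returned score and span.

## Charges, pKa values and rounding

The charge model is the standard per-group Henderson–Hasselbalch sum.
The pKa table (`ta_pka_table()`) is a Sillero-type set: C-terminus 3.1,
D 4.4, E 4.4, C 8.5, Y 10.0 (acidic); N-terminus 8.0, H 6.5, K 10.0,
R 12.0 (basic). Two conventions matter and both are exposed as flags:

* **Free termini.** Tail fragments are scored as free peptides (both
  termini ionisable). At pH 7 the free N-terminus contributes +0.91 and
  the C-terminus −1.00, so a tail with four arginines and one lysine
  scores +4.9 rather than +5.0. This convention — not the pKa decimals —
  is what determines agreement with the commonly used online calculators
  at 1-decimal precision, and it is validated in the test suite against
  a printed three-peptide reference series (+4.9 → +2.9 → +0.9).
* **Rounding.** Reported charges round half-away-from-zero to 1 decimal
  (`round_out()`, internal); full precision is kept everywhere else.
  Base `round()` is round-half-even, which is the wrong presentation
  convention here.

Both the hydropathy scale and the pKa table can be replaced from
`key=value` config files (`read_scale_config()`); ambiguity codes (B, Z,
X) and U are rejected outright because neither hydropathy nor ionisation
is defined for them.

The upstream region (default `upstream_len = 10` residues before the
TMD) gets the same charge/GRAVY treatment. Ten residues is a pragmatic
default for "the region immediately preceding the TMD"; it is a flag,
and upstream features are reported but not used by the classifier.

## Group statistics

`compare_groups()` mirrors the conventional presentation for contrasting
organelle groups: per-group mean, s.e.m. and a five-number summary
(boxes at the 25th–75th percentiles, whiskers spanning the range), plus
a two-tailed **Student** (pooled-variance) unpaired *t*-test for every
unordered pair with `*`/`**`/`***` thresholds at 0.05/0.01/0.001.
Choices made where the convention is ambiguous:

* pooled variance rather than Welch, matching the classic "unpaired
  t-test" default of common statistics GUIs; Welch is behind
  `welch = TRUE`;
* linear-interpolation (type 7) quantiles — only quartiles are displayed
  so the convention is documented rather than critical;
* no multiple-testing correction, mirroring per-pair reporting: with
  six pairs across four groups, readers should treat `*` near 0.05
  accordingly;
* zero pooled variance degenerates explicitly: equal means give
  `t = 0, p = 1`; unequal constant groups are flagged
  (`degenerate = TRUE`) rather than silently producing `NaN`.

The suite checks the pooled test against `stats::t.test(var.equal =
TRUE)` and verifies its type-I error calibration at the nominal 5% over
10,000 null simulations (n = 10 per group).

## The classifier

`ta_train()` fits one-vs-one RBF SVMs with Platt sigmoid calibration and
pairwise coupling, exactly the stack of LIBSVM as wrapped by e1071 —
the implementation this analysis tradition uses. Since no
hyperparameters are published for this task, we adopt that
implementation's defaults for two features: `cost = 1`,
`gamma = 1/2`, standardised features. All are arguments, and the
standardisation is fitted on the training set and stored in the model.

Design decisions:

* **Shared-location entries** (`PO_MITO` and friends) are excluded from
  training, consistent with restricting to three unique classes; they
  are still scored at predict time. `include_shared = TRUE` duplicates
  them into their component classes instead (off by default).
* **Probabilities** come from the package's own prediction path: RBF
  decision values from the stored support vectors, the Platt sigmoid per
  class pair, and the iterative pairwise-coupling algorithm. This makes
  models serialisable to versioned JSON (`save_model()` /
  `load_model()`, 17 significant digits — a lossless double round-trip)
  and the whole path testable: the suite checks it against e1071's own
  `predict()` to 1e-10, and checks probability normalisation at 1e-9.
* **Determinism.** Platt calibration shuffles data internally, so
  training is wrapped in a fixed, exposed seed (`seed = 0` default);
  identical calls produce byte-identical JSON. Leave-one-out CV
  (`loocv_misclassifications()`) refits standardisation per fold and
  reuses the same seed in every fold.
* **Ties and margins.** `predicted` is the argmax with exact ties broken
  by the fixed order PO > MITO > ER (ties are measure-zero but must be
  deterministic); predictions whose top-two probabilities differ by less
  than 0.1 carry a `low_margin` note.
* **Degenerate folds.** If holding out a point leaves its class with
  fewer than two members, the class is dropped from that fold and the
  held-out point counts as misclassified, with a message; a fold with
  fewer than two trainable classes is an error.
* **No special-casing.** Known hard points (e.g. a mitochondrial protein
  whose features place it among ER proteins) are simply reported as
  misclassifications; nothing is patched.
* A **fingerprint** of the training features travels with the model and
  triggers a warning when a model is evaluated against a different
  table than it was trained on.

## The synthetic generators

Two generators make every stage testable offline, at two levels:

* **Feature-level** (`synth_feature_dataset()`): Gaussian draws per
  class. The default class specification (`ta_class_specs()`) centres
  tail charge on the published group means (PO 6.03, shared 2.5, MITO
  1.12, ER 0.21) with standard deviations recovered from the published
  s.e.m. values times √n at the chosen class sizes (8/8/12/23). Group
  GRAVY means are not published; the defaults (PO 2.0, shared 1.9, MITO
  1.4, ER 2.6, sd ≈ 0.4) encode the qualitative ordering — ER most
  hydrophobic, mitochondria least — at a realistic spread. These
  defaults are the study conditions for the classifier tests and are not
  tuned further.
* **Sequence-level** (`synth_tail()`, `synth_tmd()`, `synth_record()`):
  tails place a leading Gln, then exactly `target_charge` arginines
  (charge arithmetic is sharp at pH 7: each Arg ≈ +1.000, realised
  charge = target − 0.09 ± 0.01), then neutral filler; this mirrors the
  Arg↔Ala substitution logic used experimentally. TMDs are composed from
  the two residues of {I, L, V, A, G, S} bracketing the target GRAVY, in
  proportions that land within 0.1 of it, and are arranged with the most
  hydrophobic residues at both ends. That arrangement is what guarantees
  *exact* planted-TMD recovery: any strict sub-window sheds
  above-average residues, any extension absorbs polar context or the
  tail's leading Gln/Arg, so the full window is the unique maximum (pure
  compositions tie and are resolved by the longer-window tie-break).
  Recovery is guaranteed only for targets comfortably above the
  detection threshold (≥ 1.8 in the tested lattice) and tails no longer
  than the detector's `max_tail_len`.

What the generators do *not* emulate: realistic N-terminal domains,
residue-order effects within tails, helicity, or any correlation
structure between charge and hydrophobicity. Passing tests on synthetic
data therefore demonstrate the correctness of the machinery — feature
arithmetic, boundary recovery, classifier calibration — not predictive
performance on real proteomes.

## The bundled fixture

The package ships a deterministic, versioned table
(`ta_fixture_dataset()`, version 1.0, 53 entries, 43 single-location) so
group statistics and the classifier can be exercised without downloads.
It is explicitly a *synthetic reconstruction*: one entry (ACBD5) carries
a printed C-terminal peptide sequence and is marked `verified = TRUE`;
all other entries pair protein names from the TA-protein literature with
generated C-terminal sequences whose features follow the published group
distributions, and are flagged `verified = FALSE` with a provenance note.
Exact published per-protein values can only be reproduced from the
original curated table, which users can supply through
`read_ta_dataset()` (same TSV schema); the conditional part of the
acceptance tests picks it up from `tests/testthat/dataset_s1.tsv` when
present.

## Problem sizes and tolerances used by the test suite

The suite was sized to be thorough yet quick on a single CPU: 1,000
random sequences for detector/oracle equivalence and 100 planted records
(seconds), 10,000 null simulations for t-test calibration, classifier
property checks on 18–30-point training sets. Key tolerances: 1e-9 for
probability normalisation, detector score ties and charge-oracle
agreement; 1e-10 against the LIBSVM reference; 1e-12 for model
round-trips; 0.1 GRAVY units and 0.02 charge units for generator
targets.

## Known limitations

* The TMD detector is a surrogate, not an HMM; on real multi-pass or
  signal-anchored proteins it will happily report the best C-terminal
  hydrophobic window. Upstream topology screening is out of scope.
* Two features cannot separate classes that overlap in (charge, GRAVY);
  the classifier reports calibrated uncertainty instead of pretending
  otherwise.
* The charge model ignores residue context (neighbouring-charge pKa
  shifts) and phosphorylation or other modifications.
* Only human-style single-TMD C-termini are modelled; no orthology
  handling for other lineages.
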
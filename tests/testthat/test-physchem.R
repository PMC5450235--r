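test_that("GRAVY matches the scale on reference sequences", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy(paste(amino_acids(), collapse = "")), -0.49)
  expect_equal(gravy("LLLLL"), 3.8)
  expect_error(gravy(""), "empty")
  expect_error(gravy("MKB"), "'B'")
})

test_that("GRAVY of equal-length halves averages", {
  set.seed(31)
  for (k in 1:10) {
    len <- sample(3:40, 1)
    s1 <- random_peptide(len)
    s2 <- random_peptide(len)
    expect_equal(gravy(paste0(s1, s2)), mean(c(gravy(s1), gravy(s2))))
  }
})

test_that("net charge reproduces the ACBD5 tail-charge series", {
  expect_equal(round(net_charge("QRRRRKLN"), 1), 4.9)
  expect_equal(round(net_charge("QRARAKLN"), 1), 2.9)
  expect_equal(round(net_charge("QAAAAKLN"), 1), 0.9)
  # no ionisable groups, no termini
  expect_equal(net_charge("AAAA", free_nterm = FALSE, free_cterm = FALSE), 0)
  expect_error(net_charge("AA", pH = 15), "pH")
  expect_error(net_charge(""), "empty")
})

test_that("net charge equals the per-group summation oracle", {
  set.seed(32)
  for (k in 1:30) {
    s <- random_peptide(sample(1:40, 1))
    pH <- runif(1, 2, 12)
    expect_equal(net_charge(s, pH = pH), oracle_charge(s, pH = pH),
                 tolerance = 1e-9)
  }
})

test_that("net charge is monotonically non-increasing in pH", {
  set.seed(33)
  grid <- seq(1, 13, by = 0.5)
  for (k in 1:12) {
    s <- random_peptide(sample(3:30, 1))
    q <- vapply(grid, function(p) net_charge(s, pH = p), numeric(1))
    expect_true(all(diff(q) <= 1e-12))
  }
})

test_that("appending an arginine adds almost exactly +1 at pH 7", {
  set.seed(34)
  for (k in 1:10) {
    s <- random_peptide(sample(2:25, 1))
    delta <- net_charge(paste0(s, "R")) - net_charge(s)
    expect_equal(delta, 1 / (1 + 10^(7 - 12)), tolerance = 1e-3)
  }
})

test_that("charge approaches the counting limits at extreme pH", {
  set.seed(35)
  for (k in 1:8) {
    s <- random_peptide(sample(5:30, 1))
    ch <- strsplit(s, "")[[1]]
    n_basic <- sum(ch %in% c("R", "K", "H")) + 1  # + free N-terminus
    n_acid <- sum(ch %in% c("D", "E", "C", "Y")) + 1  # + free C-terminus
    expect_equal(net_charge(s, pH = 0.1), n_basic, tolerance = 0.02)
    expect_equal(net_charge(s, pH = 13.9), -n_acid, tolerance = 0.02)
  }
})

test_that("feature vectors compose the GRAVY and charge oracles", {
  fv <- compute_features(strrep("L", 21), "QRRRRKLN")
  expect_equal(fv$tmd_gravy, 3.8)
  expect_equal(round(fv$tail_charge, 1), 4.9)
  expect_equal(fv$tail_length, 8L)
  empty <- compute_features(strrep("L", 21), "")
  expect_equal(empty$tail_charge, 0)
  expect_equal(empty$tail_length, 0L)
  expect_true(is.na(empty$upstream_gravy))
  expect_error(compute_features("", "QR"), "empty")
})

test_that("the data-frame pipeline computes features end to end", {
  df <- tibble::tibble(
    id = c("ta", "polar"),
    seq = c(paste0(strrep("S", 30), strrep("L", 21), "QRRRRKLN"),
            strrep("G", 50))
  )
  out <- compute_ta_features(df)
  expect_equal(out$status, c("detected", "no_tmd"))
  expect_equal(out$tmd_gravy[1], 3.8)
  expect_equal(round(out$tail_charge[1], 1), 4.9)
  expect_equal(out$tail_length[1], 8L)
  expect_true(all(is.na(out[2, c("tmd_gravy", "tail_charge")])))
  expect_equal(out$upstream_gravy[1], -0.8)  # ten serines
})

test_that("hydropathy and pKa tables load from key=value config files", {
  p <- tempfile(fileext = ".cfg")
  kd <- kyte_doolittle()
  writeLines(c("# scale", paste0(names(kd), "=", kd)), p)
  expect_equal(read_scale_config(p, "hydropathy"), kd)
  writeLines(paste0(names(kd)[-1], "=", kd[-1]), p)
  expect_error(read_scale_config(p, "hydropathy"), "missing residues: A")

  pka <- ta_pka_table()
  writeLines(c(paste0(names(pka$acidic), "=", pka$acidic),
               paste0(names(pka$basic), "=", pka$basic)), p)
  got <- read_scale_config(p, "pka")
  expect_equal(got$acidic, pka$acidic)
  expect_equal(got$basic, pka$basic)
  # a swapped table changes the result in the expected direction
  alt <- got
  alt$basic[["Nterm"]] <- 9.0
  expect_gt(net_charge("AAAA", pka = alt), net_charge("AAAA"))
})
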
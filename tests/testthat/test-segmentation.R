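test_that("detector finds the expected windows on constructed sequences", {
  # fully polar sequence: no qualifying window
  expect_equal(nrow(find_cterm_tmd(strrep("S", 60))), 0)
  # planted poly-Leu TMD: all pure-Leu windows tie at 3.8, the tie-break
  # (longer, then more C-terminal) selects the full 21-mer
  hit <- find_cterm_tmd(paste0(strrep("S", 30), strrep("L", 21), "QRRRRKLN"))
  expect_equal(hit$tmd_start, 31L)
  expect_equal(hit$tmd_end, 51L)
  expect_equal(hit$tmd_score, 3.8)
  # hydrophobic run too far from the C-terminus: every admissible window
  # is polar-diluted below threshold
  expect_equal(nrow(find_cterm_tmd(paste0(strrep("L", 21), strrep("S", 50)))), 0)
  # too-short input
  expect_error(find_cterm_tmd("LLLLL"), "shorter")
})

test_that("detector equals an exhaustive brute-force window search", {
  set.seed(101)
  for (k in 1:200) {
    s <- random_peptide(sample(17:120, 1))
    got <- find_cterm_tmd(s)
    want <- oracle_tmd(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$tmd_start, want$start)
      expect_equal(got$tmd_end, want$end)
      expect_equal(got$tmd_score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("N-terminal extension far from the C-terminus never moves the span", {
  set.seed(102)
  for (k in 1:25) {
    s <- paste0(random_peptide(60), synth_tmd(2.8), synth_tail(3, 6, seed = k))
    n <- nchar(s)
    base <- find_cterm_tmd(s)
    ext <- paste0(random_peptide(20), s)
    got <- find_cterm_tmd(ext)
    expect_equal(nrow(got), nrow(base))
    if (nrow(base) == 1) {
      # same span in C-terminus-anchored coordinates
      expect_equal(nchar(ext) - got$tmd_end, n - base$tmd_end)
      expect_equal(got$tmd_end - got$tmd_start, base$tmd_end - base$tmd_start)
      expect_equal(got$tmd_score, base$tmd_score, tolerance = 1e-9)
    }
  }
})

test_that("segmentation splits and reconstructs the sequence", {
  s <- paste0(strrep("S", 30), strrep("L", 21), "QRRRRKLN")
  seg <- segment_regions(s, 31, 51)
  expect_equal(seg$tail_seq, "QRRRRKLN")
  expect_equal(seg$upstream_seq, strrep("S", 10))
  expect_equal(paste0(seg$context_seq, seg$upstream_seq, seg$tmd_seq,
                      seg$tail_seq), s)
  # boundary cases
  seg <- segment_regions("LLLLLAA", 1, 5)
  expect_equal(seg$upstream_seq, "")
  expect_equal(seg$context_seq, "")
  seg <- segment_regions("AALLLLL", 3, 7)
  expect_equal(seg$tail_seq, "")
  # reconstruction on random inputs and spans
  set.seed(103)
  for (k in 1:20) {
    s <- random_peptide(sample(10:80, 1))
    a <- sample(seq_len(nchar(s) - 3), 1)
    b <- sample(seq(a + 1, nchar(s)), 1)
    seg <- segment_regions(s, a, b, upstream_len = sample(0:12, 1))
    expect_equal(paste0(seg$context_seq, seg$upstream_seq, seg$tmd_seq,
                        seg$tail_seq), s)
  }
  expect_error(segment_regions("AAAA", 2, 9), "out of bounds")
})

test_that("supplied coordinates take precedence over detection", {
  df <- tibble::tibble(
    id = c("a", "b"),
    seq = rep(paste0(strrep("S", 30), strrep("L", 21), "QRRRRKLN"), 2),
    tmd_start = c(20L, NA), tmd_end = c(45L, NA)
  )
  out <- locate_tmd(df)
  expect_equal(out$status, c("supplied", "detected"))
  expect_equal(out$tmd_start, c(20L, 31L))
  expect_equal(out$tmd_end, c(45L, 51L))
  # a record with no detectable TMD is reported, not dropped
  polar <- tibble::tibble(id = "p", seq = strrep("G", 40))
  out <- locate_tmd(polar)
  expect_equal(out$status, "no_tmd")
  expect_true(is.na(out$tmd_start))
})
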
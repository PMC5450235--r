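test_that("well-separated classes are fit perfectly and deterministically", {
  d <- separated_blobs(10, sd = 0.05, seed = 1)
  m <- ta_train(d, seed = 1)
  expect_equal(as.integer(in_sample_misclassifications(m, d)), 0)
  expect_equal(as.integer(loocv_misclassifications(d, seed = 1)), 0)
  # identical runs give byte-identical serialised models
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  save_model(ta_train(d, seed = 1), p1)
  save_model(ta_train(d, seed = 1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("degenerate training inputs are rejected", {
  d <- separated_blobs(5, seed = 2)
  expect_error(ta_train(d[d$label != "ER" | seq_len(nrow(d)) == 11, ]),
               "fewer than 2 examples")
  flat <- d
  flat$tmd_gravy <- 2
  expect_error(ta_train(flat), "zero-variance")
  expect_error(ta_train(d[c(1, 6, 11), ]), "fewer than 2")
})

test_that("probabilities are normalised and argmax is consistent", {
  d <- separated_blobs(8, sd = 0.4, seed = 3)
  m <- ta_train(d, seed = 3)
  set.seed(3)
  pts <- tibble::tibble(tail_charge = runif(40, -5, 15),
                        tmd_gravy = runif(40, 0, 5))
  pr <- predict(m, pts)
  expect_true(all(abs(pr$p_PO + pr$p_MITO + pr$p_ER - 1) < 1e-9))
  probs <- as.matrix(pr[, c("p_PO", "p_MITO", "p_ER")])
  expect_equal(pr$predicted,
               c("PO", "MITO", "ER")[apply(probs, 1, which.max)])
  # class centroids are called with confidence
  cent <- predict(m, tibble::tibble(tail_charge = c(6.03, 1.12, 0.21),
                                    tmd_gravy = c(2.0, 1.4, 2.6)))
  expect_equal(cent$predicted, c("PO", "MITO", "ER"))
  expect_true(all(c(cent$p_PO[1], cent$p_MITO[2], cent$p_ER[3]) > 0.5))
  expect_error(predict(m, tibble::tibble(tail_charge = NA_real_,
                                         tmd_gravy = 1)), "non-finite")
})

test_that("the in-package predictor matches the LIBSVM reference", {
  d <- separated_blobs(8, sd = 0.8, seed = 4)
  m <- ta_train(d, seed = 4)
  X <- as.matrix(d[, c("tail_charge", "tmd_gravy")])
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  y <- factor(d$label, levels = c("PO", "MITO", "ER"))
  set.seed(4)
  ref <- e1071::svm(Xs, y, kernel = "radial", cost = 1, gamma = 0.5,
                    probability = TRUE, scale = FALSE)
  set.seed(5)
  pts <- cbind(tail_charge = runif(25, -5, 15), tmd_gravy = runif(25, 0, 5))
  pts_s <- sweep(sweep(pts, 2, m$center), 2, m$scale, "/")
  want <- attr(predict(ref, pts_s, probability = TRUE), "probabilities")
  got <- predict(m, tibble::as_tibble(pts))
  expect_equal(as.matrix(got[, c("p_PO", "p_MITO", "p_ER")]),
               want[, c("PO", "MITO", "ER")],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("standardised models are equivariant to affine feature maps", {
  d <- separated_blobs(8, sd = 0.6, seed = 6)
  m <- ta_train(d, seed = 6)
  set.seed(6)
  pts <- tibble::tibble(tail_charge = runif(20, -3, 12),
                        tmd_gravy = runif(20, 0.5, 4))
  base <- predict(m, pts)
  for (map in list(c(a1 = 3, b1 = -2, a2 = 0.5, b2 = 10),
                   c(a1 = 0.1, b1 = 5, a2 = 7, b2 = -1))) {
    d2 <- d
    d2$tail_charge <- map["a1"] * d$tail_charge + map["b1"]
    d2$tmd_gravy <- map["a2"] * d$tmd_gravy + map["b2"]
    m2 <- ta_train(d2, seed = 6)
    pts2 <- tibble::tibble(
      tail_charge = map["a1"] * pts$tail_charge + map["b1"],
      tmd_gravy = map["a2"] * pts$tmd_gravy + map["b2"]
    )
    got <- predict(m2, pts2)
    expect_equal(as.matrix(got[, c("p_PO", "p_MITO", "p_ER")]),
                 as.matrix(base[, c("p_PO", "p_MITO", "p_ER")]),
                 tolerance = 1e-9)
  }
})

test_that("evaluating on a different dataset warns via the fingerprint", {
  d <- separated_blobs(6, seed = 7)
  m <- ta_train(d, seed = 7)
  expect_silent(in_sample_misclassifications(m, d))
  other <- separated_blobs(6, seed = 8)
  expect_warning(in_sample_misclassifications(m, other),
                 "different dataset")
})

test_that("randomly permuted labels yield roughly chance-level fits", {
  d <- separated_blobs(8, sd = 0.3, seed = 9)
  n <- nrow(d)
  errs <- vapply(1:5, function(k) {
    perm <- d
    set.seed(100 + k)
    perm$label <- sample(perm$label)
    m <- ta_train(perm, seed = k)
    as.integer(suppressWarnings(in_sample_misclassifications(m, perm)))
  }, integer(1))
  expect_gt(mean(errs) / n, 0.2)
  expect_lt(mean(errs) / n, 0.95)
})

test_that("leave-one-out handles vanishing classes explicitly", {
  d <- separated_blobs(5, sd = 0.1, seed = 10)
  expect_error(loocv_misclassifications(d[c(1, 6, 11), ]), "at least 3|fewer")
  # a 2-member class vanishes whenever one of its points is held out
  small <- d[c(1:2, 6:10, 11:15), ]
  expect_message(res <- loocv_misclassifications(small, seed = 10),
                 "counted misclassified")
  expect_gte(as.integer(res), 2)
  det <- attr(res, "details")
  expect_equal(nrow(det), nrow(small))
  # determinism
  expect_equal(as.integer(suppressMessages(
    loocv_misclassifications(small, seed = 10))), as.integer(res))
})

test_that("probability grids are consistent with point predictions", {
  d <- separated_blobs(6, sd = 0.3, seed = 11)
  m <- ta_train(d, seed = 11)
  g1 <- probability_grid(m, c(5, 5), c(2, 2), step = 1)
  expect_equal(nrow(g1), 1)
  p1 <- predict(m, tibble::tibble(tail_charge = 5, tmd_gravy = 2))
  expect_equal(g1$p_PO, p1$p_PO)
  g <- probability_grid(m, c(-2, 10), c(1, 3), step = 1)
  expect_true(all(abs(g$p_PO + g$p_MITO + g$p_ER - 1) < 1e-9))
  expect_error(probability_grid(m, c(-2, 10), c(1, 3), step = 0), "step")
  expect_error(probability_grid(m, c(10, -2), c(1, 3), step = 1), "ranges")
})

test_that("a fixture-trained model sends charged moderate-GRAVY tails to PO", {
  feats <- compute_ta_features(ta_fixture_dataset())
  m <- ta_train(feats)
  g <- probability_grid(m, c(-2, 10), c(1, 3), step = 0.5)
  corner <- g[g$tail_charge == 10 & g$tmd_gravy == 2, ]
  expect_equal(corner$predicted, "PO")
})

test_that("models survive a JSON round-trip and reject bad files", {
  d <- separated_blobs(6, sd = 0.4, seed = 12)
  m <- ta_train(d, seed = 12)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(12)
  pts <- tibble::tibble(tail_charge = runif(15, -3, 12),
                        tmd_gravy = runif(15, 0.5, 4))
  expect_equal(as.matrix(predict(m2, pts)[, 3:5]),
               as.matrix(predict(m, pts)[, 3:5]), tolerance = 1e-12)
  # version tag is enforced
  txt <- readLines(path)
  writeLines(sub('"version": "1.0"', '"version": "0.9"', txt), path)
  expect_error(load_model(path), "version")
  writeLines("{ not json", path)
  expect_error(load_model(path), "corrupt")
  expect_error(load_model(tempfile()), "not found")
})

test_that("tidy and glance summarise a fitted model", {
  d <- separated_blobs(6, sd = 0.3, seed = 13)
  m <- ta_train(d, seed = 13)
  td <- tidy(m)
  expect_equal(nrow(td), sum(m$nSV))
  expect_true(all(c("class", "tail_charge", "tmd_gravy") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n, 18)
  expect_equal(gl$in_sample_errors, 0L)
  expect_s3_class(autoplot(m, step = 0.5), "ggplot")
})
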
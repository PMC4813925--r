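test_that("per-image normalization references the best candidate", {
  feats <- tibble::tibble(
    candidate_id = 1:3,
    symmetry_line = c(0.9, 0.5, 0.2),
    contrast_plus_band = c(0.1, 0.4, -0.2),
    intensity_line = c(0.3, 0.1, 0.6),
    gain = c(3, 2, 1)
  )
  out <- normalize_features(feats)
  expect_equal(out$symmetry_line, c(0, -0.4, -0.7))
  expect_equal(out$contrast_plus_band, c(-0.3, 0, -0.6))
  expect_equal(out$intensity_line, c(0.2, 0, 0.5))
  expect_equal(out$gain, feats$gain)  # non-feature columns untouched
  expect_error(normalize_features(feats[0, ]), "no candidates")
})

test_that("logistic gate separates and scores as a calibrated posterior", {
  # perfectly separable data: training accuracy must be 1
  v <- c(seq(-3, -1, length.out = 40), seq(1, 3, length.out = 40))
  y <- rep(c(0L, 1L), each = 40)
  g <- fit_logistic(v, y, feature_name = "symmetry_line")
  expect_s3_class(g, "lumen_gate")
  acc <- mean((gate_score(g, v) >= 0.5) == (y == 1L))
  expect_equal(acc, 1)
  expect_gt(g$slope, 0)
  # labels may be given as strings
  g2 <- fit_logistic(v, ifelse(y == 1, "positive", "negative"),
                     feature_name = "symmetry_line")
  expect_equal(g2$slope, g$slope)
  expect_error(fit_logistic(v, rep(1L, 80)), "both classes")
  expect_error(fit_logistic(v, y, threshold = 1.5), "threshold")
})

test_that("logistic fit recovers known generating coefficients", {
  # draw from P(y=1|v) = plogis(4 v + 1) on balanced features
  set.seed(2024)
  n <- 1e4
  v <- runif(n, -2, 2)
  y <- rbinom(n, 1, plogis(4 * v + 1))
  g <- fit_logistic(v, y, equal_priors = FALSE, feature_name = "f")
  expect_equal(g$slope, 4, tolerance = 0.3)
  expect_equal(g$intercept, 1, tolerance = 0.15)
})

test_that("equal-prior weighting removes class-imbalance bias", {
  # same conditional model, but negatives 9x oversampled; with equal priors
  # the intercept should stay near the balanced one
  set.seed(99)
  v1 <- rnorm(500, 1); v0 <- rnorm(4500, -1)
  v <- c(v1, v0); y <- c(rep(1L, 500), rep(0L, 4500))
  g_bal <- fit_logistic(v, y, equal_priors = TRUE)
  g_raw <- fit_logistic(v, y, equal_priors = FALSE)
  # raw fit shifts the intercept by about log(1/9) relative to equal priors
  expect_equal(g_raw$intercept - g_bal$intercept, log(500 / 4500),
               tolerance = 0.25)
  # boundary of the equal-prior gate sits near v = 0 by symmetry
  expect_lt(abs(-g_bal$intercept / g_bal$slope), 0.2)
})

test_that("selection takes the bottom-most accepted candidate", {
  gate <- structure(list(feature_name = "symmetry_line", slope = 10,
                         intercept = 5, threshold = 0.5,
                         normalization = "subtract_max", n = 0L),
                    class = "lumen_gate")
  cands <- tibble::tibble(
    candidate_id = 1:3,
    end_row = c(120L, 60L, 200L),
    gain = c(3, 2, 1),
    mean_row = c(120, 60, 200),
    rows = list(rep(120L, 4), rep(60L, 4), rep(200L, 4)),
    symmetry_line = c(0, -0.1, -2)   # 1 and 2 pass, 3 rejected
  )
  sel <- select_lumen(cands, gate)
  expect_s3_class(sel, "lumen_selection")
  expect_false(sel$fallback)
  expect_identical(sel$scores$accepted, c(TRUE, TRUE, FALSE))
  expect_identical(sel$chosen_id, 1L)   # bottom-most among accepted
  expect_identical(sel$rows, rep(120L, 4))
  # all rejected -> fallback to the highest posterior
  gate$intercept <- -50
  sel2 <- select_lumen(cands, gate)
  expect_true(sel2$fallback)
  expect_identical(sel2$chosen_id, 1L)
  # empty candidate set
  sel0 <- select_lumen(cands[0, ], gate)
  expect_identical(sel0$chosen_id, NA_integer_)
  # accept-all gate reproduces the bottom-most baseline
  gate$intercept <- 50
  sel3 <- select_lumen(cands, gate)
  expect_identical(sel3$rows, select_bottom_most(cands)$rows)
})

test_that("baseline selectors behave as documented", {
  m <- matrix(0.1, 8, 5); m[6, ] <- 0.9
  dp <- dp_forward(m)
  bs <- select_best_sym(dp)
  expect_identical(bs$rows, rep(6L, 5))
  expect_equal(bs$gain, 4.5)
  expect_error(select_bottom_most(tibble::tibble()), "no candidates")
})

test_that("gate JSON round-trip and tidiers", {
  g <- fit_logistic(c(-2, -1, 1, 2), c(0, 0, 1, 1),
                    feature_name = "contrast_plus_line", threshold = 0.4)
  d <- withr::local_tempdir()
  fp <- file.path(d, "gate.json")
  write_gate(g, fp)
  g2 <- read_gate(fp)
  expect_equal(g2[names(g)], g[names(g)], tolerance = 1e-12)
  td <- tidy(g)
  expect_identical(td$term, c("(Intercept)", "contrast_plus_line"))
  expect_equal(td$estimate, c(g$intercept, g$slope))
  gl <- glance(g)
  expect_identical(gl$feature_name, "contrast_plus_line")
  expect_identical(gl$n, 4L)
})
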
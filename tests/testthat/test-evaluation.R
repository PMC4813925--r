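test_that("path correctness uses strict in-lumen bounds", {
  truth <- tibble::tibble(near_li_row = rep(10, 5), far_li_row = rep(20, 5))
  expect_equal(path_correct_fraction(rep(15L, 5), truth), 1)
  # touching a boundary counts as outside
  expect_equal(path_correct_fraction(c(10L, 20L, 15L, 15L, 15L), truth), 0.6)
  expect_equal(path_correct_fraction(rep(5L, 5), truth), 0)
  expect_true(is_correct(c(15L, 15L, 15L, 15L, 9L), truth, frac = 0.8))
  expect_false(is_correct(c(15L, 15L, 15L, 9L, 9L), truth, frac = 0.8))
  expect_error(path_correct_fraction(rep(15L, 4), truth), "widths differ")
})

test_that("ROC matches hand-computed values and sane baselines", {
  r <- roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  # best balanced accuracy: threshold 0.35 -> TPR 1, FPR 0.5 -> 0.75;
  # threshold 0.8 -> TPR 0.5, FPR 0 -> 0.75
  expect_equal(r$best_accuracy, 0.75)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  # perfect separation
  expect_equal(roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # scores independent of labels: AUC concentrates near 1/2
  set.seed(8)
  expect_equal(roc(runif(4000), rbinom(4000, 1, 0.5))$auc, 0.5,
               tolerance = 0.05)
  # AUC equals the Mann-Whitney U statistic probability on random data
  set.seed(9)
  s <- round(runif(300), 2)  # force ties to exercise the sweep
  l <- rbinom(300, 1, 0.4)
  u <- mean(outer(s[l == 1], s[l == 0], ">") +
              0.5 * outer(s[l == 1], s[l == 0], "=="))
  expect_equal(roc(s, l)$auc, u, tolerance = 1e-9)
  expect_error(roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("fold assignment partitions images nearly evenly", {
  f <- make_folds(23, 5, seed = 4)
  expect_length(f, 23)
  expect_setequal(unique(f), 1:5)
  expect_lte(diff(range(table(f))), 1)
  expect_identical(make_folds(23, 5, seed = 4), f)
  expect_false(identical(make_folds(23, 5, seed = 5), f))
})

test_that("analyze_image labels phantom candidates against the truth", {
  ph <- generate_phantom(phantom_spec(
    center_depth_mm = 18,
    deep_band = list(gap_mm = 2, level = 0.12, noise_sd = 0.08),
    seed = 21L))
  an <- lumentrace:::analyze_image(ph$image, carotid_parameters(),
                                   truth = ph$annotation)
  cc <- an$candidates
  expect_gte(nrow(cc), 2L)
  expect_true(any(cc$label == "positive"))
  expect_true(any(cc$label == "negative"))
  # the positive candidate really runs inside the lumen
  pos <- cc[cc$label == "positive", ][1, ]
  expect_gte(pos$correct_fraction, 0.8)
  # the greedy symmetry baseline also finds this clean artery
  expect_gte(an$summary$best_sym_fraction, 0.8)
  expect_gte(an$summary$max_fraction, 0.8)
})

test_that("experiment machinery aggregates a synthetic candidate table", {
  # 6 images x (none + one SNR), 3 candidates each: the in-lumen candidate
  # has feature 0 (per-image max), a decoy above the artery (excluded) and
  # a decoy below it (negative) both have -1
  mk <- function(image, noise_model, snr_db) tibble::tibble(
    image = image, noise_model = noise_model, snr_db = snr_db,
    candidate_id = 1:3,
    mean_row = c(100, 40, 180),
    symmetry_line = c(0, -1, -1),
    correct_fraction = c(1, 0, 0),
    label = c("positive", "excluded", "negative")
  )
  grid <- expand.grid(image = 1:6, nm = c("none", "speckle"),
                      stringsAsFactors = FALSE)
  cand <- dplyr::bind_rows(Map(
    function(i, nm) mk(i, nm, if (nm == "none") Inf else 10),
    grid$image, grid$nm))
  imgs <- dplyr::distinct(cand[, c("image", "noise_model", "snr_db")])
  imgs$n_kept <- 3L
  imgs$best_sym_fraction <- 1
  imgs$max_fraction <- 1
  cfg <- experiment_config(folds = 2, repetitions = 2,
                           snr_grid_db = 10, features = "symmetry_line",
                           seed = 3)
  rep_ <- lumentrace:::evaluate_candidate_tables(cand, imgs, cfg)
  expect_s3_class(rep_, "lumen_report")
  perf <- rep_$performance
  # the gate separates 0 from -1 perfectly, so only the true candidate is
  # accepted and the proposed selector is always right
  expect_true(all(perf$mean_pct[perf$method == "proposed_symmetry_line"] == 100))
  expect_true(all(perf$sd_pct == 0))
  # the greedy baseline is right by construction of best_sym_fraction;
  # bottom-most falls for the deep decoy every time
  expect_true(all(perf$mean_pct[perf$method == "best_sym"] == 100))
  expect_true(all(perf$mean_pct[perf$method == "bottom_most"] == 0))
  expect_true(all(rep_$classifier$auc_mean == 1))
  expect_setequal(unique(perf$method),
                  c("proposed_symmetry_line", "best_sym", "bottom_most"))
  expect_true(all(rep_$candidate_stage$pct_any_full == 100))
})

test_that("run_experiment produces a coherent report on a small bank", {
  # a high far-field prevalence guarantees negative training examples in
  # every fold of this tiny bank
  bank <- generate_dataset(8, seed = 43, deep_band_prob = 1)
  cfg <- experiment_config(folds = 2, repetitions = 2, snr_grid_db = 10,
                           noise_models = "speckle",
                           features = "symmetry_line", seed = 17)
  rep_ <- run_experiment(bank, cfg)
  expect_s3_class(rep_, "lumen_report")
  perf <- rep_$performance
  expect_setequal(unique(perf$method),
                  c("proposed_symmetry_line", "best_sym", "bottom_most"))
  expect_setequal(unique(perf$snr_db), c(Inf, 10))
  expect_true(all(perf$mean_pct >= 0 & perf$mean_pct <= 100))
  expect_true(all(is.finite(perf$sem_pct)))
  cs <- rep_$candidate_stage
  expect_true(all(cs$pct_any_correct >= cs$pct_any_full - 1e-9))
  expect_true(all(rep_$classifier$auc_mean >= 0 &
                    rep_$classifier$auc_mean <= 1))
  # candidate curve is monotone non-increasing in the required fraction
  cc <- rep_$candidate_curve
  for (key in split(cc, list(cc$noise_model, cc$snr_db), drop = TRUE)) {
    key <- key[order(key$required_fraction), ]
    expect_true(all(diff(key$pct_images) <= 1e-9))
  }
  # noiseless candidate stage on clean phantoms should be strong
  expect_gte(cs$pct_any_correct[cs$noise_model == "none"], 80)
  # report export round-trip
  d <- withr::local_tempdir()
  fj <- file.path(d, "r.json")
  write_report(rep_, fj)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(j$performance), nrow(perf))
  expect_output(print(rep_), "lumen_report")
})
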
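test_that("phantom rendering is deterministic and annotated consistently", {
  sp <- phantom_spec(seed = 7L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_s3_class(a, "carotid_phantom")
  img <- a$image
  expect_equal(dim(img), c(round(35 / 0.09), round(40 / 0.09)))
  ann <- a$annotation
  expect_identical(nrow(ann), ncol(img$intensities))
  # annotation geometry: lumen band of the requested diameter around the
  # centerline, inside the image
  expect_equal(ann$far_li_row - ann$near_li_row,
               rep(6 / 0.09, nrow(ann)))
  expect_equal((ann$near_li_row + ann$far_li_row) / 2, ann$centerline_row)
  expect_true(all(ann$near_li_row > 1 & ann$far_li_row < nrow(img$intensities)))
  # image content: dark on the centerline, brighter in the far wall
  cl <- round(ann$centerline_row)
  ix <- cbind(cl, ann$column)
  expect_lt(mean(img$intensities[ix]), 0.2)
  wall <- cbind(round(ann$far_li_row + 1.55 / 0.09), ann$column)  # adventitia
  expect_gt(mean(img$intensities[wall]), 0.5)
  # the centerline slope stays below the 1 px/column path connectivity
  expect_lt(max(abs(diff(ann$centerline_row))), 1)
})

test_that("plaque protrudes the far LI boundary but never crosses the center", {
  sp <- phantom_spec(plaque = list(height_mm = 2, width_mm = 10,
                                   center_frac = 0.5, level = 0.6),
                     seed = 3L)
  ph <- generate_phantom(sp)
  ann <- ph$annotation
  base <- ann$centerline_row + (6 / 0.09) / 2
  expect_lt(min(ann$far_li_row - base), -1)      # protrusion present
  expect_true(all(ann$far_li_row > ann$centerline_row))
  # protrusion is localized around the plaque center column
  mid <- which.min(ann$far_li_row - base)
  expect_lt(abs(mid - 0.5 * nrow(ann)), 0.15 * nrow(ann))
})

test_that("distractor and far-field zone render dark off the artery", {
  spd <- phantom_spec(center_depth_mm = 20,
                      distractor = list(diameter_mm = 5, gap_mm = 3,
                                        clean = TRUE),
                      deep_band = list(gap_mm = 2, level = 0.12,
                                       noise_sd = 0.08),
                      seed = 11L)
  ph <- generate_phantom(spd)
  m <- ph$image$intensities
  ann <- ph$annotation
  top_edge <- min(ann$near_li_row) - (0.3 + 0.5 + 1.5) / 0.09
  # some rows above the near wall are darker than tissue (the distractor)
  above <- m[20:floor(top_edge - 5), ]
  expect_lt(min(rowMeans(above)), 0.15)
  # the far field fades to a dark floor: the last rows are dark on average
  # but noisier than the clean lumen
  bottom <- m[(nrow(m) - 20):nrow(m), ]
  expect_lt(mean(bottom), 0.3)
  lum <- m[cbind(round(ann$centerline_row), ann$column)]
  expect_gt(sd(as.vector(bottom)), 2 * sd(lum))
  # geometry that cannot fit errors out
  expect_error(generate_phantom(phantom_spec(center_depth_mm = 5, seed = 1)),
               "fit")
})

test_that("dataset generation is reproducible with requested prevalences", {
  d1 <- generate_dataset(12, seed = 5)
  d2 <- generate_dataset(12, seed = 5)
  expect_identical(lapply(d1$image, `[[`, "intensities"),
                   lapply(d2$image, `[[`, "intensities"))
  expect_identical(d1$id, 1:12)
  expect_s3_class(d1, "tbl_df")
  # per-image independence: regenerating one spec reproduces that image
  ph <- generate_phantom(d1$spec[[4]])
  expect_identical(ph$image$intensities, d1$image[[4]]$intensities)
  # all-or-none prevalences
  d3 <- generate_dataset(6, seed = 2, distractor_prob = 1, plaque_prob = 0,
                         shadow_prob = 0, deep_band_prob = 0)
  expect_true(all(vapply(d3$spec, function(s) !is.null(s$distractor),
                         logical(1))))
  expect_true(all(vapply(d3$spec, function(s) is.null(s$plaque), logical(1))))
  # different seeds give different banks
  d4 <- generate_dataset(6, seed = 3, distractor_prob = 1)
  expect_false(identical(d3$image[[1]]$intensities,
                         d4$image[[1]]$intensities))
})

test_that("phantom banks export to disk with a manifest", {
  d <- withr::local_tempdir()
  bank <- generate_dataset(2, seed = 9)
  out <- file.path(d, "bank")
  write_phantom_dataset(bank, out)
  expect_true(file.exists(file.path(out, "phantom_001.png")))
  expect_true(file.exists(file.path(out, "phantom_002.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 9)
  expect_length(man$specs, 2)
  csv <- utils::read.csv(file.path(out, "phantom_001.csv"))
  expect_equal(csv$near_li_row, bank$annotation[[1]]$near_li_row,
               tolerance = 1e-6)
})
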
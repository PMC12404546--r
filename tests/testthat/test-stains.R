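test_that("rgb_to_od implements the base-10 Lambert-Beer transform", {
  expect_equal(as.numeric(rgb_to_od(c(255, 255, 255))$od), c(0, 0, 0))
  expect_equal(as.numeric(rgb_to_od(c(25.5, 25.5, 25.5))$od), c(1, 1, 1))
  # zero transmission is clamped, not infinite
  od0 <- as.numeric(rgb_to_od(c(0, 0, 0))$od)
  expect_true(all(is.finite(od0)))
  expect_equal(od0, rep(log10(255), 3))
  expect_error(rgb_to_od(array(1, c(4, 4, 2))), "3")
  expect_error(rgb_to_od(c(1, 2, 3), incident = 0), "incident")
})

test_that("od_to_rgb inverts rgb_to_od to within one grey level", {
  expect_equal(as.numeric(od_to_rgb(array(0, c(1, 1, 3)))), c(255, 255, 255))
  # 255 * 10^-1 = 25.5, half-up rounding gives 26
  expect_equal(as.numeric(od_to_rgb(array(1, c(1, 1, 3)))), c(26, 26, 26))
  expect_error(od_to_rgb(array(-0.1, c(1, 1, 3))), "negative")
  set.seed(11)
  img <- array(sample(1:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  back <- od_to_rgb(rgb_to_od(img))
  expect_lte(max(abs(back - img)), 1)
})

test_that("stain matrix normalization divides each row by its length", {
  m <- normalize_stain_matrix(stain_matrix(rbind(
    eosin = c(0.01, 0.13, 0.01),
    a = c(1, 0, 0),
    hematoxylin = c(0.18, 0.20, 0.08))))
  mm <- as_matrix(m)
  # independent arithmetic: each row over its Euclidean norm
  expect_equal(unname(mm["eosin", ]),
               c(0.01, 0.13, 0.01) / sqrt(0.01^2 + 0.13^2 + 0.01^2),
               tolerance = 1e-12)
  expect_equal(unname(mm["a", ]), c(1, 0, 0))
  expect_equal(unname(sqrt(rowSums(mm^2))), rep(1, 3), tolerance = 1e-12)
  # published rounded form agrees with recomputation to ~0.02 on the
  # hematoxylin row (the published eosin/DAB rows derive from unrounded
  # source measurements and drift further)
  expect_lt(max(abs(as_matrix(normalize_stain_matrix(stain_matrix_hed_raw()))[1, ] -
                    as_matrix(stain_matrix_hed_normalized())[1, ])), 0.02)
  expect_error(normalize_stain_matrix(stain_matrix(rbind(c(0, 0, 0),
                                                         c(1, 0, 0),
                                                         c(0, 1, 0)))),
               "degenerate")
})

test_that("two-stain completion yields an orthogonal unit residual", {
  sm <- complete_two_stain_matrix(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(as_matrix(sm)[3, ]), c(0, 0, 1))
  sm <- stain_matrix_hdab()
  m <- as_matrix(sm)
  expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 3), tolerance = 1e-9)
  expect_lt(abs(sum(m[1, ] * m[3, ])), 1e-6)
  expect_lt(abs(sum(m[2, ] * m[3, ])), 1e-6)
  expect_error(complete_two_stain_matrix(rbind(c(1, 1, 0), c(2, 2, 0))),
               "parallel")
})

test_that("inverting the published normalized H/E/DAB matrix reproduces the
           published deconvolution matrix", {
  d <- deconvolution_matrix(stain_matrix_hed_normalized())
  printed <- deconvolution_matrix_hed()$d
  expect_lt(max(abs(d$d - printed)), 0.02)
  expect_equal(unname(diag(d$d)), c(1.88, 1.13, 1.57), tolerance = 0.02)
})

test_that("deconvolution matrix is the exact inverse of its source", {
  sm <- stain_matrix_hdab()
  d <- deconvolution_matrix(sm)
  expect_equal(unname(d$d %*% t(as_matrix(sm))), diag(3), tolerance = 1e-6)
  id <- deconvolution_matrix(stain_matrix(diag(3), normalized = TRUE))
  expect_equal(unname(id$d), diag(3))
  expect_error(deconvolution_matrix(stain_matrix_hed_raw()), "normalized")
  near_singular <- stain_matrix(rbind(c(1, 0, 0), c(1, 1e-10, 0) /
                                        sqrt(1 + 1e-20), c(0, 0, 1)),
                                normalized = TRUE)
  expect_error(deconvolution_matrix(near_singular), "condition")
})

test_that("separate_stains recovers known per-pixel concentrations", {
  mhat <- normalize_stain_matrix(stain_matrix_hed_raw())
  d <- deconvolution_matrix(mhat)
  m <- as_matrix(mhat)
  # a pixel carrying unit hematoxylin only
  od1 <- array(m[1, ], c(1, 1, 3))
  expect_equal(as.numeric(separate_stains(od1, d)$conc), c(1, 0, 0),
               tolerance = 1e-6)
  expect_equal(as.numeric(separate_stains(array(0, c(1, 1, 3)), d)$conc),
               c(0, 0, 0))
  # forward-render (c_H, c_E, c_D) = (0.5, 0, 1.2), then unmix
  conc_true <- c(0.5, 0, 1.2)
  od <- array(rep(conc_true %*% m, each = 1), c(1, 1, 3))
  expect_equal(as.numeric(separate_stains(od, d)$conc), conc_true,
               tolerance = 1e-3)
  expect_error(separate_stains(array(0, c(2, 2, 2)), d), "3")
})

test_that("anomaly map normalizes the DAB channel into [0, 1]", {
  d <- deconvolution_matrix(stain_matrix_hdab())
  white <- array(255, c(8, 8, 3))
  am <- anomaly_map_from_image(white)
  expect_true(all(am$map == 0))
  # concentration at the saturation OD maps to exactly 1
  m <- as_matrix(stain_matrix_hdab())
  od <- array(rep(m["dab", ], each = 4), c(2, 2, 3))
  cm <- separate_stains(od, d)
  expect_equal(as.numeric(dab_anomaly_map(cm, saturation_od = 1)$map),
               rep(1, 4), tolerance = 1e-6)
  expect_error(dab_anomaly_map(cm, stain = "ki67"), "not in")
  # negative unmixing noise is clipped to zero (dab is the second stain)
  cm$conc[, , 2] <- -0.5
  expect_true(all(dab_anomaly_map(cm)$map == 0))
})

test_that("DAB support in the anomaly map matches the generator's area", {
  rec <- render_patch(quiet_spec(dab_area_fraction = 0.2, dab_mean_od = 0.8,
                                 seed = 21))
  am <- anomaly_map_from_image(rec$image)
  expect_equal(mean(am$map > 0.1), 0.2, tolerance = 0.02)
  # DAB-free negative patch: essentially empty map
  neg <- render_patch(quiet_spec(seed = 22))
  expect_lte(mean(anomaly_map_from_image(neg$image)$map), 0.02)
})

test_that("unmixing rendered patches recovers the scene concentrations", {
  # noise-free, unquantized: algebraically exact
  rec <- render_patch(quiet_spec(dab_area_fraction = 0.25, dab_mean_od = 0.9,
                                 seed = 31), quantize = FALSE)
  d <- deconvolution_matrix(stain_matrix_hdab())
  conc <- separate_stains(rgb_to_od(rec$image), d)$conc
  expect_lt(max(abs(conc[, , 1] - rec$conc$h)), 1e-3)
  expect_lt(max(abs(conc[, , 2] - rec$conc$dab)), 1e-3)
  # default stain-vector jitter + 8-bit quantization: small mean error
  recj <- render_patch(scene_spec(dab_area_fraction = 0.25, dab_mean_od = 0.9,
                                  stain_jitter_sd = 0.02, noise_sd = 0,
                                  seed = 32))
  concj <- separate_stains(rgb_to_od(recj$image), d)$conc
  err <- c(abs(concj[, , 1] - recj$conc$h), abs(concj[, , 2] - recj$conc$dab))
  expect_lte(mean(err), 0.05)
})

test_that("stain matrices round-trip through CSV and YAML", {
  sm <- stain_matrix_hed_raw()
  csv <- tempfile(fileext = ".csv")
  save_stain_matrix(sm, csv)
  expect_equal(as_matrix(load_stain_matrix(csv)), as_matrix(sm))
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("normalized: false", "stains:",
               "  - name: hematoxylin", "    od: [0.18, 0.20, 0.08]",
               "  - name: eosin", "    od: [0.01, 0.13, 0.01]",
               "  - name: dab", "    od: [0.10, 0.21, 0.29]"), yml)
  expect_equal(unname(as_matrix(load_stain_matrix(yml))),
               unname(as_matrix(sm)))
  # a 2-row CSV is completed to a full matrix
  csv2 <- tempfile(fileext = ".csv")
  m2 <- stain_matrix_hdab_raw()
  write.csv(data.frame(name = rownames(m2), R = m2[, 1], G = m2[, 2],
                       B = m2[, 3]), csv2, row.names = FALSE)
  expect_equal(as_matrix(load_stain_matrix(csv2)),
               as_matrix(stain_matrix_hdab()))
})

test_that("anomaly maps export as 8-bit grayscale PNG", {
  rec <- render_patch(quiet_spec(dab_area_fraction = 0.15, dab_mean_od = 0.7,
                                 seed = 41))
  am <- anomaly_map_from_image(rec$image)
  f <- tempfile(fileext = ".png")
  write_anomaly_png(am, f)
  back <- png::readPNG(f)
  expect_equal(dim(back), dim(am$map))
  expect_lt(max(abs(back - am$map)), 1 / 255)
})
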
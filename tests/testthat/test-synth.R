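test_that("scene rendering is a pure function of spec and seed", {
  sp <- scene_spec(dab_area_fraction = 0.1, dab_mean_od = 0.5,
                   stain_jitter_sd = 0.02, noise_sd = 2, seed = 5L)
  r1 <- render_patch(sp)
  r2 <- render_patch(sp)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$truth, r2$truth)
  # a different seed gives a different scene
  sp$seed <- 6L
  expect_false(identical(render_patch(sp)$image, r1$image))
})

test_that("rendered patches honour the requested scene statistics", {
  rec <- render_patch(quiet_spec(dab_area_fraction = 0.3, dab_mean_od = 0.8,
                                 seed = 9))
  # generator adds structures until the target is reached (upward overshoot)
  expect_gte(rec$truth$dab_area_fraction, 0.3)
  expect_lt(rec$truth$dab_area_fraction, 0.32)
  # separated DAB support matches the target area
  d <- deconvolution_matrix(stain_matrix_hdab())
  conc <- separate_stains(rgb_to_od(rec$image), d)$conc
  expect_equal(mean(conc[, , 2] > 0.1), 0.3, tolerance = 0.02)
  # DAB-free scene scores negative and leaves no anomaly signal
  neg <- render_patch(quiet_spec(seed = 10))
  expect_identical(neg$label, "negative")
  expect_lte(mean(anomaly_map_from_image(neg$image)$map), 0.02)
  # vessel-ribbon shapes reach the same area control
  rib <- render_patch(quiet_spec(dab_area_fraction = 0.15, dab_mean_od = 0.6,
                                 dab_shape = "vessel_ribbons", seed = 11))
  expect_gte(rib$truth$dab_area_fraction, 0.15)
  expect_lt(rib$truth$dab_area_fraction, 0.18)
})

test_that("semi-quantitative scoring follows the intensity and area bins", {
  expect_equal(score_patch(0, 0)[c("intensity_score", "proportion_score",
                                   "label")],
               list(intensity_score = 0L, proportion_score = 0L,
                    label = "negative"))
  top <- score_patch(1.0, 0.7)
  expect_equal(top$intensity_score, 3L)
  expect_equal(top$proportion_score, 4L)
  expect_identical(top$label, "strong_positive")
  # exhaustive check against an independent bin lookup over a value grid
  th <- default_score_thresholds()
  ods <- seq(0, 1.2, by = 0.05)
  afs <- seq(0, 0.9, by = 0.05)
  lookup_class <- c("negative", rep("weak_positive", 3), rep("positive", 2),
                    rep("strong_positive", 2))
  for (od in ods) for (af in afs) {
    si <- sum(od >= th$intensity[-1])
    sp_ <- sum(af >= th$proportion[-1])
    got <- score_patch(od, af, th)
    expect_equal(got$intensity_score, si)
    expect_equal(got$proportion_score, sp_)
    expect_identical(got$label, lookup_class[si + sp_ + 1])
  }
  bad <- default_score_thresholds()
  bad$intensity <- c(0, 0.4, 0.15, 0.8)
  expect_error(score_patch(0.5, 0.1, bad), "increasing")
})

test_that("generated datasets have exact counts, consistent labels and
           reproducible manifests", {
  ds <- generate_dataset(c(negative = 10, weak_positive = 5, positive = 5,
                           strong_positive = 5), seed = 3L)
  expect_equal(nrow(ds$manifest), 25)
  expect_equal(as.numeric(table(ds$manifest$label)[c("negative",
                                                     "weak_positive",
                                                     "positive",
                                                     "strong_positive")]),
               c(10, 5, 5, 5))
  # stored label always equals the score recomputed from the stored truth
  for (rec in ds$records) {
    expect_identical(score_patch(rec$truth$dab_mean_od,
                                 rec$truth$dab_area_fraction)$label,
                     rec$label)
  }
  ds2 <- generate_dataset(c(negative = 10, weak_positive = 5, positive = 5,
                            strong_positive = 5), seed = 3L)
  expect_identical(ds$manifest, ds2$manifest)
  expect_error(generate_dataset(c(negative = 2), class_specs = list(
    negative = list(od = c(0.5, 0.6), af = c(0.2, 0.3)))), "impossible")
})

test_that("dataset writing produces loadable PNGs and manifest", {
  dir <- file.path(tempdir(), "synthds")
  ds <- generate_dataset(c(negative = 1, weak_positive = 1, positive = 1,
                           strong_positive = 1), seed = 12L, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  recs <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(recs, 4)
  expect_equal(recs[[2]]$image, ds$records[[2]]$image)
  expect_identical(vapply(recs, `[[`, "", "label"),
                   vapply(ds$records, `[[`, "", "label"))
  unlink(dir, recursive = TRUE)
})

test_that("the default class-imbalance profile scales by half-up rounding", {
  expect_equal(unname(default_imbalance_counts()),
               c(2437, 606, 773, 742))
  expect_equal(unname(default_imbalance_counts(0.1)), c(244, 61, 77, 74))
})

test_that("stratified 7:3 splitting floors on the training side", {
  ids <- sprintf("r%04d", 1:2437)
  s <- split_dataset(ids, rep("negative", 2437), seed = 1)
  expect_length(s$train, 1705)
  expect_length(s$val, 732)
  # multi-class floor arithmetic
  labs <- rep(c("a", "b", "c"), c(424, 541, 519))
  ids <- sprintf("r%04d", seq_along(labs))
  s <- split_dataset(ids, labs, seed = 2)
  tr <- table(labs[match(s$train, ids)])
  va <- table(labs[match(s$val, ids)])
  expect_equal(as.numeric(tr[c("a", "b", "c")]), c(296, 378, 363))
  expect_equal(as.numeric(va[c("a", "b", "c")]), c(128, 163, 156))
  # disjoint, exhaustive, reproducible
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), ids)
  s2 <- split_dataset(ids, labs, seed = 2)
  expect_identical(s$train, s2$train)
  expect_length(split_dataset(letters[1:10], rep("x", 10), seed = 3)$train, 7)
  expect_error(split_dataset(character(), character(), seed = 1), "empty")
})

test_that("patchify tiles the slide and screens background", {
  white <- array(255, c(512, 512, 3))
  r <- patchify_and_screen(white)
  expect_equal(nrow(r$log), 4)
  expect_length(r$patches, 0)
  expect_equal(sum(r$log$kept) + sum(!r$log$kept), 4)
  # one fully stained quadrant survives screening
  stained <- white
  stained[1:256, 1:256, ] <- 60
  r <- patchify_and_screen(stained, tissue_fraction_min = 0.1)
  expect_length(r$patches, 1)
  expect_true(r$log$kept[r$log$row == 1 & r$log$col == 1])
  # kept set equals direct mask arithmetic on a graded slide
  grad <- array(255, c(512, 768, 3))
  fr <- c(0, 0.05, 0.12, 0.3, 0.6, 1)
  k <- 0
  for (i in 1:2) for (j in 1:3) {
    k <- k + 1
    npx <- round(fr[k] * 256)
    if (npx > 0)
      grad[(i - 1) * 256 + seq_len(npx), (j - 1) * 256 + 1:256, ] <- 50
  }
  r <- patchify_and_screen(grad, tissue_fraction_min = 0.1)
  expect_equal(r$log$kept, r$log$tissue_fraction >= 0.1)
  expect_equal(sum(r$log$kept), sum(fr >= 0.1))
  expect_error(patchify_and_screen(array(255, c(100, 100, 3))), "larger")
})

test_that("augmentation is label-preserving and seed-deterministic", {
  rec <- render_patch(quiet_spec(dab_area_fraction = 0.2, dab_mean_od = 0.275,
                                 seed = 14))
  img <- rec$image
  expect_identical(rotate90(img, 4), img)
  expect_identical(rotate90(rotate90(img, 1), 3), img)
  a1 <- augment(img, seed = 99)
  a2 <- augment(img, seed = 99)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 255))
  # maximum colour jitter cannot move a mid-bin patch across a score bin:
  # re-estimate the DAB OD of the jittered patch inside the true DAB mask
  d <- deconvolution_matrix(stain_matrix_hdab())
  for (gain in c(0.95, 1.05)) {
    jit <- pmin(pmax(floor(img * gain + 0.5), 0), 255)
    conc <- separate_stains(rgb_to_od(jit), d)$conc
    od_est <- mean(conc[, , 2][rec$dab_mask])
    expect_identical(score_patch(od_est, rec$truth$dab_area_fraction)$label,
                     rec$label)
  }
})

test_that("wider intensity separation between classes raises a linear
           probe's accuracy on anomaly-map features", {
  # three positive grades share the same area range, so only the DAB
  # intensity gap (scaled around a common centre) controls separability
  probe_acc <- function(gap_scale, seed) {
    centres <- 0.6 + (c(0.3, 0.6, 0.9) - 0.6) * gap_scale
    gen <- function(n, s) {
      recs <- list()
      k <- 0
      for (cl in 1:3) for (i in seq_len(n)) {
        k <- k + 1
        sp <- scene_spec(patch_size = 128L, n_nuclei = 20L,
                         dab_area_fraction = runif(1, 0.15, 0.25),
                         dab_mean_od = centres[cl] + runif(1, -0.02, 0.02),
                         stain_jitter_sd = 0.04, noise_sd = 4,
                         seed = s * 10000L + k)
        rec <- render_patch(sp)
        rec$label <- as.character(cl)
        recs[[k]] <- rec
      }
      recs
    }
    feat <- function(records) t(vapply(records, function(r) {
      map <- anomaly_map_from_image(r$image)$map
      sup <- map > 0.05
      c(mean(map), if (any(sup)) mean(map[sup]) else 0)
    }, c(0, 0)))
    lab <- function(records) vapply(records, `[[`, "", "label")
    set.seed(seed)
    tr <- gen(8, seed)
    va <- gen(5, seed + 500)
    X <- feat(tr); y <- lab(tr)
    centroids <- do.call(rbind, lapply(unique(y), function(cl)
      colMeans(X[y == cl, , drop = FALSE])))
    rownames(centroids) <- unique(y)
    Xv <- feat(va)
    pred <- rownames(centroids)[apply(Xv, 1, function(v)
      which.min(colSums((t(centroids) - v)^2)))]
    mean(pred == lab(va))
  }
  for (s in 1:3) {
    wide <- probe_acc(1.0, s)
    narrow <- probe_acc(0.3, s)
    expect_gte(wide, narrow)
  }
})
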
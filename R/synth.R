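# Forward simulator of labeled IHC patches. Scenes are built in concentration
# space (hematoxylin nuclei + DAB-positive structures), pushed through the
# Lambert-Beer law with unit-norm stain vectors, and quantized to 8-bit RGB.
# Because the renderer and the deconvolution share the same stain geometry,
# every generated patch carries exact per-pixel ground truth for the unmixing
# and the semi-quantitative score.

#' Scene specification for the patch simulator
#'
#' @param patch_size side length in pixels (default 256).
#' @param n_nuclei number of hematoxylin-stained nuclei.
#' @param nucleus_radius_range radius range in pixels.
#' @param dab_area_fraction target fraction of pixels covered by DAB-positive
#'   structures, in `[0, 1]`. Structures are added until the target is
#'   reached, so the achieved fraction (recorded in the truth) is the target
#'   plus at most one structure's area.
#' @param dab_mean_od DAB optical density (along the unit-norm DAB vector)
#'   inside positive structures; 0 = unstained.
#' @param dab_shape `"disks"` (cell-cluster-like blobs) or `"vessel_ribbons"`
#'   (random-walk ribbons emulating vessel cross-sections of a membrane
#'   marker).
#' @param stain_jitter_sd per-patch Gaussian jitter (OD units) applied to the
#'   raw stain vectors before renormalization; emulates staining variability.
#' @param noise_sd Gaussian pixel noise in 8-bit grey levels.
#' @param seed integer; every stochastic choice in the scene derives from it.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(patch_size = 256L, n_nuclei = 80L,
                       nucleus_radius_range = c(5, 9),
                       dab_area_fraction = 0, dab_mean_od = 0,
                       dab_shape = c("disks", "vessel_ribbons"),
                       stain_jitter_sd = 0, noise_sd = 0, seed = 1L) {
  dab_shape <- match.arg(dab_shape)
  if (dab_area_fraction < 0 || dab_area_fraction > 1)
    stop("dab_area_fraction must lie in [0, 1]")
  if (dab_mean_od < 0 || stain_jitter_sd < 0 || noise_sd < 0)
    stop("intensities and noise levels must be nonnegative")
  if (patch_size < 32) stop("patch_size too small")
  if (any(nucleus_radius_range <= 0) || diff(nucleus_radius_range) < 0)
    stop("invalid nucleus radius range")
  structure(as.list(environment()), class = "scene_spec")
}

disk_mask_add <- function(mask, cy, cx, r) {
  n <- nrow(mask)
  y0 <- max(1, floor(cy - r)); y1 <- min(n, ceiling(cy + r))
  x0 <- max(1, floor(cx - r)); x1 <- min(n, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(mask)
  ys <- y0:y1; xs <- x0:x1
  sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  mask[ys, xs] <- mask[ys, xs] | sub
  mask
}

# Add DAB structures until the covered fraction reaches the target.
dab_mask_build <- function(size, target, shape) {
  mask <- matrix(FALSE, size, size)
  if (target <= 0) return(mask)
  npx <- size * size
  guard <- 0L
  while (sum(mask) / npx < target && guard < 10000L) {
    guard <- guard + 1L
    if (shape == "disks") {
      r <- runif(1, 6, 12)
      mask <- disk_mask_add(mask, runif(1, 1, size), runif(1, 1, size), r)
    } else {
      # ribbon: correlated random walk stamped with disks of the half-width
      wid <- runif(1, 3, 6)
      len <- sample(30:80, 1)
      y <- runif(1, 1, size); x <- runif(1, 1, size)
      ang <- runif(1, 0, 2 * pi)
      for (s in seq_len(len)) {
        ang <- ang + rnorm(1, sd = 0.25)
        y <- y + 2 * sin(ang); x <- x + 2 * cos(ang)
        if (y < 1 || y > size || x < 1 || x > size) break
        mask <- disk_mask_add(mask, y, x, wid)
        if (sum(mask) / npx >= target) break
      }
    }
  }
  mask
}

jitter_rows <- function(raw_rows, sd) {
  j <- raw_rows + matrix(rnorm(length(raw_rows), sd = sd), nrow(raw_rows))
  j <- pmax(j, 1e-3)
  j / sqrt(rowSums(j^2))
}

#' Render a synthetic IHC patch
#'
#' Builds hematoxylin (nuclei) and DAB (positive structures) concentration
#' maps, mixes them into per-channel optical density with unit-norm
#' hematoxylin/DAB stain vectors (jittered per patch when
#' `stain_jitter_sd > 0`), converts to transmitted light via the Lambert-Beer
#' law, and adds Gaussian pixel noise. Deterministic given the spec (the
#' spec's `seed` drives all randomness).
#'
#' @param spec a [scene_spec()].
#' @param quantize round to 8-bit integers (default). Set `FALSE` to obtain
#'   the continuous transmitted intensities (used for algebraic round-trip
#'   checks; real images are always quantized).
#' @param thresholds score thresholds, see [score_patch()].
#' @return A `patch_record`: list with `image` (`size x size x 3`), `label`,
#'   `truth` (scores, achieved `dab_area_fraction`, `dab_mean_od`), `conc`
#'   (ground-truth `h` and `dab` concentration maps), `dab_mask`, `seed`.
#' @export
render_patch <- function(spec, quantize = TRUE,
                         thresholds = default_score_thresholds()) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  size <- spec$patch_size

  c_h <- matrix(0, size, size)
  for (i in seq_len(spec$n_nuclei)) {
    r <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
    cy <- runif(1, 1, size); cx <- runif(1, 1, size)
    dens <- runif(1, 0.4, 0.9)
    m <- disk_mask_add(matrix(FALSE, size, size), cy, cx, r)
    c_h <- pmax(c_h, dens * m)
  }

  dab_mask <- dab_mask_build(size, spec$dab_area_fraction, spec$dab_shape)
  c_d <- spec$dab_mean_od * dab_mask
  achieved <- sum(dab_mask) / (size * size)

  rows <- if (spec$stain_jitter_sd > 0)
    jitter_rows(stain_matrix_hdab_raw(), spec$stain_jitter_sd)
  else as_matrix(stain_matrix_hdab())[1:2, ]

  od <- array(0, c(size, size, 3))
  for (ch in 1:3) od[, , ch] <- c_h * rows[1, ch] + c_d * rows[2, ch]
  img <- od_to_rgb(od, quantize = FALSE)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 255)
  if (quantize) {
    img <- floor(img + 0.5)
    storage.mode(img) <- "integer"  # halves memory for bulk generation
  }

  sc <- score_patch(spec$dab_mean_od, achieved, thresholds)
  structure(list(image = img, label = sc$label,
                 truth = list(intensity_score = sc$intensity_score,
                              proportion_score = sc$proportion_score,
                              dab_area_fraction = achieved,
                              dab_mean_od = spec$dab_mean_od),
                 conc = list(h = c_h, dab = c_d),
                 dab_mask = dab_mask, seed = spec$seed, spec = spec),
            class = "patch_record")
}

#' Default semi-quantitative score thresholds
#'
#' Staining intensity (OD along the DAB vector) is scored 0-3 and the
#' positive-area proportion 0-4, each by lower-edge bins; the total score maps
#' to four classes. Bin edges and class cut points follow common
#' semi-quantitative practice and are fully configurable; they were fixed
#' before any model training and define the generator's class structure.
#'
#' @return list with `intensity` (4 lower edges), `proportion` (5 lower
#'   edges), `class_cuts` (upper total score per class, ascending).
#' @export
default_score_thresholds <- function() {
  list(intensity = c(0, 0.15, 0.4, 0.8),
       proportion = c(0, 0.01, 0.1, 0.33, 0.66),
       class_cuts = c(negative = 0, weak_positive = 3, positive = 5,
                      strong_positive = 7))
}

#' Score a patch on the intensity + proportion scale
#'
#' Intensity score: the bin of `dab_mean_od` among the intensity lower edges
#' (0-3). Proportion score: the bin of `dab_area_fraction` (0-4). The class is
#' looked up from the total score (sum of the two) against the class cut
#' points: by default 0 = negative, 1-3 = weak, 4-5 = positive, 6-7 = strong.
#'
#' @param dab_mean_od DAB optical density of positive regions.
#' @param dab_area_fraction fraction of positive pixels.
#' @param thresholds see [default_score_thresholds()].
#' @return list with `intensity_score`, `proportion_score`, `total`, `label`.
#' @export
score_patch <- function(dab_mean_od, dab_area_fraction,
                        thresholds = default_score_thresholds()) {
  ti <- thresholds$intensity; tp <- thresholds$proportion
  if (is.unsorted(ti, strictly = TRUE) || is.unsorted(tp, strictly = TRUE))
    stop("score thresholds must be strictly increasing")
  if (is.unsorted(thresholds$class_cuts, strictly = TRUE))
    stop("class cut points must be strictly increasing")
  si <- findInterval(dab_mean_od, ti[-1])
  sp <- findInterval(dab_area_fraction, tp[-1])
  total <- si + sp
  cls <- names(thresholds$class_cuts)[findInterval(total,
                                                   thresholds$class_cuts[-length(thresholds$class_cuts)] + 1L) + 1L]
  list(intensity_score = si, proportion_score = sp, total = total,
       label = cls)
}

#' Default per-class scene parameter ranges
#'
#' OD and area-fraction ranges sit well inside their score bins (with margin
#' for the generator's upward area overshoot), so every rendered patch's
#' recomputed score lands in the intended class.
#'
#' @return named list of lists with `od` and `af` ranges per class.
#' @export
default_class_specs <- function() {
  list(negative        = list(od = c(0, 0),       af = c(0, 0)),
       weak_positive   = list(od = c(0.2, 0.35),  af = c(0.03, 0.08)),
       positive        = list(od = c(0.45, 0.7),  af = c(0.15, 0.3)),
       strong_positive = list(od = c(0.85, 1.1),  af = c(0.4, 0.6)))
}

#' Default class-imbalance profile
#'
#' Per-class patch counts mimicking the imbalance of a typical single-marker
#' IHC patch collection (negative patches dominate roughly 4:1). `scale`
#' shrinks the profile with half-up rounding, e.g. `scale = 0.1` gives
#' 244 / 61 / 77 / 74.
#'
#' @param scale multiplier applied to the full-size counts.
#' @return named integer vector of per-class counts.
#' @export
default_imbalance_counts <- function(scale = 1) {
  full <- c(negative = 2437, weak_positive = 606, positive = 773,
            strong_positive = 742)
  v <- as.integer(floor(full * scale + 0.5))
  names(v) <- names(full)
  v
}

#' Generate a labeled synthetic dataset
#'
#' @param n_per_class named integer vector (names = class labels) or a single
#'   integer applied to all four default classes.
#' @param class_specs per-class `od`/`af` ranges; see [default_class_specs()].
#' @param seed master seed; each patch gets a sub-seed derived from it.
#' @param dir if non-`NULL`, write patches as PNGs plus a `manifest.csv`.
#' @param stain_jitter_sd,noise_sd,dab_shape passed to every [scene_spec()].
#' @return list with `records` (list of `patch_record`) and `manifest`
#'   (data.frame: id, path, label, scores, truth, seed). To bound memory in
#'   bulk generation, records keep the DAB mask but not the per-pixel
#'   concentration maps; call [render_patch()] directly when those are
#'   needed.
#' @export
generate_dataset <- function(n_per_class, class_specs = default_class_specs(),
                             seed = 1L, dir = NULL,
                             stain_jitter_sd = 0.02, noise_sd = 2,
                             dab_shape = "disks") {
  if (is.null(names(n_per_class))) {
    if (length(n_per_class) == 1)
      n_per_class <- setNames(rep(n_per_class, length(class_specs)),
                              names(class_specs))
    else stop("n_per_class must be named or scalar")
  }
  if (any(n_per_class < 0)) stop("counts must be nonnegative")
  thresholds <- default_score_thresholds()
  for (cl in names(n_per_class)) {
    cs <- class_specs[[cl]]
    if (is.null(cs)) stop("no class spec for '", cl, "'")
    # a class spec is impossible if its ranges can score outside the class
    for (od in cs$od) for (af in cs$af) {
      got <- score_patch(od, af, thresholds)$label
      if (got != cl)
        stop(sprintf("impossible class spec: %s ranges score as %s", cl, got))
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  records <- list()
  rows <- list()
  k <- 0L
  for (cl in names(n_per_class)) {
    cs <- class_specs[[cl]]
    for (i in seq_len(n_per_class[[cl]])) {
      k <- k + 1L
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1)
      od <- runif(1, cs$od[1], cs$od[2])
      af <- runif(1, cs$af[1], cs$af[2])
      sp <- scene_spec(dab_area_fraction = af, dab_mean_od = od,
                       dab_shape = dab_shape,
                       stain_jitter_sd = stain_jitter_sd,
                       noise_sd = noise_sd, seed = sub_seed)
      rec <- render_patch(sp, thresholds = thresholds)
      rec$conc <- NULL
      rec$id <- sprintf("patch_%05d", k)
      path <- NA_character_
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        path <- file.path(dir, paste0(rec$id, ".png"))
        png::writePNG(rec$image / 255, path)
      }
      records[[k]] <- rec
      rows[[k]] <- data.frame(id = rec$id, path = path, label = rec$label,
                              intensity_score = rec$truth$intensity_score,
                              proportion_score = rec$truth$proportion_score,
                              dab_area_fraction = rec$truth$dab_area_fraction,
                              dab_mean_od = rec$truth$dab_mean_od,
                              seed = sub_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(records = records, manifest = manifest)
}

#' Stratified train/validation split
#'
#' Splits records per class at the given ratio with the floor on the training
#' side: a class of 2,437 records at 7:3 yields 1,705 train / 732 validation.
#'
#' @param ids record ids (character) or a manifest data.frame with `id` and
#'   `label` columns.
#' @param labels class labels aligned with `ids` (ignored when `ids` is a
#'   manifest).
#' @param ratio length-2 numeric train:validation ratio (default `c(7, 3)`).
#' @param stratified split within each class (default) or overall.
#' @param seed shuffle seed.
#' @return A `split_manifest`: list with `train`, `val` (id vectors), `ratio`,
#'   `seed`, `stratified`.
#' @export
split_dataset <- function(ids, labels = NULL, ratio = c(7, 3),
                          stratified = TRUE, seed = 1L) {
  if (is.data.frame(ids)) {
    labels <- ids$label
    ids <- ids$id
  }
  if (!length(ids)) stop("empty record set: nothing to split")
  frac <- ratio[1] / sum(ratio)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (stratified) {
    if (is.null(labels)) stop("stratified split needs labels")
    if (any(table(labels) < 1)) stop("empty class in stratified split")
    train <- character()
    for (cl in unique(labels)) {
      cid <- ids[labels == cl]
      n_tr <- floor(length(cid) * frac)
      train <- c(train, sample(cid)[seq_len(n_tr)])
    }
  } else {
    train <- sample(ids)[seq_len(floor(length(ids) * frac))]
  }
  structure(list(train = sort(train), val = sort(setdiff(ids, train)),
                 ratio = ratio, seed = seed, stratified = stratified),
            class = "split_manifest")
}

#' Tile a slide into patches and screen out background
#'
#' Non-overlapping grid tiling; a tile is kept iff the fraction of "tissue"
#' pixels (mean optical density over channels above `od_threshold`) reaches
#' `tissue_fraction_min`. A pure-white slide keeps nothing.
#'
#' @param slide `H x W x 3` array in `[0, 255]`, at least one patch in size.
#' @param patch_size tile side (default 256).
#' @param tissue_fraction_min minimum tissue fraction to keep a tile.
#' @param od_threshold mean OD above which a pixel counts as tissue.
#' @return list with `patches` (kept tiles) and `log` (data.frame: one row per
#'   tile with `row`, `col`, `tissue_fraction`, `kept`).
#' @export
patchify_and_screen <- function(slide, patch_size = 256L,
                                tissue_fraction_min = 0.1,
                                od_threshold = 0.15) {
  d <- dim(slide)
  if (length(d) != 3 || d[3] != 3) stop("slide must be H x W x 3")
  if (d[1] < patch_size || d[2] < patch_size)
    stop("patch_size larger than the slide")
  nr <- d[1] %/% patch_size
  nc <- d[2] %/% patch_size
  patches <- list()
  logs <- list()
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1L
    tile <- slide[(i - 1) * patch_size + seq_len(patch_size),
                  (j - 1) * patch_size + seq_len(patch_size), , drop = FALSE]
    od <- rgb_to_od(tile)$od
    tf <- mean((od[, , 1] + od[, , 2] + od[, , 3]) / 3 > od_threshold)
    kept <- tf >= tissue_fraction_min
    logs[[k]] <- data.frame(row = i, col = j, tissue_fraction = tf,
                            kept = kept)
    if (kept) patches[[length(patches) + 1L]] <- tile
  }
  list(patches = patches, log = do.call(rbind, logs))
}

# ---------------------------------------------------------------------------
# Augmentation
# ---------------------------------------------------------------------------

#' Rotate an image by a multiple of 90 degrees
#'
#' @param img `H x W` matrix or `H x W x C` array.
#' @param k number of counter-clockwise quarter turns.
#' @return rotated image.
#' @export
rotate90 <- function(img, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(img)
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  f <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (length(dim(img)) == 2) f(img)
  else {
    out <- vapply(seq_len(dim(img)[3]), function(c) f(img[, , c]),
                  f(img[, , 1]))
    out
  }
}

resize_bilinear <- function(img, H, W) {
  if (length(dim(img)) == 2) return(resize_bilinear_matrix(img, H, W))
  vapply(seq_len(dim(img)[3]),
         function(c) resize_bilinear_matrix(img[, , c], H, W),
         matrix(0, H, W))
}

#' Label-preserving augmentation of an 8-bit patch
#'
#' Random quarter-turn rotation, random crop-and-resize (scale in
#' `[crop_min, 1]`) and bounded per-channel gain jitter (factor in
#' `1 +/- jitter_max`). With the default `jitter_max = 0.05` the induced
#' optical-density shift is at most `log10(1.05) ~= 0.021`, well under half
#' the narrowest intensity-bin gap, so the semi-quantitative class cannot
#' flip.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param ops subset of `c("rotation", "crop", "color_jitter")`.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param crop_min minimum crop scale.
#' @param jitter_max maximum relative gain change per channel.
#' @return augmented `H x W x 3` array in `[0, 255]` (8-bit quantized).
#' @export
augment <- function(img, ops = c("rotation", "crop", "color_jitter"),
                    seed = 1L, crop_min = 0.85, jitter_max = 0.05) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- dim(img)[1]; W <- dim(img)[2]
  if ("rotation" %in% ops) img <- rotate90(img, sample(0:3, 1))
  if ("crop" %in% ops) {
    s <- runif(1, crop_min, 1)
    ch <- max(2L, round(H * s)); cw <- max(2L, round(W * s))
    y0 <- sample.int(H - ch + 1L, 1); x0 <- sample.int(W - cw + 1L, 1)
    img <- resize_bilinear(img[y0 + seq_len(ch) - 1L,
                               x0 + seq_len(cw) - 1L, , drop = FALSE], H, W)
  }
  if ("color_jitter" %in% ops) {
    g <- runif(3, 1 - jitter_max, 1 + jitter_max)
    for (c in 1:3) img[, , c] <- img[, , c] * g[c]
  }
  pmin(pmax(floor(img + 0.5), 0), 255)
}
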
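# Two-branch prior-guided classifier. The IHC branch runs the backbone on the
# RGB patch and (optionally) re-weights its features with the perception
# attention; the CD branch runs an independent backbone on the single-channel
# DAB anomaly map. Both branches are globally average-pooled, concatenated,
# LayerNorm-ed and mapped by one linear layer to class logits.

#' Model configuration
#'
#' @param backbone `"small_cnn"` (default; trains on a CPU in minutes) or
#'   `"resnet18"` (the full-scale reference architecture).
#' @param classes character vector of class names; default the four-level
#'   semi-quantitative DAB grading.
#' @param use_prior include the CD branch (backbone over the anomaly map)?
#' @param use_attention include the perception attention in the IHC branch?
#' @param channels `small_cnn` stage widths.
#' @param fwb_hidden hidden width of the feature weighting block.
#' @return A `pge_config`.
#' @export
pge_config <- function(backbone = "small_cnn",
                       classes = c("negative", "weak_positive", "positive",
                                   "strong_positive"),
                       use_prior = TRUE, use_attention = TRUE,
                       channels = c(8, 16, 32, 64), fwb_hidden = 16) {
  structure(list(backbone = backbone, classes = classes,
                 use_prior = use_prior, use_attention = use_attention,
                 channels = channels, fwb_hidden = fwb_hidden),
            class = "pge_config")
}

#' Initialize a model
#'
#' He-initialized weights throughout; no pretraining is required (an external
#' initializer can overwrite `model$ihc$layers` before training if desired).
#'
#' @param config a [pge_config()].
#' @param seed integer seed for weight initialization.
#' @return A `pge_model`.
#' @export
pge_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "pge_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ihc <- backbone(config$backbone, in_channels = 3, channels = config$channels)
  cd <- if (config$use_prior)
    backbone(config$backbone, in_channels = 1, channels = config$channels)
  c_feat <- ihc$out_channels
  fwb <- if (config$use_attention) fwb_init(c_feat, config$fwb_hidden)
  d_fuse <- c_feat * (1L + as.integer(config$use_prior))
  head <- list(ln = layer_layernorm(d_fuse),
               fc = layer_linear(d_fuse, length(config$classes)))
  # zero-initialized classifier: an untrained model emits uniform class
  # probabilities (cross-entropy exactly log K), a bias-free starting point
  head$fc$par$W[] <- 0
  structure(list(config = config, ihc = ihc, cd = cd, fwb = fwb, head = head),
            class = "pge_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

pge_count_params <- function(model) {
  n <- nn_count_params(model$ihc$layers)
  if (!is.null(model$cd)) n <- n + nn_count_params(model$cd$layers)
  if (!is.null(model$fwb)) n <- n + nn_count_params(model$fwb$layers)
  n + nn_count_params(list(model$head$ln, model$head$fc))
}

#' Global average pooling
#'
#' Spatial mean per channel: `h x w x c` (or `h x w x c x n`) to a length-c
#' vector (or `c x n` matrix).
#'
#' @param f feature tensor.
#' @return numeric vector (single image) or matrix `c x n`.
#' @export
global_pool <- function(f) {
  d <- dim(f)
  if (length(d) == 3) colMeans(matrix(f, nrow = d[1] * d[2]))
  else matrix(colMeans(matrix(f, nrow = d[1] * d[2])), d[3], d[4])
}

#' Fuse pooled branch features and classify
#'
#' Concatenates the pooled IHC and CD feature vectors, applies LayerNorm over
#' the concatenated axis, then one linear layer to class logits.
#'
#' @param fo pooled IHC features (length c, or `c x n`).
#' @param fp pooled CD features (same shape), or `NULL` for a single-branch
#'   head.
#' @param head a model head (`model$head`).
#' @return logits: length-K vector or `K x n` matrix.
#' @export
fuse_and_classify <- function(fo, fp, head) {
  single <- is.null(dim(fo))
  if (single) {
    fo <- matrix(fo)
    if (!is.null(fp)) fp <- matrix(fp)
  }
  if (!is.null(fp)) {
    if (nrow(fo) != nrow(fp)) stop("branch feature lengths differ")
    x <- rbind(fo, fp)
  } else x <- fo
  r1 <- nn_layer_fwd(head$ln, x, train = FALSE)
  r2 <- nn_layer_fwd(head$fc, r1$y, train = FALSE)
  if (single) as.numeric(r2$y) else r2$y
}

# Batched forward. x_rgb: 256 x 256 x 3 x n in [0,255]; x_map: 256 x 256 x n
# (or x 1 x n) in [0,1]. `gray` optionally supplies the downsampled grayscale
# stack (16 x 16 x n); it is a pure function of x_rgb, so callers that sweep
# epochs precompute it once. Returns logits K x n, cams 16 x 16 x n (if
# attention), caches for backward, and the (buffer-updated) model.
# `input_scaled = TRUE` promises that x_rgb is already (raw/255 - 0.5), x_map
# is already a shifted 4D array (map - 0.5) and gray is supplied; the training
# loop uses it to avoid rescaling the same tensors every epoch.
pge_forward <- function(model, x_rgb, x_map = NULL, train = FALSE,
                        gray = NULL, input_scaled = FALSE) {
  d <- dim(x_rgb)
  if (length(d) == 3) dim(x_rgb) <- c(d, 1)
  d <- dim(x_rgb)
  N <- d[4]
  cache <- list()
  xin <- if (input_scaled) x_rgb else x_rgb / 255 - 0.5
  bo <- backbone_forward(model$ihc, xin, train)
  model$ihc <- bo$backbone
  f <- bo$out
  cams <- NULL
  if (!is.null(model$fwb)) {
    if (is.null(gray)) {
      if (input_scaled)
        stop("input_scaled = TRUE requires a precomputed gray stack")
      gray <- vapply(seq_len(N),
                     function(n) grayscale_downsample(x_rgb[, , , n],
                                                      model$ihc$out_grid),
                     matrix(0, model$ihc$out_grid[1], model$ihc$out_grid[2]))
    }
    at <- attention_fwd(f, gray, model$fwb, train)
    model$fwb <- at$fwb
    cams <- at$cam
    cache$at <- at$cache
    f_att <- at$out
  } else f_att <- f
  fo <- global_pool(f_att)
  fp <- NULL
  if (!is.null(model$cd)) {
    if (is.null(x_map)) stop("model has a CD branch but no anomaly map input")
    if (!input_scaled) {
      dm <- dim(x_map)
      if (length(dm) == 2) dim(x_map) <- c(dm, 1, 1)
      else if (length(dm) == 3) dim(x_map) <- c(dm[1], dm[2], 1, dm[3])
      x_map <- x_map - 0.5
    }
    if (dim(x_map)[4] != N || !all(dim(x_map)[1:2] == d[1:2]))
      stop("anomaly map batch misaligned with RGB batch")
    bp <- backbone_forward(model$cd, x_map, train)
    model$cd <- bp$backbone
    fp <- global_pool(bp$out)
    cache$bp <- bp$caches
    cache$fp_dim <- dim(bp$out)
  }
  x <- if (is.null(fp)) fo else rbind(fo, fp)
  r1 <- nn_layer_fwd(model$head$ln, x, train)
  r2 <- nn_layer_fwd(model$head$fc, r1$y, train)
  cache$bo <- bo$caches
  cache$f_dim <- dim(f)
  cache$ln <- r1$cache
  cache$fc <- r2$cache
  cache$had_prior <- !is.null(fp)
  list(logits = r2$y, cams = cams, cache = cache, model = model)
}

# Backward from d(loss)/d(logits); returns gradients structured like the
# model's parameter tree.
pge_backward <- function(model, cache, glogits) {
  r2 <- nn_layer_bwd(model$head$fc, cache$fc, glogits)
  r1 <- nn_layer_bwd(model$head$ln, cache$ln, r2$gx)
  gx <- r1$gx
  c_feat <- model$ihc$out_channels
  gfo <- gx[seq_len(c_feat), , drop = FALSE]
  grads <- list(head = list(ln = r1$grads, fc = r2$grads))
  # un-pool: spread mean gradient over the grid
  hw <- prod(cache$f_dim[1:2])
  gf_att <- array(rep(as.numeric(gfo), each = hw) / hw, cache$f_dim)
  if (!is.null(model$fwb)) {
    ab <- attention_bwd(model$fwb, cache$at, gf_att)
    gf <- ab$gf
    grads$fwb <- ab$fwb_grads
  } else gf <- gf_att
  grads$ihc <- nn_backward(model$ihc$layers, cache$bo, gf)$grads
  if (cache$had_prior) {
    gfp <- gx[c_feat + seq_len(c_feat), , drop = FALSE]
    hwp <- prod(cache$fp_dim[1:2])
    gmap_f <- array(rep(as.numeric(gfp), each = hwp) / hwp, cache$fp_dim)
    grads$cd <- nn_backward(model$cd$layers, cache$bp, gmap_f)$grads
  }
  grads
}

#' Predict class logits for patches
#'
#' @param object a `pge_model`.
#' @param x_rgb `256 x 256 x 3 x n` (or single-image `256 x 256 x 3`) array
#'   in `[0, 255]`.
#' @param x_map matching anomaly maps in `[0, 1]` (`256 x 256 x n`); computed
#'   from `x_rgb` with [anomaly_map_from_image()] when the model has a CD
#'   branch and `x_map` is `NULL`.
#' @param ... unused.
#' @return list with `logits` (`K x n`), `class` (factor of predicted
#'   labels) and `cams` (`16 x 16 x n`, if the model uses attention).
#' @export
predict.pge_model <- function(object, x_rgb, x_map = NULL, ...) {
  d <- dim(x_rgb)
  if (length(d) == 3) dim(x_rgb) <- c(d, 1)
  if (!is.null(object$cd) && is.null(x_map)) {
    N <- dim(x_rgb)[4]
    x_map <- vapply(seq_len(N),
                    function(n) anomaly_map_from_image(x_rgb[, , , n])$map,
                    matrix(0, dim(x_rgb)[1], dim(x_rgb)[2]))
  }
  r <- pge_forward(object, x_rgb, x_map, train = FALSE)
  cls <- factor(object$config$classes[max.col(t(r$logits))],
                levels = object$config$classes)
  list(logits = r$logits, class = cls, cams = r$cams)
}

#' @export
print.pge_model <- function(x, ...) {
  cat(sprintf("<pge_model> backbone=%s, classes=%d, prior=%s, attention=%s, params=%s\n",
              x$config$backbone, length(x$config$classes),
              !is.null(x$cd), !is.null(x$fwb),
              format(pge_count_params(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Serializes the full model (weights, batch-norm buffers, config) with
#' `saveRDS`.
#'
#' @param model a `pge_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
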
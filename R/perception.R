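# IHC perception module: feature-importance attention over backbone features.
# The grayscale input, downsampled to the feature grid, gates per-channel
# normalized feature maps into "mask" images; a small feature-weighting block
# (FWB) scores each channel's importance; the scores combine the raw feature
# maps into a class activation map (CAM) that both re-weights the features
# (attention) and serves as the visual explanation.

#' Luminance conversion and area-average downsampling
#'
#' Converts an RGB patch to grayscale with ITU-R 601 luminance weights
#' (0.299, 0.587, 0.114), then block-averages down to the target grid and
#' rescales to `[0, 1]`. The target must divide the input evenly (256 -> 16
#' uses 16 x 16 blocks).
#'
#' @param image `H x W x 3` array in `[0, 255]` (or an `H x W` grayscale
#'   array, used as-is).
#' @param target integer vector `(h, w)`, default `c(16, 16)`.
#' @return `h x w` matrix in `[0, 1]`.
#' @export
grayscale_downsample <- function(image, target = c(16L, 16L)) {
  if (length(dim(image)) == 3) {
    image <- as_rgb_array(image)
    g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else g <- image
  H <- nrow(g); W <- ncol(g)
  h <- target[1]; w <- target[2]
  if (H < h || W < w) stop("target larger than input: cannot upsample")
  if (H %% h != 0 || W %% w != 0)
    stop("target grid must divide the input dimensions evenly")
  fh <- H %/% h; fw <- W %/% w
  # block mean via two reshapes
  m <- matrix(colMeans(matrix(g, nrow = fh)), nrow = h)        # h x W
  m <- t(matrix(colMeans(matrix(t(m), nrow = fw)), nrow = w))  # h x w
  m / 255
}

#' Per-channel min-max normalization of a feature tensor
#'
#' Maps every channel of every image independently to `[0, 1]`. A constant
#' channel has no contrast to normalize and maps to all zeros.
#'
#' @param f array `h x w x c` (single image) or `h x w x c x n` (batch).
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_channels <- function(f) {
  single <- length(dim(f)) == 3
  if (single) dim(f) <- c(dim(f), 1)
  d <- dim(f)
  fm <- matrix(f, nrow = d[1] * d[2])  # columns: (channel, image)
  lo <- apply(fm, 2, min)
  rng <- apply(fm, 2, max) - lo
  out <- sweep(fm, 2, lo)
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, rng[pos], "/")
  out[, !pos] <- 0
  out <- array(out, d)
  if (single) dim(out) <- d[1:3]
  out
}

#' Build grayscale-gated mask images
#'
#' Elementwise product of the downsampled grayscale image with each
#' normalized feature channel: `M_c = gray * s(F_c)`.
#'
#' @param gray `h x w` matrix in `[0, 1]`.
#' @param f_norm `h x w x c` normalized feature tensor (see
#'   [normalize_channels()]).
#' @return `h x w x c` mask stack in `[0, 1]`.
#' @export
build_masks <- function(gray, f_norm) {
  d <- dim(f_norm)
  if (!all(dim(gray) == d[1:2]))
    stop("gray and feature spatial dims differ: [",
         paste(dim(gray), collapse = "x"), "] vs [",
         paste(d[1:2], collapse = "x"), "]")
  f_norm * as.numeric(gray)  # gray recycles over the channel dim
}

#' Combine channel scores into a class activation map
#'
#' `CAM = ReLU(sum_c S_c * F_c)`: a score-weighted sum of the raw feature
#' channels, rectified so only positively-contributing evidence remains.
#'
#' @param scores numeric length-c score vector.
#' @param f `h x w x c` feature tensor.
#' @return `h x w` nonnegative matrix.
#' @export
build_cam <- function(scores, f) {
  d <- dim(f)
  if (length(scores) != d[3])
    stop("score length ", length(scores), " != channel count ", d[3])
  cam <- matrix(matrix(f, ncol = d[3]) %*% scores, d[1], d[2])
  cam[cam < 0] <- 0
  cam
}

#' Apply CAM attention to a feature tensor
#'
#' Each channel is re-weighted elementwise by `(1 + CAM)`; a zero CAM leaves
#' the features exactly unchanged.
#'
#' @param cam `h x w` nonnegative matrix.
#' @param f `h x w x c` feature tensor.
#' @return `h x w x c` attention-weighted features.
#' @export
apply_attention <- function(cam, f) {
  d <- dim(f)
  if (!all(dim(cam) == d[1:2]))
    stop("cam and feature spatial dims differ")
  f * as.numeric(1 + cam)
}

# ---------------------------------------------------------------------------
# FWB: feature weighting block
# ---------------------------------------------------------------------------

# The scoring head reads the whole c-channel mask stack: two 3x3 conv layers
# with ReLU, global average pooling, a linear layer to c raw scores, and a
# sigmoid squashing them into (0, 1). Importance weights are nonnegative by
# construction (they weight, not sign, the feature channels), which fixes the
# CAM's orientation: with post-ReLU features, a score-weighted sum can only
# highlight regions of important-channel activity, never invert them.
fwb_init <- function(channels, hidden = 16) {
  list(channels = channels, hidden = hidden,
       layers = list(layer_conv(3, channels, hidden), layer_relu(),
                     layer_conv(3, hidden, hidden), layer_relu(),
                     layer_gap(),
                     layer_linear(hidden, channels)))
}

# masks: h x w x c x n -> scores c x n in (0, 1).
fwb_forward <- function(fwb, masks, train = FALSE) {
  d <- dim(masks)
  if (d[3] != fwb$channels)
    stop("mask stack has ", d[3], " channels, FWB expects ", fwb$channels)
  r <- nn_forward(fwb$layers, masks, train)
  fwb$layers <- r$layers
  scores <- 1 / (1 + exp(-r$out))
  list(scores = scores, caches = r$caches, fwb = fwb, mdim = d)
}

fwb_backward <- function(fwb, fw, gscores) {
  gpre <- gscores * fw$scores * (1 - fw$scores)
  r <- nn_backward(fwb$layers, fw$caches, gpre, need_gx = TRUE)
  list(gmasks = r$gx, grads = r$grads)
}

#' Compute FWB channel-importance scores
#'
#' Inference entry point for the feature weighting block: maps a mask stack
#' to one importance score per channel, squashed into `(0, 1)` by a sigmoid.
#' Deterministic for fixed weights.
#'
#' @param fwb an FWB head (from a [pge_init()] model, `model$fwb`).
#' @param masks `h x w x c` mask stack (see [build_masks()]).
#' @return numeric length-c score vector.
#' @export
fwb_scores <- function(fwb, masks) {
  d <- dim(masks)
  if (length(d) == 3) dim(masks) <- c(d, 1L)
  as.numeric(fwb_forward(fwb, masks)$scores)
}

# ---------------------------------------------------------------------------
# Batched attention stage used inside the model (forward + backward)
# ---------------------------------------------------------------------------

# f: 16 x 16 x c x n backbone features, gray: 16 x 16 x n.
# Returns attention-weighted features, per-image CAMs and a cache.
# Gradients flow to f along three paths: the (1+CAM) product, the CAM's
# score-weighted feature sum, and the mask stack (through the min-max
# normalization, whose per-channel min and range are treated as constants).
attention_fwd <- function(f, gray, fwb, train = FALSE) {
  d <- dim(f)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  fm <- matrix(f, nrow = hw)               # hw x (C*N)
  lo <- apply(fm, 2, min)
  rng <- apply(fm, 2, max) - lo
  inv <- ifelse(rng > 0, 1 / rng, 0)
  fnorm <- sweep(sweep(fm, 2, lo), 2, inv, "*")
  fnorm[, rng <= 0] <- 0
  gmat <- matrix(gray, nrow = hw)          # hw x N
  gidx <- rep(seq_len(N), each = C)
  masks <- fnorm * gmat[, gidx]            # hw x (C*N)
  marr <- array(masks, d)
  fw <- fwb_forward(fwb, marr, train)
  S <- fw$scores                           # C x N
  pre <- matrix(0, hw, N)
  for (n in seq_len(N))
    pre[, n] <- matrix(fm[, (n - 1) * C + seq_len(C)], ncol = C) %*% S[, n]
  cam <- pre
  cam[cam < 0] <- 0
  out <- fm * (1 + cam)[, gidx]
  list(out = array(out, d),
       cam = array(cam, c(d[1], d[2], N)),
       fwb = fw$fwb,
       cache = list(fm = fm, inv = inv, gmat = gmat, gidx = gidx, S = S,
                    pre = pre, cam = cam, fw = fw, d = d))
}

attention_bwd <- function(fwb, cache, gout) {
  d <- cache$d
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  go <- matrix(gout, nrow = hw)
  gf <- go * (1 + cache$cam)[, cache$gidx]
  # CAM path
  gS <- matrix(0, C, N)
  relu_mask <- cache$pre > 0
  for (n in seq_len(N)) {
    cols <- (n - 1) * C + seq_len(C)
    gcam <- rowSums(go[, cols, drop = FALSE] * cache$fm[, cols, drop = FALSE])
    gpre <- gcam * relu_mask[, n]
    gS[, n] <- crossprod(cache$fm[, cols, drop = FALSE], gpre)
    gf[, cols] <- gf[, cols] + outer(gpre, cache$S[, n])
  }
  # FWB path back to the features through the masks
  bw <- fwb_backward(fwb, cache$fw, gS)
  gmasks <- matrix(bw$gmasks, nrow = hw)
  gf <- gf + sweep(gmasks * cache$gmat[, cache$gidx], 2, cache$inv, "*")
  list(gf = array(gf, d), fwb_grads = bw$grads)
}

#' Export a CAM as a PNG heatmap
#'
#' Bilinearly upsamples a 16 x 16 CAM to the patch resolution, scales by the
#' per-image maximum and writes an 8-bit grayscale PNG.
#'
#' @param cam `h x w` nonnegative matrix.
#' @param path output path.
#' @param size output side length in pixels (default 256).
#' @return `path`, invisibly.
#' @export
write_cam_png <- function(cam, path, size = 256L) {
  up <- resize_bilinear_matrix(cam, size, size)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  png::writePNG(pmin(pmax(up, 0), 1), path)
  invisible(path)
}

# Bilinear resize of a matrix (align-corners = FALSE convention).
resize_bilinear_matrix <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  sy <- h / H; sx <- w / W
  yc <- pmin(pmax((seq_len(H) - 0.5) * sy - 0.5, 0), h - 1)
  xc <- pmin(pmax((seq_len(W) - 0.5) * sx - 0.5, 0), w - 1)
  y0 <- pmin(floor(yc), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(xc), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- yc - y0; wx <- xc - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx)
  b <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx)
  cc <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
  dd <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  a + b + cc + dd
}
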
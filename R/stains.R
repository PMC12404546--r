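#' @useDynLib ihcprior, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Optical-density transforms (Lambert-Beer law)
# ---------------------------------------------------------------------------

#' Convert a transmitted-light RGB image to optical density
#'
#' Brightfield microscopy follows the Lambert-Beer law: transmitted intensity
#' decays exponentially with stain amount, so the optical density
#' \eqn{OD_c = -\log_{10}(I_c / I_{0,c})} is linear in stain concentration and
#' is the space in which stains unmix additively.
#'
#' Zero transmitted light would give infinite OD; intensities are clamped to
#' `clamp` grey levels (default 1) before the logarithm so OD stays finite and
#' bounded by `log10(incident/clamp)`.
#'
#' @param image numeric array `H x W x 3` (or a single pixel of length 3) with
#'   values in `[0, 255]`.
#' @param incident incident light intensity \eqn{I_0} per channel
#'   (default 255, 8-bit white).
#' @param clamp lower clamp on transmitted intensity, in grey levels.
#' @return An `od_image`: list with `od` (same shape as `image`, nonnegative)
#'   and `incident`.
#' @export
#' @examples
#' od <- rgb_to_od(array(255, c(2, 2, 3)))
#' range(od$od)  # 0 0: white transmits fully
rgb_to_od <- function(image, incident = 255, clamp = 1) {
  if (incident <= 0) stop("incident intensity must be > 0")
  image <- as_rgb_array(image)
  od <- -log10(pmax(image, clamp) / incident)
  od <- pmax(od, 0)  # I > I0 (speckle above white) carries no stain signal
  structure(list(od = od, incident = incident), class = "od_image")
}

#' Convert optical density back to transmitted-light RGB
#'
#' Inverse of [rgb_to_od()]: \eqn{I_c = I_0 \cdot 10^{-OD_c}}.
#'
#' @param od an `od_image`, or a bare nonnegative array `H x W x 3`.
#' @param incident incident intensity; taken from the `od_image` if given.
#' @param quantize if `TRUE` (default) round half-up to integers and clip to
#'   `[0, 255]`; if `FALSE` return the continuous intensities.
#' @return numeric array of transmitted intensities, same shape as the input.
#' @export
od_to_rgb <- function(od, incident = NULL, quantize = TRUE) {
  if (inherits(od, "od_image")) {
    if (is.null(incident)) incident <- od$incident
    od <- od$od
  } else if (is.null(incident)) incident <- 255
  if (any(od < 0)) stop("negative optical density")
  img <- incident * 10^(-od)
  if (quantize) img <- pmin(pmax(floor(img + 0.5), 0), 255)  # half-up
  img
}

as_rgb_array <- function(image) {
  if (is.null(dim(image))) {
    if (length(image) != 3) stop("expected a 3-channel pixel or H x W x 3 array")
    image <- array(image, c(1, 1, 3))
  }
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an H x W x 3 array, got dims [", paste(d, collapse = ", "), "]")
  image
}

# ---------------------------------------------------------------------------
# Stain profiles and matrices
# ---------------------------------------------------------------------------

#' Create a stain profile
#'
#' A stain is characterised by its optical-density contributions in the R, G
#' and B channels, measured from a singly-stained slide. E.g. hematoxylin
#' absorbs mostly in R and G, giving OD roughly (0.18, 0.20, 0.08).
#'
#' @param name short stain name (e.g. `"hematoxylin"`, `"dab"`).
#' @param od numeric length-3 vector of nonnegative OD contributions (R, G, B).
#' @param allow_negative permit negative components. Measured stains absorb
#'   nonnegatively in every channel; only synthesized residual directions
#'   (see [complete_two_stain_matrix()]) may carry negative components.
#' @return A `stain_profile`.
#' @export
stain_profile <- function(name, od, allow_negative = FALSE) {
  od <- as.numeric(od)
  if (length(od) != 3) stop("stain OD vector must have length 3")
  if (!allow_negative && any(od < 0))
    stop("stain OD components must be nonnegative")
  structure(list(name = as.character(name)[1], od = od), class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat(sprintf("<stain_profile> %s: (%.4f, %.4f, %.4f)\n",
              x$name, x$od[1], x$od[2], x$od[3]))
  invisible(x)
}

#' Create a stain matrix
#'
#' Rows are stains, columns are R/G/B optical densities. Exactly three rows
#' are required for deconvolution; use [complete_two_stain_matrix()] to fill
#' in a residual third stain for two-stain protocols such as H-DAB.
#'
#' @param profiles a list of three [stain_profile()] objects, or a numeric
#'   `3 x 3` matrix (rows = stains) with optional rownames.
#' @param normalized whether rows are already unit-norm.
#' @return A `stain_matrix` with fields `profiles` and `normalized`.
#' @export
stain_matrix <- function(profiles, normalized = FALSE,
                         allow_negative = FALSE) {
  if (is.matrix(profiles)) {
    nm <- rownames(profiles)
    if (is.null(nm)) nm <- paste0("stain", seq_len(nrow(profiles)))
    profiles <- lapply(seq_len(nrow(profiles)),
                       function(i) stain_profile(nm[i], profiles[i, ],
                                                 allow_negative))
  }
  if (length(profiles) != 3) stop("a stain_matrix needs exactly 3 profiles")
  stopifnot(all(vapply(profiles, inherits, TRUE, "stain_profile")))
  sm <- structure(list(profiles = profiles, normalized = isTRUE(normalized)),
                  class = "stain_matrix")
  if (sm$normalized) {
    nrm <- sqrt(rowSums(as_matrix(sm)^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("normalized = TRUE but rows are not unit-norm")
  }
  sm
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat(sprintf("<stain_matrix>%s\n", if (x$normalized) " (normalized)" else ""))
  m <- as_matrix(x)
  print(round(m, 4))
  invisible(x)
}

#' Extract the numeric matrix of a `stain_matrix`
#'
#' @param sm a `stain_matrix`.
#' @return numeric `3 x 3` matrix, rows named by stain.
#' @export
as_matrix <- function(sm) {
  m <- do.call(rbind, lapply(sm$profiles, `[[`, "od"))
  rownames(m) <- stain_names(sm)
  colnames(m) <- c("R", "G", "B")
  m
}

#' @rdname as_matrix
#' @export
stain_names <- function(sm) vapply(sm$profiles, `[[`, "", "name")

#' Normalize a stain matrix to unit row norms
#'
#' Each stain's OD vector is divided by its Euclidean length so that unit
#' concentration corresponds to unit optical density along the stain
#' direction; this balances the absorption factors of the individual stains
#' before inversion.
#'
#' @param raw a `stain_matrix`.
#' @return A normalized `stain_matrix`.
#' @export
normalize_stain_matrix <- function(raw) {
  m <- as_matrix(raw)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12))
    stop("degenerate stain: all-zero OD row cannot be normalized")
  stain_matrix(m / nrm, normalized = TRUE)
}

#' Complete a two-stain matrix with a residual third stain
#'
#' Two-stain protocols (e.g. hematoxylin + DAB) give a 2 x 3 OD matrix, but
#' deconvolution needs a full rank-3 system. Following standard
#' colour-deconvolution practice, the residual third direction is the unit
#' cross product of the two normalized stain vectors: exactly orthogonal to
#' both, so the residual channel absorbs only what the two dyes cannot
#' explain and never leaks into their concentration estimates. Its
#' components may be negative (it is a direction, not a measured stain).
#'
#' @param two_rows numeric `2 x 3` matrix (rows = stains, optionally named),
#'   or a list of two [stain_profile()]s.
#' @param residual_name name for the synthesized third stain.
#' @return A normalized `stain_matrix` with three rows.
#' @export
complete_two_stain_matrix <- function(two_rows, residual_name = "residual") {
  if (is.list(two_rows) && !is.matrix(two_rows)) {
    nm <- vapply(two_rows, `[[`, "", "name")
    two_rows <- do.call(rbind, lapply(two_rows, `[[`, "od"))
    rownames(two_rows) <- nm
  }
  if (!is.matrix(two_rows) || nrow(two_rows) != 2 || ncol(two_rows) != 3)
    stop("expected a 2 x 3 stain matrix")
  nm <- rownames(two_rows)
  if (is.null(nm)) nm <- c("stain1", "stain2")
  u <- two_rows[1, ] / sqrt(sum(two_rows[1, ]^2))
  v <- two_rows[2, ] / sqrt(sum(two_rows[2, ]^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(w^2)) < 1e-8)
    stop("degenerate stain pair: rows are (near-)parallel")
  w <- w / sqrt(sum(w^2))
  if (sum(w) < 0) w <- -w  # orient towards the positive octant
  m <- rbind(u, v, w)
  rownames(m) <- c(nm, residual_name)
  stain_matrix(m, normalized = TRUE, allow_negative = TRUE)
}

# ---------------------------------------------------------------------------
# Deconvolution
# ---------------------------------------------------------------------------

#' Compute the colour-deconvolution matrix
#'
#' Inverts a normalized stain matrix. With column OD vector \eqn{y} per pixel
#' and concentration vector \eqn{C}, mixing is \eqn{y = \hat{M}^\top C}; the
#' deconvolution matrix is \eqn{D = (\hat{M}^\top)^{-1}} so that
#' \eqn{C = D\,y}. For the standard hematoxylin/eosin/DAB matrix this
#' reproduces the classical Ruifrok-Johnston deconvolution values (see
#' [deconvolution_matrix_hed()]).
#'
#' @param m_hat a normalized, invertible `stain_matrix`.
#' @return A `deconvolution_matrix`: list with `d` (3 x 3, rows named by
#'   stain so that `d %*% y` yields concentrations) and `source`.
#' @export
deconvolution_matrix <- function(m_hat) {
  if (!inherits(m_hat, "stain_matrix")) stop("expected a stain_matrix")
  if (!m_hat$normalized) stop("stain matrix must be normalized before inversion")
  m <- as_matrix(m_hat)
  kappa <- tryCatch(kappa(m, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e8)
    stop(sprintf("stain matrix is singular or ill-conditioned (condition number %.3g)",
                 kappa))
  d <- t(solve(m))
  rownames(d) <- rownames(m)
  colnames(d) <- c("R", "G", "B")
  structure(list(d = d, source = m_hat), class = "deconvolution_matrix")
}

#' @export
print.deconvolution_matrix <- function(x, ...) {
  cat("<deconvolution_matrix> C = D y, rows:\n")
  print(round(x$d, 4))
  invisible(x)
}

#' Unmix an OD image into per-stain concentrations
#'
#' Applies the deconvolution matrix to every pixel's OD vector, recovering the
#' contribution of each stain. Unmixing noise can produce small negative
#' concentrations; they are preserved here (clipping is a display choice made
#' by [dab_anomaly_map()]).
#'
#' @param od an `od_image` (or bare `H x W x 3` OD array).
#' @param d a `deconvolution_matrix`.
#' @return A `concentration_map`: list with `conc` (`H x W x 3`) and
#'   `stain_order`.
#' @export
separate_stains <- function(od, d) {
  if (!inherits(d, "deconvolution_matrix")) stop("expected a deconvolution_matrix")
  if (inherits(od, "od_image")) od <- od$od
  dm <- dim(od)
  if (length(dm) != 3 || dm[3] != 3)
    stop("expected an H x W x 3 OD array, got dims [", paste(dm, collapse = ", "), "]")
  conc <- matrix(od, ncol = 3) %*% t(d$d)  # per-pixel rows: y^T D^T = (D y)^T
  conc <- array(conc, dm)
  structure(list(conc = conc, stain_order = rownames(d$d)),
            class = "concentration_map")
}

#' Extract a normalized DAB anomaly map
#'
#' The single-channel "colour anomaly map": the selected stain's concentration
#' channel, clipped to `[0, saturation_od]` and rescaled to `[0, 1]`. Pixel
#' value reflects local DAB (positive staining) amount; an unstained white
#' patch maps to all zeros.
#'
#' @param conc a `concentration_map` from [separate_stains()].
#' @param stain stain name to extract (default `"dab"`, matched
#'   case-insensitively).
#' @param saturation_od OD at which the map saturates to 1 (default 1.0,
#'   a typical strong-DAB optical density).
#' @return An `anomaly_map`: list with `map` (`H x W` in `[0, 1]`) and `stain`.
#' @export
dab_anomaly_map <- function(conc, stain = "dab", saturation_od = 1.0) {
  if (!inherits(conc, "concentration_map")) stop("expected a concentration_map")
  idx <- match(tolower(stain), tolower(conc$stain_order))
  if (is.na(idx))
    stop(sprintf("stain '%s' not in stain order [%s]", stain,
                 paste(conc$stain_order, collapse = ", ")))
  m <- pmin(pmax(conc$conc[, , idx], 0), saturation_od) / saturation_od
  structure(list(map = m, stain = conc$stain_order[idx]), class = "anomaly_map")
}

#' Full pipeline: RGB patch to DAB anomaly map
#'
#' Convenience wrapper: RGB to OD, unmix with the (completed, normalized)
#' hematoxylin-DAB matrix, extract the DAB channel.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param deconv a `deconvolution_matrix`; default: the completed normalized
#'   H-DAB matrix.
#' @param stain,saturation_od passed to [dab_anomaly_map()].
#' @inheritParams rgb_to_od
#' @return An `anomaly_map`.
#' @export
anomaly_map_from_image <- function(image, deconv = NULL, stain = "dab",
                                   saturation_od = 1.0, incident = 255) {
  if (is.null(deconv)) deconv <- deconvolution_matrix(stain_matrix_hdab())
  od <- rgb_to_od(image, incident = incident)
  dab_anomaly_map(separate_stains(od, deconv), stain = stain,
                  saturation_od = saturation_od)
}

#' Re-render an anomaly map as an RGB image (visualization only)
#'
#' Renders the extracted stain channel back through the Lambert-Beer law using
#' the stain's own colour, reproducing the familiar "brown-only" view.
#'
#' @param amap an `anomaly_map`.
#' @param profile a [stain_profile()] giving the render colour; default the
#'   unit-norm DAB vector.
#' @param saturation_od OD assigned to map value 1.
#' @return `H x W x 3` array of 8-bit intensities.
#' @export
anomaly_to_rgb <- function(amap, profile = NULL, saturation_od = 1.0) {
  if (is.null(profile)) {
    m <- as_matrix(stain_matrix_hdab())
    profile <- stain_profile("dab", m["dab", ])
  }
  od <- outer(amap$map * saturation_od, profile$od)
  od_to_rgb(od)
}

# ---------------------------------------------------------------------------
# Built-in stain constants (Ruifrok-Johnston H/E/DAB measurements)
# ---------------------------------------------------------------------------

#' Built-in stain matrices
#'
#' Classical single-stain OD measurements for hematoxylin, eosin and DAB:
#' `stain_matrix_hed_raw()` returns the raw H/E/DAB matrix,
#' `stain_matrix_hed_normalized()` its published row-normalized form (rounded
#' to two decimals as conventionally printed), and `stain_matrix_hdab()` the
#' two-stain hematoxylin+DAB matrix completed with a residual channel and
#' normalized. `deconvolution_matrix_hed()` returns the published
#' deconvolution matrix paired with the printed normalized H/E/DAB source.
#'
#' The printed normalized matrix and its printed inverse derive from unrounded
#' source measurements, so recomputing either from the two-decimal published
#' values reproduces the other only to about +/- 0.02 per entry.
#'
#' @return A `stain_matrix` (or, for `deconvolution_matrix_hed`, a
#'   `deconvolution_matrix`).
#' @export
stain_matrix_hed_raw <- function() {
  m <- rbind(hematoxylin = c(0.18, 0.20, 0.08),
             eosin       = c(0.01, 0.13, 0.01),
             dab         = c(0.10, 0.21, 0.29))
  stain_matrix(m)
}

#' @rdname stain_matrix_hed_raw
#' @export
stain_matrix_hed_normalized <- function() {
  m <- rbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin       = c(0.07, 0.99, 0.11),
             dab         = c(0.27, 0.57, 0.78))
  sm <- stain_matrix(m)
  sm$normalized <- TRUE  # published rounded values; norms are 1 to ~1e-2
  sm
}

#' @rdname stain_matrix_hed_raw
#' @export
stain_matrix_hdab_raw <- function() {
  rbind(hematoxylin = c(0.18, 0.20, 0.08),
        dab         = c(0.10, 0.21, 0.29))
}

#' @rdname stain_matrix_hed_raw
#' @export
stain_matrix_hdab <- function() {
  complete_two_stain_matrix(stain_matrix_hdab_raw())
}

#' @rdname stain_matrix_hed_raw
#' @export
deconvolution_matrix_hed <- function() {
  d <- rbind(hematoxylin = c(1.88, -0.07, -0.60),
             eosin       = c(-1.02, 1.13, -0.48),
             dab         = c(-0.55, -0.13, 1.57))
  colnames(d) <- c("R", "G", "B")
  structure(list(d = d, source = stain_matrix_hed_normalized()),
            class = "deconvolution_matrix")
}

# ---------------------------------------------------------------------------
# IO
# ---------------------------------------------------------------------------

#' Read and write stain matrices
#'
#' `load_stain_matrix()` reads a stain matrix from YAML (`stains:` list of
#' `name` + `od`) or CSV (columns `name, R, G, B`); `save_stain_matrix()`
#' writes the CSV form.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` or `.csv`).
#' @param sm a `stain_matrix`.
#' @return `load_stain_matrix`: a `stain_matrix` (2-row CSVs are completed via
#'   [complete_two_stain_matrix()]).
#' @export
load_stain_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    rows <- y$stains
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r$od)))
    rownames(m) <- vapply(rows, function(r) r$name, "")
    normalized <- isTRUE(y$normalized)
  } else if (ext == "csv") {
    d <- read.csv(path, stringsAsFactors = FALSE)
    m <- as.matrix(d[, c("R", "G", "B")])
    rownames(m) <- d$name
    normalized <- FALSE
  } else stop("unsupported stain matrix format: .", ext)
  if (nrow(m) == 2) return(complete_two_stain_matrix(m))
  if (nrow(m) != 3) stop("expected 2 or 3 stain rows, got ", nrow(m))
  stain_matrix(m, normalized = if (exists("normalized")) normalized else FALSE)
}

#' @rdname load_stain_matrix
#' @export
save_stain_matrix <- function(sm, path) {
  m <- as_matrix(sm)
  write.csv(data.frame(name = rownames(m), R = m[, 1], G = m[, 2], B = m[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

#' Write an anomaly map as an 8-bit grayscale PNG
#'
#' @param amap an `anomaly_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_anomaly_png <- function(amap, path) {
  png::writePNG(pmin(pmax(amap$map, 0), 1), path)
  invisible(path)
}
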
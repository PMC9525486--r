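# Synthetic fixtures with analytically known ground truth: toy label volumes,
# degenerate/analytic dose kernels, and immunohistochemistry-style section
# images. Everything is generated in code; no external data.

#' Make a toy label volume with known structure
#'
#' @param kind `"checkerboard"` (period-2 tumor/CAF alternation: every tumor
#'   voxel is face-adjacent to a CAF, L = spacing everywhere),
#'   `"stripes"` (CAF sheets of width 1 separating tumor stripes of width
#'   `width`: interior-stripe L_mean = spacing * (width + 1) / 2),
#'   `"shell"` (central tumor ball with a peripheral CAF shell), or
#'   `"blob"` (thresholded smooth random field).
#' @param size edge length in voxels (cube), <= 64 for test-tier fixtures.
#' @param spacing_um voxel spacing (default 20).
#' @param width tumor stripe width in voxels (stripes only).
#' @param scale_um correlation length (blob only).
#' @param tumor_fraction target tumor fraction (shell/blob only).
#' @param seed RNG seed (blob only).
#' @param density density recorded in the volume, g/cm^3.
#' @return a `label_volume` covering the full cube (no outside voxels except
#'   for `"shell"`, which keeps the cube inside).
#' @export
make_toy_labelmap <- function(kind = c("checkerboard", "stripes", "shell", "blob"),
                              size = 16L, spacing_um = 20, width = 3L,
                              scale_um = 120, tumor_fraction = 0.75,
                              seed = 1L, density = 1.05) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size > 64L) stop("test-tier fixtures are capped at 64^3")
  n <- c(size, size, size)
  idx <- function(axis) {
    v <- seq_len(size)
    if (axis == 1) array(v, n)
    else if (axis == 2) array(rep(v, each = size), n)
    else array(rep(v, each = size * size), n)
  }
  labels <- switch(kind,
    checkerboard = {
      par <- (idx(1) + idx(2) + idx(3)) %% 2L
      array(ifelse(par == 0L, 1L, 2L), n)
    },
    stripes = {
      period <- width + 1L
      array(ifelse(idx(1) %% period == 0L, 2L, 1L), n)
    },
    shell = {
      cc <- (idx(1) - (size + 1) / 2)^2 + (idx(2) - (size + 1) / 2)^2 +
            (idx(3) - (size + 1) / 2)^2
      R <- (size - 1) / 2
      inside <- cc <= R^2
      r_t <- stats::quantile(sqrt(cc[inside]), tumor_fraction, names = FALSE)
      array(ifelse(!inside, 0L, ifelse(sqrt(cc) <= r_t, 1L, 2L)), n)
    },
    blob = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed)
      noise <- array(rnorm(prod(n)), n)
      sig <- scale_um / 2 / spacing_um
      g <- exp(-0.5 * (pmin(seq_len(size) - 1, size - (seq_len(size) - 1)) / sig)^2)
      K <- array(g, n) * array(rep(g, each = size), n) *
           array(rep(g, each = size * size), n)
      sm <- Re(fft(fft(noise) * fft(K / sum(K)), inverse = TRUE)) / prod(n)
      thr <- stats::quantile(sm, tumor_fraction, names = FALSE)
      array(ifelse(sm <= thr, 1L, 2L), n)
    })
  structure(list(labels = labels,
                 grid = grid_spec(spacing_um, n, "center"),
                 density = density,
                 provenance = list(morphology = paste0("toy-", kind),
                                   scale = scale_um, seed = seed)),
            class = "label_volume")
}

#' Make an analytic test kernel
#'
#' @param kind `"delta"` (all dose in the central voxel), `"flat"` (uniform
#'   over the cube), or `"gaussian"` (isotropic Gaussian of standard deviation
#'   `sigma_vox` voxels).
#' @param shape odd cube edge length in voxels.
#' @param total_Gy_per_decay total kernel sum (Gy/decay), default 1.
#' @param spacing_um voxel spacing, default 20.
#' @param sigma_vox Gaussian width in voxels (gaussian only).
#' @return a `dose_kernel`.
#' @export
make_test_kernel <- function(kind = c("delta", "flat", "gaussian"), shape = 9L,
                             total_Gy_per_decay = 1, spacing_um = 20,
                             sigma_vox = 1.5) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (shape %% 2L == 0L) stop("kernel shape must be odd")
  n <- rep(shape, 3L)
  c0 <- (shape + 1L) / 2L
  values <- switch(kind,
    delta = { v <- array(0, n); v[c0, c0, c0] <- total_Gy_per_decay; v },
    flat = array(total_Gy_per_decay / prod(n), n),
    gaussian = {
      x <- seq_len(shape) - c0
      r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
      v <- exp(-r2 / (2 * sigma_vox^2))
      v * total_Gy_per_decay / sum(v)
    })
  structure(list(values = values, spacing_um = spacing_um,
                 nuclide = paste0("synthetic-", kind), primaries = NA,
                 density = NA, symmetrized = TRUE),
            class = "dose_kernel")
}

#' Generate a synthetic immunohistochemistry-style section image
#'
#' Emulates a FAP-stained section: blue (hematoxylin-like) tumor nests
#' interleaved with red (FAP-positive) CAF regions on a white background
#' outside a tissue disc. The tumor/CAF partition is drawn at the requested
#' tumor ratio by quantile-thresholding a smooth random field (or periodic
#' cube field), so the ground-truth labels and their metrics are known
#' exactly and returned alongside the rendered image.
#'
#' @param size_px image edge length in pixels.
#' @param pixel_size_um pixel size, micrometres (<= 20; default 5).
#' @param tumor_ratio ground-truth tumor fraction of tissue (default 0.712).
#' @param scale_um characteristic tumor-nest size, micrometres.
#' @param noise_sd additive Gaussian channel noise SD (default 0: noiseless).
#' @param morphology `"blob-field"` or `"interspersed-cubes"` pattern.
#' @param seed RNG seed.
#' @return list with `image` (an `ihc_image`: h x w x 3 array in \\[0,1\\] with
#'   attribute `pixel_size_um`), `truth_labels` (matrix, 0 background,
#'   1 tumor, 2 CAF, at image resolution), `tumor_ratio`, and
#'   `truth_labels_20um` ground truth at the 20 um analysis grid with its
#'   `lmean_um`.
#' @export
make_synthetic_ihc <- function(size_px = 500L, pixel_size_um = 5,
                               tumor_ratio = 0.712, scale_um = 300,
                               noise_sd = 0, morphology = c("blob-field",
                                                            "interspersed-cubes"),
                               seed = 1L) {
  morphology <- match.arg(morphology)
  if (!(tumor_ratio > 0 && tumor_ratio < 1)) stop("tumor_ratio must be in (0,1)")
  if (pixel_size_um > 20) stop("pixel size must be <= 20 um")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  size_px <- as.integer(size_px)
  n <- c(size_px, size_px)
  xs <- (seq_len(size_px) - (size_px + 1) / 2) * pixel_size_um
  X <- matrix(xs, size_px, size_px)
  Y <- matrix(xs, size_px, size_px, byrow = TRUE)
  Rdisc <- 0.48 * size_px * pixel_size_um
  tissue <- X^2 + Y^2 <= Rdisc^2
  f <- if (morphology == "blob-field") {
    noise <- matrix(rnorm(prod(n)), n[1], n[2])
    sig <- scale_um / 2 / pixel_size_um
    g <- exp(-0.5 * (pmin(seq_len(size_px) - 1, size_px - (seq_len(size_px) - 1)) / sig)^2)
    K <- outer(g, g)
    Re(fft(fft(noise) * fft(K / sum(K)), inverse = TRUE)) / prod(n)
  } else {
    off <- runif(2, 0, scale_um)
    ux <- abs(((xs + off[1]) %% scale_um) / scale_um - 0.5)
    uy <- abs(((xs + off[2]) %% scale_um) / scale_um - 0.5)
    pmax(matrix(ux, n[1], n[2]), matrix(uy, n[1], n[2], byrow = TRUE))
  }
  fv <- f[tissue] + runif(sum(tissue)) * 1e-9
  k_t <- round(tumor_ratio * length(fv))
  if (k_t < 1 || k_t >= length(fv)) stop("infeasible tumor_ratio for this size")
  thr <- sort(fv, partial = k_t)[k_t]
  labels <- matrix(0L, n[1], n[2])
  labels[tissue] <- ifelse(fv <= thr, 1L, 2L)
  # render: tumor = hematoxylin blue, CAF = FAP red, background = white
  img <- array(1, c(n, 3L))
  col_t <- c(0.25, 0.30, 0.75)
  col_c <- c(0.85, 0.15, 0.20)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[labels == 1L] <- col_t[ch]
    pl[labels == 2L] <- col_c[ch]
    if (noise_sd > 0) pl <- pl + rnorm(prod(n), 0, noise_sd)
    img[, , ch] <- pmin(pmax(pl, 0), 1)
  }
  attr(img, "pixel_size_um") <- pixel_size_um
  class(img) <- "ihc_image"
  # ground truth at the 20 um analysis grid: majority label per block
  truth20 <- .block_mode_labels(labels, pixel_size_um, 20)
  fld <- tryCatch(compute_nearest_caf_distances(truth20, spacing = 20),
                  error = function(e) NULL)
  list(image = img, truth_labels = labels,
       tumor_ratio = sum(labels == 1L) / sum(labels != 0L),
       truth_labels_20um = truth20,
       lmean_um = if (is.null(fld)) NA_real_ else l_mean(fld))
}

# majority-vote block downsampling of a 2D label matrix
.block_mode_labels <- function(labels, pixel_size_um, target_um) {
  fac <- round(target_um / pixel_size_um)
  nr <- nrow(labels) %/% fac
  nc <- ncol(labels) %/% fac
  lab <- labels[seq_len(nr * fac), seq_len(nc * fac)]
  counts <- vapply(0:2, function(v) {
    m <- matrix(as.numeric(lab == v), nrow(lab), ncol(lab))
    m <- rowsum(m, rep(seq_len(nr), each = fac))
    t(rowsum(t(m), rep(seq_len(nc), each = fac)))
  }, matrix(0, nr, nc))
  out <- apply(counts, c(1, 2), which.max) - 1L
  matrix(as.integer(out), nr, nc)
}
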
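# 2D immunohistochemistry-style analysis chain: block-mean downsampling to the
# 20 um cell grid, red/non-red CAF-vs-tumor segmentation, tumor ratio, and the
# 4-direction nearest-CAF distance distribution and mean.

#' Block-mean downsample an RGB section image to a coarser pixel size
#'
#' Averages non-overlapping blocks of pixels so the output pixel size equals
#' `target_um` (default 20, the analysis cell size). The input pixel size must
#' evenly divide the target (upsampling is refused). Trailing rows/columns that
#' do not fill a block are dropped.
#'
#' @param image an `ihc_image` (h x w x 3 array in \\[0,1\\] with attribute
#'   `pixel_size_um`) or plain array plus `pixel_size_um`.
#' @param target_um output pixel size, micrometres (default 20).
#' @param pixel_size_um input pixel size when `image` lacks the attribute.
#' @return downsampled `ihc_image` with `pixel_size_um = target_um`.
#' @export
downsample_to_20um <- function(image, target_um = 20, pixel_size_um = NULL) {
  ps <- attr(image, "pixel_size_um") %||% pixel_size_um
  if (is.null(ps)) stop("pixel size unknown")
  if (ps > target_um) stop("input pixel size exceeds the target: no upsampling")
  fac <- target_um / ps
  if (abs(fac - round(fac)) > 1e-8)
    stop("pixel size must evenly divide ", target_um, " um")
  fac <- as.integer(round(fac))
  nr <- dim(image)[1] %/% fac
  nc <- dim(image)[2] %/% fac
  out <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    m <- image[seq_len(nr * fac), seq_len(nc * fac), ch]
    m <- rowsum(m, rep(seq_len(nr), each = fac)) / fac
    out[, , ch] <- t(rowsum(t(m), rep(seq_len(nc), each = fac)) / fac)
  }
  attr(out, "pixel_size_um") <- target_um
  class(out) <- "ihc_image"
  out
}

#' Segment CAF (red) versus tumor (non-red) pixels
#'
#' A pixel is CAF when its redness score `r - max(g, b)` exceeds
#' `redness_threshold`; otherwise it is tumor if it belongs to tissue
#' (non-white), or background if near-white (`min(r,g,b) > white_threshold`).
#' Background pixels are excluded from all ratios.
#'
#' @param image an `ihc_image` (expected already downsampled to 20 um).
#' @param redness_threshold redness margin on \\[0,1\\] channels (default 0.15).
#' @param white_threshold minimum channel value above which a pixel counts as
#'   background (default 0.9).
#' @return integer label matrix: 0 background, 1 tumor, 2 CAF.
#' @export
segment_caf_tumor <- function(image, redness_threshold = 0.15,
                              white_threshold = 0.9) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  redness <- r - pmax(g, b)
  background <- pmin(r, pmin(g, b)) > white_threshold
  labels <- matrix(1L, nrow(r), ncol(r))
  labels[redness > redness_threshold] <- 2L
  labels[background & labels != 2L] <- 0L
  labels
}

#' Analyze a segmented section: tumor ratio, L distribution, L_mean
#'
#' Computes the tumor-to-CAF ratio over tissue pixels, the 4-direction
#' nearest-CAF distance for every tumor pixel ([compute_nearest_caf_distances()]
#' with rays stopped at background/image edge), a distance histogram in bins of
#' one pixel width, and the mean distance over defined pixels.
#'
#' @param labels integer label matrix (0 background, 1 tumor, 2 CAF), e.g.
#'   from [segment_caf_tumor()].
#' @param spacing_um pixel size, micrometres (default 20).
#' @return a `segmented_section`: list with `labels`, `tumor_ratio_pct`,
#'   `l_histogram` (data frame: `l_um`, `n`), `l_mean_um`,
#'   `undefined_fraction`.
#' @export
analyze_section <- function(labels, spacing_um = 20) {
  if (!any(labels == 2L)) stop("no CAF pixels: L is undefined everywhere")
  fld <- compute_nearest_caf_distances(labels, spacing = spacing_um)
  d <- fld$distance_um[is.finite(fld$distance_um)]
  steps <- sort(unique(d / spacing_um))
  hist <- data.frame(l_um = steps * spacing_um,
                     n = vapply(steps, function(s) sum(d == s * spacing_um), 0))
  structure(list(labels = labels,
                 tumor_ratio_pct = 100 * sum(labels == 1L) / sum(labels != 0L),
                 l_histogram = hist,
                 l_mean_um = mean(d),
                 undefined_fraction = undefined_fraction(fld)),
            class = "segmented_section")
}

#' Full synthetic-section pipeline: downsample, segment, analyze
#'
#' @param image an `ihc_image` at native resolution.
#' @param redness_threshold,white_threshold passed to [segment_caf_tumor()].
#' @return a `segmented_section` (see [analyze_section()]).
#' @export
analyze_ihc_image <- function(image, redness_threshold = 0.15,
                              white_threshold = 0.9) {
  ds <- downsample_to_20um(image)
  analyze_section(segment_caf_tumor(ds, redness_threshold, white_threshold),
                  spacing_um = 20)
}

#' @export
print.segmented_section <- function(x, ...) {
  cat(sprintf("<segmented_section> tumor ratio %.1f%%, L_mean %.0f um\n",
              x$tumor_ratio_pct, x$l_mean_um))
  invisible(x)
}
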
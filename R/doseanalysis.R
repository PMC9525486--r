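# Summary statistics of the dose microdistribution: cumulative dose-volume
# histograms, efficacy ratios (mean target dose over mean whole-mass dose),
# and the fraction of target voxels above a relative dose threshold.

.as_dose_array <- function(dose) {
  if (inherits(dose, "dose_map")) dose$dose_Gy else dose
}

#' Cumulative dose-volume histogram
#'
#' `volume_pct(d) = 100 * |{v in target : dose[v] >= d}| / |target|`,
#' evaluated at uniform dose edges from 0 to the target maximum. The curve
#' starts at 100% at dose 0 and is monotone non-increasing.
#'
#' @param dose a `dose_map` or dose array, Gy.
#' @param target_mask logical array selecting the target voxels (non-empty).
#' @param n_bins number of uniform bins (default 512).
#' @return a `dvh_curve` data frame: `dose_Gy`, `volume_pct`.
#' @export
cumulative_dvh <- function(dose, target_mask, n_bins = 512L) {
  d <- .as_dose_array(dose)[target_mask]
  if (!length(d)) stop("empty target mask")
  edges <- seq(0, max(d), length.out = n_bins + 1L)
  sorted <- sort(d)
  # voxels strictly below each edge; >= edge = n - below
  below <- findInterval(edges, sorted, left.open = TRUE)
  out <- data.frame(dose_Gy = edges,
                    volume_pct = 100 * (length(d) - below) / length(d))
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Efficacy ratio: mean target dose over mean whole-mass dose
#'
#' `ER = mean(dose | target) / mean(dose | SM)`. An ER of 1 means the target
#' received the same mean absorbed dose as the whole spherical mass; energy
#' escaping the mass is not part of either mean.
#'
#' @param dose a `dose_map` or dose array, Gy.
#' @param target_mask logical array, target voxels (subset of the mass).
#' @param sm_mask logical array, whole spherical-mass voxels.
#' @return efficacy ratio (dimensionless).
#' @export
efficacy_ratio <- function(dose, target_mask, sm_mask) {
  d <- .as_dose_array(dose)
  if (!any(target_mask) || !any(sm_mask)) stop("empty mask")
  if (any(target_mask & !sm_mask)) stop("target must be a subset of the mass")
  m_sm <- mean(d[sm_mask])
  if (m_sm == 0) stop("zero mean dose over the spherical mass")
  mean(d[target_mask]) / m_sm
}

#' Fraction of target voxels at or above a relative dose threshold
#'
#' The threshold is `fraction` times the maximum dose over the whole spherical
#' mass (not per-target). For low-count alpha runs a single hot voxel can
#' destabilize this max-normalized metric; `winsorize = TRUE` takes the
#' 99.99th percentile of the in-mass dose as the maximum instead.
#'
#' @param dose a `dose_map` or dose array, Gy.
#' @param target_mask logical array, target voxels.
#' @param sm_mask logical array, whole-mass voxels (defaults to `target_mask`).
#' @param fraction relative threshold in (0, 1), default 0.10.
#' @param winsorize logical, default `FALSE`.
#' @return percentage of target voxels receiving at least the threshold dose.
#' @export
fraction_above_relative_threshold <- function(dose, target_mask,
                                              sm_mask = target_mask,
                                              fraction = 0.10,
                                              winsorize = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  d <- .as_dose_array(dose)
  if (!any(target_mask)) stop("empty target mask")
  dsm <- d[sm_mask]
  mx <- if (winsorize) quantile(dsm, 1 - 1e-4, names = FALSE) else max(dsm)
  if (mx == 0) stop("all-zero dose over the mass")
  100 * mean(d[target_mask] >= fraction * mx)
}

#' Analyze all source/target pairings of a model
#'
#' Produces the six standard reports per nuclide: the four pairings
#' S(tumor <- tumor), S(CAF <- tumor), S(tumor <- CAF), S(CAF <- CAF) plus the
#' whole-mass targets S(SM <- tumor) and S(SM <- CAF). Each report carries the
#' efficacy ratio, mean doses, the fraction of target voxels at or above 10%
#' of the whole-mass maximum dose, and the cumulative DVH.
#'
#' @param labels a `label_volume` shared by both dose maps.
#' @param dose_tumor_src `dose_map` with tumors as sources.
#' @param dose_caf_src `dose_map` with CAFs as sources.
#' @param nuclide nuclide label recorded in the reports.
#' @param n_decays decay budget recorded in the reports.
#' @param lmean_um optional model L_mean metadata.
#' @param n_bins DVH bins.
#' @param winsorize passed to [fraction_above_relative_threshold()].
#' @return list of six `analysis_report` objects, named
#'   `"<target><-<source>"`.
#' @export
analyze_pairings <- function(labels, dose_tumor_src, dose_caf_src, nuclide,
                             n_decays, lmean_um = NA_real_, n_bins = 512L,
                             winsorize = FALSE) {
  stopifnot(inherits(labels, "label_volume"))
  for (dm in list(dose_tumor_src, dose_caf_src))
    if (!identical(dim(.as_dose_array(dm)), dim(labels$labels)))
      stop("dose map grid does not match the label volume")
  sm <- labels$labels != 0L
  masks <- list(tumor = labels$labels == 1L, caf = labels$labels == 2L, sm = sm)
  pairings <- list(c("tumor", "tumor"), c("caf", "tumor"),
                   c("tumor", "caf"), c("caf", "caf"),
                   c("sm", "tumor"), c("sm", "caf"))
  out <- lapply(pairings, function(p) {
    target <- p[1]; source <- p[2]
    dm <- if (source == "tumor") dose_tumor_src else dose_caf_src
    rep <- list(
      source_label = source, target_label = target, nuclide = nuclide,
      n_decays = n_decays, lmean_um = lmean_um,
      er = efficacy_ratio(dm, masks[[target]], sm),
      mean_dose_target_Gy = mean(.as_dose_array(dm)[masks[[target]]]),
      mean_dose_sm_Gy = mean(.as_dose_array(dm)[sm]),
      frac_ge_10pct_max = fraction_above_relative_threshold(
        dm, masks[[target]], sm, 0.10, winsorize = winsorize),
      frac_below_1pct_mean = 100 * mean(
        .as_dose_array(dm)[masks[[target]]] <
          0.01 * mean(.as_dose_array(dm)[sm])),
      dvh = cumulative_dvh(dm, masks[[target]], n_bins))
    class(rep) <- "analysis_report"
    rep
  })
  names(out) <- vapply(pairings, function(p) paste0(p[1], "<-", p[2]), "")
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s S(%s <- %s): ER %.3f, frac>=10%%max %.1f%%\n",
              x$nuclide, x$target_label, x$source_label, x$er,
              x$frac_ge_10pct_max))
  invisible(x)
}

#' Flatten pairing reports to a summary data frame
#'
#' @param reports list of `analysis_report` (from [analyze_pairings()]).
#' @return data frame, one row per report (DVH curves dropped).
#' @export
pairing_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(nuclide = r$nuclide, source = r$source_label,
               target = r$target_label, n_decays = r$n_decays,
               lmean_um = r$lmean_um, er = r$er,
               mean_dose_target_Gy = r$mean_dose_target_Gy,
               mean_dose_sm_Gy = r$mean_dose_sm_Gy,
               frac_ge_10pct_max = r$frac_ge_10pct_max,
               frac_below_1pct_mean = r$frac_below_1pct_mean,
               row.names = NULL)))
}
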
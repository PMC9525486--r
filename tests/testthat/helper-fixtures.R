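# shared fixtures, built once per test run and cached
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_small_sphere <- function() fx_get("small_sphere", function()
  build_spherical_mask(600, 20))

fx_stripes <- function() fx_get("stripes", function()
  make_toy_labelmap("stripes", size = 16, width = 3))

fx_lu <- function() fx_get("lu", function() load_decay_scheme("Lu-177"))
fx_ac <- function() fx_get("ac", function() load_decay_scheme("Ac-225"))
fx_spt_a <- function() fx_get("spt_a", function() load_stopping_power("alpha"))
fx_spt_e <- function() fx_get("spt_e", function() load_stopping_power("electron"))

# trapezoid integration helper used by several oracles
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# ladder of five clustering levels on a 1 mm sphere, analogous to the full
# 3 mm reference models; built once
fx_ladder <- function() fx_get("ladder", function() {
  mask <- build_spherical_mask(1000, 20)
  specs <- list(
    cluster_spec("interspersed-cubes", 120, seed = 2),
    cluster_spec("interspersed-cubes", 400, seed = 2),
    cluster_spec("blob-field", 150, seed = 2),
    cluster_spec("shell", 250, seed = 2),
    cluster_spec("shell", 600, seed = 2))
  lapply(specs, function(sp) {
    v <- generate_cluster_labels(mask, sp)
    attr(v, "achieved_lmean") <- l_mean(compute_nearest_caf_distances(v))
    v
  })
})

fx_ladder_doses <- function() fx_get("ladder_doses", function() {
  ac <- fx_ac()
  set.seed(77)
  kern <- generate_beta_kernel(fx_lu(), shape = 61, primaries = 3e4,
                               n_batches = 5)
  lapply(fx_ladder(), function(v) {
    list(lmean = attr(v, "achieved_lmean"),
         ac_caf = energy_to_dose(simulate_alpha_dose(v, "caf", 3e4, ac)),
         ac_tum = energy_to_dose(simulate_alpha_dose(v, "tumor", 3e4, ac)),
         lu_caf = convolve_superposition(build_activity_map(v, "caf", 1e7), kern),
         lu_tum = convolve_superposition(build_activity_map(v, "tumor", 1e7), kern),
         sm = v$labels != 0L, caf = v$labels == 2L, tum = v$labels == 1L)
  })
})
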
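# shared fixture builders; everything is generated in code at test time

quiet_noise <- function() noise_model(background = 0, read_noise_sd = 0,
                                      poisson = FALSE)

# frame from a bare matrix at 1 um/px
mat_frame <- function(m, pixel_size = 1, channel = "liposome")
  lipoclust:::as_frame(m, pixel_size = pixel_size, channel = channel)

# scene with clusters of the given sizes, placed with generous separation
sized_scene <- function(ks, morphology = "compact", seed = 1,
                        field_shape = c(384, 384), monomer_radius = 0.1, ...) {
  scene_from_state(tabulate(ks, max(ks)), morphology = morphology,
                   field_shape = field_shape, monomer_radius = monomer_radius,
                   seed = seed, ...)
}

# render + quantify one scene, returning the feature table
quantify_scene <- function(sc, seed = 1,
                           params = preprocess_params(threshold_method = "triangle"),
                           noise = noise_model(), ...) {
  fr <- render_frame(sc, "liposome", noise, seed = seed)
  quantify_timeseries(list(fr), params = params, ...)$features
}

# average single-liposome intensity from a fresh monomer calibration scene
calibrate_monomer_intensity <- function(seed = 101) {
  sc <- sized_scene(rep(1, 25), seed = seed, field_shape = c(256, 256))
  feats <- quantify_scene(sc, seed = seed + 1)
  estimate_monomer_intensity(feats, rg_cutoff_um = 0.6)
}

# match measured features to ground-truth clusters by centroid distance and
# return the truth row index per feature
match_truth <- function(features, scene) {
  tt <- scene_truth_table(scene)
  ps <- scene$pixel_size
  vapply(seq_len(nrow(features)), function(i)
    which.min((tt$x_um - features$col[i] * ps)^2 +
              (tt$y_um - features$row[i] * ps)^2), integer(1))
}

# master-equation oracle for the pure-birth adsorption process:
# dP_k/dt = lambda * (r(k-1) P_{k-1} - r(k) P_k) with r(k) = k+1 (linear)
# or r(k) = 1 (constant); returns the pmf over 0..kmax at time t
birth_master_equation <- function(lambda, t, rate_rule = "linear",
                                  kmax = 200) {
  rates <- if (rate_rule == "linear") (0:kmax) + 1 else rep(1, kmax + 1)
  rhs <- function(tt, p, parms) {
    influx <- c(0, rates[-(kmax + 1)] * p[-(kmax + 1)])
    list(lambda * (influx - rates * p))
  }
  p0 <- c(1, numeric(kmax))
  sol <- deSolve::ode(p0, c(0, t), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  as.numeric(sol[2, -1])
}
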
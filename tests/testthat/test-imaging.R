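test_that("top-hat preprocessing removes flat and slowly varying background", {
  pp <- preprocess_params(tophat_radius = 5, gaussian_sigma = 1.5)
  # flat raster -> zero
  out <- preprocess_liposome_channel(mat_frame(matrix(7, 64, 64)), pp)
  expect_equal(max(out$raster), 0)
  # single bright pixel: peak survives in place, attenuated by the discrete
  # Gaussian kernel's centre mass (direct-convolution oracle)
  x <- matrix(0, 64, 64); x[33, 33] <- 1000
  out <- preprocess_liposome_channel(mat_frame(x), pp)
  expect_equal(which.max(out$raster), which.max(x))
  g <- exp(-((-6:6)^2) / (2 * 1.5^2))
  W <- outer(g, g); W <- W / sum(W)
  expect_equal(max(out$raster), 1000 * W[7, 7], tolerance = 0.02)
  # gentle linear ramp leaves the filtered spot unchanged within 5% of peak
  ramp <- outer(seq(0, 5, length.out = 64), seq(0, 5, length.out = 64), `+`)
  out_r <- preprocess_liposome_channel(mat_frame(x + ramp), pp)
  expect_lt(max(abs(out_r$raster - out$raster)) / max(out$raster), 0.05)
  expect_error(preprocess_liposome_channel(mat_frame(matrix(0, 5, 5)),
                                           preprocess_params(tophat_radius = 10)),
               "larger")
})

test_that("rolling-ball preprocessing is offset invariant and non-negative", {
  pp <- preprocess_params(rollingball_radius = 15, gaussian_sigma = 1)
  expect_equal(max(preprocess_rna_channel(mat_frame(matrix(7, 64, 64)),
                                          pp)$raster), 0)
  ij <- expand.grid(i = 1:64, j = 1:64)
  sp <- matrix(500 * exp(-((ij$i - 32)^2 + (ij$j - 32)^2) / 8), 64, 64)
  i0 <- sum(preprocess_rna_channel(mat_frame(sp), pp)$raster)
  i500 <- sum(preprocess_rna_channel(mat_frame(sp + 500), pp)$raster)
  expect_equal(i500, i0, tolerance = 0.02)
  set.seed(1)
  noisy <- matrix(rnorm(64 * 64, 10, 5), 64, 64)
  expect_gte(min(preprocess_rna_channel(mat_frame(noisy), pp)$raster), 0)
})

test_that("segmentation resolves separated spots and merges adjacent ones", {
  expect_equal(max(segment_features(mat_frame(matrix(0, 64, 64)))), 0)
  spot <- function(nr, cx, cy, sigma = 2, amp = 1000) {
    ij <- expand.grid(i = 1:nr, j = 1:nr)
    matrix(amp * exp(-((ij$i - cy)^2 + (ij$j - cx)^2) / (2 * sigma^2)), nr, nr)
  }
  far <- spot(128, 40, 64) + spot(128, 80, 64)    # 20 sigma apart
  expect_equal(max(segment_features(mat_frame(far))), 2)
  near <- spot(128, 63, 64) + spot(128, 65, 64)   # 1 sigma apart
  expect_equal(max(segment_features(mat_frame(near))), 1)
})

test_that("connectivity setting controls diagonal merging", {
  m <- matrix(0, 16, 16)
  m[3:5, 3:5] <- 1; m[6:8, 6:8] <- 1   # blocks touching at one corner
  expect_equal(max(segment_features(mat_frame(m),
                                    preprocess_params(connectivity = 8,
                                                      min_feature_area = 4))), 1)
  expect_equal(max(segment_features(mat_frame(m),
                                    preprocess_params(connectivity = 4,
                                                      min_feature_area = 4))), 2)
})

test_that("rg measurements match discrete closed forms", {
  # two equal pixels at distance d -> rg = d/2 * pixel_size
  lab <- matrix(0L, 9, 9); lab[3, 3] <- 1L; lab[3, 7] <- 1L
  ras <- matrix(0, 9, 9); ras[lab == 1L] <- 5
  m <- measure_features(lab, mat_frame(ras, pixel_size = 0.5))
  expect_equal(m$rg_um, 0.5 * 4 / 2)
  # single pixel -> rg 0
  lab1 <- matrix(0L, 5, 5); lab1[3, 3] <- 1L
  ras1 <- matrix(0, 5, 5); ras1[3, 3] <- 1
  expect_equal(measure_features(lab1, mat_frame(ras1))$rg_um, 0)
  # uniform disk radius R: rg -> R/sqrt(2), within 3% at R = 20 (brute-force
  # discrete sum is the measurement itself; closed form is the oracle)
  R <- 20; nr <- 64
  ij <- expand.grid(i = 0:(nr - 1), j = 0:(nr - 1))
  inside <- (ij$i - 32)^2 + (ij$j - 32)^2 <= R^2
  lab2 <- matrix(as.integer(inside), nr, nr)
  ras2 <- matrix(as.numeric(inside), nr, nr)
  m2 <- measure_features(lab2, mat_frame(ras2))
  expect_equal(m2$rg_um, R / sqrt(2), tolerance = 0.03)
  expect_gte(m2$circularity, 0.85)
})

test_that("zero-intensity features are flagged and excluded", {
  lab <- matrix(0L, 8, 8); lab[2:3, 2:3] <- 1L
  ras <- matrix(0, 8, 8)
  m <- measure_features(lab, mat_frame(ras), background = 0)
  expect_false(m$valid)
  expect_true(is.na(m$rg_um))
})

test_that("segmentation and rg are intensity-scale invariant", {
  sc <- sized_scene(c(1, 3, 7), seed = 20, field_shape = c(128, 128))
  fr <- render_frame(sc, "liposome", quiet_noise())
  for (c_scale in c(0.5, 13)) {
    fr2 <- fr; fr2$raster <- c_scale * fr$raster
    lab1 <- segment_features(preprocess_liposome_channel(fr))
    lab2 <- segment_features(preprocess_liposome_channel(fr2))
    expect_identical(lab1, lab2)
    m1 <- measure_features(lab1, fr)
    m2 <- measure_features(lab2, fr2)
    expect_equal(m2$rg_um, m1$rg_um, tolerance = 1e-10)
    expect_equal(m2$total_intensity, c_scale * m1$total_intensity,
                 tolerance = 1e-10)
  }
})

test_that("particles per cluster is the intensity ratio estimator", {
  expect_equal(particles_per_cluster(150, 150), 1)
  expect_equal(particles_per_cluster(750, 150), 5)
  expect_equal(particles_per_cluster(c(10, 400), 150, integerize = TRUE),
               c(1, 3))
  expect_error(particles_per_cluster(100, 0))
  # linearity in I by construction
  I <- runif(10, 100, 1e4)
  expect_equal(particles_per_cluster(3 * I, 150),
               3 * particles_per_cluster(I, 150))
})

test_that("estimated particle counts track ground truth at high SNR", {
  I1 <- calibrate_monomer_intensity(101)
  sc <- generate_ground_truth(15, size_law = list(type = "geometric", mean = 4),
                              morphology = "fractal", field_shape = c(384, 384),
                              seed = 11)
  feats <- quantify_scene(sc, seed = 12)
  idx <- match_truth(feats, sc)
  tt <- scene_truth_table(sc)
  rel_err <- abs(feats$total_intensity / I1 - tt$k[idx]) / tt$k[idx]
  expect_lte(median(rel_err), 0.15)
})

test_that("rg estimator recovers ground truth after PSF de-broadening", {
  sc <- sized_scene(c(30, 60, 120, 240), seed = 40)
  feats <- quantify_scene(sc, seed = 41, psf_sigma = 0.3)
  feats <- feats[feats$valid & !feats$border_flag, ]
  idx <- match_truth(feats, sc)
  tt <- scene_truth_table(sc)
  tol <- pmax(0.05 * tt$rg_true_um[idx], sc$pixel_size)
  expect_true(all(abs(feats$rg_corr_um - tt$rg_true_um[idx]) < tol))
})

test_that("circularity separates compact disks from chains", {
  fd <- quantify_scene(sized_scene(rep(300, 4), seed = 51),
                       seed = 52, params = preprocess_params())
  expect_true(all(fd$circularity >= 0.85))
  fc <- quantify_scene(sized_scene(rep(20, 5), morphology = "chain",
                                   monomer_radius = 0.25, seed = 53),
                       seed = 54, params = preprocess_params())
  expect_true(all(fc$circularity <= 0.5))
})

test_that("fractal-dimension fit recovers exact and rendered scaling", {
  # noiseless power law k = rg^2 -> slope exactly 2
  rg <- seq(0.2, 4, length.out = 20)
  fit <- fit_fractal_dimension(rg, rg^2)
  expect_equal(fit$df, 2, tolerance = 1e-12)
  expect_error(fit_fractal_dimension(rg[1:5], rg[1:5]^2), "features")
  expect_error(fit_fractal_dimension(rep(c(1, 2), 10), rep(c(1, 4), 10)),
               "dynamic range")
  # rendered chains and compact disks, end to end
  I1 <- calibrate_monomer_intensity(101)
  ch <- do.call(rbind, lapply(1:3, function(r)
    quantify_scene(sized_scene(seq(6, 30, by = 3), morphology = "chain",
                               seed = 200 + 2 * r),
                   seed = 201 + 2 * r, psf_sigma = 0.3)))
  ch <- ch[ch$valid & !ch$border_flag, ]
  fit_c <- fit_fractal_dimension(ch$rg_corr_um, ch$total_intensity / I1)
  expect_gt(fit_c$df, 0.9); expect_lt(fit_c$df, 1.2)
  dk <- do.call(rbind, lapply(1:3, function(r)
    quantify_scene(sized_scene(round(seq(20, 400, length.out = 8)),
                               seed = 300 + 2 * r),
                   seed = 301 + 2 * r, psf_sigma = 0.3)))
  dk <- dk[dk$valid & !dk$border_flag, ]
  fit_d <- fit_fractal_dimension(dk$rg_corr_um, dk$total_intensity / I1)
  expect_gt(fit_d$df, 1.8); expect_lt(fit_d$df, 2.1)
})

test_that("colocalization metrics hit their closed-form anchors", {
  set.seed(61)
  a <- mat_frame(matrix(runif(256^2), 256))
  expect_equal(colocalization(a, a)$pearson, 1)
  inv <- mat_frame(max(a$raster) - a$raster)
  expect_equal(colocalization(a, inv)$pearson, -1)
  b <- mat_frame(matrix(runif(256^2), 256))
  expect_lt(abs(colocalization(a, b)$pearson), 0.05)  # ~3/sqrt(n)
  cc <- colocalization(a, mat_frame(matrix(1, 256, 256)))
  expect_true(is.na(cc$pearson))
  expect_identical(cc$flag, "constant_channel")
})

test_that("manders fractions reflect channel overlap", {
  sc <- generate_ground_truth(20, size_law = list(type = "fixed", k = 2),
                              coloc_fraction = 1, seed = 62,
                              field_shape = c(256, 256))
  lip <- render_frame(sc, "liposome", quiet_noise())
  rna <- render_frame(sc, "rna", quiet_noise())
  cc <- colocalization(lip, rna)
  expect_gt(cc$pearson, 0.95)
  # thresholded overlap keeps most of each channel's intensity (PSF tails
  # below threshold carry the rest)
  expect_gt(cc$mandersA, 0.6)
  expect_gt(cc$mandersB, 0.6)
})

test_that("time-series summaries are consistent with the feature table", {
  res <- quantify_timeseries(list(matrix(0, 64, 64)), pixel_size = 0.325)
  expect_equal(nrow(res$features), 0)
  expect_equal(res$summary$n_features, 0)
  sc1 <- sized_scene(c(1, 2, 4), seed = 70, field_shape = c(256, 256))
  sc2 <- sized_scene(c(2, 3, 6), seed = 71, field_shape = c(256, 256))
  frames <- list(render_frame(sc1, "liposome", noise_model(), seed = 72),
                 render_frame(sc2, "liposome", noise_model(), seed = 73))
  res <- quantify_timeseries(frames, timestamps = c(0, 5),
                             params = preprocess_params(threshold_method = "triangle"))
  expect_equal(res$summary$time_min, c(0, 5))
  for (i in 1:2) {
    sub <- res$features[res$features$frame == i, ]
    expect_equal(res$summary$n_features[i], nrow(sub))
    use <- sub$valid & !sub$border_flag
    expect_equal(res$summary$mean_rg_um[i], mean(sub$rg_um[use]))
  }
})
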
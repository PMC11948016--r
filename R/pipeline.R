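# Config-driven pipeline runners: generate fixtures, quantify stacks, fit
# models. Each run validates its config before any side effect and writes the
# resolved config plus a checksum manifest next to its outputs.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

require_fields <- function(config, fields, where) {
  missing <- setdiff(fields, names(config))
  if (length(missing))
    stop(sprintf("config for %s is missing required field(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(config)
}

write_manifest <- function(out_dir, files) {
  sums <- tools::md5sum(files)
  manifest <- data.frame(file = basename(files), md5 = unname(sums),
                         stringsAsFactors = FALSE)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

echo_config <- function(out_dir, config, name = "run_config.json") {
  path <- file.path(out_dir, name)
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Generate a rendered fixture bundle from a config
#'
#' Builds per-frame ground-truth scenes whose geometric size-law mean grows
#' as `1 + t/tau` (constant-kernel growth), renders a two-channel stack, and
#' writes `stack.tif`, `truth.csv`, the resolved config and a checksum
#' manifest into the output directory.
#'
#' @param config list (or JSON path) with fields: `out` (directory), `seed`,
#'   `times` (minutes, strictly increasing), and optional `scene` overrides
#'   (`n_clusters`, `tau`, `morphology`, `target_df`, `coloc_fraction`,
#'   `field_shape`, `pixel_size`, `monomer_radius`, `flux_liposome`,
#'   `flux_rna`) and `noise` overrides (`background`, `read_noise_sd`,
#'   `poisson`, `psf_sigma`).
#' @return Invisible list with `files`, `truth`, `scenes`.
#' @export
run_generate <- function(config) {
  config <- read_config(config)
  require_fields(config, c("out", "times"), "run_generate")
  times <- as.numeric(config$times)
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("'times' must be non-empty and strictly increasing")
  sc <- config$scene %||% list()
  nz <- config$noise %||% list()
  noise <- noise_model(background = nz$background %||% 100,
                       read_noise_sd = nz$read_noise_sd %||% 2,
                       poisson = nz$poisson %||% TRUE,
                       psf_sigma = nz$psf_sigma %||% 0.3)
  tau <- sc$tau %||% 10
  seed <- config$seed %||% NULL
  set_seed_if(seed)
  scene_seeds <- sample.int(.Machine$integer.max, length(times))
  scenes <- lapply(seq_along(times), function(i)
    generate_ground_truth(
      n_clusters = sc$n_clusters %||% 60,
      size_law = list(type = "geometric", mean = 1 + times[i] / tau),
      morphology = sc$morphology %||% "fractal",
      target_df = sc$target_df %||% 1.5,
      coloc_fraction = sc$coloc_fraction %||% 1,
      field_shape = sc$field_shape %||% c(256, 256),
      pixel_size = sc$pixel_size %||% 0.325,
      monomer_radius = sc$monomer_radius %||% 0.1,
      flux_liposome = sc$flux_liposome %||% 2000,
      flux_rna = sc$flux_rna %||% 1000,
      timestamp = times[i],
      scene_id = sprintf("frame%03d", i),
      seed = scene_seeds[i]))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_timelapse(scenes, noise = noise, seed = seed,
                               out_dir = config$out)
  cfg_path <- echo_config(config$out, config)
  manifest <- write_manifest(config$out, c(bundle$files, config = cfg_path))
  invisible(list(files = c(bundle$files, config = cfg_path,
                           manifest = manifest),
                 truth = bundle$truth, scenes = scenes))
}

#' Quantify an image stack from a config
#'
#' Reads a two-channel multi-page TIFF (page order liposome, rna per frame,
#' as written by [run_generate()]) or a single-channel stack, runs the
#' segmentation and measurement chain, and writes `features.csv`,
#' `summary.csv`, the resolved parameters and a manifest.
#'
#' @param config list (or JSON path) with fields: `stack` (TIFF path), `out`
#'   (directory), `pixel_size`; optional `channels` (2 default, 1 for a
#'   single-channel stack), `timestamps`, `params` (see
#'   [preprocess_params()]), `monomer_mean_intensity`, `psf_sigma`.
#' @return Invisible list with `features`, `summary`, `files`.
#' @export
run_quantify <- function(config) {
  config <- read_config(config)
  require_fields(config, c("stack", "out", "pixel_size"), "run_quantify")
  pages <- read_stack(config$stack)
  nch <- config$channels %||% 2L
  if (length(pages) %% nch != 0)
    stop("page count is not a multiple of the channel count")
  nf <- length(pages) / nch
  lipo <- pages[seq(1, length(pages), by = nch)]
  rna <- if (nch >= 2) pages[seq(2, length(pages), by = nch)] else NULL
  pp <- config$params %||% list()
  params <- preprocess_params(
    tophat_radius = pp$tophat_radius %||% 5,
    gaussian_sigma = pp$gaussian_sigma %||% 1,
    rollingball_radius = pp$rollingball_radius %||% 15,
    threshold_method = pp$threshold_method %||% "otsu",
    min_feature_area = pp$min_feature_area %||% 4,
    connectivity = pp$connectivity %||% 8)
  res <- quantify_timeseries(
    lipo, params = params, pixel_size = config$pixel_size,
    timestamps = config$timestamps %||% NULL, channel = "liposome",
    co_frames = rna,
    monomer_mean_intensity = config$monomer_mean_intensity %||% NULL,
    psf_sigma = config$psf_sigma %||% NULL)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  f_feat <- file.path(config$out, "features.csv")
  f_summ <- file.path(config$out, "summary.csv")
  write.csv(res$features, f_feat, row.names = FALSE)
  write.csv(res$summary, f_summ, row.names = FALSE)
  cfg_path <- echo_config(config$out, config, "params.json")
  manifest <- write_manifest(config$out, c(f_feat, f_summ, cfg_path))
  invisible(list(features = res$features, summary = res$summary,
                 files = c(features = f_feat, summary = f_summ,
                           params = cfg_path, manifest = manifest)))
}

#' Fit growth and adsorption models from summary tables
#'
#' Fits, as available in the inputs: the growth timescale `tau` from the
#' cluster-count decay `N(t) = N0/(1 + t/tau)`, the power-law growth exponent
#' `z` of mean rg, the fractal dimension from a feature table, the
#' mean-versus-ratio adsorption line, and the patchy growth-rate scale `k0`.
#' Every fit records its window and diagnostics; results are written as JSON.
#'
#' @param config list (or JSON path) with fields: `out` (directory); one or
#'   more of `summary` (per-frame summary CSV or data frame with `time_min`,
#'   `n_features`, `mean_rg_um`), `features` (feature table with `rg_um` and
#'   `k_hat`), `adsorption` (table with `mass_ratio`, `mean_intensity`),
#'   `patchy` (table with `f`, `rate`); optional `rg_window`.
#' @return Invisible list of fit objects; written to `fits.json`.
#' @export
run_fit <- function(config) {
  config <- read_config(config)
  require_fields(config, "out", "run_fit")
  get_table <- function(x, required, name) {
    if (is.null(x)) return(NULL)
    tab <- if (is.character(x)) read.csv(x) else as.data.frame(x)
    miss <- setdiff(required, names(tab))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", name,
                   paste(miss, collapse = ", ")))
    tab
  }
  fits <- list()
  summ <- get_table(config$summary, c("time_min", "n_features"), "summary")
  if (!is.null(summ)) {
    nfit <- fit_growth(summ$time_min, summ$n_features, type = "N")
    fits$tau <- list(estimate = nfit$tau, n0 = nfit$n0,
                     r_squared = nfit$r_squared, n_points = nfit$n_points)
    if ("mean_rg_um" %in% names(summ)) {
      gfit <- fit_growth(summ$time_min, summ$mean_rg_um, type = "rg",
                         tau = nfit$tau,
                         window = config$rg_window %||% NULL)
      fits$growth <- list(z = gfit$z, a = gfit$a, z_se = gfit$z_se,
                          window = gfit$window, r_squared = gfit$r_squared)
    }
  }
  feats <- get_table(config$features, c("rg_um", "k_hat"), "features")
  if (!is.null(feats)) {
    ffit <- tryCatch(fit_fractal_dimension(feats$rg_um, feats$k_hat,
                                           k_min = config$k_min %||% 1),
                     error = function(e) e)
    fits$fractal <- if (inherits(ffit, "error")) list(error = conditionMessage(ffit))
                    else list(d_f = ffit$df, se = ffit$se, a = ffit$a,
                              n = ffit$n, r_squared = ffit$r_squared)
  }
  ads <- get_table(config$adsorption, c("mass_ratio", "mean_intensity"),
                   "adsorption")
  if (!is.null(ads))
    fits$adsorption <- fit_mean_vs_ratio(ads$mass_ratio, ads$mean_intensity)
  pat <- get_table(config$patchy, c("f", "rate"), "patchy")
  if (!is.null(pat))
    fits$patchy <- fit_growth_rate_scale(pat$f, pat$rate)
  if (!length(fits)) stop("no fittable inputs supplied")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  f_fit <- file.path(config$out, "fits.json")
  jsonlite::write_json(fits, f_fit, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  cfg_path <- echo_config(config$out, config[!vapply(config, is.data.frame,
                                                     logical(1))],
                          "fit_config.json")
  write_manifest(config$out, c(f_fit, cfg_path))
  invisible(fits)
}
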
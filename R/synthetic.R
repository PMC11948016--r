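#' Camera and optics noise model for rendered scenes
#'
#' Describes the forward model applied when a ground-truth scene is rendered
#' into a raster: an isotropic 2-D Gaussian point-spread function, a slowly
#' varying additive background plane, Poisson shot noise and Gaussian read
#' noise.
#'
#' @param background background level, photons per pixel.
#' @param background_gradient length-2 numeric, photons per pixel of linear
#'   background ramp along (row, col).
#' @param read_noise_sd Gaussian read noise standard deviation, photons.
#' @param poisson logical, apply Poisson shot noise.
#' @param psf_sigma standard deviation of the Gaussian point-spread function,
#'   micrometres.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background = 100, background_gradient = c(0, 0),
                        read_noise_sd = 2, poisson = TRUE, psf_sigma = 0.3) {
  assert_scalar_num(background, "background", lower = 0)
  assert_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  assert_scalar_num(psf_sigma, "psf_sigma", lower = 0, strict_lower = TRUE)
  if (length(background_gradient) != 2L || any(!is.finite(background_gradient)))
    stop("'background_gradient' must be two finite numbers")
  structure(list(background = background,
                 background_gradient = as.numeric(background_gradient),
                 read_noise_sd = read_noise_sd,
                 poisson = isTRUE(poisson),
                 psf_sigma = psf_sigma),
            class = "noise_model")
}

offsets_rg <- function(offsets) {
  ctr <- colMeans(offsets)
  sqrt(mean((offsets[, 1] - ctr[1])^2 + (offsets[, 2] - ctr[2])^2))
}

chain_offsets <- function(k, monomer_radius) {
  x <- (seq_len(k) - (k + 1) / 2) * 2 * monomer_radius
  cbind(x = x, y = rep(0, k))
}

hex_offsets <- function(k, monomer_radius) {
  # close-packed hexagonal lattice, k sites nearest the origin
  n <- ceiling(sqrt(k)) + 2L
  ij <- expand.grid(i = -n:n, j = -n:n)
  x <- 2 * monomer_radius * (ij$i + ij$j / 2)
  y <- 2 * monomer_radius * (sqrt(3) / 2) * ij$j
  ord <- order(x^2 + y^2)
  cbind(x = x[ord[seq_len(k)]], y = y[ord[seq_len(k)]])
}

hit_and_stick_offsets <- function(k, monomer_radius) {
  # off-lattice diffusion-limited hit-and-stick growth: each new monomer
  # random-walks in from a launch circle until it touches the cluster
  d <- 2 * monomer_radius
  pos <- matrix(0, nrow = k, ncol = 2)
  if (k == 1L) return(pos)
  rmax <- 0
  for (m in 2:k) {
    repeat {
      launch <- rmax + 5 * d
      kill <- launch + 20 * d
      th <- runif(1, 0, 2 * pi)
      p <- launch * c(cos(th), sin(th))
      stuck <- FALSE
      for (step in seq_len(10000L)) {
        dx <- pos[seq_len(m - 1L), 1] - p[1]
        dy <- pos[seq_len(m - 1L), 2] - p[2]
        dist <- sqrt(dx * dx + dy * dy)
        jmin <- which.min(dist)
        dmin <- dist[jmin]
        if (dmin <= d * (1 + 1e-9)) {
          # stick at exact contact with the nearest monomer
          u <- p - pos[jmin, ]
          nu <- sqrt(sum(u * u))
          u <- if (nu > 0) u / nu else c(1, 0)
          pos[m, ] <- pos[jmin, ] + d * u
          stuck <- TRUE
          break
        }
        if (sqrt(sum(p * p)) > kill) break
        # adaptive step: large far from the cluster, fine near contact
        s <- max(dmin - d, 0.25 * d)
        th2 <- runif(1, 0, 2 * pi)
        p <- p + s * c(cos(th2), sin(th2))
      }
      if (stuck) break
    }
    rmax <- max(rmax, sqrt(sum(pos[m, ]^2)))
  }
  colnames(pos) <- c("x", "y")
  pos
}

#' Generate monomer offsets for a cluster of tunable fractal dimension
#'
#' Produces `k` non-overlapping monomer positions (micrometres, relative to
#' the cluster centroid). `target_df = 1` gives a straight chain,
#' `target_df = 2` hexagonal close packing, and intermediate values use
#' off-lattice hit-and-stick growth, which empirically yields mass-radius
#' scaling exponents around 1.4-1.7.
#'
#' @param k monomer count, positive integer.
#' @param target_df target fractal dimension in `[1, 2]`.
#' @param monomer_radius monomer radius, micrometres.
#' @param seed optional RNG seed.
#' @return A `k x 2` matrix of centred (x, y) offsets in micrometres.
#' @export
generate_fractal_cluster <- function(k, target_df = 1.5, monomer_radius = 0.1,
                                     seed = NULL) {
  assert_scalar_num(k, "k", lower = 1)
  assert_scalar_num(target_df, "target_df", lower = 1, upper = 2)
  assert_scalar_num(monomer_radius, "monomer_radius", lower = 0,
                    strict_lower = TRUE)
  set_seed_if(seed)
  k <- as.integer(k)
  off <- if (k == 1L) {
    matrix(0, 1, 2, dimnames = list(NULL, c("x", "y")))
  } else if (target_df <= 1) {
    chain_offsets(k, monomer_radius)
  } else if (target_df >= 2) {
    hex_offsets(k, monomer_radius)
  } else {
    hit_and_stick_offsets(k, monomer_radius)
  }
  sweep(off, 2, colMeans(off))
}

morphology_df <- function(morphology, target_df) {
  switch(morphology,
         chain = 1,
         compact = 2,
         fractal = target_df,
         stop("unknown morphology tag: ", morphology))
}

#' Generate a ground-truth scene of RNA-liposome clusters
#'
#' Draws per-cluster monomer counts from a size law (geometric with a given
#' mean, or fixed), builds cluster morphologies, and places clusters uniformly
#' at random in the field with bounded non-overlap retries. A fraction
#' `coloc_fraction` of the clusters carry RNA flux; the rest are RNA-dark.
#'
#' @param n_clusters number of clusters to place (may be 0).
#' @param size_law list: `list(type = "geometric", mean = m)` (support 1, 2,
#'   ...) or `list(type = "fixed", k = k)`.
#' @param morphology `"compact"`, `"chain"` or `"fractal"`.
#' @param target_df fractal dimension used when `morphology = "fractal"`.
#' @param coloc_fraction fraction of clusters carrying RNA flux, in `[0, 1]`.
#' @param field_shape `(rows, cols)` of the raster, pixels.
#' @param pixel_size micrometres per pixel.
#' @param monomer_radius monomer radius, micrometres.
#' @param flux_liposome,flux_rna photons per monomer in each channel.
#' @param border_margin_um margin kept free around the field border.
#' @param min_separation_um minimum edge-to-edge separation between cluster
#'   bounding circles, so diffraction-blurred features stay resolvable.
#' @param timestamp minutes since mixing, carried into the truth table.
#' @param scene_id identifier string.
#' @param seed optional RNG seed; scenes are reproducible for a fixed seed.
#' @param max_retries placement retries per cluster before failing.
#' @return An object of class `gt_scene`.
#' @export
generate_ground_truth <- function(n_clusters,
                                  size_law = list(type = "geometric", mean = 4),
                                  morphology = c("compact", "chain", "fractal"),
                                  target_df = 1.5,
                                  coloc_fraction = 1,
                                  field_shape = c(256, 256),
                                  pixel_size = 0.325,
                                  monomer_radius = 0.1,
                                  flux_liposome = 2000,
                                  flux_rna = 1000,
                                  border_margin_um = 2,
                                  min_separation_um = 2,
                                  timestamp = 0,
                                  scene_id = "scene",
                                  seed = NULL,
                                  max_retries = 1000L) {
  morphology <- match.arg(morphology)
  assert_scalar_num(n_clusters, "n_clusters", lower = 0)
  assert_scalar_num(coloc_fraction, "coloc_fraction", lower = 0, upper = 1)
  assert_scalar_num(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (length(field_shape) != 2L || any(field_shape < 1))
    stop("'field_shape' must be two positive integers")
  set_seed_if(seed)
  n_clusters <- as.integer(n_clusters)

  ks <- if (n_clusters == 0L) {
    integer(0)
  } else if (identical(size_law$type, "geometric")) {
    m <- size_law$mean
    assert_scalar_num(m, "size_law$mean", lower = 1)
    if (m == 1) rep(1L, n_clusters) else 1L + rgeom(n_clusters, prob = 1 / m)
  } else if (identical(size_law$type, "fixed")) {
    rep(as.integer(size_law$k), n_clusters)
  } else stop("unknown size_law type: ", size_law$type)

  df <- morphology_df(morphology, target_df)
  extent <- (field_shape - 1) * pixel_size  # (y, x) extent of pixel centres

  clusters <- vector("list", n_clusters)
  placed_xy <- matrix(NA_real_, n_clusters, 2)
  placed_r <- numeric(n_clusters)
  n_rna <- round(coloc_fraction * n_clusters)
  rna_idx <- if (n_clusters > 0) sample.int(n_clusters, n_rna) else integer(0)

  for (i in seq_len(n_clusters)) {
    off <- generate_fractal_cluster(ks[i], target_df = df,
                                    monomer_radius = monomer_radius)
    brad <- max(sqrt(rowSums(off^2))) + monomer_radius
    lo <- border_margin_um + brad
    hi_x <- extent[2] - border_margin_um - brad
    hi_y <- extent[1] - border_margin_um - brad
    if (hi_x < lo || hi_y < lo)
      stop("cluster too large for the field given the border margin")
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ctr <- c(runif(1, lo, hi_x), runif(1, lo, hi_y))
      if (i == 1L ||
          all(sqrt((placed_xy[seq_len(i - 1L), 1] - ctr[1])^2 +
                   (placed_xy[seq_len(i - 1L), 2] - ctr[2])^2) >
              placed_r[seq_len(i - 1L)] + brad + min_separation_um)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("could not place cluster %d without overlap after %d retries",
                   i, max_retries))
    placed_xy[i, ] <- ctr
    placed_r[i] <- brad
    clusters[[i]] <- list(
      cluster_id = i,
      k = ks[i],
      centroid_um = ctr,          # (x, y)
      monomer_offsets = off,      # centred, micrometres
      rg_true_um = offsets_rg(off),
      flux_liposome = flux_liposome,
      flux_rna = if (i %in% rna_idx) flux_rna else 0,
      morphology = morphology
    )
  }

  structure(list(scene_id = scene_id, pixel_size = pixel_size,
                 field_shape = as.integer(field_shape),
                 clusters = clusters, timestamp = timestamp,
                 monomer_radius = monomer_radius),
            class = "gt_scene")
}

#' @export
print.gt_scene <- function(x, ...) {
  ks <- vapply(x$clusters, `[[`, numeric(1), "k")
  cat(sprintf("Ground-truth scene '%s': %d clusters, field %dx%d px (%.3f um/px), t = %g min\n",
              x$scene_id, length(x$clusters), x$field_shape[1], x$field_shape[2],
              x$pixel_size, x$timestamp))
  if (length(ks))
    cat(sprintf("  monomers per cluster: mean %.2f, range [%d, %d]\n",
                mean(ks), min(ks), max(ks)))
  invisible(x)
}

#' Truth table for one or more scenes
#'
#' @param scene a `gt_scene` (or list of them) as produced by
#'   [generate_ground_truth()].
#' @param frame frame index (or vector, one per scene).
#' @return A data frame with one row per cluster: `scene_id`, `frame`,
#'   `cluster_id`, `k`, `x_um`, `y_um`, `rg_true_um`, `flux_lipo`,
#'   `flux_rna`, `morphology`.
#' @export
scene_truth_table <- function(scene, frame = 1L) {
  scenes <- if (inherits(scene, "gt_scene")) list(scene) else scene
  frame <- rep_len(frame, length(scenes))
  rows <- mapply(function(s, fr) {
    if (!length(s$clusters))
      return(data.frame(scene_id = character(0), frame = integer(0),
                        cluster_id = integer(0), k = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        rg_true_um = numeric(0), flux_lipo = numeric(0),
                        flux_rna = numeric(0), morphology = character(0)))
    do.call(rbind, lapply(s$clusters, function(cl)
      data.frame(scene_id = s$scene_id, frame = fr, cluster_id = cl$cluster_id,
                 k = cl$k, x_um = cl$centroid_um[1], y_um = cl$centroid_um[2],
                 rg_true_um = cl$rg_true_um, flux_lipo = cl$flux_liposome,
                 flux_rna = cl$flux_rna, morphology = cl$morphology)))
  }, scenes, frame, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render one channel of a scene into a raster
#'
#' Each monomer contributes an isotropic Gaussian spot whose integrated flux
#' equals its per-channel photon flux; a background plane is added, then
#' optional Poisson shot noise and Gaussian read noise. Pixel values are
#' clipped at zero. Rendering is deterministic for a fixed seed.
#'
#' @param scene a `gt_scene`.
#' @param channel `"liposome"` or `"rna"`.
#' @param noise a [noise_model()].
#' @param seed optional RNG seed for the noise draws.
#' @param frame_index frame index carried in the result.
#' @return An object of class `image_frame` with fields `raster` (photons),
#'   `channel`, `frame_index`, `pixel_size`, `timestamp`.
#' @export
render_frame <- function(scene, channel = c("liposome", "rna"),
                         noise = noise_model(), seed = NULL, frame_index = 1L) {
  channel <- match.arg(channel)
  stopifnot(inherits(scene, "gt_scene"), inherits(noise, "noise_model"))
  set_seed_if(seed)
  nr <- scene$field_shape[1]
  nc <- scene$field_shape[2]
  ps <- scene$pixel_size
  sig <- noise$psf_sigma
  raster <- matrix(0, nr, nc)
  win <- ceiling(5 * sig / ps)
  for (cl in scene$clusters) {
    flux <- if (channel == "liposome") cl$flux_liposome else cl$flux_rna
    if (flux <= 0) next
    for (m in seq_len(nrow(cl$monomer_offsets))) {
      x <- cl$centroid_um[1] + cl$monomer_offsets[m, 1]
      y <- cl$centroid_um[2] + cl$monomer_offsets[m, 2]
      c0 <- x / ps  # 0-based pixel coordinates of the monomer
      r0 <- y / ps
      cols <- max(0, floor(c0) - win):min(nc - 1, ceiling(c0) + win)
      rows <- max(0, floor(r0) - win):min(nr - 1, ceiling(r0) + win)
      if (!length(cols) || !length(rows)) next
      gx <- exp(-((cols - c0) * ps)^2 / (2 * sig^2))
      gy <- exp(-((rows - r0) * ps)^2 / (2 * sig^2))
      patch <- (flux * ps^2 / (2 * pi * sig^2)) * outer(gy, gx)
      raster[rows + 1, cols + 1] <- raster[rows + 1, cols + 1] + patch
    }
  }
  bg <- noise$background +
    outer((seq_len(nr) - 1) * noise$background_gradient[1],
          (seq_len(nc) - 1) * noise$background_gradient[2], `+`)
  raster <- raster + bg
  if (noise$poisson)
    raster <- matrix(rpois(length(raster), pmax(raster, 0)), nr, nc)
  if (noise$read_noise_sd > 0)
    raster <- raster + matrix(rnorm(length(raster), 0, noise$read_noise_sd),
                              nr, nc)
  raster <- pmax(raster, 0)
  structure(list(raster = raster, channel = channel,
                 frame_index = as.integer(frame_index),
                 pixel_size = ps, timestamp = scene$timestamp),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("Image frame (%s channel): %d x %d px, %.3f um/px, t = %g min\n",
              x$channel, nrow(x$raster), ncol(x$raster), x$pixel_size,
              x$timestamp))
  invisible(x)
}

#' Build a scene from a coagulation state vector
#'
#' Expands the k-mer counts of a [smol_state] into individual clusters and
#' places them in a field, so simulated aggregation trajectories can be
#' rendered as image time series.
#'
#' @param state a `smol_state` (integer counts) or a named numeric vector of
#'   counts indexed by k.
#' @param morphology,target_df cluster morphology (see
#'   [generate_ground_truth()]).
#' @param max_clusters cap on rendered clusters (subsampled preserving the
#'   size law) to keep rendering tractable.
#' @inheritParams generate_ground_truth
#' @return A `gt_scene`.
#' @export
scene_from_state <- function(state, morphology = "fractal", target_df = 1.5,
                             coloc_fraction = 1,
                             field_shape = c(256, 256), pixel_size = 0.325,
                             monomer_radius = 0.1, flux_liposome = 2000,
                             flux_rna = 1000, border_margin_um = 2,
                             scene_id = "scene", seed = NULL,
                             max_clusters = 500L) {
  counts <- if (inherits(state, "smol_state")) state$counts else state
  tstamp <- if (inherits(state, "smol_state")) state$t else 0
  counts <- round(counts)
  ks <- rep(seq_along(counts), counts)
  set_seed_if(seed)
  if (length(ks) > max_clusters) ks <- sample(ks, max_clusters)
  df <- morphology_df(morphology, target_df)
  extent <- (field_shape - 1) * pixel_size
  n <- length(ks)
  n_rna <- round(coloc_fraction * n)
  rna_idx <- if (n > 0) sample.int(n, n_rna) else integer(0)
  clusters <- vector("list", n)
  placed_xy <- matrix(NA_real_, n, 2)
  placed_r <- numeric(n)
  for (i in seq_len(n)) {
    off <- generate_fractal_cluster(ks[i], target_df = df,
                                    monomer_radius = monomer_radius)
    brad <- max(sqrt(rowSums(off^2))) + monomer_radius
    lo <- border_margin_um + brad
    hi_x <- extent[2] - border_margin_um - brad
    hi_y <- extent[1] - border_margin_um - brad
    if (hi_x < lo || hi_y < lo)
      stop("cluster too large for the field given the border margin")
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ctr <- c(runif(1, lo, hi_x), runif(1, lo, hi_y))
      if (i == 1L ||
          all(sqrt((placed_xy[seq_len(i - 1L), 1] - ctr[1])^2 +
                   (placed_xy[seq_len(i - 1L), 2] - ctr[2])^2) >
              placed_r[seq_len(i - 1L)] + brad + 2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop(sprintf("could not place cluster %d without overlap", i))
    placed_xy[i, ] <- ctr
    placed_r[i] <- brad
    clusters[[i]] <- list(cluster_id = i, k = ks[i], centroid_um = ctr,
                          monomer_offsets = off, rg_true_um = offsets_rg(off),
                          flux_liposome = flux_liposome,
                          flux_rna = if (i %in% rna_idx) flux_rna else 0,
                          morphology = morphology)
  }
  structure(list(scene_id = scene_id, pixel_size = pixel_size,
                 field_shape = as.integer(field_shape), clusters = clusters,
                 timestamp = tstamp, monomer_radius = monomer_radius),
            class = "gt_scene")
}

#' Render a two-channel time-lapse stack from a trajectory
#'
#' Takes either a list of explicit `gt_scene`s or a list of `smol_state`
#' snapshots (e.g. from [simulate_gillespie()]), renders one two-channel frame
#' per time point, and optionally writes a multi-page 16-bit TIFF (page order:
#' liposome then rna for each frame), a ground-truth CSV and a JSON config
#' echo.
#'
#' @param trajectory list of `gt_scene` or of `smol_state` (times strictly
#'   increasing).
#' @param noise a [noise_model()].
#' @param seed RNG seed; per-frame render seeds are derived from it.
#' @param out_dir if non-NULL, directory to write `stack.tif`, `truth.csv`
#'   and `config.json` into (created if missing).
#' @param ... passed to [scene_from_state()] when the trajectory is made of
#'   state vectors.
#' @return Invisible list with `frames` (per time point, `liposome` and `rna`
#'   `image_frame`s), `scenes`, `truth` (data frame) and `files`.
#' @export
generate_timelapse <- function(trajectory, noise = noise_model(), seed = NULL,
                               out_dir = NULL, ...) {
  if (!length(trajectory)) stop("empty trajectory")
  scenes <- if (inherits(trajectory[[1]], "gt_scene")) {
    trajectory
  } else {
    set_seed_if(seed)
    lapply(seq_along(trajectory), function(i)
      scene_from_state(trajectory[[i]], scene_id = sprintf("frame%03d", i), ...))
  }
  times <- vapply(scenes, `[[`, numeric(1), "timestamp")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("trajectory times must be strictly increasing")
  set_seed_if(seed)
  frame_seeds <- if (is.null(seed)) rep(list(NULL), 2 * length(scenes))
                 else as.list(sample.int(.Machine$integer.max, 2 * length(scenes)))
  frames <- lapply(seq_along(scenes), function(i) {
    list(liposome = render_frame(scenes[[i]], "liposome", noise,
                                 seed = frame_seeds[[2 * i - 1]], frame_index = i),
         rna = render_frame(scenes[[i]], "rna", noise,
                            seed = frame_seeds[[2 * i]], frame_index = i))
  })
  truth <- scene_truth_table(scenes, frame = seq_along(scenes))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pages <- unlist(lapply(frames, function(fr)
      list(fr$liposome$raster, fr$rna$raster)), recursive = FALSE)
    tif <- file.path(out_dir, "stack.tif")
    write_stack(pages, tif)
    csv <- file.path(out_dir, "truth.csv")
    write.csv(truth, csv, row.names = FALSE)
    cfg <- file.path(out_dir, "config.json")
    jsonlite::write_json(list(n_frames = length(frames),
                              channels = c("liposome", "rna"),
                              pixel_size = scenes[[1]]$pixel_size,
                              psf_sigma = noise$psf_sigma,
                              background = noise$background,
                              seed = seed),
                         cfg, auto_unbox = TRUE, pretty = TRUE)
    files <- c(stack = tif, truth = csv, config = cfg)
  }
  invisible(list(frames = frames, scenes = scenes, truth = truth,
                 files = files))
}

#' Write rasters as a multi-page 16-bit TIFF
#'
#' Pixel values are photons, clipped at 65535.
#' @param pages list of numeric matrices.
#' @param path output file.
#' @export
write_stack <- function(pages, path) {
  scaled <- lapply(pages, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack()]
#'
#' @param path TIFF file.
#' @return List of numeric matrices in photons.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
}
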
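#' Preprocessing and segmentation parameters
#'
#' Parameters of the segmentation chain: morphological white top-hat then
#' Gaussian smoothing for the liposome channel, rolling-ball background
#' subtraction then Gaussian smoothing for the RNA channel, automatic global
#' thresholding, connected components, small-object rejection.
#'
#' @param tophat_radius disc radius of the top-hat structuring element, px.
#' @param gaussian_sigma Gaussian smoothing sigma, px.
#' @param rollingball_radius radius of the rolling-ball background estimator,
#'   px.
#' @param threshold_method `"otsu"` (default) or `"triangle"`.
#' @param min_feature_area minimum connected-component area kept, px.
#' @param connectivity 4 or 8 (default) pixel connectivity.
#' @return Object of class `preprocess_params`.
#' @export
preprocess_params <- function(tophat_radius = 5, gaussian_sigma = 1,
                              rollingball_radius = 15,
                              threshold_method = c("otsu", "triangle"),
                              min_feature_area = 4, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  assert_scalar_num(tophat_radius, "tophat_radius", lower = 1)
  assert_scalar_num(gaussian_sigma, "gaussian_sigma", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(rollingball_radius, "rollingball_radius", lower = 1)
  assert_scalar_num(min_feature_area, "min_feature_area", lower = 1)
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  structure(list(tophat_radius = as.integer(tophat_radius),
                 gaussian_sigma = gaussian_sigma,
                 rollingball_radius = as.integer(rollingball_radius),
                 threshold_method = threshold_method,
                 min_feature_area = as.integer(min_feature_area),
                 connectivity = as.integer(connectivity)),
            class = "preprocess_params")
}

as_frame <- function(x, pixel_size = NULL, channel = "liposome",
                     frame_index = 1L, timestamp = 0) {
  if (inherits(x, "image_frame")) return(x)
  if (is.null(pixel_size)) stop("'pixel_size' required for a bare matrix")
  structure(list(raster = as.matrix(x), channel = channel,
                 frame_index = as.integer(frame_index),
                 pixel_size = pixel_size, timestamp = timestamp),
            class = "image_frame")
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                                  shape = "disc")

replace_raster <- function(frame, raster) {
  frame$raster <- pmax(as.matrix(raster), 0)
  frame
}

#' Preprocess the liposome channel (white top-hat, then Gaussian)
#'
#' @param frame an `image_frame` (or matrix with `pixel_size` supplied to
#'   [as_frame()] beforehand).
#' @param params a [preprocess_params()].
#' @return An `image_frame` with the filtered, non-negative raster. Filtered
#'   rasters are used for mask-making only; intensity measurements are taken
#'   on the original raster.
#' @export
preprocess_liposome_channel <- function(frame, params = preprocess_params()) {
  stopifnot(inherits(frame, "image_frame"))
  kern <- disc_brush(params$tophat_radius)
  if (any(dim(kern) > dim(frame$raster)))
    stop("top-hat structuring element larger than the raster")
  # EBImage grayscale morphology saturates at 1; rescaling is exact because
  # erosion/dilation commute with positive scaling
  mx <- max(frame$raster)
  x <- if (mx > 0)
    mx * as.matrix(EBImage::whiteTopHat(frame$raster / mx, kern))
  else frame$raster
  x <- EBImage::gblur(x, sigma = params$gaussian_sigma)
  replace_raster(frame, x)
}

#' Preprocess the RNA channel (rolling-ball background subtraction, then
#' Gaussian)
#'
#' The rolling-ball background is estimated by grayscale opening with a disc
#' structuring element of the given radius, the standard morphological
#' approximation.
#'
#' @inheritParams preprocess_liposome_channel
#' @return An `image_frame` with the background-subtracted, smoothed,
#'   non-negative raster.
#' @export
preprocess_rna_channel <- function(frame, params = preprocess_params()) {
  stopifnot(inherits(frame, "image_frame"))
  kern <- disc_brush(params$rollingball_radius)
  if (any(dim(kern) > dim(frame$raster)))
    stop("rolling-ball structuring element larger than the raster")
  mx <- max(frame$raster)
  bg <- if (mx > 0) mx * as.matrix(EBImage::opening(frame$raster / mx, kern))
        else frame$raster
  x <- pmax(frame$raster - bg, 0)
  x <- EBImage::gblur(x, sigma = params$gaussian_sigma)
  replace_raster(frame, x)
}

triangle_threshold <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor((x - min(x)) / (diff(range(x)) + 1e-12) *
                                  nbins), 0) + 1L, nbins), nbins)
  peak <- which.max(h)
  # tail on the side with the longer histogram range
  lo <- min(which(h > 0)); hi <- max(which(h > 0))
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  idx <- if (end > peak) peak:end else end:peak
  hx <- idx; hy <- h[idx]
  # distance from the line connecting (peak, h[peak]) and (end, h[end])
  x1 <- peak; y1 <- h[peak]; x2 <- end; y2 <- h[end]
  d <- abs((y2 - y1) * hx - (x2 - x1) * hy + x2 * y1 - y2 * x1)
  bt <- hx[which.max(d)]
  min(x) + bt / nbins * (diff(range(x)) + 1e-12)
}

# merge 4-connected labels that touch diagonally into 8-connected components
merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  map <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Segment a preprocessed frame into labeled features
#'
#' Global automatic threshold (Otsu by default), binary mask, connected
#' components at the configured connectivity, and rejection of components
#' below `min_feature_area`. An all-zero frame yields an empty label map, not
#' an error.
#'
#' @param frame a preprocessed `image_frame`.
#' @param params a [preprocess_params()].
#' @return Integer label matrix (background 0, features 1..n).
#' @export
segment_features <- function(frame, params = preprocess_params()) {
  stopifnot(inherits(frame, "image_frame"))
  x <- frame$raster
  if (max(x) <= 0) return(matrix(0L, nrow(x), ncol(x)))
  y <- x / max(x)
  thr <- switch(params$threshold_method,
                otsu = EBImage::otsu(EBImage::Image(y), range = c(0, 1)),
                triangle = triangle_threshold(y))
  mask <- y > thr
  lab <- EBImage::bwlabel(mask)        # 4-connectivity
  lab <- matrix(as.integer(round(as.matrix(lab))), nrow(x), ncol(x))
  if (params$connectivity == 8 && max(lab) > 1) lab <- merge_diagonal(lab)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    keep <- which(areas >= params$min_feature_area)
    map <- integer(max(lab))
    map[keep] <- seq_along(keep)
    lab[lab > 0] <- map[lab[lab > 0]]
  }
  lab
}

# perimeter as the length of the traced object contour (unit and sqrt(2)
# steps); falls back to the equivalent-disc perimeter for degenerate contours
contour_perimeters <- function(lab) {
  n <- max(lab)
  if (n == 0) return(numeric(0))
  oc <- EBImage::ocontour(lab)
  areas <- tabulate(lab[lab > 0], n)
  vapply(seq_len(n), function(i) {
    pts <- oc[[i]]
    if (is.null(pts) || nrow(pts) < 3) return(2 * sqrt(pi * areas[i]))
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
    sum(d)
  }, numeric(1))
}

#' Measure features on the original raster
#'
#' For each labeled feature: total intensity, intensity-weighted centroid,
#' intensity-weighted radius of gyration
#' `rg = pixel_size * sqrt(sum I_p |r_p - r_cm|^2 / sum I_p)`, circularity
#' `4 pi area / perimeter^2` (clipped to `[0, 1]`), area, perimeter, and an
#' optional co-channel intensity (sum of a second channel under the mask).
#' Intensities are always taken from the original (unfiltered) raster.
#' Features with zero total intensity get `rg = NA` and `valid = FALSE`;
#' features touching the frame border are flagged.
#'
#' @param labels integer label matrix from [segment_features()].
#' @param frame the original `image_frame` the labels were derived from.
#' @param co_frame optional second-channel `image_frame` of the same shape.
#' @param background scalar background level subtracted from the original
#'   raster before intensities are summed and used as rg weights; `"auto"`
#'   (default) uses the median of the pixels outside all features, `0`
#'   disables the correction.
#' @return A data frame with one row per feature: `feature_id`, `frame`,
#'   `time_min`, `channel`, `row`, `col` (0-based intensity-weighted
#'   centroid), `area_px`, `perimeter_px`, `total_intensity`, `rg_um`,
#'   `circularity`, `co_channel_intensity`, `border_flag`, `valid`.
#' @export
measure_features <- function(labels, frame, co_frame = NULL,
                             background = "auto") {
  stopifnot(inherits(frame, "image_frame"))
  nr <- nrow(labels); nc <- ncol(labels)
  n <- max(labels)
  empty <- data.frame(feature_id = integer(0), frame = integer(0),
                      time_min = numeric(0), channel = character(0),
                      row = numeric(0), col = numeric(0), area_px = integer(0),
                      perimeter_px = numeric(0), total_intensity = numeric(0),
                      rg_um = numeric(0), circularity = numeric(0),
                      co_channel_intensity = numeric(0),
                      border_flag = logical(0), valid = logical(0))
  if (n == 0) return(empty)
  ras <- frame$raster
  bgval <- if (identical(background, "auto")) {
    out_px <- ras[labels == 0]
    if (length(out_px)) median(out_px) else 0
  } else as.numeric(background)
  co <- if (!is.null(co_frame)) co_frame$raster else NULL
  co_bg <- if (!is.null(co)) {
    if (identical(background, "auto")) median(co[labels == 0]) else 0
  } else 0
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  rows0 <- (idx - 1L) %% nr          # 0-based row
  cols0 <- (idx - 1L) %/% nr         # 0-based col
  I <- pmax(ras[idx] - bgval, 0)
  perim <- contour_perimeters(labels)
  ps <- frame$pixel_size
  out <- lapply(seq_len(n), function(i) {
    sel <- lab_v == i
    Ii <- I[sel]; ri <- rows0[sel]; ci <- cols0[sel]
    tot <- sum(Ii)
    area <- sum(sel)
    border <- any(ri == 0 | ri == nr - 1 | ci == 0 | ci == nc - 1)
    if (tot <= 0) {
      return(data.frame(feature_id = i, frame = frame$frame_index,
                        time_min = frame$timestamp, channel = frame$channel,
                        row = mean(ri), col = mean(ci), area_px = area,
                        perimeter_px = perim[i], total_intensity = tot,
                        rg_um = NA_real_, circularity = NA_real_,
                        co_channel_intensity = if (is.null(co)) NA_real_
                                               else sum(pmax(co[idx[sel]] - co_bg, 0)),
                        border_flag = border, valid = FALSE))
    }
    rcm <- sum(Ii * ri) / tot
    ccm <- sum(Ii * ci) / tot
    rg <- ps * sqrt(sum(Ii * ((ri - rcm)^2 + (ci - ccm)^2)) / tot)
    circ <- min(max(4 * pi * area / perim[i]^2, 0), 1)
    data.frame(feature_id = i, frame = frame$frame_index,
               time_min = frame$timestamp, channel = frame$channel,
               row = rcm, col = ccm, area_px = area, perimeter_px = perim[i],
               total_intensity = tot, rg_um = rg, circularity = circ,
               co_channel_intensity = if (is.null(co)) NA_real_
                                      else sum(pmax(co[idx[sel]] - co_bg, 0)),
               border_flag = border, valid = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate particles (monomers) per cluster from total intensity
#'
#' The estimated particle count is the feature's total fluorescent intensity
#' divided by the average single-liposome intensity from a calibration frame.
#'
#' @param total_intensity feature total intensity (vector allowed).
#' @param monomer_mean_intensity average single-liposome intensity (> 0).
#' @param integerize round to the nearest integer, floored at 1.
#' @return Estimated monomer count(s).
#' @export
particles_per_cluster <- function(total_intensity, monomer_mean_intensity,
                                  integerize = FALSE) {
  assert_scalar_num(monomer_mean_intensity, "monomer_mean_intensity",
                    lower = 0, strict_lower = TRUE)
  k <- total_intensity / monomer_mean_intensity
  if (integerize) pmax(1, round(k)) else k
}

#' Average single-liposome intensity from a calibration feature table
#'
#' Uses valid, non-border features whose radius of gyration is below a
#' monomer cutoff (defaults to just above the PSF width, where isolated
#' monomers land).
#'
#' @param features feature table from [measure_features()].
#' @param rg_cutoff_um monomer cutoff on `rg_um`, micrometres.
#' @return Mean total intensity of the selected features.
#' @export
estimate_monomer_intensity <- function(features, rg_cutoff_um = 0.4) {
  sel <- features$valid & !features$border_flag &
    !is.na(features$rg_um) & features$rg_um <= rg_cutoff_um
  if (!any(sel)) stop("no monomer-sized calibration features found")
  mean(features$total_intensity[sel])
}

#' Fit the fractal dimension from mass-size scaling
#'
#' Ordinary least squares of `log(k)` on `log(rg)`: the slope is the fractal
#' dimension d_f in the mass-radius law `k ~ (rg / a)^{d_f}`.
#'
#' @param rg_um radii of gyration, micrometres.
#' @param k_hat estimated monomer counts (same length).
#' @param k_min features with `k_hat < k_min` are dropped before fitting.
#' @param min_features minimum number of features required.
#' @param min_dynamic_range required ratio `max(rg) / min(rg)`.
#' @return Object of class `fractal_fit`: `df` (slope), `se`, `intercept`,
#'   `a` (monomer scale, micrometres), `n`, `r_squared`.
#' @export
fit_fractal_dimension <- function(rg_um, k_hat, k_min = 1,
                                  min_features = 10, min_dynamic_range = 4) {
  keep <- is.finite(rg_um) & is.finite(k_hat) & rg_um > 0 & k_hat >= k_min
  rg_um <- rg_um[keep]; k_hat <- k_hat[keep]
  if (length(rg_um) < min_features)
    stop(sprintf("need >= %d features with k_hat >= %g; got %d",
                 min_features, k_min, length(rg_um)))
  if (max(rg_um) / min(rg_um) < min_dynamic_range)
    stop(sprintf("insufficient rg dynamic range: %.2fx < %gx required",
                 max(rg_um) / min(rg_um), min_dynamic_range))
  fit <- ols_line(log(rg_um), log(k_hat))
  structure(list(df = fit$slope,
                 se = fit$slope_se,
                 intercept = fit$intercept,
                 a = exp(-fit$intercept / fit$slope),
                 n = length(rg_um),
                 r_squared = fit$r_squared),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("Fractal dimension fit: d_f = %.3f +/- %.3f (n = %d, R^2 = %.3f, a = %.3f um)\n",
              x$df, x$se, x$n, x$r_squared, x$a))
  invisible(x)
}

#' Two-channel colocalization metrics
#'
#' Pearson correlation of pixel intensities over an optional mask, and
#' Manders overlap fractions over automatic (Otsu) per-channel thresholds:
#' `mandersA` is the fraction of channel-A intensity lying where channel B is
#' above its threshold, and vice versa.
#'
#' @param frame_a,frame_b `image_frame`s of identical shape.
#' @param mask optional logical or label matrix restricting the Pearson
#'   computation.
#' @return List with `pearson`, `mandersA`, `mandersB`, and `flag`
#'   (`"constant_channel"` when Pearson is undefined).
#' @export
colocalization <- function(frame_a, frame_b, mask = NULL) {
  a <- frame_a$raster; b <- frame_b$raster
  if (!all(dim(a) == dim(b))) stop("frames must have the same shape")
  sel <- if (is.null(mask)) rep(TRUE, length(a)) else as.vector(mask > 0)
  av <- as.vector(a)[sel]; bv <- as.vector(b)[sel]
  flag <- NULL
  pearson <- if (sd(av) == 0 || sd(bv) == 0) {
    flag <- "constant_channel"
    NA_real_
  } else cor(av, bv)
  thr_a <- if (max(a) > min(a)) EBImage::otsu(EBImage::Image(a / max(a)),
                                              range = c(0, 1)) * max(a) else Inf
  thr_b <- if (max(b) > min(b)) EBImage::otsu(EBImage::Image(b / max(b)),
                                              range = c(0, 1)) * max(b) else Inf
  mandersA <- if (sum(a) > 0) sum(a[b > thr_b]) / sum(a) else NA_real_
  mandersB <- if (sum(b) > 0) sum(b[a > thr_a]) / sum(b) else NA_real_
  list(pearson = pearson, mandersA = mandersA, mandersB = mandersB,
       flag = flag)
}

#' Quantify a time series of frames
#'
#' Runs preprocess, segment and measure on every frame of a stack and
#' concatenates the per-feature records; returns per-frame summaries (feature
#' count, mean rg, mean estimated particle count, exclusion counts). Border
#' and zero-intensity features are excluded from the rg statistics but
#' counted.
#'
#' @param frames list of `image_frame`s (one channel) or numeric matrices.
#' @param params a [preprocess_params()].
#' @param pixel_size required when `frames` are bare matrices.
#' @param timestamps optional per-frame times (minutes).
#' @param channel channel tag governing the preprocessing chain.
#' @param co_frames optional matching list for the co-channel intensity.
#' @param monomer_mean_intensity optional calibration for `k_hat`.
#' @param psf_sigma optional PSF sigma (micrometres); when given, a
#'   de-broadened `rg_corr_um = sqrt(max(rg^2 - 2 psf_sigma^2, 0))` column is
#'   added (the isotropic 2-D Gaussian PSF contributes `2 sigma^2` to the
#'   two-coordinate radius of gyration, since rg is additive in quadrature
#'   under convolution).
#'   added.
#' @return List with `features` (data frame) and `summary` (one row per
#'   frame).
#' @export
quantify_timeseries <- function(frames, params = preprocess_params(),
                                pixel_size = NULL, timestamps = NULL,
                                channel = c("liposome", "rna"),
                                co_frames = NULL,
                                monomer_mean_intensity = NULL,
                                psf_sigma = NULL) {
  channel <- match.arg(channel)
  n <- length(frames)
  feats <- vector("list", n)
  summ <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- as_frame(frames[[i]], pixel_size = pixel_size, channel = channel,
                   frame_index = i,
                   timestamp = if (is.null(timestamps)) i - 1 else timestamps[i])
    if (inherits(frames[[i]], "image_frame")) {
      fr$frame_index <- i
      if (!is.null(timestamps)) fr$timestamp <- timestamps[i]
    }
    pre <- if (channel == "liposome") preprocess_liposome_channel(fr, params)
           else preprocess_rna_channel(fr, params)
    lab <- segment_features(pre, params)
    co <- if (!is.null(co_frames))
      as_frame(co_frames[[i]], pixel_size = fr$pixel_size, channel = "rna",
               frame_index = i, timestamp = fr$timestamp) else NULL
    tab <- measure_features(lab, fr, co_frame = co)
    if (!is.null(monomer_mean_intensity) && nrow(tab))
      tab$k_hat <- particles_per_cluster(tab$total_intensity,
                                         monomer_mean_intensity)
    else tab$k_hat <- if (nrow(tab)) NA_real_ else numeric(0)
    if (!is.null(psf_sigma) && nrow(tab))
      tab$rg_corr_um <- sqrt(pmax(tab$rg_um^2 - 2 * psf_sigma^2, 0))
    else tab$rg_corr_um <- if (nrow(tab)) NA_real_ else numeric(0)
    feats[[i]] <- tab
    use <- tab$valid & !tab$border_flag
    summ[[i]] <- data.frame(
      frame = i,
      time_min = fr$timestamp,
      n_features = nrow(tab),
      n_excluded_border = sum(tab$border_flag),
      n_excluded_zero = sum(!tab$valid),
      mean_rg_um = if (any(use)) mean(tab$rg_um[use]) else NA_real_,
      median_rg_um = if (any(use)) median(tab$rg_um[use]) else NA_real_,
      mean_k_hat = if (any(use)) mean(tab$k_hat[use]) else NA_real_)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  list(features = features, summary = do.call(rbind, summ))
}
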
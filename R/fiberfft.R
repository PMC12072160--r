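#' Configuration for ROI spectral analysis
#'
#' Parameters of the 2D-FFT fiber-organization metrics. Defaults: 100x100
#' pixel ROIs; radial frequency band 0.02-0.30 cycles/pixel for the angular
#' profile (the lower edge excludes the DC neighbourhood and slow
#' illumination gradients, the upper edge the noise floor near Nyquist); 36
#' angular bins (5 degree resolution); a Tukey window (flat center, cosine
#' taper over the outer quarter) to suppress edge leakage while keeping the
#' full ROI aperture; spectral-amplitude weighting of the angular profile
#' (robust to the heavy-tailed per-bin power of speckle-like textures);
#' top-quartile power mask for the eccentricity moments.
#'
#' @param roi_size ROI side length in pixels.
#' @param band Radial band `c(r_min, r_max)` in cycles/pixel.
#' @param n_bins Number of angular bins over `[0, pi)`.
#' @param window `"tukey"` (default), `"hann"` or `"none"`.
#' @param weight Angular profile weighting: `"amplitude"` (default, sums
#'   `|F|`) or `"power"` (sums `|F|^2`).
#' @param power_quantile Quantile below which spectral power is zeroed
#'   before the eccentricity moments.
#' @return A list of class `fft_config`.
#' @export
fft_config <- function(roi_size = 100, band = c(0.02, 0.30), n_bins = 36,
                       window = c("tukey", "hann", "none"),
                       weight = c("amplitude", "power"),
                       power_quantile = 0.75) {
  window <- match.arg(window)
  weight <- match.arg(weight)
  if (roi_size < 2) stop("`roi_size` must be >= 2")
  if (length(band) != 2 || band[1] < 0 || band[1] >= band[2] || band[2] > 0.5)
    stop("`band` must satisfy 0 <= r_min < r_max <= 0.5 (Nyquist)")
  if (n_bins < 1) stop("`n_bins` must be >= 1")
  if (power_quantile < 0 || power_quantile >= 1)
    stop("`power_quantile` must be in [0, 1)")
  structure(list(roi_size = as.integer(roi_size), band = band,
                 n_bins = as.integer(n_bins), window = window,
                 weight = weight, power_quantile = power_quantile),
            class = "fft_config")
}

#' Select regions of interest in an image
#'
#' Places `n` non-overlapping square ROIs. Strategies: `grid` tiles the
#' image row-major from the top-left corner; `random` places ROIs by
#' seeded rejection sampling; `mask` restricts to positions where at least
#' 90% of the ROI pixels fall inside a user-supplied binary cell-interior
#' mask. Pixel coordinates are 0-based and an ROI origin is its top-left
#' corner with half-open extent `[row, row+size) x [col, col+size)`.
#'
#' @param image Numeric matrix.
#' @param n Number of ROIs.
#' @param size ROI side length (default 100).
#' @param strategy `"grid"`, `"random"` or `"mask"`.
#' @param mask Logical/0-1 matrix of the same dimensions (mask strategy).
#' @param seed Seed for the random strategy.
#' @param min_inside Minimum fraction of ROI pixels inside the mask.
#' @return A data.frame with 0-based columns `row`, `col`; attribute `size`.
#' @export
select_rois <- function(image, n, size = 100,
                        strategy = c("grid", "random", "mask"),
                        mask = NULL, seed = NULL, min_inside = 0.9) {
  strategy <- match.arg(strategy)
  h <- nrow(image); w <- ncol(image)
  if (h < size || w < size)
    stop(sprintf("image (%dx%d) smaller than ROI size %d", h, w, size))
  if (n < 1) stop("`n` must be >= 1")
  done <- function(df) {
    attr(df, "size") <- as.integer(size)
    df
  }
  if (strategy == "grid") {
    nr <- floor(h / size); nc <- floor(w / size)
    if (n > nr * nc)
      stop(sprintf("cannot place %d non-overlapping ROIs; max feasible is %d",
                   n, nr * nc))
    cells <- expand.grid(col = seq_len(nc) - 1, row = seq_len(nr) - 1)
    return(done(data.frame(row = cells$row[seq_len(n)] * size,
                           col = cells$col[seq_len(n)] * size)))
  }
  if (strategy == "mask") {
    if (is.null(mask)) stop("mask strategy requires a `mask` image")
    if (!all(dim(mask) == dim(image)))
      stop("`mask` must match the image dimensions")
    mask <- matrix(as.logical(mask), nrow(mask))
    stride <- max(1L, floor(size / 4))
    cand <- expand.grid(row = seq(0L, h - size, by = stride),
                        col = seq(0L, w - size, by = stride))
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand$row[i]; cc <- cand$col[i]
      mean(mask[(r + 1):(r + size), (cc + 1):(cc + size)]) >= min_inside
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    chosen <- cand[0, ]
    for (i in seq_len(nrow(cand))) {
      if (nrow(chosen) == n) break
      overlap <- nrow(chosen) > 0 &&
        any(abs(chosen$row - cand$row[i]) < size &
            abs(chosen$col - cand$col[i]) < size)
      if (!overlap) chosen <- rbind(chosen, cand[i, ])
    }
    if (nrow(chosen) < n)
      stop(sprintf("cannot place %d non-overlapping in-mask ROIs; max feasible is %d",
                   n, nrow(chosen)))
    rownames(chosen) <- NULL
    return(done(chosen))
  }
  # random: seeded rejection sampling of non-overlapping origins
  place <- function() {
    chosen <- data.frame(row = integer(0), col = integer(0))
    attempts <- 0L
    while (nrow(chosen) < n && attempts < 1000L * n) {
      r <- sample.int(h - size + 1, 1) - 1L
      cc <- sample.int(w - size + 1, 1) - 1L
      overlap <- nrow(chosen) > 0 &&
        any(abs(chosen$row - r) < size & abs(chosen$col - cc) < size)
      if (!overlap) chosen <- rbind(chosen, data.frame(row = r, col = cc))
      attempts <- attempts + 1L
    }
    chosen
  }
  chosen <- if (is.null(seed)) place() else withr::with_seed(seed, place())
  if (nrow(chosen) < n)
    stop(sprintf("cannot place %d non-overlapping ROIs; placed %d",
                 n, nrow(chosen)))
  done(chosen)
}

# pixels of one ROI (0-based origin, half-open extent)
roi_pixels <- function(image, roi, size = attr(roi, "size") %||% 100, i = 1) {
  r <- roi$row[i]; cc <- roi$col[i]
  image[(r + 1):(r + size), (cc + 1):(cc + size)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# move the DC bin of an FFT output to the center
fftshift2 <- function(m) {
  ish <- c((floor(nrow(m) / 2) + 1):nrow(m), 1:floor(nrow(m) / 2))
  jsh <- c((floor(ncol(m) / 2) + 1):ncol(m), 1:floor(ncol(m) / 2))
  m[ish, jsh]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Tukey (tapered cosine) window: flat over the central 1 - alpha fraction
tukey_window <- function(n, alpha = 0.25) {
  t <- (0:(n - 1)) / (n - 1)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' 2D power spectrum of an ROI
#'
#' Subtracts the ROI mean, optionally applies a separable taper window
#' (Tukey with a quarter taper, or Hann), takes the 2D discrete Fourier
#' transform and returns the squared modulus with the DC bin shifted to the
#' center. With `window = "none"` the spectrum conserves energy:
#' `sum(power) == n_pixels * sum((x - mean(x))^2)` (Parseval). A constant
#' ROI yields an all-zero spectrum, which is valid and flagged by
#' downstream metrics as missing.
#'
#' @param pixels Numeric matrix (one ROI).
#' @param window `"tukey"` (default), `"hann"` or `"none"`.
#' @return A list of class `fiber_spectrum`: `power` (DC-centered matrix),
#'   `fy`, `fx` (frequency per row/column bin, cycles/pixel).
#' @export
power_spectrum <- function(pixels, window = c("tukey", "hann", "none")) {
  window <- match.arg(window)
  if (!is.matrix(pixels) || any(!is.finite(pixels)))
    stop("`pixels` must be a finite numeric matrix")
  x <- pixels - mean(pixels)
  if (window == "hann")
    x <- x * outer(hann_window(nrow(x)), hann_window(ncol(x)))
  if (window == "tukey")
    x <- x * outer(tukey_window(nrow(x)), tukey_window(ncol(x)))
  P <- fftshift2(Mod(stats::fft(x))^2)
  structure(list(power = P,
                 fy = (seq_len(nrow(x)) - 1 - floor(nrow(x) / 2)) / nrow(x),
                 fx = (seq_len(ncol(x)) - 1 - floor(ncol(x) / 2)) / ncol(x),
                 window = window),
            class = "fiber_spectrum")
}

# frequency-coordinate matrices and DC index of a spectrum
spectrum_coords <- function(spec) {
  FY <- matrix(spec$fy, length(spec$fy), length(spec$fx))
  FX <- matrix(spec$fx, length(spec$fy), length(spec$fx), byrow = TRUE)
  list(FY = FY, FX = FX, R = sqrt(FY^2 + FX^2),
       dc = cbind(which(spec$fy == 0), which(spec$fx == 0)))
}

#' Angular power profile of a spectrum
#'
#' Sums spectral power over an annulus `r_min <= r <= r_max` (DC excluded)
#' into angular bins over `[0, pi)`; the orientation of each frequency bin
#' is folded modulo pi since the spectrum of a real image is point-symmetric.
#' The profile is normalized to unit sum when total power is positive.
#' Angles refer to frequency space: an image of fibers with axis theta
#' concentrates spectral power around theta + pi/2. With
#' `weight = "amplitude"` the bins sum the spectral amplitude `|F|`
#' instead of the power `|F|^2`, which tames the heavy-tailed per-bin
#' power of speckle-like fiber textures (the pipeline default, see
#' [fft_config()]).
#'
#' @param spec A `fiber_spectrum`.
#' @param band Radial band `c(r_min, r_max)` in cycles/pixel.
#' @param n_bins Number of angular bins.
#' @param weight `"power"` (default) or `"amplitude"`.
#' @return A list of class `angular_profile`: `theta` (bin centers) and
#'   `power` (normalized bin mass).
#' @export
angular_power_profile <- function(spec, band = c(0.02, 0.30), n_bins = 36,
                                  weight = c("power", "amplitude")) {
  weight <- match.arg(weight)
  stopifnot(inherits(spec, "fiber_spectrum"))
  if (band[1] < 0 || band[1] >= band[2] || band[2] > 0.5 + 1e-12)
    stop("`band` must satisfy 0 <= r_min < r_max <= Nyquist (0.5)")
  co <- spectrum_coords(spec)
  sel <- co$R >= band[1] & co$R <= band[2] & co$R > 0
  if (!any(sel)) stop("empty annulus: no frequency bins in the band")
  theta <- atan2(co$FY[sel], co$FX[sel]) %% pi
  bin <- pmin(floor(theta / (pi / n_bins)) + 1L, n_bins)
  mass <- if (weight == "amplitude") sqrt(spec$power[sel]) else
    spec$power[sel]
  p <- vapply(seq_len(n_bins), function(k) sum(mass[bin == k]), numeric(1))
  tot <- sum(p)
  if (tot > 0) p <- p / tot
  structure(list(theta = (seq_len(n_bins) - 0.5) * pi / n_bins, power = p),
            class = "angular_profile")
}

#' Anisotropy amplitude of an angular profile
#'
#' The magnitude of the second circular harmonic of the angular power
#' distribution, `|sum_k p(theta_k) exp(2i theta_k)|`: 0 for an isotropic
#' profile, 1 for power concentrated at a single axis. The dominant axis is
#' half the argument of the same sum, mapped to `[0, pi)`. This is the
#' fiber-alignment "amplitude" index; it is scale-invariant because the
#' profile is normalized.
#'
#' @param profile An `angular_profile`.
#' @return A list with `amplitude` and `orientation` (both `NA` when the
#'   profile carries no power).
#' @export
amplitude_metric <- function(profile) {
  stopifnot(inherits(profile, "angular_profile"))
  tot <- sum(profile$power)
  if (!is.finite(tot) || tot <= 0)
    return(list(amplitude = NA_real_, orientation = NA_real_))
  p <- profile$power / tot
  z <- sum(p * exp(2i * profile$theta))
  list(amplitude = Mod(z), orientation = (Arg(z) / 2) %% pi)
}

#' Spectral eccentricity
#'
#' Eccentricity of the inertia ellipse of the 2D power distribution: with
#' the DC bin excluded and power below the `power_quantile` quantile zeroed
#' (stabilizing the moments against the noise floor), the power-weighted
#' second central moments in frequency space define an ellipse with
#' semi-axes `a >= b`; eccentricity is `sqrt(1 - b^2/a^2)`. Circularly
#' symmetric spectra give 0, spectra confined to a line through DC give 1;
#' elongated spectra indicate oriented fibers.
#'
#' @param spec A `fiber_spectrum`.
#' @param power_quantile Masking quantile in `[0, 1)` (default 0.75).
#' @return Eccentricity in `[0, 1]`, or `NA` if no power remains.
#' @export
spectral_eccentricity <- function(spec, power_quantile = 0.75) {
  stopifnot(inherits(spec, "fiber_spectrum"))
  co <- spectrum_coords(spec)
  P <- spec$power
  P[co$dc] <- 0
  thr <- stats::quantile(P, power_quantile, names = FALSE)
  P[P < thr] <- 0
  tot <- sum(P)
  if (tot <= 0) return(NA_real_)
  w <- P / tot
  mx <- sum(w * co$FX); my <- sum(w * co$FY)
  cxx <- sum(w * (co$FX - mx)^2)
  cyy <- sum(w * (co$FY - my)^2)
  cxy <- sum(w * (co$FX - mx) * (co$FY - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  if (ev[1] <= 0) return(NA_real_)
  sqrt(1 - max(ev[2], 0) / ev[1])
}

#' Spectral metrics of one ROI
#'
#' Composes the per-ROI measurements: mean fluorescence intensity (raw image
#' units), anisotropy amplitude and dominant fiber orientation from the
#' angular power profile, and spectral eccentricity from the masked moment
#' ellipse. The orientation reported is the fiber axis in image space
#' (the spectral axis rotated by 90 degrees), in `[0, pi)`. A constant
#' (blank) ROI yields the background intensity with missing
#' amplitude/orientation/eccentricity.
#'
#' @param image Numeric matrix.
#' @param roi One-row data.frame with 0-based `row`, `col` (see
#'   [select_rois()]), or a list with those fields.
#' @param config An [fft_config()].
#' @return A one-row data.frame: `roi_row`, `roi_col`, `intensity`,
#'   `amplitude`, `eccentricity`, `orientation`.
#' @export
roi_metrics <- function(image, roi, config = fft_config()) {
  size <- config$roi_size
  px <- image[(roi$row[1] + 1):(roi$row[1] + size),
              (roi$col[1] + 1):(roi$col[1] + size)]
  intensity <- mean(px)
  if (stats::sd(px) == 0) {
    return(data.frame(roi_row = roi$row[1], roi_col = roi$col[1],
                      intensity = intensity, amplitude = NA_real_,
                      eccentricity = NA_real_, orientation = NA_real_))
  }
  spec <- power_spectrum(px, window = config$window)
  prof <- angular_power_profile(spec, band = config$band,
                                n_bins = config$n_bins,
                                weight = config$weight)
  am <- amplitude_metric(prof)
  ecc <- spectral_eccentricity(spec, config$power_quantile)
  orientation <- if (is.na(am$orientation)) NA_real_ else
    (am$orientation + pi / 2) %% pi   # fibers are orthogonal to their spectrum
  data.frame(roi_row = roi$row[1], roi_col = roi$col[1],
             intensity = intensity, amplitude = am$amplitude,
             eccentricity = ecc, orientation = orientation)
}

#' Spectral metrics for all ROIs of an image
#'
#' @param image Numeric matrix.
#' @param rois Data.frame from [select_rois()]; if `NULL`, `n` ROIs are
#'   selected with the given strategy.
#' @param config An [fft_config()].
#' @param n,strategy,seed Passed to [select_rois()] when `rois` is `NULL`.
#' @return A data.frame, one row per ROI.
#' @export
image_metrics <- function(image, rois = NULL, config = fft_config(), n = 5,
                          strategy = "grid", seed = NULL) {
  if (is.null(rois))
    rois <- select_rois(image, n = n, size = config$roi_size,
                        strategy = strategy, seed = seed)
  do.call(rbind, lapply(seq_len(nrow(rois)), function(i)
    roi_metrics(image, rois[i, , drop = FALSE], config)))
}

#' Aggregate ROI metrics
#'
#' Summarizes a metric per group (or per image, or overall) as the median
#' with a confidence interval from [median_ci()]. Missing metric values
#' (e.g. blank ROIs) are excluded and counted.
#'
#' @param metrics Data.frame of per-ROI metrics, with a grouping column when
#'   `group` is given and an `image` column when `level = "image"`.
#' @param value Metric column to summarize (default `"amplitude"`).
#' @param group Optional grouping column name (e.g. `"condition"`).
#' @param level `"roi"` summarizes pooled ROI values; `"image"` first
#'   averages ROIs within each image (more conservative).
#' @param conf_level Confidence level.
#' @param ci_method `"bootstrap"` or `"order_statistic"` (see [median_ci()]).
#' @param seed Seed for the bootstrap.
#' @return A data.frame: `group`, `n`, `n_missing`, `median`, `lo`, `hi`.
#' @export
aggregate_metrics <- function(metrics, value = "amplitude", group = NULL,
                              level = c("roi", "image"), conf_level = 0.95,
                              ci_method = "bootstrap", seed = NULL) {
  level <- match.arg(level)
  if (!value %in% colnames(metrics)) stop("no column `", value, "`")
  g <- if (is.null(group)) rep("all", nrow(metrics)) else metrics[[group]]
  if (level == "image") {
    if (!"image" %in% colnames(metrics))
      stop("level = \"image\" requires an `image` column")
    agg <- stats::aggregate(metrics[[value]],
                            list(group = g, image = metrics$image),
                            mean, na.rm = TRUE)
    g <- agg$group
    vals <- agg$x
  } else vals <- metrics[[value]]
  out <- lapply(split(vals, g), function(v) {
    n_missing <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("no non-missing values in a group")
    ci <- median_ci(v, level = conf_level, method = ci_method, seed = seed)
    data.frame(n = length(v), n_missing = n_missing, median = ci$median,
               lo = ci$lo, hi = ci$hi)
  })
  cbind(data.frame(group = names(out)), do.call(rbind, out), row.names = NULL)
}

#' Rotate an image about its center
#'
#' Bilinear rotation used for equivariance checks of the spectral metrics.
#' Pixels mapping outside the source are filled with `fill`. Angles are in
#' degrees, positive in the direction from the x (column) axis toward the
#' y (row) axis — the same convention as fiber orientations.
#'
#' @param image Numeric matrix.
#' @param angle_deg Rotation angle in degrees.
#' @param fill Fill value for out-of-range pixels (default: image mean).
#' @return Rotated matrix of the same dimensions.
#' @export
rotate_image <- function(image, angle_deg, fill = mean(image)) {
  h <- nrow(image); w <- ncol(image)
  a <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  J <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  I <- matrix(seq_len(h), h, w) - cy
  # inverse map: source coordinates of each output pixel
  sx <- cos(a) * J + sin(a) * I + cx
  sy <- -sin(a) * J + cos(a) * I + cy
  j0 <- floor(sx); i0 <- floor(sy)
  fx <- sx - j0; fy <- sy - i0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    v <- matrix(fill, h, w)
    v[ok] <- image[cbind(ii[ok], jj[ok])]
    v
  }
  out <- (1 - fy) * ((1 - fx) * val(i0, j0) + fx * val(i0, j0 + 1)) +
    fy * ((1 - fx) * val(i0 + 1, j0) + fx * val(i0 + 1, j0 + 1))
  out
}
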
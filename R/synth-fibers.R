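#' Parameters for the synthetic filament-image generator
#'
#' Describes a fluorescence-like image of actin filaments as a sum of
#' anti-aliased straight line segments on a constant background with additive
#' Gaussian noise. Segment orientations follow an axial von-Mises
#' distribution: `kappa = 0` gives uniformly oriented (isotropic) fibers,
#' large `kappa` gives fibers aligned around `mean_orientation`. Orientations
#' are axial, i.e. theta and theta + pi describe the same fiber.
#'
#' @param width,height Image dimensions in pixels; at least 128 so a 100x100
#'   region of interest fits.
#' @param n_fibers Number of segments (0 gives a pure-noise image).
#' @param kappa Von-Mises concentration (>= 0) of the axial orientation
#'   distribution (applied on the doubled angle, the standard axial
#'   construction).
#' @param mean_orientation Mean fiber axis in radians, in `[0, pi)`.
#' @param fiber_length Segment length in pixels (default 25, a fine dense
#'   meshwork; at a typical 60x confocal magnification cortical actin
#'   filaments span tens of pixels).
#' @param fiber_width Gaussian cross-section full width (pixels); the
#'   rendered profile is `exp(-d^2 / (2 * (fiber_width/2)^2))`.
#' @param fiber_intensity Peak added intensity per fiber (image units).
#' @param background Constant background level.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; the generator draws from its own RNG stream.
#' @return A validated list of class `fiber_sim_params`.
#' @export
fiber_sim_params <- function(width = 256, height = 256, n_fibers = 400,
                             kappa = 0, mean_orientation = 0,
                             fiber_length = 25, fiber_width = 2,
                             fiber_intensity = 100, background = 10,
                             noise_sd = 5, seed = 1L) {
  if (width < 128 || height < 128)
    stop("image dimensions must be >= 128 so that 100x100 ROIs fit")
  if (n_fibers < 0) stop("`n_fibers` must be >= 0")
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (mean_orientation < 0 || mean_orientation >= pi)
    stop("`mean_orientation` must be in [0, pi)")
  if (fiber_length <= 0 || fiber_width <= 0 || fiber_intensity <= 0)
    stop("fiber geometry/intensity parameters must be positive")
  if (background < 0 || noise_sd < 0)
    stop("`background` and `noise_sd` must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_fibers = as.integer(n_fibers), kappa = kappa,
                 mean_orientation = mean_orientation,
                 fiber_length = fiber_length, fiber_width = fiber_width,
                 fiber_intensity = fiber_intensity, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fiber_sim_params")
}

#' Axial von-Mises orientation sampler
#'
#' Draws fiber axes in `[0, pi)` whose doubled angles follow a von-Mises
#' distribution with mean `2 * mu` and concentration `kappa` (the standard
#' construction for undirected, 180-degree-periodic data). `kappa = 0`
#' reduces to the uniform distribution on `[0, pi)`. Sampling uses the
#' Best-Fisher rejection algorithm.
#'
#' @param n Number of draws.
#' @param mu Mean axis in radians.
#' @param kappa Concentration >= 0.
#' @return Numeric vector of orientations in `[0, pi)`.
#' @export
rvonmises_axial <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, pi))
  # Best & Fisher (1979) envelope-rejection sampler on the doubled angle
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    ce <- kappa * (r - f)
    if (ce * (2 - ce) - u[2] > 0 || log(ce / u[2]) + 1 - ce >= 0) {
      phi <- sign(u[3] - 0.5) * acos(f) + 2 * mu
      out[i] <- (phi / 2) %% pi
      i <- i + 1L
    }
  }
  out
}

#' Simulate a filament image
#'
#' Renders the fibers described by [fiber_sim_params()] into a non-negative
#' real-valued image. Each fiber is an anti-aliased segment with a Gaussian
#' cross-section, centered uniformly at random in the image, with an axial
#' von-Mises orientation. Background and Gaussian noise are added last and
#' the image is clipped at zero.
#'
#' @param params A `fiber_sim_params` object.
#' @return A numeric `height x width` matrix (class `fiber_image`), row index
#'   = image row (y, increasing downwards), column index = x. Attributes
#'   record the parameters and the sampled orientations.
#' @export
simulate_fiber_image <- function(params) {
  stopifnot(inherits(params, "fiber_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    img <- matrix(0, p$height, p$width)
    theta <- rvonmises_axial(p$n_fibers, p$mean_orientation, p$kappa)
    cx <- stats::runif(p$n_fibers, 0, p$width)
    cy <- stats::runif(p$n_fibers, 0, p$height)
    sigma <- p$fiber_width / 2
    half <- p$fiber_length / 2
    pad <- 3 * sigma
    for (k in seq_len(p$n_fibers)) {
      ux <- cos(theta[k]); uy <- sin(theta[k])
      x0 <- cx[k] - half * ux; x1 <- cx[k] + half * ux
      y0 <- cy[k] - half * uy; y1 <- cy[k] + half * uy
      jmin <- max(1L, floor(min(x0, x1) - pad)); jmax <- min(p$width, ceiling(max(x0, x1) + pad))
      imin <- max(1L, floor(min(y0, y1) - pad)); imax <- min(p$height, ceiling(max(y0, y1) + pad))
      if (jmin > jmax || imin > imax) next
      xs <- (jmin:jmax) - 0.5   # pixel-center coordinates
      ys <- (imin:imax) - 0.5
      dx <- outer(rep(1, length(ys)), xs - cx[k])
      dy <- outer(ys - cy[k], rep(1, length(xs)))
      t_along <- pmin(pmax(dx * ux + dy * uy, -half), half)
      d2 <- (dx - t_along * ux)^2 + (dy - t_along * uy)^2
      img[imin:imax, jmin:jmax] <- img[imin:imax, jmin:jmax] +
        p$fiber_intensity * exp(-d2 / (2 * sigma^2))
    }
    img <- img + p$background +
      matrix(stats::rnorm(length(img), 0, p$noise_sd), nrow(img))
    img <- pmax(img, 0)
    attr(img, "params") <- params
    attr(img, "orientations") <- theta
    class(img) <- c("fiber_image", class(img))
    img
  })
}

#' Write / read a fiber image
#'
#' Images are written as 16-bit grayscale TIFF (or PNG), linearly scaled to
#' the full bit range; the linear scale (offset and factor) is recorded in a
#' JSON sidecar (`<path>.json`) so that reading restores the original units.
#'
#' @param image Numeric matrix with non-negative finite values.
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @return `write_fiber_image` returns `path` invisibly; `read_fiber_image`
#'   returns the image matrix in original units (if a sidecar is present)
#'   or in `[0, 1]` units otherwise.
#' @export
write_fiber_image <- function(image, path) {
  stopifnot(is.matrix(image), all(is.finite(image)), min(image) >= 0)
  lo <- min(image); hi <- max(image)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (image - lo) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported image extension: ", ext)
  jsonlite::write_json(list(offset = lo, scale = scale, bit_depth = 16L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiber_image
#' @export
read_fiber_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]   # grayscale channel
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * sc$scale + sc$offset
  }
  img
}
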
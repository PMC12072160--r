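test_that("ROI selection is geometric, non-overlapping and validated", {
  img <- matrix(0, 100, 100)
  r1 <- select_rois(img, 1, strategy = "grid")
  expect_equal(unlist(r1), c(row = 0, col = 0))
  expect_error(select_rois(matrix(0, 99, 200), 1), "smaller than ROI")
  big <- matrix(0, 512, 512)
  r9 <- select_rois(big, 9, strategy = "grid")
  expect_equal(nrow(r9), 9)
  for (i in 1:8) for (j in (i + 1):9)
    expect_true(abs(r9$row[i] - r9$row[j]) >= 100 ||
                abs(r9$col[i] - r9$col[j]) >= 100)
  expect_error(select_rois(big, 26, strategy = "grid"), "max feasible is 25")
  # random strategy: deterministic given seed, disjoint
  ra <- select_rois(big, 6, strategy = "random", seed = 7)
  rb <- select_rois(big, 6, strategy = "random", seed = 7)
  expect_identical(ra, rb)
  for (i in 1:5) for (j in (i + 1):6)
    expect_true(abs(ra$row[i] - ra$row[j]) >= 100 ||
                abs(ra$col[i] - ra$col[j]) >= 100)
  # mask strategy restricts to the cell interior
  mask <- matrix(FALSE, 512, 512); mask[1:220, 1:220] <- TRUE
  rm_ <- select_rois(big, 2, strategy = "mask", mask = mask)
  expect_true(all(rm_$row + 100 <= 232 & rm_$col + 100 <= 232))
  expect_error(select_rois(big, 2, strategy = "mask"), "requires a `mask`")
})

test_that("power spectra conserve energy and localize a cosine grating", {
  withr::with_seed(31, roi <- matrix(runif(100 * 100), 100, 100))
  sp <- power_spectrum(roi, window = "none")
  x <- roi - mean(roi)
  expect_equal(sum(sp$power), length(x) * sum(x^2), tolerance = 1e-8)
  # grating cos(2 pi f y) concentrates at the two bins (+-f, 0)
  f <- 10 / 100
  g <- outer(cos(2 * pi * f * (0:99)), rep(1, 100))
  spg <- power_spectrum(g, window = "none")
  hot <- which(spg$power > max(spg$power) * 1e-6, arr.ind = TRUE)
  expect_equal(nrow(hot), 2)
  expect_setequal(spg$fy[hot[, 1]], c(-f, f))
  expect_true(all(spg$fx[hot[, 2]] == 0))
  # constant ROI: zero spectrum is valid
  expect_true(all(power_spectrum(matrix(5, 100, 100))$power == 0))
})

test_that("angular profiles behave on rings, deltas and rotations", {
  base <- power_spectrum(matrix(5, 100, 100), window = "none")
  co <- list(fy = base$fy, fx = base$fx)
  R <- sqrt(outer(co$fy^2, co$fx^2, "+"))
  # isotropic ring of equal power -> uniform profile
  ring <- base
  sel <- R >= 0.1 & R <= 0.2
  ring$power[sel] <- 1
  pr <- angular_power_profile(ring, band = c(0.05, 0.3), n_bins = 36)
  # equal power per bin: profile must equal the bin-count distribution
  theta_sel <- atan2(matrix(base$fy, 100, 100)[sel],
                     matrix(base$fx, 100, 100, byrow = TRUE)[sel]) %% pi
  counts <- tabulate(pmin(floor(theta_sel / (pi / 36)) + 1, 36), 36)
  expect_equal(pr$power, counts / sum(counts))
  expect_lt(amplitude_metric(pr)$amplitude, 0.02)
  # single symmetric bin pair at angle phi -> delta at phi mod pi
  phi_spec <- base
  iy <- which.min(abs(base$fy - 0.1)); ix <- which.min(abs(base$fx - 0.1))
  iy2 <- which.min(abs(base$fy + 0.1)); ix2 <- which.min(abs(base$fx + 0.1))
  phi_spec$power[iy, ix] <- 1; phi_spec$power[iy2, ix2] <- 1
  prd <- angular_power_profile(phi_spec, band = c(0.05, 0.3), n_bins = 36)
  expect_equal(sum(prd$power > 0), 1)
  expect_lt(axial_diff(prd$theta[which.max(prd$power)], pi / 4), pi / 36)
  expect_error(angular_power_profile(base, band = c(0.001, 0.005)),
               "empty annulus")
  # rotating the ROI by 90 degrees circularly shifts the profile by pi/2
  img <- simulate_fiber_image(fiber_sim_params(kappa = 8, seed = 13))
  roi <- img[1:100, 1:100]
  roi90 <- t(roi)[100:1, ]                      # exact 90-degree rotation
  p1 <- angular_power_profile(power_spectrum(roi), n_bins = 36)
  p2 <- angular_power_profile(power_spectrum(roi90), n_bins = 36)
  shifted <- c(p2$power[19:36], p2$power[1:18])  # shift by 18 bins = pi/2
  expect_gt(cor(p1$power, shifted), 0.95)
})

test_that("amplitude metric hits its analytic limits", {
  theta <- (seq_len(36) - 0.5) * pi / 36
  uni <- structure(list(theta = theta, power = rep(1 / 36, 36)),
                   class = "angular_profile")
  expect_equal(amplitude_metric(uni)$amplitude, 0, tolerance = 1e-12)
  delta <- structure(list(theta = theta,
                          power = c(1, rep(0, 35))),
                     class = "angular_profile")
  expect_equal(amplitude_metric(delta)$amplitude, 1)
  expect_equal(amplitude_metric(delta)$orientation, theta[1])
  # two equal deltas a quarter-turn apart cancel in the 2-theta harmonic
  two <- structure(list(theta = theta,
                        power = as.numeric(seq_len(36) %in% c(1, 19)) / 2),
                   class = "angular_profile")
  expect_lt(amplitude_metric(two)$amplitude, 1e-12)
  none <- structure(list(theta = theta, power = rep(0, 36)),
                    class = "angular_profile")
  expect_true(is.na(amplitude_metric(none)$amplitude))
})

test_that("spectral eccentricity separates symmetric, linear and noisy spectra", {
  base <- power_spectrum(matrix(5, 100, 100), window = "none")
  R <- sqrt(outer(base$fy^2, base$fx^2, "+"))
  ring <- base; ring$power[R >= 0.1 & R <= 0.2] <- 1
  expect_lt(spectral_eccentricity(ring, 0), 0.05)       # circular symmetry
  # vertical grating: power on a single line through DC -> eccentricity 1
  g <- outer(cos(2 * pi * 0.1 * (0:99)), rep(1, 100))
  expect_equal(spectral_eccentricity(power_spectrum(g, window = "none")), 1)
  blank <- power_spectrum(matrix(1, 100, 100))
  expect_true(is.na(spectral_eccentricity(blank)))
})

test_that("isotropic noise gives low eccentricity, aligned fibers high", {
  # oracle-computed floor: the masked moment ellipse of pure noise has mean
  # eccentricity ~0.25 (sqrt singularity of ecc at isotropy); aligned
  # fibers are near 1
  eccs <- vapply(1:10, function(s) {
    img <- simulate_fiber_image(fiber_sim_params(n_fibers = 0, seed = s))
    image_metrics(img, n = 1)$eccentricity
  }, numeric(1))
  expect_lt(mean(eccs), 0.3)
  img8 <- simulate_fiber_image(fiber_sim_params(kappa = 8, seed = 1))
  expect_gt(image_metrics(img8, n = 1)$eccentricity, 0.8)
})

test_that("roi metrics compose, stay scale-invariant and flag blank ROIs", {
  img <- simulate_fiber_image(fiber_sim_params(kappa = 8, seed = 17))
  roi <- data.frame(row = 50, col = 50)
  m <- roi_metrics(img, roi)
  expect_equal(m$intensity, mean(img[51:150, 51:150]))
  expect_true(m$amplitude > 0.2 && m$amplitude <= 1)
  expect_true(m$eccentricity > 0.5)
  # intensity rescaling x -> 2x leaves amplitude essentially unchanged
  m2 <- roi_metrics(img * 2, roi)
  expect_lt(abs(m2$amplitude - m$amplitude), 0.02)
  expect_lt(abs(m2$eccentricity - m$eccentricity), 0.02)
  expect_equal(m2$intensity, 2 * m$intensity)
  blank <- matrix(7, 200, 200)
  mb <- roi_metrics(blank, roi)
  expect_equal(mb$intensity, 7)
  expect_true(is.na(mb$amplitude) && is.na(mb$eccentricity))
})

test_that("amplitude rises with orientation concentration per seed pair", {
  pairs <- vapply(1:20, function(s) {
    a0 <- mean(image_metrics(simulate_fiber_image(
      fiber_sim_params(kappa = 0, seed = s)), n = 2)$amplitude)
    a8 <- mean(image_metrics(simulate_fiber_image(
      fiber_sim_params(kappa = 8, seed = s)), n = 2)$amplitude)
    a8 > a0
  }, logical(1))
  expect_gte(sum(pairs), 19)
})

test_that("aggregate_metrics summarizes per group with median CIs", {
  df <- data.frame(condition = rep(c("CTR", "FSH"), each = 5),
                   image = rep(c("i1", "i2"), 5),
                   amplitude = c(1:5, 6:10))
  out <- aggregate_metrics(df, group = "condition", seed = 1)
  expect_equal(out$median[out$group == "CTR"], 3)
  expect_equal(out$n, c(5, 5))
  # missing metrics are excluded and counted
  df$amplitude[1] <- NA
  out2 <- aggregate_metrics(df, group = "condition", seed = 1)
  expect_equal(out2$n_missing[out2$group == "CTR"], 1)
  # image-level averaging first
  out3 <- aggregate_metrics(df, group = "condition", level = "image",
                            seed = 1)
  expect_equal(out3$n, c(2, 2))
})
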
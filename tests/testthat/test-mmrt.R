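# MMRT evaluation, closed-form fitting, thermodynamic profiles, KIE and
# bootstrap uncertainty.

test_that("ln rate matches direct evaluation with physical constants", {
  co <- phys_constants()
  p <- mmrt_params(dH_T0 = 50, dS_T0 = 0, dCp = 0, T0 = 300)
  expect_equal(mmrt_ln_rate(p, 300),
               log(co$kB * 300 / co$h) - 50000 / (co$R * 300),
               tolerance = 1e-12)
  expect_error(mmrt_ln_rate(p, -1), "positive")
})

test_that("dCp does not affect ln k at the reference temperature", {
  p0 <- mmrt_params(60, 0.1, 0, T0 = 348)
  p1 <- mmrt_params(60, 0.1, -5, T0 = 348)
  p2 <- mmrt_params(60, 0.1, 3, T0 = 348)
  expect_equal(mmrt_ln_rate(p0, 348), mmrt_ln_rate(p1, 348))
  expect_equal(mmrt_ln_rate(p0, 348), mmrt_ln_rate(p2, 348))
  expect_false(isTRUE(all.equal(mmrt_ln_rate(p0, 320),
                                mmrt_ln_rate(p1, 320))))
})

test_that("negative dCp gives a unique interior optimum at the analytic root", {
  p <- mmrt_params(54.7, 1.27, -3.0, T0 = 348)
  grid <- seq(280, 420, by = 0.001)
  lnk <- mmrt_ln_rate(p, grid)
  expect_equal(mmrt_t_opt(p), grid[which.max(lnk)], tolerance = 0.002)
  # interior and unique: curve decreases on both sides
  i <- which.max(lnk)
  expect_true(i > 1 && i < length(grid))
  expect_true(all(diff(lnk[1:i]) > 0) && all(diff(lnk[i:length(lnk)]) < 0))
})

test_that("noiseless series are recovered to 1e-8 relative", {
  true <- mmrt_params(54.7, -0.069, -3.0, T0 = 348)
  T <- seq(293, 358, length.out = 10)
  ser <- temperature_rate_series(T, exp(mmrt_ln_rate(true, T)))
  f <- fit_mmrt(ser, T0 = 348)
  expect_equal(coef(f)[["dH_T0"]], 54.7, tolerance = 1e-8)
  expect_equal(coef(f)[["dS_T0"]], -0.069, tolerance = 1e-8)
  expect_equal(coef(f)[["dCp"]], -3.0, tolerance = 1e-8)
})

test_that("closed-form solution equals an iterative nonlinear solve", {
  ser <- gen_mmrt_series(54.7, -3.0, 348, 348, 10, noise_sd = 0.02, seed = 9)
  f <- fit_mmrt(ser, T0 = 348)
  obj <- function(th) {
    p <- mmrt_params(th[1], th[2], th[3], T0 = 348)
    sum((log(ser$rate) - mmrt_ln_rate(p, ser$temperature))^2)
  }
  opt <- optim(coef(f) * c(1.05, 1.1, 0.9), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(coef(f)), unname(opt$par), tolerance = 1e-6)
})

test_that("fits are invariant under reparameterization of T0", {
  ser <- gen_mmrt_series(54.7, -3.0, 348, 348, 10, noise_sd = 0.02, seed = 10)
  f298 <- fit_mmrt(ser, T0 = 298)
  f348 <- fit_mmrt(ser, T0 = 348)
  expect_equal(coef(f298)[["dCp"]], coef(f348)[["dCp"]], tolerance = 1e-10)
  grid <- seq(290, 360, length.out = 50)
  expect_equal(mmrt_ln_rate(f298$params, grid), mmrt_ln_rate(f348$params, grid),
               tolerance = 1e-10)
  # dH/dS transform consistently between reference temperatures
  dCp <- coef(f348)[["dCp"]]
  expect_equal(coef(f298)[["dH_T0"]],
               coef(f348)[["dH_T0"]] + dCp * (298 - 348), tolerance = 1e-8)
  expect_equal(coef(f298)[["dS_T0"]],
               coef(f348)[["dS_T0"]] + dCp * log(298 / 348), tolerance = 1e-8)
})

test_that("Eyring limit: dCp = 0 data fit linearly and dCp stays within noise", {
  # exact linearity of the basis at zero noise
  ser0 <- gen_mmrt_series(60, 0, 348, 348, 10, noise_sd = 0, seed = 1)
  co <- phys_constants()
  y <- log(ser0$rate) - log(co$kB * ser0$temperature / co$h)
  lin <- lm(y ~ I(1 / ser0$temperature))
  expect_lt(max(abs(residuals(lin))), 1e-10)
  # with noise, fitted dCp is within 3 SE in at least 95% of seeds
  hits <- vapply(1:60, function(s) {
    ser <- gen_mmrt_series(60, 0, 348, 348, 10, noise_sd = 0.02, seed = s)
    f <- fit_mmrt(ser, T0 = 348)
    abs(coef(f)[["dCp"]]) < 3 * f$se[["dCp"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dCp recovery is unbiased across the studied range", {
  T <- seq(293, 358, length.out = 14)
  for (dCp_true in c(-3, -1, 0, 1.4)) {
    est <- vapply(1:200, function(s) {
      ser <- gen_mmrt_series(60, dCp_true, 348, 348, 10,
                             temperatures = T, noise_sd = 0.02,
                             seed = 5000 + s)
      coef(fit_mmrt(ser, T0 = 348))[["dCp"]]
    }, numeric(1))
    bias <- mean(est) - dCp_true
    expect_lt(abs(bias), 0.1 * sd(est))
  }
})

test_that("thermodynamic profiles obey their defining identities", {
  p <- mmrt_params(54.7, 1.27, -3.0, T0 = 348)
  grid <- seq(290, 360, by = 0.5)
  prof <- thermo_profile(p, grid)
  expect_equal(prof$dG, prof$dH - grid * prof$dS)     # exact identity
  expect_equal(thermo_profile(p, 348)$dH, 54.7)
  expect_equal(thermo_profile(p, 348)$dS, 1.27)
  # finite-difference slope of dH equals dCp
  expect_equal(diff(prof$dH) / diff(grid), rep(-3.0, length(grid) - 1),
               tolerance = 1e-9)
  # dCp = 0: constant dH and dS
  prof0 <- thermo_profile(mmrt_params(60, 0.1, 0, T0 = 348), grid)
  expect_equal(max(prof0$dH) - min(prof0$dH), 0)
  expect_equal(max(prof0$dS) - min(prof0$dS), 0)
})

test_that("KIE of identical series is identically 1 with zero ddCp", {
  ser <- gen_mmrt_series(67.9, -1.1, 348, 348, 10, noise_sd = 0.02,
                         substrate = "d-galactose", seed = 11)
  kp <- fit_kie_pair(ser, ser, T0 = 348)
  expect_equal(kp$kie, rep(1, length(kp$T_grid)))
  expect_equal(kp$ddCp, 0)
})

test_that("with equal curvature the KIE is log-linear in 1/T", {
  h <- gen_mmrt_series(60, -2, 348, 348, 10, noise_sd = 0,
                       substrate = "s", seed = 1)
  d <- gen_mmrt_series(65, -2, 348, 348, 10 / 1.7, noise_sd = 0,
                       substrate = "s", isotopologue = "1-D", seed = 1)
  kp <- fit_kie_pair(h, d, T0 = 348)
  pH <- attr(h, "true_params"); pD <- attr(d, "true_params")
  co <- phys_constants()
  closed <- exp((pH$dS_T0 - pD$dS_T0) * 1000 / co$R -
                  (pH$dH_T0 - pD$dH_T0) * 1000 / (co$R * kp$T_grid))
  expect_equal(kp$kie, closed, tolerance = 1e-6)
  expect_lt(abs(kp$ddCp), 1e-6)
})

test_that("mismatched substrate labels are rejected", {
  a <- gen_mmrt_series(60, -2, 348, 348, 10, substrate = "a", seed = 1)
  b <- gen_mmrt_series(60, -2, 348, 348, 10, substrate = "b", seed = 1)
  expect_error(fit_kie_pair(a, b), "labels differ")
})

test_that("bootstrap CIs are seed-deterministic and degenerate at zero noise", {
  ser0 <- gen_mmrt_series(54.7, -3.0, 348, 348, 10, noise_sd = 0, seed = 1)
  f0 <- fit_mmrt(ser0)
  expect_warning(b0 <- bootstrap_ci(f0, n_boot = 100, seed = 1), "zero-width")
  expect_equal(b0$ci[, 1], b0$ci[, 2])
  ser <- gen_mmrt_series(54.7, -3.0, 348, 348, 10, noise_sd = 0.02, seed = 2)
  f <- fit_mmrt(ser)
  b1 <- bootstrap_ci(f, n_boot = 150, seed = 7)
  b2 <- bootstrap_ci(f, n_boot = 150, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_lt(b1$ci["dCp", 1], coef(f)[["dCp"]])
  expect_gt(b1$ci["dCp", 2], coef(f)[["dCp"]])
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  T1 <- seq(293, 358, length.out = 14)
  T2 <- seq(293, 358, length.out = 28)
  w <- vapply(list(T1, T2), function(T) {
    ser <- gen_mmrt_series(54.7, -3.0, 348, 348, 10, temperatures = T,
                           noise_sd = 0.02, seed = 33)
    ci <- bootstrap_ci(fit_mmrt(ser), n_boot = 200, seed = 5)$ci
    ci["dCp", 2] - ci["dCp", 1]
  }, numeric(1))
  ratio <- w[1] / w[2]
  expect_gt(ratio, 1.05)   # wider with fewer points
  expect_lt(ratio, 2.3)    # of the order sqrt(2)
})
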
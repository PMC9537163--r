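test_that("coherence is zero without a field and kicks to mu A / hbar", {
  g <- fx("grid")
  mode <- vib_mode(1148, 0.33)
  w0 <- waveform(g, rep(0, g$n))
  expect_true(all(coherence_trajectory(w0, mode)$rho == 0))
  # near-delta drive: carrier-free Gaussian of area A
  gd <- time_grid(-200, 0.1, 42001)
  t <- grid_times_s(gd)
  sig <- 0.5e-15
  E0 <- 1e6
  wd <- waveform(gd, E0 * exp(-t^2 / (2 * sig^2)))
  A <- E0 * sig * sqrt(2 * pi)
  tr <- coherence_trajectory(wd, mode)
  t_fs <- grid_times_fs(gd)
  after <- t_fs > 5 & t_fs < 3000
  jump <- debye_to_Cm(0.33) * A / cet_constants$hbar
  gam <- fwhm_to_gamma(19.4)
  expect_equal(Mod(tr$rho[after]),
               jump * exp(-gam * t[after]), tolerance = 0.02)
  # decay rate recovered from the log-magnitude slope
  fitslope <- stats::coef(stats::lm(log(Mod(tr$rho[after])) ~ t[after]))[2]
  expect_equal(unname(fitslope), -gam, tolerance = 0.01)
})

test_that("without relaxation the post-pulse coherence magnitude is constant", {
  mode <- vib_mode(1148, 0.33)
  tr <- coherence_trajectory(fx("fce"), mode, relax = FALSE)
  after <- grid_times_fs(fx("grid")) > 300
  m <- Mod(tr$rho[after])
  expect_lt(diff(range(m)) / mean(m), 1e-6)
})

test_that("rotating frame preserves magnitude; RWA removes 2w content", {
  mode <- vib_mode(1280, 0.38)
  tr <- coherence_trajectory(fx("fce"), mode)
  trr <- coherence_trajectory(fx("fce"), mode, rwa = TRUE)
  rf <- rotating_frame(tr)
  expect_equal(Mod(rf$rho), Mod(tr$rho), tolerance = 1e-12)
  spec_of <- function(z) {
    npad <- length(z)
    om <- cetscope:::.fft_omega(npad, 0.5e-15)
    list(nu = omega_to_wavenumber(om), p = Mod(stats::fft(z))^2)
  }
  # RWA trajectory in the frame is smooth: negligible power beyond w_k
  sr <- spec_of(rotating_frame(trr)$rho)
  hi <- abs(sr$nu) > 1280
  expect_lt(sum(sr$p[hi]) / sum(sr$p), 1e-4)
  # the non-RWA difference concentrates near 2 w_k
  sd_ <- spec_of(rotating_frame(tr)$rho - rotating_frame(trr)$rho)
  pk <- sd_$nu[which.max(sd_$p)]
  expect_equal(pk, 2 * 1280, tolerance = 0.1)
})

test_that("the counter-rotating cycloid has one bump per field half-cycle", {
  mode <- vib_mode(1280, 0.38)
  d <- rotating_frame(coherence_trajectory(fx("fce"), mode))$rho -
    rotating_frame(coherence_trajectory(fx("fce"), mode, rwa = TRUE))$rho
  env <- Mod(cetscope:::analytic_signal(fx("fce")$field))
  active <- env > 0.1 * max(env)
  x <- Re(d[active])
  n_bumps <- sum(diff(sign(diff(x))) < 0)
  t_active <- sum(active) * 0.5e-15
  n_halfcycles <- 2 * t_active * cet_constants$c * 126000
  expect_equal(n_bumps, n_halfcycles, tolerance = 0.3)
})

test_that("time- and frequency-domain polarizations agree (dual route)", {
  w <- fx("fce")
  s <- fx("expt")
  pt <- polarization(w, s, method = "time")$p
  pf <- polarization(w, s, method = "frequency")$p
  expect_lt(sqrt(mean((pt - pf)^2)) / sqrt(mean(pt^2)), 0.005)
  expect_silent(polarization(w, s, method = "time", verify = TRUE))
  # linear in concentration
  s2 <- sample_preset("table1_experiment", beta_mg_ml = 20)
  p2 <- polarization(w, s2, method = "time")$p
  expect_equal(p2, 2 * pt, tolerance = 1e-10)
  w0 <- waveform(w$grid, rep(0, w$grid$n))
  expect_true(all(polarization(w0, s)$p == 0))
})

test_that("excited-state population stays perturbative and scales quadratically", {
  s <- fx("expt")
  w <- fx("fce")  # 75 kV/cm peak field
  p <- excited_population(coherence_trajectory(w, s$modes[[2]]))
  expect_lte(p, 3e-3)
  expect_gt(p, 0)
  wh <- waveform(w$grid, 2 * w$field, w$meta)
  ph <- excited_population(coherence_trajectory(wh, s$modes[[2]]))
  expect_equal(ph / p, 4, tolerance = 1e-9)
  g <- fx("grid")
  expect_equal(excited_population(
    coherence_trajectory(waveform(g, rep(0, g$n)), s$modes[[1]])), 0)
})

test_that("thin-sample CET equals the coherence energy tally", {
  w <- fx("fce")
  sthin <- sample_preset("table1_experiment", beta_mg_ml = 0.2)
  trs <- lapply(sthin$modes, function(m) coherence_trajectory(w, m))
  chk <- cet_coherence_check(cet(w, propagate(w, sthin)), trs, sthin)
  expect_lt(chk$residual, 0.02)
  expect_equal(chk$scale, 1, tolerance = 0.02)
  # the identity is a thin-sample statement: the residual grows with beta
  sfull <- fx("expt")
  trsf <- lapply(sfull$modes, function(m) coherence_trajectory(w, m))
  chkf <- cet_coherence_check(cet(w, fx("fce_trans")), trsf, sfull)
  expect_gt(chkf$residual, chk$residual)
  # empty sample: both sides vanish
  s0 <- sample_preset("table1_experiment", beta_mg_ml = 0)
  chk0 <- cet_coherence_check(cet(w, w), trsf, s0)
  expect_equal(chk0$residual, 0)
})

test_that("energy transfer proceeds in half-cycle steps", {
  stF <- subcycle_steps(fx("fce_cet"), fx("fce"))
  expect_gt(stF$fraction_compliant, 0.9)
  halfT <- 1e15 / (2 * cet_constants$c * 126000)
  expect_equal(stF$median_step_fs, halfT, tolerance = 0.1)
  stC <- subcycle_steps(fx("cpe_cet"), fx("cpe"))
  expect_equal(stC$median_step_fs, halfT, tolerance = 0.1)
  expect_gt(stC$n_steps, 50)
  # no sample, no steps
  g <- fx("grid")
  zero <- structure(list(grid = g, cet = rep(0, g$n), meta = NULL),
                    class = "cet_trace")
  st0 <- subcycle_steps(zero, fx("fce"))
  expect_identical(st0$n_steps, 0L)
})

test_that("chirped excitation produces coherent transients", {
  mx <- cet_local_maxima(fx("cpe_cet"), prominence = 0.02, min_sep_fs = 60)
  expect_gte(nrow(mx), 2)
  # single-mode run attributes transients to that mode: the CET maxima
  # sit near maxima of |rho|^2 (delayed by the dissipation tally, which
  # flattens CET around the coherence peak)
  s1 <- sample_spec(vib_mode(1135, 0.30), beta_mg_ml = 10)
  tr1 <- cet(fx("cpe"), propagate(fx("cpe"), s1))
  mx1 <- cet_local_maxima(tr1, prominence = 0.02, min_sep_fs = 60)
  co <- coherence_trajectory(fx("cpe"), s1$modes[[1]])
  r2 <- structure(list(grid = fx("grid"), cet = Mod(co$rho)^2, meta = NULL),
                  class = "cet_trace")
  mr <- cet_local_maxima(r2, prominence = 0.02, min_sep_fs = 60)
  expect_gte(nrow(mx1), 1)
  for (tm in mx1$time_fs)
    expect_lt(min(abs(mr$time_fs - tm)), 60)
  # |rho| in the rotating frame is non-monotone after resonance passage
  rf <- Mod(rotating_frame(co)$rho)
  late <- grid_times_fs(fx("grid")) > 100 & grid_times_fs(fx("grid")) < 1500
  expect_gt(sum(diff(sign(diff(rf[late]))) < 0), 1)
})

test_that("mode-subset CET reconstructs the two-mode result additively", {
  w <- fx("fce")
  s <- sample_preset("table1_experiment", beta_mg_ml = 1)
  both <- cet(w, propagate(w, s))
  parts <- lapply(1:2, function(k) {
    sk <- s; sk$modes <- s$modes[k]
    cet(w, propagate(w, sk))$cet
  })
  expect_lt(max(abs(parts[[1]] + parts[[2]] - both$cet)) / max(both$cet),
            0.02)
})
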
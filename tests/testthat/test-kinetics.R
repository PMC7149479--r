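test_that("survival normalisation fixes sigma(0) = 1 and permanent binders stay flat", {
  occ <- as_occupancy(matrix(TRUE, 3L, 20L))
  cur <- survival_curve(occ)
  expect_equal(cur$sigma[1L], 1)
  expect_true(all(cur$sigma == 1))
})

test_that("survival matches the frozen worked example", {
  # 11 frames at 1 ns, one lipid occupied frames 2..5 (0-based):
  # raw sigma(0) = 4/11, sigma(1) = (3/10)/(4/11), sigma(4) = 0
  occ <- matrix(FALSE, 1L, 11L)
  occ[1L, 3:6] <- TRUE
  cur <- survival_curve(as_occupancy(occ))
  expect_equal(attr(cur, "sigma0_raw"), 4 / 11)
  expect_equal(cur$sigma[1L], 1)
  expect_equal(cur$sigma[2L], (3 / 10) / (4 / 11))
  expect_equal(cur$sigma[5L], 0)
})

test_that("identical lipids average to the single-lipid curve", {
  occ1 <- matrix(FALSE, 1L, 30L)
  occ1[1L, 5:17] <- TRUE
  occ2 <- occ1[c(1L, 1L, 1L), ]
  expect_equal(survival_curve(as_occupancy(occ1))$sigma,
               survival_curve(as_occupancy(occ2))$sigma)
})

test_that("survival equals double-loop enumeration on random occupancies", {
  set.seed(77)
  for (rep in 1:60) {
    nl <- sample(1:12, 1L)
    nf <- sample(5:60, 1L)
    occ <- matrix(runif(nl * nf) < runif(1L, 0.1, 0.9), nl, nf)
    if (!any(occ)) occ[1L, 1L] <- TRUE
    g <- sample(0:2, 1L)
    got <- survival_curve(as_occupancy(occ), gap_tolerance = g)
    want <- sigma_oracle(occ, gap_tolerance = g)
    expect_identical(got$t, want$t)
    expect_equal(got$sigma, want$sigma, tolerance = 1e-12)
    if (g == 0L) expect_true(all(diff(got$sigma) <= 1e-12))
  }
})

test_that("gap tolerance bridges short interruptions only", {
  occ <- matrix(FALSE, 1L, 12L)
  occ[1L, c(2:4, 6L, 8:10)] <- TRUE   # gaps of length 1 at 5 and 7
  strict <- survival_curve(as_occupancy(occ))
  bridged <- survival_curve(as_occupancy(occ), gap_tolerance = 1L)
  # with bridging the whole 2..10 block is one interval
  expect_gt(bridged$sigma[9L], 0)
  expect_equal(strict$sigma[9L], 0)
})

test_that("all-false occupancy is rejected", {
  expect_error(survival_curve(as_occupancy(matrix(FALSE, 2L, 10L))),
               "no interacting lipids")
})

test_that("biexponential fit recovers noiseless parameters", {
  tt <- seq(0, 200, by = 1)
  fit <- fit_biexponential(
    analytic_curve(tt, 0.7 * exp(-tt / 2) + 0.3 * exp(-tt / 40)),
    fit_t_max = 200
  )
  expect_equal(fit$theta1, 2, tolerance = 0.01)
  expect_equal(fit$theta2, 40, tolerance = 0.01)
  expect_equal(fit$reported_residence_time, fit$theta2)
  expect_equal(fit$A, 0.7, tolerance = 0.01)
  # label ordering is enforced: theta1 <= theta2 always
  expect_lte(fit$theta1, fit$theta2)
})

test_that("pure single-exponential data collapse gracefully", {
  tt <- seq(0, 200, by = 1)
  fit <- fit_biexponential(analytic_curve(tt, exp(-tt / 10)), fit_t_max = 200)
  expect_equal(fit$reported_residence_time, 10, tolerance = 0.01)
  expect_true(min(fit$A, fit$B) < 0.01 || abs(fit$theta1 - 10) < 0.1)
})

test_that("time constants beyond the window are flagged, short fits rejected", {
  tt <- seq(0, 100, by = 1)
  fit <- fit_biexponential(
    analytic_curve(tt, 0.5 * exp(-tt / 5) + 0.5 * exp(-tt / 500)),
    fit_t_max = 100
  )
  expect_true(fit$exceeds_window)
  expect_error(
    fit_biexponential(analytic_curve(seq(0, 6, 1), exp(-seq(0, 6, 1)))),
    "at least 8"
  )
})

test_that("residence times recover planted Markov kinetics", {
  # mean bound dwell 20 ns (k_off such that geometric mean = 20 frames)
  occ <- simulate_site_occupancy(400L, 800L, k_on = 0.05,
                                 k_off = 1 - exp(-1 / 20),
                                 short_fraction = 2 / 3, k_off_short = 0.5,
                                 seed = 512L)
  events <- sum(apply(unclass(occ), 1L, function(r) {
    sum(diff(c(FALSE, r)) == 1L)
  }))
  expect_gte(events, 500L)
  fit <- fit_biexponential(survival_curve(occ))
  expect_equal(fit$reported_residence_time, 20, tolerance = 0.15)
})

test_that("two sites with different dwells are ordered and recovered", {
  fits <- lapply(c(5, 50), function(theta) {
    ts <- max(2, theta / 10)
    occ <- simulate_site_occupancy(
      400L, max(600L, 30L * theta), k_on = 0.05,
      k_off = 1 - exp(-1 / theta),
      short_fraction = (theta / ts) / (1 + theta / ts),
      k_off_short = 1 - exp(-1 / ts), seed = 900L + theta
    )
    fit_biexponential(survival_curve(occ))
  })
  est <- vapply(fits, `[[`, numeric(1L), "reported_residence_time")
  expect_lt(est[1L], est[2L])
  expect_equal(est[1L], 5, tolerance = 0.2)
  expect_equal(est[2L], 50, tolerance = 0.2)
})

test_that("site-resolved residence composition propagates errors", {
  sys <- generate_system(synthetic_spec(n_frames = 120L, seed = 17L))
  rec <- contact_events(sys$trajectory, sys$topology, "PIP2")
  # site 2 has no PIP2 affinity: occupancy is empty there
  expect_error(
    residence_time_for_site(rec, sys$truth$sites$residues[[2L]]),
    "no interacting lipids"
  )
  fit <- residence_time_for_site(rec, sys$truth$sites$residues[[1L]])
  expect_s3_class(fit, "residence_fit")
  expect_s3_class(fit$curve, "survival_curve")
  expect_gt(fit$reported_residence_time, 0)
})

test_that("tidy and glance expose the fit in broom shape", {
  tt <- seq(0, 120, by = 1)
  fit <- fit_biexponential(
    analytic_curve(tt, 0.6 * exp(-tt / 3) + 0.4 * exp(-tt / 25)),
    fit_t_max = 120
  )
  td <- tidy(fit)
  expect_equal(td$term, c("A", "B", "theta1", "theta2"))
  expect_equal(nrow(glance(fit)), 1L)
  expect_equal(glance(fit)$residence_time, fit$theta2)
})
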
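test_that("influence functions are continuous piecewise-linear with a dead zone", {
  f <- influence_function(-2, 2, 0.5, 0.8)
  expect_equal(f$form, "trilinear")
  expect_equal(influence_value(f, c(-4, -2, 0, 2, 4)),
               c(0.5 * (-4 + 2), 0, 0, 0, 0.8 * (4 - 2)))
  # continuity at the thresholds
  eps <- 1e-9
  expect_equal(influence_value(f, -2 - eps), 0, tolerance = 1e-8)
  expect_equal(influence_value(f, 2 + eps), 0, tolerance = 1e-8)
  expect_equal(influence_function(-1)$form, "bilinear")
  expect_equal(influence_function()$form, "null")
  expect_error(influence_function(3, -3), "nth <= pth")
  r <- repair_term(-3, 2)
  expect_equal(repair_value(r, c(-5, -3, -2.9, 0)), c(2, 2, 0, 0))
  expect_equal(repair_value(repair_term(), c(-5, 5)), c(0, 0))
})

test_that("steady_state is the fixed point of the uninfluenced recursion", {
  expect_equal(steady_state(0, 0.7), 0)
  expect_error(steady_state(1, 1), "r = 1")
  a <- -0.3; r <- 0.55
  u <- steady_state(a, r)
  expect_equal(r * u + a, u)
})

test_that("uninfluenced OLS recovers (a, r) exactly from noiseless data", {
  x <- numeric(60); x[1] <- 5
  for (t in 1:59) x[t + 1] <- 0.5 * x[t] + 1
  fit <- estimate_uninfluenced(x, partner = rep(0, 60))
  expect_equal(fit$a, 1, tolerance = 1e-10)
  expect_equal(fit$r, 0.5, tolerance = 1e-10)
  expect_equal(fit$n_points, 59L)
})

test_that("uninfluenced OLS rejects unusable designs", {
  expect_error(estimate_uninfluenced(rnorm(20), partner = rep(1, 20)),
               "0 uninfluenced")
  expect_error(estimate_uninfluenced(rep(2, 20), partner = rep(0, 20)),
               "singular|constant")
  expect_error(estimate_uninfluenced(rnorm(10), rnorm(5)), "lengths differ")
})

test_that("uninfluenced OLS is consistent under window noise", {
  errs <- t(sapply(1:30, function(seed) {
    x <- withr::with_seed(seed, {
      x <- numeric(150); x[1] <- 0
      for (t in 1:149) x[t + 1] <- 0.4 * x[t] - 0.2 + rnorm(1, 0, 0.5)
      x
    })
    fit <- estimate_uninfluenced(x, partner = rep(0, 150))
    c(abs(fit$a + 0.2), abs(fit$r - 0.4))
  }))
  expect_lt(median(errs[, 1]), 0.15)
  expect_lt(median(errs[, 2]), 0.15)
})

test_that("influence thresholds and slopes are recovered from noiseless data", {
  truth <- influence_function(-2, 2, 0.5, 0.5)
  z <- withr::with_seed(5, sample(seq(-4, 4, by = 1), 200, replace = TRUE))
  x <- numeric(201)
  for (t in 1:200) x[t + 1] <- 0.3 * x[t] + 0.1 + influence_value(truth, z[t])
  fit <- estimate_influence(x, c(z, 0), a = 0.1, r = 0.3)
  expect_equal(fit$form, "trilinear")
  expect_equal(fit$nth, -2)
  expect_equal(fit$pth, 2)
  expect_equal(fit$neg_slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$pos_slope, 0.5, tolerance = 1e-9)
})

test_that("an unvisited regime downgrades the influence form", {
  truth <- influence_function(pth = 2, pos_slope = 0.5)
  z <- withr::with_seed(6, runif(100, 1, 5))   # partner only ever positive
  x <- numeric(101)
  for (t in 1:100) x[t + 1] <- 0.3 * x[t] + influence_value(truth, z[t])
  fit <- estimate_influence(x, c(z, 0), a = 0, r = 0.3)
  expect_equal(fit$form, "bilinear")
  expect_true(is.na(fit$nth))
  # thresholds live on observed partner scores, so recovery is exact only
  # up to the sample's resolution around the true threshold
  expect_equal(fit$pth, 2, tolerance = 0.1)
  expect_warning(
    null_fit <- estimate_influence(rnorm(10), rep(0, 10), 0, 0.3),
    "no influenced points")
  expect_equal(null_fit$form, "null")
})

test_that("repair is recovered when present and inactive when impossible", {
  # noiseless: null influence plus a repair step at -3 of strength 2
  z <- withr::with_seed(7, runif(120, -6, 6))
  truth_rep <- repair_term(-3, 2)
  x <- numeric(121)
  for (t in 1:120) x[t + 1] <- 0.3 * x[t] - 0.1 + repair_value(truth_rep, z[t])
  fit <- estimate_repair(x, c(z, 0), a = -0.1, r = 0.3)
  expect_true(fit$active)
  expect_equal(fit$strength, 2, tolerance = 1e-9)
  # recovered threshold is the largest observed score still inside the step
  expect_equal(fit$threshold, max(z[z <= -3]), tolerance = 1e-9)

  # no negative partner scores: nothing to trigger repair
  zp <- withr::with_seed(8, runif(50, 1, 4))
  xp <- withr::with_seed(9, rnorm(51))
  expect_false(estimate_repair(xp, c(zp, 0), a = 0, r = 0)$active)
})

test_that("repair strength is estimated within tolerance under noise", {
  truth_rep <- repair_term(-3, 2)
  errs <- sapply(1:20, function(seed) {
    withr::with_seed(seed, {
      z <- runif(150, -6, 6)
      x <- numeric(151)
      for (t in 1:150)
        x[t + 1] <- 0.3 * x[t] - 0.1 + repair_value(truth_rep, z[t]) +
          rnorm(1, 0, 0.5)
      fit <- estimate_repair(x, c(z, 0), a = -0.1, r = 0.3)
      if (fit$active) abs(fit$strength - 2) else Inf
    })
  })
  expect_lt(median(errs), 0.5)
})

test_that("the coupled map fixes the steady-state pair under null influence", {
  m <- dyad_model(actor_params("therapist", a = -0.3, r = 0.5),
                  actor_params("client", a = 0.2, r = 0.6))
  fp <- c(m$therapist$unss, m$client$unss)
  expect_equal(unname(step_dyad(m, fp)), fp)
  # geometric convergence at rate max(|r_T|, |r_C|)
  start <- fp + c(4, -3)
  tr <- iterate_dyad(m, start, steps = 25)
  dev_T <- abs(tr[, "T"] - fp[1])
  dev_C <- abs(tr[, "C"] - fp[2])
  expect_equal(dev_T, 4 * 0.5^(0:25))
  expect_equal(dev_C, 3 * 0.6^(0:25))
  expect_lt(max(abs(tr[26, ] - fp)), 0.6^25 * 3 + 0.5^25 * 4 + 1e-9)
})

test_that("iteration returns the full trajectory and guards overflow", {
  m <- dyad_model(actor_params("therapist", a = 0, r = 0.5),
                  actor_params("client", a = 0, r = 0.5))
  tr <- iterate_dyad(m, c(1, 1), steps = 10)
  expect_equal(dim(tr), c(11L, 2L))
  expect_false(attr(tr, "truncated"))
  bad <- dyad_model(actor_params("therapist", a = 0, r = 3),
                    actor_params("client", a = 0, r = 3))
  tr2 <- iterate_dyad(bad, c(10, 10), steps = 50, overflow = 1e4)
  expect_true(attr(tr2, "truncated"))
  expect_lt(nrow(tr2), 51L)
})

test_that("the full dyad fit recovers a coupled model under window noise", {
  true <- dyad_model(
    actor_params("therapist", a = -0.2, r = 0.4,
                 influence = influence_function(-1, 1, 0.4, 0.4)),
    actor_params("client", a = 0.15, r = 0.5,
                 influence = influence_function(-1, 1, 0.4, 0.4)))
  ser <- generate_dyad_series(dyad_spec(true, n_windows = 300,
                                        noise_sd = 0.5, seed = 11))
  fit <- fit_dyad(ser$therapist, ser$client, repair = FALSE)
  expect_equal(fit$therapist$a, true$therapist$a, tolerance = 0.3)
  expect_equal(fit$therapist$r, true$therapist$r, tolerance = 0.3)
  expect_equal(fit$client$a, true$client$a, tolerance = 0.3)
  expect_equal(fit$client$r, true$client$r, tolerance = 0.3)
})

test_that("the steady-state identity holds on every published parameter row", {
  p <- spaff_fixture("params")
  expect_equal(nrow(p), 12L)
  expect_true(all(abs(p$unss - steady_state(p$a2, p$r2)) < 5e-6))
})
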
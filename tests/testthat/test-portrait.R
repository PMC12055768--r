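test_that("a null-influence dyad has exactly one critical point at the steady states", {
  m <- dyad_model(actor_params("therapist", a = -0.3, r = 0.5),
                  actor_params("client", a = 0.2, r = 0.6))
  cp <- critical_points(m)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$T, m$therapist$unss)
  expect_equal(cp$C, m$client$unss)
  expect_equal(cp$stability, "attractor")
  # expanding dynamics flip the classification
  rep_ <- dyad_model(actor_params("therapist", a = 0, r = 1.5),
                     actor_params("client", a = 0, r = 1.2))
  expect_equal(critical_points(rep_)$stability, "repeller")
  sad <- dyad_model(actor_params("therapist", a = 0, r = 1.5),
                    actor_params("client", a = 0, r = 0.2))
  expect_equal(critical_points(sad)$stability, "saddle")
})

test_that("attractors are genuine fixed points of the map", {
  for (seed in 1:10) {
    m <- rand_piecewise_model(seed)
    cp <- critical_points(m)
    for (i in seq_len(nrow(cp))) {
      s <- c(cp$T[i], cp$C[i])
      expect_lt(max(abs(step_dyad(m, s) - s)), 1e-8)
    }
  }
})

test_that("analytic critical points match an independent fixed-point search", {
  for (seed in 1:20) {
    m <- rand_piecewise_model(seed + 100)
    cp <- critical_points(m)
    brute <- brute_critical_points(m)
    # restrict both to a common bounded window
    inside <- function(T, C) abs(T) <= 9 & abs(C) <= 9
    cp <- cp[inside(cp$T, cp$C), , drop = FALSE]
    brute <- brute[inside(brute[, 1], brute[, 2]), , drop = FALSE]
    expect_equal(nrow(cp), nrow(brute),
                 info = sprintf("model seed %d", seed + 100))
    for (i in seq_len(nrow(cp))) {
      d <- apply(brute, 1, function(b)
        max(abs(b - c(cp$T[i], cp$C[i]))))
      expect_lt(min(d), 1e-3)
    }
  }
})

test_that("stable null-influence trajectories approach the unique attractor", {
  m <- dyad_model(actor_params("therapist", a = 0.1, r = 0.8),
                  actor_params("client", a = -0.4, r = -0.3))
  fp <- c(m$therapist$unss, m$client$unss)
  for (start in list(c(12, -12), c(-7, 3), c(0.5, 0.5))) {
    tr <- iterate_dyad(m, start, steps = 200)
    expect_lt(max(abs(tr[201, ] - fp)), 1e-6)
  }
})

test_that("session starting coordinates average the opening fraction", {
  expect_equal(session_start_point(rep(2.5, 30), rep(-1, 30)),
               c(C = -1, T = 2.5))
  ther <- c(6, 0, 0, -6, rep(1, 36))
  expect_equal(unname(session_start_point(ther, ther, fraction = 0.1)),
               c(0, 0))
  x <- withr::with_seed(3, rnorm(50))
  expect_equal(unname(session_start_point(x, x, fraction = 1)[["T"]]),
               mean(x))
  expect_error(session_start_point(numeric(0), 1), "empty")
  expect_error(session_start_point(1, 1, fraction = 0), "fraction")
})

test_that("quadrant labels follow the signs of the coordinates", {
  expect_equal(classify_quadrant(T = 1, C = -1),
               "therapist positive-client negative")
  expect_equal(classify_quadrant(T = -1, C = -1),
               "therapist negative-client negative")
  expect_equal(classify_quadrant(T = -0.2, C = 3),
               "therapist negative-client positive")
  expect_equal(classify_quadrant(T = 0, C = 0), "boundary")
  expect_equal(classify_quadrant(T = 0.5, C = 0), "boundary")
})

test_that("portraits carry trajectories, critical points and session paths", {
  m <- fixture_dyad(1, influence = "config")
  start <- c(C = -2, T = 1)
  p <- build_portrait(m, seq(-6, 6, 2), seq(-6, 6, 2), steps = 10,
                      session_start = start)
  expect_s3_class(p, "phase_portrait")
  expect_length(p$trajectories, 49L)
  expect_true(all(vapply(p$trajectories, nrow, 1L) <= 11L))
  expect_equal(p$session_start, start)
  expect_equal(nrow(p$session_trajectory), 11L)
  expect_equal(p$session_end, p$session_trajectory[11, ])
})

test_that("rendering writes a deterministic image", {
  m <- dyad_model(actor_params("therapist", a = -0.3, r = 0.5),
                  actor_params("client", a = 0.2, r = 0.6))
  p <- build_portrait(m, seq(-4, 4, 2), seq(-4, 4, 2), steps = 5,
                      session_start = c(C = 2, T = -2))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_portrait(p, f1)
  render_portrait(p, f2)
  expect_gt(file.size(f1), 0)
  expect_identical(png::readPNG(f1), png::readPNG(f2))

  # a portrait with no critical points still renders the flow
  div <- dyad_model(actor_params("therapist", a = 1, r = 1),
                    actor_params("client", a = 1, r = 1))
  pdiv <- build_portrait(div, seq(-4, 4, 2), seq(-4, 4, 2), steps = 3)
  expect_equal(nrow(pdiv$critical_points), 0L)
  f3 <- withr::local_tempfile(fileext = ".png")
  render_portrait(pdiv, f3)
  expect_gt(file.size(f3), 0)
})
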
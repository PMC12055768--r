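# Independent oracles and small generators shared across test files.

# Brute-force sup |F_n - F| on a dense grid augmented with the sample points
# and points just below them (captures the left-limit side of each jump).
brute_ks_D <- function(x, reference, n_grid = 1e6) {
  cdf <- if (reference == "normal_fitted") {
    m <- mean(x); s <- sd(x)
    function(q) pnorm(q, m, s)
  } else {
    m <- mean(x)
    function(q) pexp(q, 1 / m)
  }
  lo <- min(x) - 4 * max(sd(x), 1e-3)
  hi <- max(x) + 4 * max(sd(x), 1e-3)
  g <- sort(c(seq(lo, hi, length.out = n_grid), x, x - 1e-9))
  Fn <- ecdf(x)(g)
  max(abs(Fn - cdf(g)))
}

# Random stable dyad with piecewise-linear influence and optional repair.
rand_piecewise_model <- function(seed) {
  withr::with_seed(seed, {
    mk <- function(actor) {
      r <- runif(1, -0.6, 0.7)
      a <- runif(1, -1.5, 1.5)
      nth <- if (runif(1) < 0.8) runif(1, -6, -0.5) else NA_real_
      pth <- if (runif(1) < 0.8) runif(1, 0.5, 6) else NA_real_
      inf <- influence_function(nth, pth,
                                neg_slope = runif(1, -0.3, 0.3),
                                pos_slope = runif(1, -0.3, 0.3))
      rp <- if (runif(1) < 0.4)
        repair_term(runif(1, -8, -2), runif(1, 0.5, 2)) else repair_term()
      actor_params(actor, a, r, influence = inf, repair = rp)
    }
    dyad_model(mk("therapist"), mk("client"))
  })
}

# Fixed-point search that knows nothing about the region structure:
# minimise |step(s) - s|^2 from many starts, keep near-exact zeros.
brute_critical_points <- function(model, starts = seq(-10, 10, by = 2)) {
  obj <- function(s) sum((step_dyad(model, s) - s)^2)
  grid <- expand.grid(T = starts, C = starts)
  sols <- list()
  for (i in seq_len(nrow(grid))) {
    o <- suppressWarnings(
      optim(c(grid$T[i], grid$C[i]), obj, method = "Nelder-Mead",
            control = list(reltol = 1e-15, maxit = 5000)))
    if (o$value < 1e-12) sols <- c(sols, list(o$par))
  }
  if (!length(sols)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, sols)
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1)
    for (i in 2:nrow(m))
      for (j in 1:(i - 1))
        if (keep[j] && max(abs(m[i, ] - m[j, ])) < 5e-3) keep[i] <- FALSE
  m[keep, , drop = FALSE]
}

# Frozen study conditions for the parameter-recovery simulations: a stable
# dyad whose steady states sit near zero so both actors regularly pass
# through the partner-neutral band.
recovery_true_model <- function() {
  dyad_model(
    actor_params("therapist", a = -0.2, r = 0.4,
                 influence = influence_function(-0.8, 0.8, 0.4, 0.4)),
    actor_params("client", a = 0.15, r = 0.5,
                 influence = influence_function(-0.8, 0.8, 0.4, 0.4)))
}

rand_code_stream <- function(seed, length_s = 120) {
  withr::with_seed(seed,
    code_stream(sample(spaff_code_names(), length_s, replace = TRUE)))
}
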
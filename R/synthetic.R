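#' Specification for a synthetic per-second code stream
#'
#' Emulates the output of observational affect coding as a sticky
#' first-order Markov chain: at each second the previous code repeats with
#' probability `persistence`, otherwise a code is drawn from the stationary
#' propensities.  Real coded sessions are dominated by Neutral with bursts
#' of a few other codes; a high Neutral propensity plus persistence around
#' 0.5-0.9 reproduces that texture (though not any psychologically
#' meaningful sequencing).
#'
#' @param length_s Stream length in seconds.
#' @param code_propensity Named probability vector over (a subset of) the
#'   canonical codes; must sum to 1.
#' @param persistence Repeat probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `stream_spec`.
#' @export
stream_spec <- function(length_s, code_propensity, persistence = 0.8,
                        seed = 1L) {
  stopifnot(length_s >= 1, persistence >= 0, persistence < 1)
  unknown <- setdiff(names(code_propensity), spaff_code_names())
  if (length(unknown))
    stop("unknown code(s) in propensity: ", paste(unknown, collapse = ", "))
  if (any(code_propensity < 0) || abs(sum(code_propensity) - 1) > 1e-8)
    stop("propensities must be non-negative and sum to 1")
  structure(list(length_s = as.integer(length_s),
                 code_propensity = code_propensity,
                 persistence = persistence, seed = as.integer(seed)),
            class = "stream_spec")
}

#' Generate a synthetic code stream
#'
#' @param spec A [stream_spec()].
#' @param actor Actor label for the resulting stream.
#' @return A [code_stream()]; bit-reproducible for a fixed `spec$seed`.
#' @export
generate_stream <- function(spec, actor = c("therapist", "client")) {
  stopifnot(inherits(spec, "stream_spec"))
  actor <- match.arg(actor)
  codes <- names(spec$code_propensity)
  out <- withr::with_seed(spec$seed, {
    draw <- sample(codes, spec$length_s, replace = TRUE,
                   prob = spec$code_propensity)
    stick <- stats::runif(spec$length_s) < spec$persistence
    res <- character(spec$length_s)
    res[1] <- draw[1]
    for (t in seq_len(spec$length_s)[-1])
      res[t] <- if (stick[t]) res[t - 1L] else draw[t]
    res
  })
  code_stream(out, actor)
}

#' Specification for a synthetic dyad series
#'
#' @param true_model A [dyad_model()] (a stable one is recommended:
#'   inertias inside the unit interval and modest influence slopes).
#' @param n_windows Number of windows to simulate.
#' @param noise_sd SD of the additive Gaussian window noise (score units).
#' @param seed Integer seed.
#' @return A `dyad_spec`.
#' @export
dyad_spec <- function(true_model, n_windows = 150L, noise_sd = 0.5,
                      seed = 1L) {
  stopifnot(inherits(true_model, "dyad_model"), n_windows >= 2,
            noise_sd >= 0)
  structure(list(true_model = true_model, n_windows = as.integer(n_windows),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dyad_spec")
}

#' Simulate a dyad's window-score series
#'
#' Iterates the coupled map from the pair of uninfluenced steady states
#' plus a small Gaussian perturbation (starting near the steady states
#' keeps short series from being dominated by transients), adding
#' independent `N(0, noise_sd)` noise to each actor at every window.
#'
#' @param spec A [dyad_spec()].
#' @param overflow Divergence guard; exceeding it aborts with the step
#'   index.
#' @return List with `therapist` and `client` [weighted_series()] of
#'   length `n_windows`; bit-reproducible for a fixed `spec$seed`.
#' @export
generate_dyad_series <- function(spec, overflow = 1e6) {
  stopifnot(inherits(spec, "dyad_spec"))
  m <- spec$true_model
  n <- spec$n_windows
  sd_ <- spec$noise_sd
  states <- withr::with_seed(spec$seed, {
    out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("T", "C")))
    state <- c(m$therapist$unss, m$client$unss) + stats::rnorm(2, 0, sd_)
    out[1L, ] <- state
    for (k in seq_len(n - 1L)) {
      state <- step_dyad(m, state) + stats::rnorm(2, 0, sd_)
      if (max(abs(state)) > overflow)
        stop(sprintf("trajectory diverged at step %d", k))
      out[k + 1L, ] <- state
    }
    out
  })
  list(therapist = weighted_series(states[, "T"], "therapist"),
       client = weighted_series(states[, "C"], "client"))
}

#' Construct a code stream realising a given window-score series
#'
#' Inverts [weight_and_window()]: for every window it finds a multiset of
#' `window_s` codes whose weights sum to the target score (enumerating
#' code-weight multisets, which is cheap because the weight table has few
#' distinct values), then orders the seconds randomly under `seed`.  The
#' round trip `weight_and_window(stream_for_series(s))` reproduces `s`
#' up to floating-point summation order.
#'
#' @param series [weighted_series()] or numeric vector of window scores.
#' @param weights Named weight vector.
#' @param seed Integer seed for the within-window arrangement.
#' @param window_s Window length in seconds.
#' @param actor Actor label.
#' @return A [code_stream()] of `length(series) * window_s` seconds.
#' @export
stream_for_series <- function(series, weights = default_weight_table(),
                              seed = 1L, window_s = 6L,
                              actor = c("therapist", "client")) {
  actor <- match.arg(actor)
  scores <- as.numeric(series)
  if (!length(scores)) stop("empty series")
  wvals <- sort(unique(unname(weights)))
  # representative code per distinct weight value
  rep_code <- vapply(wvals, function(w)
    names(weights)[which(unname(weights) == w)[1]], character(1))
  combos <- multiset_sums(wvals, window_s)
  codes <- withr::with_seed(seed, {
    unlist(lapply(seq_along(scores), function(i) {
      hit <- which(abs(combos$sums - scores[i]) < 1e-9)
      if (!length(hit))
        stop(sprintf("window %d: score %g has no %d-second composition",
                     i, scores[i], window_s))
      # canonical choice among compositions: the most neutral one
      hit <- hit[which.min(combos$counts[hit, , drop = FALSE] %*% abs(wvals))]
      counts <- combos$counts[hit, ]
      sample(rep(rep_code, counts))
    }))
  })
  code_stream(codes, actor)
}

# All multisets of size k from values v: counts matrix and their sums.
multiset_sums <- function(v, k) {
  n <- length(v)
  idx <- utils::combn(n + k - 1L, k)          # combinations with repetition
  idx <- idx - (seq_len(k) - 1L)              # map to value indices
  counts <- t(apply(idx, 2L, function(col) tabulate(col, nbins = n)))
  sums <- as.numeric(counts %*% v)
  list(counts = counts, sums = sums)
}
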
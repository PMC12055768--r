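#' Piecewise-linear influence function
#'
#' The influence of one partner's current window score `z` on the other's
#' next score.  The trilinear form has a dead zone between a negative
#' threshold `nth` and a positive threshold `pth` (both in score units;
#' `nth <= pth`, and despite the names either may sit anywhere on the score
#' axis) with linear response beyond each threshold:
#' `I(z) = neg_slope * (z - nth)` for `z <= nth`, `0` inside the dead zone,
#' `pos_slope * (z - pth)` for `z >= pth`.  Dropping one threshold gives a
#' bilinear function; dropping both gives the null (zero) function.
#'
#' @param nth,pth Thresholds (score units); `NA` for an absent regime.
#' @param neg_slope,pos_slope Slopes (influence per score unit) of the
#'   active regimes; ignored where the regime is absent.
#' @return An `influence_function` with a `form` field (`"trilinear"`,
#'   `"bilinear"` or `"null"`).
#' @export
influence_function <- function(nth = NA_real_, pth = NA_real_,
                               neg_slope = 0, pos_slope = 0) {
  has_n <- !is.na(nth); has_p <- !is.na(pth)
  if (has_n && has_p && nth > pth) stop("need nth <= pth")
  form <- if (has_n && has_p) "trilinear" else if (has_n || has_p)
    "bilinear" else "null"
  structure(list(form = form,
                 nth = as.numeric(nth), pth = as.numeric(pth),
                 neg_slope = if (has_n) as.numeric(neg_slope) else NA_real_,
                 pos_slope = if (has_p) as.numeric(pos_slope) else NA_real_),
            class = "influence_function")
}

#' Evaluate an influence function
#' @param f An [influence_function()].
#' @param z Partner scores (vectorised).
#' @return Influence values, same length as `z`.
#' @export
influence_value <- function(f, z) {
  out <- numeric(length(z))
  if (!is.na(f$nth)) {
    lo <- z <= f$nth
    out[lo] <- f$neg_slope * (z[lo] - f$nth)
  }
  if (!is.na(f$pth)) {
    hi <- z >= f$pth
    out[hi] <- f$pos_slope * (z[hi] - f$pth)
  }
  out
}

#' Repair term
#'
#' A constant positive correction `sr` that switches on when the partner's
#' score drops to or below a (typically negative) threshold `kr`; it models
#' the damping of negative spirals.
#'
#' @param threshold `kr`, score units.
#' @param strength `sr`, influence units.
#' @param active If `FALSE` the term is identically zero.
#' @return A `repair_term`.
#' @export
repair_term <- function(threshold = NA_real_, strength = NA_real_,
                        active = !is.na(threshold)) {
  structure(list(active = isTRUE(active),
                 threshold = as.numeric(threshold),
                 strength = as.numeric(strength)),
            class = "repair_term")
}

#' Evaluate a repair term
#' @param r A [repair_term()].
#' @param z Partner scores (vectorised).
#' @return Repair values.
#' @export
repair_value <- function(r, z) {
  if (!r$active) return(numeric(length(z)))
  ifelse(z <= r$threshold, r$strength, 0)
}

#' One actor's fitted model parameters
#'
#' The actor's next score is
#' `x[t+1] = r * x[t] + a + I(partner[t]) + R(partner[t])`:
#' `r` is the inertia (tendency to remain in the current emotional state,
#' `|r| < 1` for stability), `a` the initial-state constant (the actor's
#' uninfluenced disposition), `I` the partner's influence function and `R`
#' the repair term.  The uninfluenced steady state is `a / (1 - r)`.
#'
#' @param actor `"therapist"` or `"client"`.
#' @param a Initial state (score units).
#' @param r Inertia (dimensionless).
#' @param influence [influence_function()] of the partner's score on this
#'   actor.
#' @param repair [repair_term()] triggered by the partner's score.
#' @return An `actor_params`.
#' @export
actor_params <- function(actor = c("therapist", "client"), a, r,
                         influence = influence_function(),
                         repair = repair_term()) {
  actor <- match.arg(actor)
  stopifnot(is.finite(a), is.finite(r))
  structure(list(actor = actor, a = as.numeric(a), r = as.numeric(r),
                 unss = if (r != 1) steady_state(a, r) else NA_real_,
                 influence = influence, repair = repair),
            class = "actor_params")
}

#' Uninfluenced steady state
#'
#' Fixed point of `x[t+1] = r x[t] + a`: the score an actor settles at when
#' the partner exerts no influence.
#'
#' @param a Initial state.
#' @param r Inertia; must not equal 1.
#' @return `a / (1 - r)`.
#' @examples
#' steady_state(-0.1324441, 0.3611994)
#' @export
steady_state <- function(a, r) {
  if (any(r == 1)) stop("no fixed point when r = 1")
  a / (1 - r)
}

#' A fitted dyad
#' @param therapist,client [actor_params()] for each actor.
#' @return A `dyad_model`.
#' @export
dyad_model <- function(therapist, client) {
  stopifnot(inherits(therapist, "actor_params"),
            inherits(client, "actor_params"))
  structure(list(therapist = therapist, client = client),
            class = "dyad_model")
}

#' @export
print.dyad_model <- function(x, ...) {
  fmt <- function(p) sprintf(
    "  %-9s a = %7.4f  r = %7.4f  UnSS = %7.4f  influence: %s  repair: %s",
    p$actor, p$a, p$r, p$unss, p$influence$form,
    if (p$repair$active) sprintf("kr = %.2f, sr = %.2f",
                                 p$repair$threshold, p$repair$strength)
    else "inactive")
  cat("<dyad_model>\n", fmt(x$therapist), "\n", fmt(x$client), "\n", sep = "")
  invisible(x)
}

uninfluenced_idx <- function(partner, epsilon) {
  n <- length(partner)
  which(abs(partner[seq_len(n - 1L)]) <= epsilon)
}

#' Estimate the uninfluenced parameters (a, r)
#'
#' Ordinary least squares on the lag-1 regression
#' `x[t+1] = r x[t] + a`, restricted to windows where the partner is
#' neutral (partner score within `epsilon` of zero), so that the influence
#' and repair terms are structurally zero.
#'
#' @param self,partner Equal-length numeric series ([weighted_series()] or
#'   plain vectors).
#' @param epsilon Neutrality band on the partner score (default 0.25; with
#'   the default weight table an all-Neutral window scores 0.6, so pass
#'   `epsilon = 0.6` when windows of pure Neutral should count as neutral).
#' @return List with `a`, `r` and `n_points` (number of uninfluenced
#'   transitions used).
#' @export
estimate_uninfluenced <- function(self, partner, epsilon = 0.25) {
  self <- as.numeric(self); partner <- as.numeric(partner)
  if (length(self) != length(partner)) stop("series lengths differ")
  idx <- uninfluenced_idx(partner, epsilon)
  if (length(idx) < 3L)
    stop(sprintf("only %d uninfluenced point(s); need at least 3",
                 length(idx)))
  x <- self[idx]; y <- self[idx + 1L]
  if (stats::sd(x) == 0) stop("singular design: constant self score")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(a = unname(co[1]), r = unname(co[2]), n_points = length(idx))
}

#' Estimate a piecewise-linear influence function
#'
#' Works on the residuals `e[t] = x[t+1] - (r x[t] + a)` at windows where
#' the partner is not neutral.  Candidate thresholds are scanned over the
#' distinct observed partner scores; within a candidate regime the slope is
#' the no-intercept least-squares fit of `e` on `(z - threshold)`.  All
#' forms (trilinear, both bilinear orientations, null) are scored by total
#' SSE over the influenced points; a regime needs at least `min_points`
#' supporting observations (with some spread away from the threshold) to be
#' eligible, which is how sessions in which one regime is never visited
#' come out bilinear.  SSE ties go to the form with fewer regimes, then to
#' the smallest-magnitude thresholds.
#'
#' @param self,partner Equal-length numeric series.
#' @param a,r Uninfluenced parameters from [estimate_uninfluenced()].
#' @param epsilon Neutrality band (see [estimate_uninfluenced()]).
#' @param min_points Minimum supporting points per active regime.
#' @return An [influence_function()]; null (with a warning) when no window
#'   has a non-neutral partner.
#' @export
estimate_influence <- function(self, partner, a, r, epsilon = 0.25,
                               min_points = 3L) {
  self <- as.numeric(self); partner <- as.numeric(partner)
  if (length(self) != length(partner)) stop("series lengths differ")
  n <- length(self)
  t_idx <- which(abs(partner[seq_len(n - 1L)]) > epsilon)
  if (length(t_idx) == 0L) {
    warning("no influenced points; returning null influence")
    return(influence_function())
  }
  z <- partner[t_idx]
  e <- self[t_idx + 1L] - (r * self[t_idx] + a)

  zs <- sort(unique(z))
  neg_cand <- Filter(function(th) regime_ok(z, z <= th, th, min_points), zs)
  pos_cand <- Filter(function(th) regime_ok(z, z >= th, th, min_points), zs)

  cands <- list(list(nth = NA_real_, pth = NA_real_))
  for (th in neg_cand) cands <- c(cands, list(list(nth = th, pth = NA_real_)))
  for (th in pos_cand) cands <- c(cands, list(list(nth = NA_real_, pth = th)))
  for (nt in neg_cand) for (pt in pos_cand)
    if (nt < pt) cands <- c(cands, list(list(nth = nt, pth = pt)))

  best <- NULL
  for (cc in cands) {
    fit <- fit_influence_given(z, e, cc$nth, cc$pth)
    cand <- c(cc, fit, list(n_regimes = sum(!is.na(c(cc$nth, cc$pth))),
                            mag = sum(abs(c(cc$nth, cc$pth)), na.rm = TRUE)))
    if (is.null(best) ||
        cand$sse < best$sse - 1e-9 ||
        (abs(cand$sse - best$sse) <= 1e-9 &&
           (cand$n_regimes < best$n_regimes ||
              (cand$n_regimes == best$n_regimes && cand$mag < best$mag))))
      best <- cand
  }
  influence_function(best$nth, best$pth, best$neg_slope, best$pos_slope)
}

regime_ok <- function(z, in_regime, th, min_points) {
  sum(in_regime) >= min_points && sum((z[in_regime] - th)^2) > 0
}

fit_influence_given <- function(z, e, nth, pth) {
  pred <- numeric(length(z))
  neg_slope <- NA_real_; pos_slope <- NA_real_
  if (!is.na(nth)) {
    lo <- z <= nth
    u <- z[lo] - nth
    neg_slope <- sum(e[lo] * u) / sum(u^2)
    pred[lo] <- neg_slope * u
  }
  if (!is.na(pth)) {
    hi <- z >= pth
    u <- z[hi] - pth
    pos_slope <- sum(e[hi] * u) / sum(u^2)
    pred[hi] <- pos_slope * u
  }
  list(neg_slope = neg_slope, pos_slope = pos_slope, sse = sum((e - pred)^2))
}

#' Estimate the repair term
#'
#' After removing the fitted influence, scans candidate thresholds over the
#' distinct negative partner scores and measures the mean residual lift
#' among windows at or below each candidate.  The threshold maximising the
#' explained sum of squares (`n_below * lift^2`) wins, provided it has at
#' least `min_points` supporting windows and a positive lift; ties go to
#' the smallest-magnitude threshold.  When no candidate qualifies the term
#' is returned inactive, mirroring sessions without an estimable repair.
#'
#' @param self,partner Equal-length numeric series.
#' @param a,r Uninfluenced parameters.
#' @param influence Fitted [influence_function()].
#' @param epsilon Neutrality band.
#' @param min_points Minimum supporting windows.
#' @return A [repair_term()].
#' @export
estimate_repair <- function(self, partner, a, r,
                            influence = influence_function(),
                            epsilon = 0.25, min_points = 3L) {
  self <- as.numeric(self); partner <- as.numeric(partner)
  n <- length(self)
  t_idx <- which(abs(partner[seq_len(n - 1L)]) > epsilon)
  if (length(t_idx) == 0L) return(repair_term())
  z <- partner[t_idx]
  d <- self[t_idx + 1L] - (r * self[t_idx] + a) - influence_value(influence, z)
  cand <- sort(unique(z[z < 0]), decreasing = TRUE)  # smallest magnitude first
  best <- NULL
  for (kr in cand) {
    below <- z <= kr
    m <- sum(below)
    if (m < min_points) next
    s <- mean(d[below])
    if (s <= 0) next
    score <- m * s^2
    if (is.null(best) || score > best$score + 1e-12)
      best <- list(threshold = kr, strength = s, score = score)
  }
  if (is.null(best)) repair_term()
  else repair_term(best$threshold, best$strength)
}

#' Fit the full dyadic model for one session
#'
#' Runs [estimate_uninfluenced()], [estimate_influence()] and
#' [estimate_repair()] for each actor in turn, each actor's influence and
#' repair being driven by the partner's score.
#'
#' @param therapist,client [weighted_series()] (or numeric vectors) of
#'   equal length from the same session.
#' @param epsilon Neutrality band on the partner score.
#' @param min_points Minimum supporting points per influence/repair regime.
#' @param repair If `FALSE`, skip repair estimation (terms left inactive).
#' @return A [dyad_model()].
#' @export
fit_dyad <- function(therapist, client, epsilon = 0.25, min_points = 3L,
                     repair = TRUE) {
  fit_one <- function(self, partner, who) {
    ur <- estimate_uninfluenced(self, partner, epsilon)
    inf <- estimate_influence(self, partner, ur$a, ur$r, epsilon, min_points)
    rep_ <- if (repair)
      estimate_repair(self, partner, ur$a, ur$r, inf, epsilon, min_points)
    else repair_term()
    actor_params(who, ur$a, ur$r, influence = inf, repair = rep_)
  }
  dyad_model(fit_one(therapist, client, "therapist"),
             fit_one(client, therapist, "client"))
}

#' Advance the dyad one window
#'
#' Simultaneous (parallel) update of both actors:
#' `T' = r_T T + a_T + I_T(C) + R_T(C)` and
#' `C' = r_C C + a_C + I_C(T) + R_C(T)`, where `I_T`/`R_T` are the
#' influence and repair terms stored in the therapist's parameters (driven
#' by the client's score) and vice versa.  An alternating (therapist-first)
#' update is available for sensitivity checks.
#'
#' @param model A [dyad_model()].
#' @param state Numeric `c(T, C)`: therapist then client score.
#' @param alternating If `TRUE`, the therapist moves first and the client
#'   responds to the updated therapist score.
#' @return Numeric `c(T, C)` at the next window.
#' @export
step_dyad <- function(model, state, alternating = FALSE) {
  stopifnot(inherits(model, "dyad_model"), length(state) == 2L,
            all(is.finite(state)))
  Tt <- state[1]; Ct <- state[2]
  th <- model$therapist; cl <- model$client
  T1 <- th$r * Tt + th$a + influence_value(th$influence, Ct) +
    repair_value(th$repair, Ct)
  Cin <- if (alternating) T1 else Tt
  C1 <- cl$r * Ct + cl$a + influence_value(cl$influence, Cin) +
    repair_value(cl$repair, Cin)
  c(T = unname(T1), C = unname(C1))
}

#' Iterate the dyadic map
#'
#' @param model A [dyad_model()].
#' @param state Starting `c(T, C)`.
#' @param steps Number of applications of [step_dyad()].
#' @param overflow Guard: iteration stops (with a `truncated` attribute on
#'   the result) once `max(abs(state))` exceeds this.
#' @param alternating Passed to [step_dyad()].
#' @return `(steps + 1) x 2` matrix of states including the start; fewer
#'   rows with `attr(,"truncated") = TRUE` if the trajectory diverged.
#' @export
iterate_dyad <- function(model, state, steps = 10L, overflow = 1e6,
                         alternating = FALSE) {
  stopifnot(steps >= 1L)
  out <- matrix(NA_real_, nrow = steps + 1L, ncol = 2L,
                dimnames = list(NULL, c("T", "C")))
  out[1L, ] <- state
  truncated <- FALSE
  for (k in seq_len(steps)) {
    state <- step_dyad(model, state, alternating)
    if (max(abs(state)) > overflow) {
      out <- out[seq_len(k), , drop = FALSE]
      truncated <- TRUE
      break
    }
    out[k + 1L, ] <- state
  }
  attr(out, "truncated") <- truncated
  out
}
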
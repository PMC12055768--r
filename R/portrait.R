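#' Build a phase portrait of a fitted dyad
#'
#' The dyad's state space is the (client score, therapist score) plane.
#' For every start point on a rectangular lattice the map is iterated
#' `steps` times (10 by default) to draw the flow; critical points are
#' located analytically: the thresholds of the two influence/repair
#' functions partition the plane into rectangles on which the map is
#' affine, the fixed-point equations are solved in each rectangle, and a
#' solution is kept when it lies inside its own rectangle.  Stability comes
#' from the eigenvalues of the region's Jacobian
#' `[[r_T, dI_T/dC], [dI_C/dT, r_C]]`: all moduli below 1 is an attractor,
#' exactly one above 1 a saddle, otherwise a repeller.
#'
#' @param model A [dyad_model()].
#' @param grid_client,grid_therapist Numeric vectors of lattice start
#'   coordinates (default `seq(-12, 12, by = 1)`, wide enough for 6-second
#'   sums under the default weight table).
#' @param steps Iterations per trajectory (default 10).
#' @param session_start Optional `c(C0, T0)` start coordinates (client
#'   first, as plotted on x) for the session's projected trajectory, e.g.
#'   from [session_start_point()].
#' @param overflow Divergence guard passed to [iterate_dyad()].
#' @return A `phase_portrait` list: `model`, `grid`, `trajectories` (list
#'   of state matrices), `critical_points` (data.frame with `T`, `C`,
#'   `stability`, `quadrant`), `steps`, and when a start is given
#'   `session_start`, `session_trajectory`, `session_end`.
#' @export
build_portrait <- function(model, grid_client = seq(-12, 12, by = 1),
                           grid_therapist = seq(-12, 12, by = 1),
                           steps = 10L, session_start = NULL,
                           overflow = 1e6) {
  stopifnot(inherits(model, "dyad_model"), steps >= 1L,
            length(grid_client) >= 2L, length(grid_therapist) >= 2L)
  starts <- expand.grid(C = grid_client, T = grid_therapist,
                        KEEP.OUT.ATTRS = FALSE)
  trajectories <- lapply(seq_len(nrow(starts)), function(i)
    iterate_dyad(model, c(starts$T[i], starts$C[i]), steps,
                 overflow = overflow))
  cp <- critical_points(model)
  out <- list(model = model,
              grid = list(client = grid_client, therapist = grid_therapist),
              trajectories = trajectories, critical_points = cp,
              steps = as.integer(steps))
  if (!is.null(session_start)) {
    st <- c(session_start[[2]], session_start[[1]])  # internal order (T, C)
    tr <- iterate_dyad(model, st, steps, overflow = overflow)
    out$session_start <- c(C = unname(session_start[[1]]),
                           T = unname(session_start[[2]]))
    out$session_trajectory <- tr
    out$session_end <- tr[nrow(tr), ]
  }
  structure(out, class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase_portrait: %d trajectories, %d steps>\n",
              length(x$trajectories), x$steps))
  if (nrow(x$critical_points)) print(x$critical_points) else
    cat("no critical points\n")
  invisible(x)
}

# Affine pieces of an actor's partner-driven term I(z) + R(z):
# intervals between threshold breakpoints, each with intercept + slope.
partner_term_pieces <- function(params) {
  f <- params$influence; rp <- params$repair
  breaks <- sort(unique(stats::na.omit(c(f$nth, f$pth,
                                         if (rp$active) rp$threshold))))
  edges <- c(-Inf, breaks, Inf)
  pieces <- lapply(seq_len(length(edges) - 1L), function(i) {
    lo <- edges[i]; hi <- edges[i + 1L]
    # two probe points inside the open interval determine the affine piece
    if (is.infinite(lo) && is.infinite(hi)) {
      p1 <- 0; p2 <- 1
    } else if (is.infinite(lo)) {
      p1 <- hi - 1; p2 <- hi - 2
    } else if (is.infinite(hi)) {
      p1 <- lo + 1; p2 <- lo + 2
    } else {
      p1 <- lo + (hi - lo) / 3; p2 <- lo + 2 * (hi - lo) / 3
    }
    v1 <- influence_value(f, p1) + repair_value(rp, p1)
    v2 <- influence_value(f, p2) + repair_value(rp, p2)
    slope <- if (p1 == p2) 0 else (v2 - v1) / (p2 - p1)
    list(lo = lo, hi = hi, slope = slope, intercept = v1 - slope * p1)
  })
  pieces
}

#' Critical points of the piecewise-affine dyadic map
#'
#' @param model A [dyad_model()].
#' @param tol Tolerance for region membership and deduplication.
#' @return data.frame with columns `T`, `C`, `stability` (`"attractor"`,
#'   `"saddle"`, `"repeller"`) and `quadrant`.
#' @export
critical_points <- function(model, tol = 1e-8) {
  th <- model$therapist; cl <- model$client
  pieces_C <- partner_term_pieces(th)  # therapist update, function of C
  pieces_T <- partner_term_pieces(cl)  # client update, function of T
  found <- list()
  for (pc in pieces_C) for (pt in pieces_T) {
    # T = rT T + aT + u0 + u1 C ; C = rC C + aC + v0 + v1 T
    A <- matrix(c(1 - th$r, -pc$slope,
                  -pt$slope, 1 - cl$r), 2, 2, byrow = TRUE)
    b <- c(th$a + pc$intercept, cl$a + pt$intercept)
    if (abs(det(A)) < 1e-12) next
    sol <- solve(A, b)
    Tstar <- sol[1]; Cstar <- sol[2]
    if (Cstar < pc$lo - tol || Cstar > pc$hi + tol) next
    if (Tstar < pt$lo - tol || Tstar > pt$hi + tol) next
    J <- matrix(c(th$r, pc$slope, pt$slope, cl$r), 2, 2, byrow = TRUE)
    ev <- Mod(eigen(J, only.values = TRUE)$values)
    stab <- if (all(ev < 1)) "attractor" else
      if (sum(ev > 1) == 1) "saddle" else "repeller"
    found <- c(found, list(c(T = unname(Tstar), C = unname(Cstar),
                             stab = stab)))
  }
  if (!length(found))
    return(data.frame(T = numeric(0), C = numeric(0),
                      stability = character(0), quadrant = character(0)))
  df <- data.frame(T = as.numeric(vapply(found, `[[`, "", "T")),
                   C = as.numeric(vapply(found, `[[`, "", "C")),
                   stability = vapply(found, `[[`, "", "stab"))
  # points straddling a region boundary are found from both sides: dedupe
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) > 1L)
    for (i in 2:nrow(df))
      for (j in 1:(i - 1L))
        if (keep[j] && abs(df$T[i] - df$T[j]) < 1e-6 &&
            abs(df$C[i] - df$C[j]) < 1e-6) keep[i] <- FALSE
  df <- df[keep, , drop = FALSE]
  df$quadrant <- mapply(classify_quadrant, df$T, df$C)
  rownames(df) <- NULL
  df
}

#' Session starting coordinates
#'
#' Mean of each actor's first `fraction` of window scores (the opening
#' one-tenth of the session by default), giving the point from which the
#' session's projected trajectory is launched.
#'
#' @param therapist,client [weighted_series()] or numeric vectors.
#' @param fraction Fraction of windows to average, in `(0, 1]`.
#' @return Named numeric `c(C, T)`: client coordinate (x-axis) then
#'   therapist coordinate (y-axis).
#' @export
session_start_point <- function(therapist, client, fraction = 0.10) {
  therapist <- as.numeric(therapist); client <- as.numeric(client)
  if (!length(therapist) || !length(client)) stop("empty series")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k_t <- ceiling(fraction * length(therapist))
  k_c <- ceiling(fraction * length(client))
  c(C = mean(client[seq_len(k_c)]), T = mean(therapist[seq_len(k_t)]))
}

#' Quadrant label of a state-space point
#'
#' @param T,C Therapist and client coordinates.
#' @return One of `"therapist positive-client positive"`,
#'   `"therapist positive-client negative"`,
#'   `"therapist negative-client positive"`,
#'   `"therapist negative-client negative"`, or `"boundary"` when either
#'   coordinate is 0.
#' @export
classify_quadrant <- function(T, C) {
  stopifnot(is.finite(T), is.finite(C))
  if (T == 0 || C == 0) return("boundary")
  paste0("therapist ", if (T > 0) "positive" else "negative",
         "-client ", if (C > 0) "positive" else "negative")
}

portrait_layers_df <- function(portrait) {
  segs <- do.call(rbind, lapply(portrait$trajectories, function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    data.frame(x = tr[-nrow(tr), "C"], y = tr[-nrow(tr), "T"],
               xend = tr[-1, "C"], yend = tr[-1, "T"])
  }))
  segs
}

#' Plot / render a phase portrait
#'
#' Trajectory flow in grey, critical points as red diamonds (attractors)
#' or open triangles, and when present the session's projected path as a
#' black line from a green square (start) to a black circle (end).
#'
#' @param portrait A [build_portrait()] result.
#' @return A ggplot object.
#' @export
plot_portrait <- function(portrait) {
  stopifnot(inherits(portrait, "phase_portrait"))
  segs <- portrait_layers_df(portrait)
  lim_x <- range(portrait$grid$client)
  lim_y <- range(portrait$grid$therapist)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::coord_cartesian(xlim = lim_x, ylim = lim_y) +
    ggplot2::labs(x = "client score", y = "therapist score") +
    ggplot2::theme_minimal()
  cp <- portrait$critical_points
  if (nrow(cp)) {
    p <- p + ggplot2::geom_point(
      data = cp,
      ggplot2::aes(x = .data$C, y = .data$T, shape = .data$stability),
      colour = "red", size = 3) +
      ggplot2::scale_shape_manual(
        values = c(attractor = 18, saddle = 2, repeller = 6))
  }
  if (!is.null(portrait$session_trajectory)) {
    tr <- as.data.frame(portrait$session_trajectory)
    p <- p +
      ggplot2::geom_path(data = tr,
                         ggplot2::aes(x = .data$C, y = .data$T),
                         colour = "black", linewidth = 0.8) +
      ggplot2::annotate("point", x = portrait$session_start[["C"]],
                        y = portrait$session_start[["T"]],
                        shape = 15, colour = "green3", size = 3) +
      ggplot2::annotate("point", x = portrait$session_end[["C"]],
                        y = portrait$session_end[["T"]],
                        shape = 16, colour = "black", size = 3)
  }
  p
}

#' @rdname plot_portrait
#' @param path Output file (`.png`).
#' @param width,height,dpi Device size in inches and resolution.
#' @return `render_portrait()`: the path, invisibly.
#' @export
render_portrait <- function(portrait, path, width = 6, height = 6, dpi = 96) {
  p <- plot_portrait(portrait)
  grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
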
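#' Read a coded session from CSV
#'
#' Expects columns `time_s` (0-based integer second), `actor`
#' (`therapist`/`client`) and `code` (canonical SPAFF name), the layout a
#' per-second observational coding export reduces to.  Each actor's
#' seconds must form a contiguous `0..T-1` sequence without duplicates.
#'
#' @param path CSV file path.
#' @return List with `therapist` and `client` [code_stream()]s.
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "actor", "code")
  if (!all(need %in% names(df)))
    stop("expected header time_s,actor,code")
  bad_actor <- which(!(df$actor %in% c("therapist", "client")))
  if (length(bad_actor))
    stop(sprintf("unknown actor '%s' at line %d",
                 df$actor[bad_actor[1]], bad_actor[1] + 1L))
  bad_code <- which(!(df$code %in% spaff_code_names()))
  if (length(bad_code))
    stop(sprintf("unknown code '%s' at line %d",
                 df$code[bad_code[1]], bad_code[1] + 1L))
  out <- lapply(c(therapist = "therapist", client = "client"), function(a) {
    sub <- df[df$actor == a, ]
    if (!nrow(sub)) stop("missing actor: ", a)
    if (anyDuplicated(sub$time_s))
      stop(sprintf("%s: duplicated second %d", a,
                   sub$time_s[anyDuplicated(sub$time_s)]))
    sub <- sub[order(sub$time_s), ]
    expect <- seq(0L, nrow(sub) - 1L)
    if (!all(sub$time_s == expect)) {
      gap <- expect[which(sub$time_s != expect)[1]]
      stop(sprintf("%s: seconds not contiguous from 0 (first gap at %d)",
                   a, gap))
    }
    code_stream(sub$code, a)
  })
  out
}

#' Write a coded session to CSV
#' @param streams List with `therapist` and `client` [code_stream()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(streams, path) {
  df <- do.call(rbind, lapply(streams, function(s)
    data.frame(time_s = seq_along(s$codes) - 1L, actor = s$actor,
               code = s$codes)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write session summaries, model parameters or a KS table to CSV
#'
#' `write_params_csv()` mirrors the published parameter-table layout
#' (columns `a2`, `r2`, `UnSS`, `nth`, `pth`, `kr`, `sr`, with `"N/A"` for
#' absent thresholds/repair) plus the fitted influence slopes so the file
#' round-trips losslessly through [read_params_csv()].
#'
#' @param summaries For `write_summary_csv()`: a `session_summary` or list
#'   of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  utils::write.csv(summary_to_df(summaries), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @param model A [dyad_model()] (or list of them, named by session).
#' @export
write_params_csv <- function(model, path) {
  if (inherits(model, "dyad_model")) model <- list(session = model)
  na_fmt <- function(x) ifelse(is.na(x), "N/A", format(x, digits = 10))
  df <- do.call(rbind, lapply(names(model), function(sid) {
    m <- model[[sid]]
    do.call(rbind, lapply(list(m$therapist, m$client), function(p)
      data.frame(session = sid, actor = p$actor,
                 a2 = na_fmt(p$a), r2 = na_fmt(p$r), UnSS = na_fmt(p$unss),
                 nth = na_fmt(p$influence$nth), pth = na_fmt(p$influence$pth),
                 neg_slope = na_fmt(p$influence$neg_slope),
                 pos_slope = na_fmt(p$influence$pos_slope),
                 kr = na_fmt(if (p$repair$active) p$repair$threshold
                             else NA_real_),
                 sr = na_fmt(if (p$repair$active) p$repair$strength
                             else NA_real_))))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_params_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), c("session", "actor")))
    df[[col]] <- suppressWarnings(as.numeric(ifelse(df[[col]] == "N/A",
                                                    NA, df[[col]])))
  df
}

#' @rdname write_summary_csv
#' @param ks_table data.frame from [ks_scan()].
#' @export
write_ks_csv <- function(ks_table, path) {
  utils::write.csv(ks_table, path, row.names = FALSE)
  invisible(path)
}

#' Packaged study fixtures
#'
#' Verbatim transcriptions of the published six-session study tables for
#' the therapist (Marlatt) and client (Kevin): per-code seconds with the
#' percentages as printed, meta-state tables, fitted model parameters, and
#' the reported Kolmogorov-Smirnov D statistics together with the fitted
#' reference under which each table's values reproduce.  Printed
#' percentages are retained even where they are internally inconsistent
#' with the seconds; analyses in this package always recompute percentages
#' from seconds and row-sum session totals.
#'
#' @param name One of `"marlatt_codes"`, `"kevin_codes"`, `"marlatt_meta"`,
#'   `"kevin_meta"`, `"totals"`, `"params"`, `"printed_d"`.
#' @return A data.frame.
#' @export
spaff_fixture <- function(name = c("marlatt_codes", "kevin_codes",
                                   "marlatt_meta", "kevin_meta",
                                   "totals", "params", "printed_d")) {
  name <- match.arg(name)
  file <- switch(name,
                 marlatt_codes = , kevin_codes = "table_codes.csv",
                 marlatt_meta = , kevin_meta = "table_meta.csv",
                 totals = "table_totals.csv",
                 params = "table_params.csv",
                 printed_d = "printed_d.csv")
  path <- system.file("extdata", file, package = "spaffdyn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name %in% c("marlatt_codes", "marlatt_meta"))
    df <- df[df$actor == "marlatt", ]
  if (name %in% c("kevin_codes", "kevin_meta"))
    df <- df[df$actor == "kevin", ]
  rownames(df) <- NULL
  df
}

#' Session summaries re-derived from the fixture code tables
#'
#' Builds one [summary_from_seconds()] per session from the transcribed
#' per-code seconds; session totals are the row sums, which is what makes
#' the recomputed percentages reproduce the printed ones.
#'
#' @param actor `"marlatt"` (therapist) or `"kevin"` (client).
#' @return Named list of six `session_summary` objects.
#' @export
fixture_summaries <- function(actor = c("marlatt", "kevin")) {
  actor <- match.arg(actor)
  df <- spaff_fixture(paste0(actor, "_codes"))
  role <- if (actor == "marlatt") "therapist" else "client"
  sessions <- sort(unique(df$session))
  out <- lapply(sessions, function(s) {
    sub <- df[df$session == s, ]
    summary_from_seconds(stats::setNames(sub$seconds, sub$code),
                         session_id = paste0("session", s), actor = role)
  })
  stats::setNames(out, paste0("session", sessions))
}

#' Exact per-session percentage matrix from the fixtures
#'
#' @param actor `"marlatt"` or `"kevin"`.
#' @param kind `"code"` for the 20 individual codes, `"meta"` for the four
#'   meta-states (Neutral excluded in both cases' KS scans is up to the
#'   caller; all rows are returned).
#' @return Numeric matrix, rows = items, columns = six sessions.
#' @export
fixture_percent_matrix <- function(actor = c("marlatt", "kevin"),
                                   kind = c("code", "meta")) {
  actor <- match.arg(actor)
  kind <- match.arg(kind)
  sums <- fixture_summaries(actor)
  cols <- lapply(sums, function(s) {
    if (kind == "code") s$per_code_percent
    else 100 * s$meta_seconds / s$total_seconds
  })
  do.call(cbind, cols)
}

#' Dyad model from the published parameter table
#'
#' The printed tables report the uninfluenced parameters, influence
#' thresholds and repair terms but not the influence slopes, so a portrait
#' built from them needs slopes supplied by configuration; with
#' `influence = "null"` the influence functions are dropped entirely,
#' leaving the linear uninfluenced dynamics.
#'
#' @param session Session number 1-6.
#' @param influence `"config"` (use thresholds with `slopes`) or `"null"`.
#' @param slopes Length-2 `c(neg, pos)` slope applied to both actors'
#'   influence functions (influence units per score unit).
#' @param repair Include the printed repair terms where present.
#' @return A [dyad_model()].
#' @export
fixture_dyad <- function(session, influence = c("config", "null"),
                         slopes = c(0.5, 0.5), repair = TRUE) {
  influence <- match.arg(influence)
  pars <- spaff_fixture("params")
  one <- function(actor_fix, role) {
    p <- pars[pars$actor == actor_fix & pars$session == session, ]
    stopifnot(nrow(p) == 1L)
    inf <- if (influence == "null") influence_function() else
      influence_function(p$nth, p$pth, slopes[1], slopes[2])
    rp <- if (repair && !is.na(p$kr)) repair_term(p$kr, p$sr) else
      repair_term()
    actor_params(role, p$a2, p$r2, influence = inf, repair = rp)
  }
  dyad_model(one("marlatt", "therapist"), one("kevin", "client"))
}
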
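#' Summarise a session's SPAFF usage
#'
#' Counts the seconds spent in each of the 20 codes, converts them to
#' percentages of the session's coded length, and aggregates into total
#' positive / total negative seconds and the four meta-states
#' (positive affect, facilitate, negative affect, control) plus Neutral.
#' Tense Humor counts toward the negative total and the negative-affect
#' meta-state (see [spaff_codes()]).
#'
#' @param stream A [code_stream()].
#' @param session_id Label for the session.
#' @return A `session_summary` list with elements `session_id`, `actor`,
#'   `per_code_seconds`, `total_seconds`, `per_code_percent`,
#'   `total_positive_s`, `total_negative_s` and `meta_seconds`.
#' @examples
#' s <- code_stream(c(rep("Neutral", 50), rep("Interest", 10)))
#' summarize_session(s, "demo")$per_code_percent[["Interest"]]
#' @export
summarize_session <- function(stream, session_id = "session") {
  stopifnot(inherits(stream, "code_stream"))
  if (length(stream) == 0L) stop("empty code stream")
  seconds <- per_code_table(table(factor(stream$codes,
                                         levels = spaff_code_names())))
  summary_from_seconds(seconds, session_id = session_id, actor = stream$actor)
}

per_code_table <- function(x) {
  out <- stats::setNames(rep(0, 20L), spaff_code_names())
  out[names(x)] <- as.numeric(x)
  out
}

#' Build a session summary from per-code second counts
#'
#' Used both by [summarize_session()] and to re-derive published session
#' tables from their individual code rows, where the session length is not
#' reported and must be taken as the row sum.
#'
#' @param per_code_seconds Named numeric vector of seconds; codes not named
#'   are taken as 0.
#' @param session_id,actor Labels.
#' @return A `session_summary` (see [summarize_session()]).
#' @export
summary_from_seconds <- function(per_code_seconds, session_id = "session",
                                 actor = "therapist") {
  unknown <- setdiff(names(per_code_seconds), spaff_code_names())
  if (length(unknown))
    stop("unknown code(s): ", paste(unknown, collapse = ", "))
  seconds <- per_code_table(per_code_seconds)
  total <- session_total(seconds)
  if (total <= 0) stop("session has no coded seconds")
  codes <- spaff_codes()
  val <- stats::setNames(codes$valence, codes$code)
  structure(list(
    session_id = session_id,
    actor = actor,
    per_code_seconds = seconds,
    total_seconds = total,
    per_code_percent = 100 * seconds / total,
    total_positive_s = sum(seconds[val[names(seconds)] == "positive"]),
    total_negative_s = sum(seconds[val[names(seconds)] == "negative"]),
    meta_seconds = meta_state_seconds(seconds)
  ), class = "session_summary")
}

#' Seconds per meta-state
#'
#' @param per_code_seconds Named numeric vector of seconds per code (or a
#'   `session_summary`).
#' @return Named numeric vector over `positive_affect`, `facilitate`,
#'   `negative_affect`, `control`, `neutral`.
#' @export
meta_state_seconds <- function(per_code_seconds) {
  if (inherits(per_code_seconds, "session_summary"))
    per_code_seconds <- per_code_seconds$per_code_seconds
  codes <- spaff_codes()
  ms <- stats::setNames(codes$meta_state, codes$code)
  states <- c("positive_affect", "facilitate", "negative_affect",
              "control", "neutral")
  out <- vapply(states, function(s)
    sum(per_code_seconds[names(per_code_seconds) %in%
                           names(ms)[ms == s]], na.rm = TRUE), numeric(1))
  stats::setNames(out, states)
}

#' Total coded seconds from a per-code table
#'
#' @param per_code_seconds Named numeric vector of seconds.
#' @return Sum of the entries (0 for an empty mapping).
#' @export
session_total <- function(per_code_seconds) {
  if (length(per_code_seconds) == 0L) return(0)
  sum(per_code_seconds)
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary: %s / %s, %d s coded>\n",
              x$session_id, x$actor, round(x$total_seconds)))
  nz <- x$per_code_seconds[x$per_code_seconds > 0]
  df <- data.frame(seconds = nz,
                   percent = round(x$per_code_percent[names(nz)], 2))
  print(df[order(-df$seconds), , drop = FALSE])
  cat(sprintf("total positive %g s, total negative %g s\n",
              x$total_positive_s, x$total_negative_s))
  invisible(x)
}

#' Flatten session summaries to a data.frame
#'
#' One row per (session, actor, code) with seconds and percent, followed by
#' one row per meta-state and the positive/negative totals (`kind` column
#' distinguishes them), suitable for CSV export via [write_summary_csv()].
#'
#' @param summaries A `session_summary` or list of them.
#' @return data.frame with columns `session_id`, `actor`, `kind`, `item`,
#'   `seconds`, `percent`.
#' @export
summary_to_df <- function(summaries) {
  if (inherits(summaries, "session_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    meta_pct <- 100 * s$meta_seconds / s$total_seconds
    rbind(
      data.frame(session_id = s$session_id, actor = s$actor, kind = "code",
                 item = names(s$per_code_seconds),
                 seconds = unname(s$per_code_seconds),
                 percent = unname(s$per_code_percent)),
      data.frame(session_id = s$session_id, actor = s$actor, kind = "meta",
                 item = names(s$meta_seconds),
                 seconds = unname(s$meta_seconds),
                 percent = unname(meta_pct)),
      data.frame(session_id = s$session_id, actor = s$actor, kind = "total",
                 item = c("total_positive", "total_negative", "total"),
                 seconds = c(s$total_positive_s, s$total_negative_s,
                             s$total_seconds),
                 percent = c(100 * s$total_positive_s / s$total_seconds,
                             100 * s$total_negative_s / s$total_seconds,
                             100))
    )
  }))
}
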
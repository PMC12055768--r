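#' Canonical SPAFF code table
#'
#' The Specific Affect Coding System (SPAFF) assigns one of 20 mutually
#' exclusive affect codes to each second of an interaction: one neutral
#' code, seven conventionally "positive" codes and twelve "negative" codes.
#' For session totals and the four meta-states this package groups Tense
#' Humor with the negative codes, following the arithmetic of the published
#' session tables rather than the conventional positive list (a tense joke
#' carries tension; the meta-state grouping treats it as negative affect).
#'
#' @return A data.frame with one row per code and columns
#'   \describe{
#'     \item{code}{canonical code name}
#'     \item{valence}{grouping used for total positive / total negative /
#'       neutral seconds: `"positive"`, `"negative"` or `"neutral"`}
#'     \item{meta_state}{one of `"positive_affect"`, `"facilitate"`,
#'       `"negative_affect"`, `"control"`, `"neutral"`}
#'   }
#' @examples
#' table(spaff_codes()$meta_state)
#' @export
spaff_codes <- function() {
  df <- rbind(
    data.frame(code = c("Affection", "Humor", "Surprise/Joy"),
               meta_state = "positive_affect"),
    data.frame(code = c("Low Validation", "High Validation", "Interest"),
               meta_state = "facilitate"),
    data.frame(code = c("Anger", "Sadness", "Whining", "Disgust",
                        "Contempt", "Tension", "Tense Humor"),
               meta_state = "negative_affect"),
    data.frame(code = c("Belligerence", "Low Domineering", "High Domineering",
                        "Criticism", "Defensiveness", "Stonewalling"),
               meta_state = "control"),
    data.frame(code = "Neutral", meta_state = "neutral")
  )
  df$valence <- c(positive_affect = "positive", facilitate = "positive",
                  negative_affect = "negative", control = "negative",
                  neutral = "neutral")[df$meta_state]
  rownames(df) <- NULL
  df[, c("code", "valence", "meta_state")]
}

#' Names of the 20 canonical SPAFF codes
#' @return Character vector of length 20.
#' @export
spaff_code_names <- function() spaff_codes()$code

#' Default per-second code weights
#'
#' SPAFF analyses weight each per-second code by a signed score before
#' summing over 6-second windows.  The historical weight values are not
#' part of the public coding manuals, so this package ships a configurable
#' default that follows the marital-interaction literature's conventions:
#' strongly positive codes at +4, mildly positive at +2, Neutral at a small
#' positive +0.1, mild negatives at -1, hostile negatives at -2 to -4 with
#' Contempt most negative.  Treat these as an analysis configuration, not
#' as ground truth; [read_weight_config()] loads alternatives.
#'
#' @return Named numeric vector over all 20 codes (units: affect score per
#'   second).
#' @seealso [validate_weight_table()], [weight_and_window()]
#' @export
default_weight_table <- function() {
  c("Affection" = 4, "High Validation" = 4, "Humor" = 4, "Surprise/Joy" = 4,
    "Low Validation" = 2, "Interest" = 2,
    "Neutral" = 0.1,
    "Tense Humor" = -1, "Tension" = -1, "Whining" = -1, "Sadness" = -1,
    "Anger" = -1, "Low Domineering" = -1, "High Domineering" = -1,
    "Belligerence" = -2, "Defensiveness" = -2, "Criticism" = -2,
    "Stonewalling" = -2,
    "Disgust" = -3, "Contempt" = -4)
}

#' Validate a weight table
#'
#' Checks that a named weight vector covers all 20 canonical codes, has no
#' extraneous entries, and respects the sign conventions: negative-valence
#' codes weigh at most 0, positive-valence codes at least 0 (Neutral may
#' carry a small positive weight).
#'
#' @param weights Named numeric vector of per-second weights.
#' @return Character vector of human-readable violations; empty when valid.
#' @examples
#' validate_weight_table(default_weight_table())
#' @export
validate_weight_table <- function(weights) {
  codes <- spaff_codes()
  out <- character()
  missing <- setdiff(codes$code, names(weights))
  if (length(missing))
    out <- c(out, paste0("missing code: ", missing))
  extra <- setdiff(names(weights), codes$code)
  if (length(extra))
    out <- c(out, paste0("unknown code: ", extra))
  present <- intersect(codes$code, names(weights))
  for (cd in present) {
    v <- codes$valence[codes$code == cd]
    w <- unname(weights[[cd]])
    if (!is.finite(w)) {
      out <- c(out, paste0("non-finite weight: ", cd))
    } else if (v == "negative" && w > 0) {
      out <- c(out, paste0("sign constraint: ", cd,
                           " is negative-valence but has weight ", w))
    } else if (v == "positive" && w < 0) {
      out <- c(out, paste0("sign constraint: ", cd,
                           " is positive-valence but has weight ", w))
    }
  }
  out
}

#' Construct a per-second code stream
#'
#' @param codes Character vector, one canonical SPAFF code per second
#'   (0-based time; element `i` covers second `i - 1`).
#' @param actor `"therapist"` or `"client"`.
#' @return A `code_stream` object.
#' @export
code_stream <- function(codes, actor = c("therapist", "client")) {
  actor <- match.arg(actor)
  codes <- as.character(codes)
  if (length(codes) == 0L) stop("empty code stream")
  bad <- which(!(codes %in% spaff_code_names()))
  if (length(bad))
    stop(sprintf("unknown code '%s' at second %d", codes[bad[1]], bad[1] - 1L))
  structure(list(actor = actor, codes = codes), class = "code_stream")
}

#' @export
length.code_stream <- function(x) length(x$codes)

#' @export
print.code_stream <- function(x, ...) {
  cat(sprintf("<code_stream: %s, %d s, %d distinct codes>\n",
              x$actor, length(x$codes), length(unique(x$codes))))
  invisible(x)
}

#' Construct a windowed weighted-score series
#'
#' @param scores Numeric vector of per-window scores.
#' @param actor `"therapist"` or `"client"`.
#' @param window_s Window length in seconds (default 6).
#' @return A `weighted_series`: numeric vector with `actor` and `window_s`
#'   attributes.
#' @export
weighted_series <- function(scores, actor = c("therapist", "client"),
                            window_s = 6L) {
  actor <- match.arg(actor)
  stopifnot(is.numeric(scores), window_s >= 1)
  structure(as.numeric(scores), actor = actor, window_s = as.integer(window_s),
            class = "weighted_series")
}

#' @export
print.weighted_series <- function(x, ...) {
  cat(sprintf("<weighted_series: %s, %d windows of %d s>\n",
              attr(x, "actor"), length(x), attr(x, "window_s")))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Weight a code stream and sum over windows
#'
#' Each second's code is replaced by its signed weight and consecutive
#' non-overlapping windows of `window_s` seconds are summed, turning a
#' categorical per-second stream into the numeric series the dyadic model
#' is fitted to (900 coded seconds yield 150 six-second scores).  Windows
#' are half-open `[k*window_s, (k+1)*window_s)` on 0-based time; a trailing
#' partial window is discarded.
#'
#' @param stream A [code_stream()].
#' @param weights Named numeric weight vector covering every code present
#'   (default [default_weight_table()]).
#' @param window_s Window length in seconds, at least 1 (default 6).
#' @return A [weighted_series()] of `floor(length(stream)/window_s)` scores.
#' @examples
#' s <- code_stream(rep("Neutral", 12))
#' weight_and_window(s, c(Neutral = 0), window_s = 6)
#' @export
weight_and_window <- function(stream, weights = default_weight_table(),
                              window_s = 6L) {
  stopifnot(inherits(stream, "code_stream"))
  window_s <- as.integer(window_s)
  if (window_s < 1L) stop("window_s must be >= 1")
  codes <- stream$codes
  unknown <- which(!(codes %in% names(weights)))
  if (length(unknown))
    stop(sprintf("no weight for code '%s' at second %d",
                 codes[unknown[1]], unknown[1] - 1L))
  w <- unname(weights[codes])
  n_win <- length(w) %/% window_s
  if (n_win == 0L)
    return(weighted_series(numeric(0), stream$actor, window_s))
  used <- w[seq_len(n_win * window_s)]
  scores <- colSums(matrix(used, nrow = window_s))
  weighted_series(scores, stream$actor, window_s)
}

#' Read / write a weight and grouping configuration
#'
#' The configuration is a YAML mapping with a `weights:` block (one entry
#' per canonical code) and optionally a `window_s:` entry.
#'
#' @param path File path.
#' @return `read_weight_config()`: named numeric weight vector.
#' @export
read_weight_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  w <- unlist(cfg$weights)
  if (is.null(w)) stop("config has no 'weights' block")
  storage.mode(w) <- "double"
  w
}

#' @rdname read_weight_config
#' @param weights Named numeric weight vector.
#' @param window_s Window length recorded alongside the weights.
#' @export
write_weight_config <- function(weights, path, window_s = 6L) {
  yaml::write_yaml(list(window_s = as.integer(window_s),
                        weights = as.list(weights)), path)
  invisible(path)
}
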
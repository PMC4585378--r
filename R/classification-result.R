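#' Construct a classification result
#'
#' Candidate classes are ordered control first, then increasing hours; ties in
#' the winning score are broken toward the earlier class and flagged.
#'
#' @param scores Named numeric vector of per-class scores. Names are
#'   `"control"` or hours.
#' @param higher_is_better `TRUE` when larger scores win (signature scores,
#'   vote tallies); `FALSE` for distances.
#' @param method Label of the producing classifier.
#' @return A `classification_result` with fields `scores`, `winner`, `margin`
#'   (winner vs runner-up, always >= 0 in the winning direction), `tie`,
#'   `confidence` (filled by [assign_confidence()]), `method`.
#' @export
classification_result <- function(scores, higher_is_better = TRUE,
                                  method = "unspecified") {
  if (is.null(names(scores)) || length(scores) < 1L)
    stop("`scores` must be a named vector")
  ord <- class_order(names(scores))
  scores <- scores[ord]
  eff <- if (higher_is_better) scores else -scores
  best <- max(eff)
  winners <- which(eff == best)
  winner <- names(scores)[winners[1L]]
  margin <- if (length(scores) >= 2L) best - max(eff[-winners[1L]]) else Inf
  structure(list(scores = scores, winner = winner, margin = margin,
                 tie = length(winners) > 1L, confidence = NA_character_,
                 higher_is_better = higher_is_better, method = method),
            class = "classification_result")
}

# control first, then ascending hours, then anything else
class_order <- function(nm) {
  hours <- suppressWarnings(as.numeric(nm))
  key <- ifelse(nm == "control", -Inf, hours)
  key[is.na(key)] <- Inf
  order(key)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result (", x$method, "): winner = ", x$winner,
      ", margin = ", format(x$margin, digits = 4), sep = "")
  if (!is.na(x$confidence)) cat(", confidence =", x$confidence)
  if (x$tie) cat(" [tie]")
  cat("\n")
  invisible(x)
}

#' Assign a confidence tier from the score margin
#'
#' A margin above `high` between the winner and the runner-up marks a
#' high-confidence call, a margin between `medium` and `high` (inclusive) a
#' medium one, anything smaller (including ties) low.
#'
#' @param result A `classification_result` scored over >= 2 classes.
#' @param high Margin above which the call is high confidence (default 100).
#' @param medium Lower bound of the medium band (default 50).
#' @return The result with `confidence` filled in.
#' @export
assign_confidence <- function(result, high = 100, medium = 50) {
  stopifnot(inherits(result, "classification_result"))
  if (length(result$scores) < 2L)
    stop("confidence needs >= 2 scored classes")
  m <- result$margin
  result$confidence <- if (m > high) "high" else if (m >= medium) "medium" else "low"
  result
}

#' Coarse healing period of a class label
#'
#' Maps an hour to the early (3--24 h), middle (48--168 h) or late
#' (336--672 h) post-injury period; `"control"` maps to itself.
#'
#' @param label `"control"` or hours (numeric or character), vectorized.
#' @return Character vector of `"control"`, `"early"`, `"middle"`, `"late"`.
#' @export
coarse_period <- function(label) {
  out <- character(length(label))
  lab <- as.character(label)
  hours <- suppressWarnings(as.numeric(lab))
  out[lab == "control"] <- "control"
  num <- !is.na(hours)
  out[num & hours <= 24] <- "early"
  out[num & hours > 24 & hours <= 168] <- "middle"
  out[num & hours > 168] <- "late"
  if (any(out == "")) stop("unrecognized class label: ", lab[out == ""][1L])
  out
}
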
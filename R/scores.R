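# Molt score codes. Growing feathers are scored as decimal fractions of full
# length (0.1-0.9); a missing feather (empty follicle) scores 0.05; feathers
# completed in the current episode of molt score 1 (new), those from the
# previous episode 2 (old), and two episodes back 3 (very old).

SCORE_CODES <- c(0.05, seq(0.1, 0.9, by = 0.1), 1, 2, 3)
SCORE_EPS <- 1e-9

#' Parse a molt score code
#'
#' Validates a raw score token against the permitted code set
#' \{0.05, 0.1, ..., 0.9, 1, 2, 3\}.
#'
#' @param x character or numeric vector of score tokens; \code{NA} or empty
#'   strings denote unscored loci and pass through as \code{NA}.
#' @param context optional string (e.g. \code{"row 3, column P5"}) included in
#'   the error message for an invalid code.
#' @return numeric vector of validated codes.
#' @examples
#' parse_score(c("0.5", "0.05", "1", ""))
#' @export
parse_score <- function(x, context = NULL) {
  if (is.character(x)) {
    x <- trimws(x)
    x[x == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(x))
    bad_num <- !is.na(x) & is.na(val)
  } else {
    val <- as.numeric(x)
    bad_num <- rep(FALSE, length(val))
  }
  ok <- is.na(val) | vapply(val, function(v)
    isTRUE(any(abs(v - SCORE_CODES) < SCORE_EPS)), logical(1))
  bad <- bad_num | !ok
  if (any(bad)) {
    shown <- if (is.character(x)) x[bad] else format(val[bad])
    stop("invalid molt score code", if (!is.null(context)) paste0(" (", context, ")"),
         ": ", paste(unique(shown), collapse = ", "),
         "; allowed codes are 0.05, 0.1-0.9, 1, 2, 3", call. = FALSE)
  }
  # snap to the canonical code to avoid decimal representation drift
  out <- rep(NA_real_, length(val))
  nn <- which(!is.na(val))
  out[nn] <- SCORE_CODES[vapply(val[nn],
                                function(v) which.min(abs(v - SCORE_CODES)),
                                integer(1))]
  out
}

#' Score categories
#'
#' Maps score codes to feather-age categories: 0.05 is \code{missing},
#' 0.1-0.9 \code{growing}, 1 \code{new}, 2 \code{old}, 3 \code{very_old}.
#' A locus is \emph{active} (part of an ongoing replacement) when it is
#' missing or growing.
#'
#' @param code numeric vector of score codes (\code{NA} = unscored).
#' @return \code{score_category}: factor with levels \code{missing},
#'   \code{growing}, \code{new}, \code{old}, \code{very_old};
#'   \code{is_active_score}: logical (\code{FALSE} for unscored loci).
#' @export
score_category <- function(code) {
  lv <- c("missing", "growing", "new", "old", "very_old")
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & abs(code - 0.05) < SCORE_EPS] <- "missing"
  out[!is.na(code) & code >= 0.1 - SCORE_EPS & code <= 0.9 + SCORE_EPS] <- "growing"
  out[!is.na(code) & abs(code - 1) < SCORE_EPS] <- "new"
  out[!is.na(code) & abs(code - 2) < SCORE_EPS] <- "old"
  out[!is.na(code) & abs(code - 3) < SCORE_EPS] <- "very_old"
  factor(out, levels = lv)
}

#' @rdname score_category
#' @export
is_active_score <- function(code) {
  !is.na(code) & code < 1 - SCORE_EPS
}

# growth fraction of an active score: a missing feather counts as a growing
# feather of fraction 0
score_fraction <- function(code) {
  ifelse(abs(code - 0.05) < SCORE_EPS, 0, code)
}

is_new_score <- function(code) !is.na(code) & abs(code - 1) < SCORE_EPS
is_old_score <- function(code) !is.na(code) & code >= 2 - SCORE_EPS
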
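# Statistical support for replacement direction and series structure:
# exact binomial sign tests on pooled direction tallies, wave detection
# within a series, and the frequency of stepwise (multi-wave) molt.

#' Exact binomial sign test for a direction tally
#'
#' One-sided exact binomial tail probability for an observed split of
#' distal vs proximal direction scores: with \eqn{n} scores and \eqn{k} the
#' larger count, \eqn{p = P(X \ge k)} for \eqn{X \sim Binomial(n, 1/2)}.
#' Ambiguous scores must be excluded before calling.
#'
#' @param n_distal,n_proximal non-negative counts.
#' @return the p-value; 1 when both counts are zero.
#' @examples
#' sign_test(8, 6)    # 0.395
#' sign_test(11, 7)   # 0.240
#' @export
sign_test <- function(n_distal, n_proximal) {
  if (n_distal < 0 || n_proximal < 0)
    stop("direction counts must be non-negative", call. = FALSE)
  n <- n_distal + n_proximal
  if (n == 0) return(1)
  k <- max(n_distal, n_proximal)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Pooled direction tally over a range of adjacent pairs
#'
#' Sums the distal/proximal/ambiguous counts of a molt summary over an
#' inclusive range of pairs, e.g. all within-primary pairs or the outer
#' secondary segment.
#'
#' @param summary a \code{molt_summary}.
#' @param from_pair,to_pair pair labels (such as \code{"P1/P2"},
#'   \code{"S7/S8"}) or pair indices; order is immaterial.
#' @return list with \code{n_distal}, \code{n_proximal}, \code{n_ambiguous},
#'   \code{pairs} (the labels pooled) and \code{p} (the sign test on the
#'   unambiguous counts).
#' @examples
#' \dontrun{pooled_direction(tab, "P1/P2", "P9/P10")}
#' @export
pooled_direction <- function(summary, from_pair, to_pair = from_pair) {
  idx <- function(p) if (is.character(p)) pair_index(p, summary$chain)
                     else as.integer(p)
  rng <- sort(c(idx(from_pair), idx(to_pair)))
  sel <- summary$pair_counts$pair_index >= rng[1] &
         summary$pair_counts$pair_index <= rng[2]
  pc <- summary$pair_counts[sel, ]
  out <- list(n_distal = sum(pc$distal), n_proximal = sum(pc$proximal),
              n_ambiguous = sum(pc$ambiguous), pairs = pc$pair)
  out$p <- sign_test(out$n_distal, out$n_proximal)
  out
}

#' Detect replacement waves within a molt series
#'
#' A wave is a maximal run of consecutive active (growing or missing) loci in
#' series order.  Runs separated by at least one fully grown feather are
#' distinct waves.  Unscored loci break runs conservatively (waves are never
#' merged across unknowns) and are reported with a warning.
#'
#' @param scores named numeric score vector for one record, or a one-row
#'   \code{wing_records} table.
#' @param series a \code{molt_series}.
#' @return list with \code{n_waves}, \code{waves} (list of locus vectors in
#'   series order) and \code{has_unscored}.
#' @examples
#' s <- stats::setNames(c(1, 1, 0.6, 2, 2, 1, 0.3, 2, 2, 2), paste0("P", 1:10))
#' detect_waves(s, molt_series("primaries", paste0("P", 1:10)))$n_waves  # 2
#' @export
detect_waves <- function(scores, series) {
  if (is.data.frame(scores)) scores <- record_scores(scores, 1L, series$chain)
  s <- scores[series$loci]
  active <- is_active_score(s)
  has_unscored <- anyNA(s)
  if (has_unscored && any(active))
    warning("unscored loci inside series '", series$name,
            "' break waves conservatively", call. = FALSE)
  waves <- list()
  run <- character(0)
  for (i in seq_along(s)) {
    if (active[i]) {
      run <- c(run, series$loci[i])
    } else if (length(run)) {
      waves[[length(waves) + 1L]] <- run
      run <- character(0)
    }
  }
  if (length(run)) waves[[length(waves) + 1L]] <- run
  list(n_waves = length(waves), waves = waves, has_unscored = has_unscored)
}

#' Frequency of stepwise molt in a series
#'
#' Counts records in active molt of the series (at least one wave) and
#' records with two or more waves, the conservative published criterion for
#' stepwise replacement.
#'
#' @param records a \code{wing_records} table.
#' @param series a \code{molt_series}.
#' @return list with \code{n_molting}, \code{n_stepwise}, \code{fraction},
#'   \code{percent} (truncated to 0.1, see [stepwise_percent()]), and
#'   \code{histogram} (counts of records with 1, 2, 3, ... waves).
#' @export
stepwise_frequency <- function(records, series) {
  nw <- vapply(seq_len(nrow(records)), function(i)
    suppressWarnings(
      detect_waves(record_scores(records, i, series$chain), series))$n_waves,
    integer(1))
  n_molting <- sum(nw >= 1L)
  n_stepwise <- sum(nw >= 2L)
  if (n_molting == 0L) {
    warning("no records in active molt of series '", series$name,
            "'; stepwise fraction reported as 0", call. = FALSE)
    fraction <- 0
  } else {
    fraction <- n_stepwise / n_molting
  }
  hist <- if (n_molting) table(factor(nw[nw >= 1L], levels = seq_len(max(nw))))
          else table(factor(integer(0), levels = 1L))
  list(n_molting = n_molting, n_stepwise = n_stepwise, fraction = fraction,
       percent = stepwise_percent(n_stepwise, max(n_molting, 1L)),
       histogram = hist)
}

#' Stepwise percentage, truncated to one decimal
#'
#' Reported percentages of stepwise molt are truncated (not rounded) to
#' 0.1\%, the conservative convention used for the published values
#' (35/166 is reported as 21.0\%, 5/39 as 12.8\%).
#'
#' @param n_stepwise,n_molting counts.
#' @return percentage on the 0-100 scale, truncated to one decimal.
#' @examples
#' stepwise_percent(35, 166)  # 21.0
#' stepwise_percent(5, 39)    # 12.8
#' @export
stepwise_percent <- function(n_stepwise, n_molting) {
  if (n_molting <= 0) stop("n_molting must be positive", call. = FALSE)
  floor(1000 * n_stepwise / n_molting + 1e-9) / 10
}
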
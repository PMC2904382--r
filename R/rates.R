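# Growth-band rates, primary-length sums, the mean number of simultaneously
# growing primaries, and the molt-duration formula d = l / (r * y).

#' Round half away from zero
#'
#' Commercial rounding at the printed precision (1085.25 mm reports as
#' 1085.3), as opposed to \code{round()}'s round-half-even.
#'
#' @param x numeric vector (non-negative use intended).
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Feather growth rate from growth-band spacing
#'
#' One pair of light/dark growth bands corresponds to 24 h of growth, so the
#' mean distance between adjacent band pairs is the daily elongation rate in
#' mm/day.  Each bird's rate is the mean of its measured inter-band
#' distances (the measurement protocol uses six sequential pairs); the
#' population rate is the unweighted mean of the per-bird rates.
#'
#' @param bands per-bird inter-band distances (mm): a list of numeric
#'   vectors, or a data.frame whose numeric columns hold the distances (an
#'   id column, if present, labels the output).
#' @return list with \code{per_bird} (named numeric) and \code{mean}.
#' @examples
#' growth_rate(list(a = c(2, 3, 4, 2, 3, 4), b = rep(2.5, 6)))
#' @export
growth_rate <- function(bands) {
  if (is.data.frame(bands)) {
    num <- vapply(bands, is.numeric, logical(1))
    ids <- if ("specimen_id" %in% names(bands)) bands$specimen_id
           else as.character(seq_len(nrow(bands)))
    bands <- lapply(seq_len(nrow(bands)), function(i)
      as.numeric(bands[i, num, drop = TRUE]))
    names(bands) <- ids
  }
  if (length(bands) == 0L) stop("no growth-band series given", call. = FALSE)
  per_bird <- vapply(bands, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0L)
      stop("empty inter-band distance list", call. = FALSE)
    if (any(d <= 0)) stop("inter-band distances must be positive",
                          call. = FALSE)
    mean(d)
  }, numeric(1))
  list(per_bird = per_bird, mean = mean(per_bird))
}

#' Summed primary length per bird
#'
#' @param matrix data.frame with one row per specimen and complete numeric
#'   columns \code{P1}...\code{P10} of feather lengths in mm.
#' @return list with \code{per_bird} sums, \code{mean}, and \code{reported}
#'   (the mean rounded half-up to 0.1 mm).
#' @examples
#' m <- as.data.frame(matrix(100, 1, 10, dimnames = list(NULL, paste0("P", 1:10))))
#' summed_primary_length(m)$per_bird  # 1000
#' @export
summed_primary_length <- function(matrix) {
  pcols <- paste0("P", 1:10)
  if (!all(pcols %in% names(matrix)))
    stop("length matrix must have columns P1..P10", call. = FALSE)
  m <- as.matrix(matrix[, pcols])
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("missing primary lengths at: ",
         paste(sprintf("row %d %s", idx[, 1], pcols[idx[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  if (any(m <= 0)) stop("feather lengths must be positive", call. = FALSE)
  per_bird <- rowSums(m)
  list(per_bird = per_bird, mean = mean(per_bird),
       reported = round_half_up(mean(per_bird), 1))
}

#' Mean number of primaries growing per wing from wave tallies
#'
#' The numerator is the total number of growing primaries: the wave counts
#' weighted by the number of waves, plus the extra feathers from birds
#' growing two adjacent primaries within one wave.  The denominator is
#' either the birds growing primaries (\code{"primary_molters"}) or all
#' birds growing primaries or secondaries (\code{"quill_molters"}, which
#' adds the secondary-only molters and corrects for the pause between
#' successive primaries of a wave).
#'
#' @param tallies named list or vector with elements \code{one_wave},
#'   \code{two_waves}, \code{three_waves}, \code{extra_adjacent},
#'   \code{secondary_only} (absent elements count 0).
#' @param denominator \code{"primary_molters"} or \code{"quill_molters"}.
#' @return list with \code{numerator}, \code{denominator}, \code{y}, and
#'   \code{reported} (\code{y} rounded half-up to 0.01).
#' @examples
#' t4 <- c(one_wave = 128, two_waves = 32, three_waves = 1,
#'         extra_adjacent = 4, secondary_only = 13)
#' mean_growing_per_wing(t4, "primary_molters")$reported  # 1.24
#' mean_growing_per_wing(t4, "quill_molters")$reported    # 1.14
#' @export
mean_growing_per_wing <- function(tallies,
                                  denominator = c("primary_molters",
                                                  "quill_molters")) {
  denominator <- match.arg(denominator)
  g <- function(k) if (k %in% names(tallies)) as.numeric(tallies[[k]]) else 0
  waves <- c(one_wave = 1, two_waves = 2, three_waves = 3)
  num <- sum(vapply(names(waves), function(k) g(k) * waves[[k]], numeric(1))) +
    g("extra_adjacent")
  n_primary <- g("one_wave") + g("two_waves") + g("three_waves")
  den <- if (denominator == "primary_molters") n_primary
         else n_primary + g("secondary_only")
  if (den == 0) stop("zero denominator: no molting birds tallied",
                     call. = FALSE)
  y <- num / den
  list(numerator = num, denominator = den, y = y,
       reported = round_half_up(y, 2))
}

#' Mean growing feathers per wing from records
#'
#' Snapshot-based counterpart of [mean_growing_per_wing()]: the mean number
#' of active loci of a series among records in active molt of that series
#' (optionally widening the denominator to records active in any of
#' \code{extra_series}).
#'
#' @param records a \code{wing_records} table.
#' @param series the \code{molt_series} whose growing feathers are counted.
#' @param extra_series optional list of \code{molt_series} whose molters are
#'   added to the denominator (e.g. the secondary series, for the
#'   quill-molters denominator).
#' @return list with \code{numerator}, \code{denominator}, \code{y}.
#' @export
growing_per_wing <- function(records, series, extra_series = NULL) {
  n_active <- function(loci) vapply(seq_len(nrow(records)), function(i)
    sum(is_active_score(as.numeric(records[i, loci]))), numeric(1))
  g <- n_active(series$loci)
  in_denom <- g > 0
  if (!is.null(extra_series)) {
    if (inherits(extra_series, "molt_series")) extra_series <- list(extra_series)
    for (s in extra_series) in_denom <- in_denom | n_active(s$loci) > 0
  }
  den <- sum(in_denom)
  if (den == 0) stop("no molting records for series '", series$name, "'",
                     call. = FALSE)
  list(numerator = sum(g), denominator = den, y = sum(g) / den)
}

#' Molt duration from the three-variable formula
#'
#' Time in days to replace a molt series without interruption:
#' \deqn{d = l / (r \cdot y)} with \eqn{l} the summed feather length (mm),
#' \eqn{r} the growth rate (mm/day), and \eqn{y} the mean number of feathers
#' growing simultaneously.  \code{"published"} reproduces published
#' whole-day figures by pre-rounding the inputs to their printed precision
#' (\eqn{l} to 0.1 mm, \eqn{r} to 0.01 mm/d, \eqn{y} to 0.01) and rounding
#' \eqn{d} to whole days; \code{"full_precision"} propagates the inputs
#' unrounded.
#'
#' @param l,r,y positive numbers (see above).
#' @param rounding \code{"full_precision"} (default) or \code{"published"}.
#' @return duration in days.
#' @examples
#' molt_duration(1085.3, 2.86, 1.24, "published")  # 306
#' molt_duration(1085.3, 2.86, 1.14, "published")  # 333
#' @export
molt_duration <- function(l, r, y,
                          rounding = c("full_precision", "published")) {
  rounding <- match.arg(rounding)
  if (any(c(l, r, y) <= 0))
    stop("l, r and y must all be positive", call. = FALSE)
  if (rounding == "published") {
    l <- round_half_up(l, 1)
    r <- round_half_up(r, 2)
    y <- round_half_up(y, 2)
    round_half_up(l / (r * y), 0)
  } else {
    l / (r * y)
  }
}

#' Rescale a stepwise percentage by series length
#'
#' Adjusts a stepwise-molt percentage observed in one series upward (or
#' down) in proportion to the number of feathers in a target series, for
#' comparison across series of different length.
#'
#' @param pct percentage (0-100 scale).
#' @param n_source_series,n_target_series feather counts of the two series.
#' @return rescaled percentage.
#' @examples
#' adjusted_stepwise_percent(12.8, 7, 10)  # 18.29 -> reported 18.3
#' @export
adjusted_stepwise_percent <- function(pct, n_source_series, n_target_series) {
  if (n_source_series <= 0 || n_target_series <= 0)
    stop("series lengths must be positive", call. = FALSE)
  pct * n_target_series / n_source_series
}

#' Exact Mann-Whitney rank test by enumeration
#'
#' Exact two-sample rank test for small samples: \eqn{U_1} counts pairs
#' \eqn{(x, y)} with \eqn{x > y}, counting ties 0.5.  P-values come from the
#' exact permutation distribution (all \code{choose(n1+n2, n1)} group
#' assignments), which handles ties without approximation:
#' \code{p_less}/\code{p_greater} are the one-sided tail probabilities of
#' \eqn{U_1}, and \code{p_two_sided} the probability that \eqn{\min(U_1,
#' U_2)} is at most the observed minimum.
#'
#' @param x,y numeric samples.
#' @return list with \code{U1}, \code{U2}, \code{U} (the minimum),
#'   \code{p_less}, \code{p_greater}, \code{p_one_sided} (smaller tail) and
#'   \code{p_two_sided}.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6, 7))$U  # 0
#' @export
mann_whitney_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (choose(n, n1) > 5e5)
    stop("sample too large for exact enumeration", call. = FALSE)
  u_stat <- function(a, b) {
    cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
    sum(cmp)
  }
  U1 <- u_stat(x, y)
  U2 <- n1 * n2 - U1
  pool <- c(x, y)
  combs <- utils::combn(n, n1)
  perm_U1 <- apply(combs, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  perm_min <- pmin(perm_U1, n1 * n2 - perm_U1)
  eps <- 1e-9
  p_less <- mean(perm_U1 <= U1 + eps)
  p_greater <- mean(perm_U1 >= U1 - eps)
  list(U1 = U1, U2 = U2, U = min(U1, U2),
       p_less = p_less, p_greater = p_greater,
       p_one_sided = min(p_less, p_greater),
       p_two_sided = mean(perm_min <= min(U1, U2) + eps))
}

#' Monthly molt-breeding overlap summary
#'
#' Per-month fraction of records in active primary molt, aligned with nest
#' counts, plus an exact rank test comparing the molting fractions between
#' two user-declared month groups.
#'
#' @param records a \code{wing_records} table with months.
#' @param nest_counts named numeric vector or data.frame (\code{month},
#'   \code{nests}) of breeding records per month; optional.
#' @param group1,group2 month vectors (1-12) to compare; both must be
#'   non-empty and have monthly fractions available.
#' @return list with \code{monthly} (data.frame \code{month}, \code{n},
#'   \code{n_molting}, \code{fraction}, \code{nests}) and \code{test} (see
#'   [mann_whitney_exact()]).
#' @export
monthly_overlap <- function(records, nest_counts = NULL,
                            group1 = NULL, group2 = NULL) {
  pcols <- paste0("P", 1:10)
  has_month <- !is.na(records$month)
  if (!any(has_month)) stop("no records carry a month", call. = FALSE)
  molting <- vapply(seq_len(nrow(records)), function(i)
    any(is_active_score(as.numeric(records[i, pcols]))), logical(1))
  monthly <- data.frame(month = 1:12)
  monthly$n <- vapply(1:12, function(m) sum(has_month & records$month == m),
                      integer(1))
  monthly$n_molting <- vapply(1:12, function(m)
    sum(has_month & records$month == m & molting), integer(1))
  monthly$fraction <- ifelse(monthly$n > 0, monthly$n_molting / monthly$n, NA)
  monthly$nests <- 0
  if (!is.null(nest_counts)) {
    if (is.data.frame(nest_counts)) {
      monthly$nests[match(nest_counts$month, monthly$month)] <-
        nest_counts$nests
    } else {
      monthly$nests[as.integer(names(nest_counts))] <- as.numeric(nest_counts)
    }
  }
  test <- NULL
  if (!is.null(group1) && !is.null(group2)) {
    if (length(group1) == 0L || length(group2) == 0L)
      stop("month groups must be non-empty", call. = FALSE)
    f1 <- monthly$fraction[monthly$month %in% group1]
    f2 <- monthly$fraction[monthly$month %in% group2]
    if (anyNA(f1) || anyNA(f2))
      stop("a compared month has no records", call. = FALSE)
    test <- mann_whitney_exact(f1, f2)
  }
  list(monthly = monthly, test = test)
}

#' Headline duration report from measurement tables
#'
#' Convenience wrapper combining the primary-length matrix, growth-band
#' rates, and wave tallies into the duration estimates under both rounding
#' modes, plus stepwise percentages when stepwise tallies are given.
#'
#' @param lengths data.frame for [summed_primary_length()].
#' @param bands input for [growth_rate()].
#' @param tallies input for [mean_growing_per_wing()].
#' @param stepwise optional data.frame with columns \code{series},
#'   \code{n_molting}, \code{n_stepwise}, and \code{n_feathers}; percentages
#'   are rescaled to the first row's series length.
#' @return list with \code{l}, \code{r}, \code{y_primary}, \code{y_quill},
#'   \code{d} (data.frame of durations by denominator and rounding mode) and
#'   \code{stepwise} (if given).
#' @export
duration_report <- function(lengths, bands, tallies, stepwise = NULL) {
  l <- summed_primary_length(lengths)
  r <- growth_rate(bands)
  y1 <- mean_growing_per_wing(tallies, "primary_molters")
  y2 <- mean_growing_per_wing(tallies, "quill_molters")
  d <- expand.grid(denominator = c("primary_molters", "quill_molters"),
                   rounding = c("published", "full_precision"),
                   stringsAsFactors = FALSE)
  d$days <- mapply(function(den, mode) {
    y <- if (den == "primary_molters") y1 else y2
    molt_duration(l$mean, r$mean, y$y, mode)
  }, d$denominator, d$rounding)
  out <- list(l = l, r = r, y_primary = y1, y_quill = y2, d = d)
  if (!is.null(stepwise)) {
    sw <- stepwise
    sw$percent <- mapply(stepwise_percent, sw$n_stepwise, sw$n_molting)
    ref_n <- sw$n_feathers[1]
    sw$adjusted_percent <- round_half_up(
      mapply(adjusted_stepwise_percent, sw$percent, sw$n_feathers, ref_n), 1)
    out$stepwise <- sw
  }
  out
}
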
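# Stochastic molt simulator. Continuous-time replacement of flight feathers
# within declared series: each wave grows one feather at a time in series
# order with a pause between feathers; arrests (breeding-demand
# interruptions) freeze all new drops while growing feathers complete; when
# molt resumes, every interrupted wave continues at its next feather AND a
# new wave initiates at the series seed — the ontogenetic mechanism that
# generates stepwise molt. Cross-sectional snapshots discretize feather
# states into the standard score codes.

#' Default feather lengths for the simulator
#'
#' Primary lengths are the per-locus means of the bundled adult length
#' measurements; secondary lengths are a nominal 50 mm (the study species'
#' secondaries are short and subequal; no published measurements exist).
#'
#' @return named numeric vector of lengths (mm) for P1..P10 and S1..S11.
#' @export
default_feather_lengths <- function() {
  path <- system.file("extdata", "hemiprocne_primary_lengths.csv",
                      package = "moltwave")
  lens <- colMeans(utils::read.csv(path)[, paste0("P", 1:10)])
  c(lens, stats::setNames(rep(50, 11), paste0("S", 1:11)))
}

#' Simulator parameters
#'
#' @param series list of \code{molt_series} to simulate (default: the wing
#'   series of [default_series_config()]).
#' @param feather_lengths named numeric vector of full feather lengths (mm)
#'   covering every simulated locus.
#' @param growth_rate feather elongation rate, mm/day.
#' @param pause_days delay between completing one feather of a wave and
#'   dropping the next.
#' @param arrest_hazard per-day probability (hazard) of a molt arrest while
#'   molt is not already arrested.
#' @param arrest_duration_mean mean of the exponential arrest duration, days.
#' @param misclassification_prob probability that a fully grown feather's
#'   new/old age is recorded flipped in a snapshot.
#' @param max_waves cap on simultaneously live waves per series (3 is the
#'   observed maximum in the study species).
#' @param triggers named list: for a series name, \code{list(series =,
#'   locus =)} delays its first seeding until the named series first drops
#'   the given locus.  Default: both secondary series seed when the primary
#'   wave reaches P6, matching the observed delay of secondary molt.
#' @param seed integer RNG seed used by [simulate_dataset()].
#' @return object of class \code{simulation_params}.
#' @export
simulation_params <- function(series = NULL, feather_lengths = NULL,
                              growth_rate = 2.86, pause_days = 5,
                              arrest_hazard = 0.004,
                              arrest_duration_mean = 60,
                              misclassification_prob = 0,
                              max_waves = 3, triggers = NULL, seed = NULL) {
  if (is.null(series)) {
    cfg <- default_series_config()
    series <- cfg$series[c("primaries", "outer_secondaries",
                           "inner_secondaries")]
  }
  if (inherits(series, "molt_series")) series <- list(series)
  names(series) <- vapply(series, `[[`, character(1), "name")
  if (is.null(feather_lengths)) feather_lengths <- default_feather_lengths()
  loci <- unlist(lapply(series, `[[`, "loci"))
  missing_len <- setdiff(loci, names(feather_lengths))
  if (length(missing_len))
    stop("no feather length for: ", paste(missing_len, collapse = ", "),
         call. = FALSE)
  if (any(feather_lengths[loci] <= 0) || growth_rate <= 0)
    stop("feather lengths and growth rate must be positive", call. = FALSE)
  if (pause_days < 0 || arrest_hazard < 0 || arrest_duration_mean <= 0)
    stop("pause, hazard and arrest duration must be non-negative",
         call. = FALSE)
  if (misclassification_prob < 0 || misclassification_prob > 1)
    stop("misclassification_prob must be in [0, 1]", call. = FALSE)
  if (is.null(triggers)) {
    triggers <- list()
    for (nm in c("outer_secondaries", "inner_secondaries"))
      if (nm %in% names(series) && "primaries" %in% names(series))
        triggers[[nm]] <- list(series = "primaries", locus = "P6")
  }
  for (nm in names(triggers)) {
    tr <- triggers[[nm]]
    if (!tr$series %in% names(series) || !is.null(triggers[[tr$series]]))
      stop("trigger for '", nm, "' must reference an untriggered simulated ",
           "series", call. = FALSE)
  }
  structure(list(series = series, feather_lengths = feather_lengths,
                 growth_rate = growth_rate, pause_days = pause_days,
                 arrest_hazard = arrest_hazard,
                 arrest_duration_mean = arrest_duration_mean,
                 misclassification_prob = misclassification_prob,
                 max_waves = max_waves, triggers = triggers, seed = seed),
            class = "simulation_params")
}

# arrest schedule on [0, duration]: onset waiting times are exponential with
# the given hazard (clock paused during arrests), durations exponential
draw_arrests <- function(hazard, dur_mean, duration) {
  onset <- numeric(0); end <- numeric(0)
  if (hazard > 0) {
    t <- 0
    repeat {
      t_on <- t + stats::rexp(1, rate = hazard)
      if (t_on >= duration) break
      t_off <- t_on + stats::rexp(1, rate = 1 / dur_mean)
      onset <- c(onset, t_on); end <- c(end, t_off)
      t <- t_off
    }
  }
  data.frame(onset = onset, end = end)
}

# push a time out of any arrest interval it falls in
defer_if_arrested <- function(t, arrests) {
  if (nrow(arrests) == 0L) return(t)
  hit <- which(arrests$onset <= t & t < arrests$end)
  if (length(hit)) arrests$end[hit[1L]] else t
}

# simulate one series given the global arrest schedule; returns feather
# replacement rows and realized seed-initiation events
sim_series <- function(sdef, start_time, arrests, params, duration) {
  loci <- sdef$loci
  nl <- length(loci)
  lens <- params$feather_lengths[loci]
  rate <- params$growth_rate
  if (!is.finite(start_time) || start_time >= duration)
    return(list(feathers = data.frame(series = character(0),
                                      locus = character(0), drop = numeric(0),
                                      completion = numeric(0),
                                      episode = integer(0)),
                seeds = data.frame(time = numeric(0), episode = integer(0))))
  seeds_pending <- defer_if_arrested(start_time, arrests)
  if (nrow(arrests))
    seeds_pending <- c(seeds_pending,
                       arrests$end[arrests$end > start_time &
                                   arrests$end < duration])
  seeds_pending <- sort(unique(seeds_pending))
  seed_ptr <- 1L
  episode <- 0L
  waves <- list()  # each: list(next_i, ready, start, episode)
  last_drop <- rep(-Inf, nl)
  growing_until <- rep(-Inf, nl)
  f_series <- character(0); f_locus <- character(0)
  f_drop <- numeric(0); f_comp <- numeric(0); f_epi <- integer(0)
  s_time <- numeric(0); s_epi <- integer(0)
  eps <- 1e-9

  repeat {
    wave_ready <- if (length(waves))
      min(vapply(waves, `[[`, numeric(1), "ready")) else Inf
    seed_t <- if (seed_ptr <= length(seeds_pending))
      seeds_pending[seed_ptr] else Inf
    t <- min(wave_ready, seed_t)
    if (t >= duration) break
    if (seed_t <= wave_ready) {          # seed initiations first on ties
      seed_ptr <- seed_ptr + 1L
      if (length(waves) < params$max_waves) {
        episode <- episode + 1L
        waves[[length(waves) + 1L]] <- list(next_i = 1L, ready = seed_t,
                                            start = seed_t, episode = episode)
        s_time <- c(s_time, seed_t); s_epi <- c(s_epi, episode)
      }
      next
    }
    wi <- which.min(vapply(waves, `[[`, numeric(1), "ready"))
    w <- waves[[wi]]
    if (w$next_i > nl) {                 # final feather completed: retire
      waves[[wi]] <- NULL
      next
    }
    t2 <- defer_if_arrested(w$ready, arrests)
    if (t2 > w$ready + eps) {            # frozen: no drops during an arrest
      waves[[wi]]$ready <- t2
      next
    }
    i <- w$next_i
    if (last_drop[i] >= w$start - eps || growing_until[i] > t + eps) {
      waves[[wi]] <- NULL                # caught the wave ahead: merge
      next
    }
    last_drop[i] <- t
    comp <- t + lens[i] / rate
    growing_until[i] <- comp
    f_series <- c(f_series, sdef$name); f_locus <- c(f_locus, loci[i])
    f_drop <- c(f_drop, t); f_comp <- c(f_comp, comp)
    f_epi <- c(f_epi, w$episode)
    waves[[wi]]$next_i <- i + 1L
    # a wave stays live (and counts against the cap) until its final feather
    # completes; otherwise it pauses before the next drop
    waves[[wi]]$ready <- if (i == nl) comp else comp + params$pause_days
  }
  list(feathers = data.frame(series = f_series, locus = f_locus,
                             drop = f_drop, completion = f_comp,
                             episode = f_epi, stringsAsFactors = FALSE),
       seeds = data.frame(time = s_time, episode = s_epi))
}

#' Simulate one bird's feather replacement history
#'
#' Draws a global arrest schedule and advances each configured series'
#' waves through time (see the package vignette for the full event rules).
#' Uses the ambient RNG state; [simulate_dataset()] manages seeding.
#'
#' @param params a \code{simulation_params}.
#' @param duration_days simulated horizon.
#' @return object of class \code{molt_history}: \code{feathers} (data.frame
#'   \code{series}, \code{locus}, \code{drop}, \code{completion},
#'   \code{episode}), \code{seeds} (per-series seed initiation events),
#'   \code{arrests}, \code{duration}, and the \code{params} used.
#' @export
simulate_bird <- function(params, duration_days = 1095) {
  stopifnot(inherits(params, "simulation_params"))
  arrests <- draw_arrests(params$arrest_hazard, params$arrest_duration_mean,
                          duration_days)
  results <- list()
  ord <- c(setdiff(names(params$series), names(params$triggers)),
           names(params$triggers))
  for (nm in ord) {
    tr <- params$triggers[[nm]]
    start <- if (is.null(tr)) 0 else {
      fx <- results[[tr$series]]$feathers
      hit <- fx$drop[fx$locus == tr$locus]
      if (length(hit)) min(hit) else Inf
    }
    results[[nm]] <- sim_series(params$series[[nm]], start, arrests, params,
                                duration_days)
  }
  feathers <- do.call(rbind, lapply(results, `[[`, "feathers"))
  rownames(feathers) <- NULL
  seeds <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$seeds
    if (nrow(s)) cbind(series = nm, s) else NULL
  }))
  if (is.null(seeds))
    seeds <- data.frame(series = character(0), time = numeric(0),
                        episode = integer(0))
  structure(list(feathers = feathers, seeds = seeds, arrests = arrests,
                 duration = duration_days, params = params),
            class = "molt_history")
}

#' @export
print.molt_history <- function(x, ...) {
  cat(sprintf("molt history: %d feather replacements, %d seed initiations, %d arrests over %g days\n",
              nrow(x$feathers), nrow(x$seeds), nrow(x$arrests), x$duration))
  invisible(x)
}

#' Cross-sectional snapshot of a simulated bird
#'
#' Discretizes the feather states at day \code{t} into score codes: a
#' growing feather scores its length fraction rounded to the nearest tenth
#' and clipped to \[0.1, 0.9\], or 0.05 (missing) below fraction 0.05; a fully
#' grown feather scores 1 (new) if it completed during the current molt
#' episode of its series (since the most recent seed initiation), else 2
#' (old).  New/old ages are flipped independently with the configured
#' misclassification probability.
#'
#' @param history a \code{molt_history}.
#' @param t snapshot day.
#' @param specimen_id id for the emitted record.
#' @return a one-row \code{wing_records} table (loci outside the simulated
#'   series are unscored).
#' @export
snapshot_record <- function(history, t, specimen_id = "sim1") {
  params <- history$params
  fx <- history$feathers
  scores <- numeric(0)
  for (nm in names(params$series)) {
    sdef <- params$series[[nm]]
    sd_seeds <- history$seeds[history$seeds$series == nm, ]
    cur_seed <- if (nrow(sd_seeds) && any(sd_seeds$time <= t))
      max(sd_seeds$time[sd_seeds$time <= t]) else Inf
    for (loc in sdef$loci) {
      rows <- fx[fx$locus == loc & fx$series == nm, ]
      growing <- rows[rows$drop <= t & t < rows$completion, ]
      if (nrow(growing)) {
        g <- growing[1L, ]
        f <- params$growth_rate * (t - g$drop) / params$feather_lengths[[loc]]
        code <- if (f < 0.05) 0.05
                else min(0.9, max(0.1, round_half_up(f, 1)))
      } else {
        done <- rows[rows$completion <= t, ]
        code <- if (nrow(done) && max(done$completion) >= cur_seed) 1 else 2
        if (params$misclassification_prob > 0 &&
            stats::runif(1) < params$misclassification_prob)
          code <- 3 - code               # flip new <-> old
      }
      scores[loc] <- code
    }
  }
  month <- (floor(t / 30.4375) %% 12) + 1
  scores_to_record(scores, specimen_id = specimen_id, age_class = "adult",
                   month = month)
}

#' Simulate a cross-sectional specimen dataset
#'
#' Simulates \code{n_birds} independent birds and takes one snapshot per
#' bird at a uniform random time in the sampling window, emulating a museum
#' collection.  Fully reproducible from \code{params$seed}.
#'
#' @param params a \code{simulation_params}.
#' @param n_birds number of birds.
#' @param window numeric length-2 sampling window in days.
#' @return object of class \code{molt_simulation}: \code{records} (a
#'   \code{wing_records} table), \code{histories}, \code{times},
#'   \code{params}, \code{window}.
#' @export
simulate_dataset <- function(params, n_birds, window = c(0, 1095)) {
  stopifnot(inherits(params, "simulation_params"), n_birds >= 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  histories <- vector("list", n_birds)
  times <- numeric(n_birds)
  recs <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    times[b] <- stats::runif(1, window[1], window[2])
    histories[[b]] <- simulate_bird(params, duration_days = max(window))
    recs[[b]] <- snapshot_record(histories[[b]], times[b],
                                 specimen_id = sprintf("sim%04d", b))
  }
  records <- if (n_birds) {
    df <- do.call(rbind, lapply(recs, as.data.frame))
    as_wing_records(df)
  } else {
    as_wing_records(data.frame(specimen_id = character(0),
                               age_class = character(0)))
  }
  structure(list(records = records, histories = histories, times = times,
                 params = params, window = window),
            class = "molt_simulation")
}

#' @export
print.molt_simulation <- function(x, ...) {
  cat(sprintf("molt simulation: %d birds sampled in [%g, %g] days\n",
              length(x$histories), x$window[1], x$window[2]))
  invisible(x)
}

#' Growing-feather count over time for one series
#'
#' @param history a \code{molt_history}.
#' @param series_name name of a simulated series.
#' @param times numeric vector of evaluation days.
#' @return integer vector of simultaneously growing feathers.
#' @export
growing_profile <- function(history, series_name, times) {
  fx <- history$feathers[history$feathers$series == series_name, ]
  vapply(times, function(t) sum(fx$drop <= t & t < fx$completion), numeric(1))
}

#' Time-averaged growing count realized in a simulation
#'
#' Average number of simultaneously growing feathers of a series over the
#' sampling window, conditional on at least one growing (the quantity the
#' snapshot estimator [growing_per_wing()] targets), pooled over birds.
#'
#' @param sim a \code{molt_simulation}.
#' @param series_name simulated series name.
#' @param step evaluation grid spacing, days.
#' @return list with \code{y_bar} (conditional mean), \code{p_molting}
#'   (fraction of bird-days with the series active).
#' @export
realized_mean_growing <- function(sim, series_name, step = 2) {
  grid <- seq(sim$window[1], sim$window[2], by = step)
  tot <- 0; act <- 0; n <- 0
  for (h in sim$histories) {
    g <- growing_profile(h, series_name, grid)
    tot <- tot + sum(g)
    act <- act + sum(g > 0)
    n <- n + length(g)
  }
  if (act == 0) stop("series never active over the window", call. = FALSE)
  list(y_bar = tot / act, p_molting = act / n)
}

#' Uninterrupted completion time realized in a simulation
#'
#' The time one uninterrupted molt of the series would take at the feather
#' concurrency actually realized in the simulation:
#' \eqn{\sum l / (r \cdot \bar y)} with \eqn{\bar y} the history-derived
#' time-average of the growing count conditional on molt being active
#' ([realized_mean_growing()]).
#'
#' @inheritParams realized_mean_growing
#' @return days.
#' @export
realized_completion_time <- function(sim, series_name, step = 2) {
  sdef <- sim$params$series[[series_name]]
  l <- sum(sim$params$feather_lengths[sdef$loci])
  yb <- realized_mean_growing(sim, series_name, step)$y_bar
  l / (sim$params$growth_rate * yb)
}
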
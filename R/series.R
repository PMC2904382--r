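# Molt series: contiguous sets of feathers replaced successively and in one
# direction. The final model for Hemiprocne mystacea has the ten primaries as
# one series (replaced distally), the outer secondaries S1-S7 (proximally),
# the inner secondaries S11-S8 (distally), the inner rectrices R4-R1
# (proximally), and R5 as a series of its own.

#' Define a molt series
#'
#' A molt series is an ordered, chain-contiguous run of feather loci, listed
#' from the seed (the first feather replaced) to the terminal feather (the
#' last).  The replacement direction is implied by the chain ranks: ascending
#' ranks mean distal replacement, descending proximal.
#'
#' @param name series name.
#' @param loci character vector of locus labels, seed first.
#' @return An object of class \code{molt_series} with fields \code{name},
#'   \code{loci}, \code{chain}, and \code{direction} (\code{"distal"},
#'   \code{"proximal"}, or \code{NA} for a single-feather series).
#' @examples
#' molt_series("primaries", paste0("P", 1:10))
#' molt_series("outer_rectrix", "R5")
#' @export
molt_series <- function(name, loci) {
  check_locus(loci)
  chains <- unique(locus_chain(loci))
  if (length(chains) != 1L)
    stop("series '", name, "' mixes wing and tail loci", call. = FALSE)
  r <- chain_rank(loci)
  if (anyDuplicated(r))
    stop("series '", name, "' repeats a locus", call. = FALSE)
  if (length(r) > 1L) {
    d <- diff(r)
    if (!(all(d == 1L) || all(d == -1L)))
      stop("series '", name, "' is not contiguous and strictly monotone ",
           "along the chain", call. = FALSE)
  }
  direction <- if (length(r) == 1L) NA_character_
               else if (r[2] > r[1]) "distal" else "proximal"
  structure(list(name = name, loci = loci, chain = chains,
                 direction = direction),
            class = "molt_series")
}

series_seed <- function(s) s$loci[1L]
series_terminal <- function(s) s$loci[length(s$loci)]

#' @export
print.molt_series <- function(x, ...) {
  cat(sprintf("molt series '%s' (%s chain, %s): %s\n", x$name, x$chain,
              if (is.na(x$direction)) "single feather" else x$direction,
              paste(x$loci, collapse = " -> ")))
  invisible(x)
}

#' Assemble a series configuration
#'
#' Bundles molt series into a configuration and checks that no two series
#' share a locus.  Series may live on either chain; operations select the
#' series relevant to the chain they work on.
#'
#' @param ... \code{molt_series} objects (or a single list of them).
#' @return object of class \code{series_config}.
#' @seealso [default_series_config()]
#' @export
series_config <- function(...) {
  series <- list(...)
  if (length(series) == 1L && !inherits(series[[1L]], "molt_series"))
    series <- series[[1L]]
  if (!all(vapply(series, inherits, logical(1), "molt_series")))
    stop("all arguments must be molt_series objects", call. = FALSE)
  all_loci <- unlist(lapply(series, `[[`, "loci"))
  if (anyDuplicated(all_loci))
    stop("series overlap at loci: ",
         paste(unique(all_loci[duplicated(all_loci)]), collapse = ", "),
         call. = FALSE)
  names(series) <- vapply(series, `[[`, character(1), "name")
  structure(list(series = series), class = "series_config")
}

#' The final series model for Hemiprocne mystacea
#'
#' Primaries P1-P10 replaced distally as a single series; outer secondaries
#' S1-S7 replaced proximally; inner secondaries S11-S8 replaced distally;
#' inner rectrices R4-R1 replaced proximally; the outermost rectrix R5 as its
#' own series.
#'
#' @return a \code{series_config}.
#' @export
default_series_config <- function() {
  series_config(
    molt_series("primaries", paste0("P", 1:10)),
    molt_series("outer_secondaries", paste0("S", 1:7)),
    molt_series("inner_secondaries", paste0("S", 11:8)),
    molt_series("inner_rectrices", paste0("R", 4:1)),
    molt_series("outer_rectrix", "R5")
  )
}

#' @export
print.series_config <- function(x, ...) {
  cat("series configuration:\n")
  for (s in x$series) {
    cat("  "); print(s)
  }
  invisible(x)
}

# named vector: series name for every locus of `chain` (NA if unassigned)
locus_series_map <- function(config, chain) {
  ch <- chain_loci(chain)
  out <- stats::setNames(rep(NA_character_, length(ch)), ch)
  for (s in config$series)
    if (s$chain == chain) out[s$loci] <- s$name
  out
}

# pair indices (rank of proximal member) whose two loci belong to different
# declared series
boundary_pairs <- function(config, chain) {
  m <- locus_series_map(config, chain)
  n <- length(m)
  i <- seq_len(n - 1L)
  cross <- !is.na(m[i]) & !is.na(m[i + 1L]) & m[i] != m[i + 1L]
  i[cross]
}
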
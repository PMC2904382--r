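# Molt summary tables: per-locus nodal/terminal/growing counts and per-pair
# direction counts, in raw form and in the iterated form in which direction
# scores that cross a series boundary are reassigned to nodal/terminal
# counts, leaving columns of zeros between series.

new_molt_summary <- function(chain, locus_counts, pair_counts, variant,
                             n_records) {
  structure(list(chain = chain, loci = chain_loci(chain),
                 locus_counts = locus_counts, pair_counts = pair_counts,
                 variant = variant, n_records = n_records),
            class = "molt_summary")
}

empty_molt_summary <- function(chain, variant = "raw", n_records = 0L) {
  ch <- chain_loci(chain)
  n <- length(ch)
  new_molt_summary(
    chain,
    data.frame(locus = ch, nodal = 0, terminal = 0, n_growing = 0,
               stringsAsFactors = FALSE),
    data.frame(pair_index = seq_len(n - 1L),
               pair = pair_label(chain, seq_len(n - 1L)),
               distal = 0, proximal = 0, ambiguous = 0,
               stringsAsFactors = FALSE),
    variant, n_records)
}

#' Raw molt summary table
#'
#' Accumulates per-record annotations ([annotate_record()]) into counts: for
#' every locus the number of records in which it was nodal, terminal, or
#' active (growing/missing), and for every adjacent pair the number of
#' distal, proximal and ambiguous direction scores.
#'
#' @param records a \code{wing_records} table.
#' @param chain \code{"wing"} or \code{"tail"}.
#' @return object of class \code{molt_summary} (variant \code{"raw"}).
#' @export
raw_summary <- function(records, chain = "wing") {
  out <- empty_molt_summary(chain, "raw", nrow(records))
  if (nrow(records) == 0L) return(out)
  ch <- out$loci
  for (i in seq_len(nrow(records))) {
    s <- record_scores(records, i, chain)
    ann <- annotate_record(s, chain)
    out$locus_counts$n_growing <- out$locus_counts$n_growing +
      as.numeric(is_active_score(s[ch]))
    out$locus_counts$nodal <- out$locus_counts$nodal +
      as.numeric(ch %in% ann$nodal)
    out$locus_counts$terminal <- out$locus_counts$terminal +
      as.numeric(ch %in% ann$terminal)
    if (nrow(ann$pairs))
      for (k in seq_len(nrow(ann$pairs))) {
        j <- ann$pairs$pair_index[k]
        d <- ann$pairs$direction[k]
        out$pair_counts[j, d] <- out$pair_counts[j, d] + 1
      }
  }
  out
}

# total classification mass: nodal + terminal + all direction scores.
# Iteration conserves this quantity exactly (splits are half-integers, which
# doubles represent exactly).
summary_mass <- function(x) {
  sum(x$locus_counts$nodal) + sum(x$locus_counts$terminal) +
    sum(x$pair_counts$distal) + sum(x$pair_counts$proximal) +
    sum(x$pair_counts$ambiguous)
}

# reassignment of one cross-boundary direction score (or half-score) to the
# growing member: an old neighbor makes it nodal; a new (or growing) neighbor
# makes the terminal feather of its series terminal, and the seed of its
# series nodal when its within-series neighbor is old/unscored, terminal when
# new or growing.  Generalizes the published wrist (P1/S1), S7/S8, and
# rectrix R4/R5 rules.
reassign_cross_score <- function(tab, records, rec_i, chain, member,
                                 neighbor_new, config, smap, weight) {
  sname <- smap[[member]]
  if (is.na(sname)) {
    warning("cross-boundary score at ", member,
            " not in any declared series; left in place", call. = FALSE)
    return(list(tab = tab, moved = FALSE))
  }
  sdef <- config$series[[sname]]
  row <- match(member, tab$locus_counts$locus)
  if (!neighbor_new) {
    tab$locus_counts$nodal[row] <- tab$locus_counts$nodal[row] + weight
  } else if (member == series_terminal(sdef)) {
    tab$locus_counts$terminal[row] <- tab$locus_counts$terminal[row] + weight
  } else if (member == series_seed(sdef)) {
    nxt <- sdef$loci[2L]
    nxt_score <- records[[nxt]][rec_i]
    if (is_new_score(nxt_score) || is_active_score(nxt_score)) {
      tab$locus_counts$terminal[row] <- tab$locus_counts$terminal[row] + weight
    } else {
      tab$locus_counts$nodal[row] <- tab$locus_counts$nodal[row] + weight
    }
  } else {
    warning("cross-boundary score at ", member, " which is neither seed nor ",
            "terminal of series '", sname, "'; treated as nodal", call. = FALSE)
    tab$locus_counts$nodal[row] <- tab$locus_counts$nodal[row] + weight
  }
  list(tab = tab, moved = TRUE)
}

#' Iterated molt summary table
#'
#' Re-derives every direction score that spans a boundary between declared
#' molt series from the record list, removes it from the pair counts and
#' reassigns it to the nodal or terminal count of the growing member (see
#' Details).  Within-series pair counts are unchanged; after iteration every
#' cross-boundary pair column is exactly zero, and the total mass
#' (nodal + terminal + direction scores) is conserved.  Ambiguous
#' cross-boundary scores (both members growing, equal length) are split 0.5
#' to each member; a pair with both members growing but unequal is split the
#' same way, since each member fronts a wave of its own series.
#'
#' @details Reassignment rules for the growing member of a cross-boundary
#'   pair: (i) neighbor old — nodal; (ii) neighbor new and the member is the
#'   terminal feather of its series — terminal; (iii) neighbor new and the
#'   member is the seed of its series — nodal when its within-series neighbor
#'   is old or unscored (a freshly initiated series), terminal when that
#'   neighbor is new or growing.  A growing cross-boundary neighbor counts as
#'   new for this decision.
#'
#' @param raw a raw \code{molt_summary}.
#' @param records the \code{wing_records} table the raw summary was built
#'   from (reassignment depends on per-record feather states).
#' @param config a \code{series_config} whose series lie on the summary's
#'   chain.
#' @return a \code{molt_summary} with variant \code{"iterated"}.  Iterating a
#'   table whose cross-boundary columns are already zero returns it
#'   unchanged.
#' @export
iterate_summary <- function(raw, records, config) {
  stopifnot(inherits(raw, "molt_summary"), inherits(config, "series_config"))
  chain <- raw$chain
  smap <- locus_series_map(config, chain)
  covered <- names(smap)[!is.na(smap)]
  if (length(covered) == 0L)
    stop("series configuration has no series on the ", chain, " chain",
         call. = FALSE)
  bp <- boundary_pairs(config, chain)
  out <- raw
  out$variant <- "iterated"
  if (length(bp) == 0L) return(out)

  cross_mass <- sum(out$pair_counts[bp, c("distal", "proximal", "ambiguous")])
  if (cross_mass == 0) return(out)  # already iterated: identity

  ch <- raw$loci
  for (i in seq_len(nrow(records))) {
    s <- record_scores(records, i, chain)
    ann <- suppressWarnings(annotate_record(s, chain))
    if (!nrow(ann$pairs)) next
    for (k in which(ann$pairs$pair_index %in% bp)) {
      j <- ann$pairs$pair_index[k]
      d <- ann$pairs$direction[k]
      a <- ch[j]; b <- ch[j + 1L]              # proximal, distal member
      act_a <- is_active_score(s[[a]]); act_b <- is_active_score(s[[b]])
      if (act_a && act_b) {
        res <- reassign_cross_score(out, records, i, chain, a,
                                    neighbor_new = TRUE, config, smap, 0.5)
        if (!res$moved) next
        out <- res$tab
        res <- reassign_cross_score(out, records, i, chain, b,
                                    neighbor_new = TRUE, config, smap, 0.5)
        out <- res$tab
      } else {
        member <- if (act_a) a else b
        other <- if (act_a) b else a
        res <- reassign_cross_score(out, records, i, chain, member,
                                    neighbor_new = is_new_score(s[[other]]),
                                    config, smap, 1)
        if (!res$moved) next
        out <- res$tab
      }
      out$pair_counts[j, d] <- out$pair_counts[j, d] - 1
    }
  }
  if (any(out$pair_counts[bp, c("distal", "proximal", "ambiguous")] != 0))
    warning("cross-boundary pair counts not fully cleared; raw summary and ",
            "record list disagree", call. = FALSE)
  out
}

#' @export
print.molt_summary <- function(x, ...) {
  cat(sprintf("molt summary (%s chain, %s, %d records)\n", x$chain,
              x$variant, x$n_records))
  print(render_table(x), ...)
  invisible(x)
}

#' Render a molt summary in the published table layout
#'
#' Lays the summary out with one column per locus and the pair columns
#' between them, rows nodal / distal / proximal / ambiguous / terminal /
#' n_growing.  Within each declared series segment the direction (distal or
#' proximal) whose pooled count exceeds the other is flagged as predominant
#' (rendered with a trailing \code{*}); ties are not flagged.
#'
#' @param table a \code{molt_summary}.
#' @param config optional \code{series_config} defining the segments used for
#'   the emphasis rule; with \code{NULL} the whole chain is one segment.
#' @return object of class \code{molt_summary_render}: a character matrix
#'   plus an \code{emphasis} data.frame (\code{pair}, \code{direction}).
#' @export
render_table <- function(table, config = NULL) {
  ch <- table$loci
  n <- length(ch)
  npair <- n - 1L
  # segments of pair indices over which direction counts are pooled
  if (is.null(config)) {
    segments <- list(seq_len(npair))
  } else {
    smap <- locus_series_map(config, table$chain)
    segments <- lapply(unique(stats::na.omit(smap)), function(sn) {
      loci_in <- names(smap)[!is.na(smap) & smap == sn]
      r <- sort(chain_rank(loci_in))
      r[-length(r)]  # pairs fully inside the series
    })
    segments <- Filter(length, segments)
  }
  emph <- data.frame(pair = character(0), direction = character(0),
                     stringsAsFactors = FALSE)
  flag <- matrix(FALSE, nrow = npair, ncol = 2,
                 dimnames = list(NULL, c("distal", "proximal")))
  for (seg in segments) {
    d <- sum(table$pair_counts$distal[seg])
    p <- sum(table$pair_counts$proximal[seg])
    if (d > p) flag[seg, "distal"] <- TRUE
    if (p > d) flag[seg, "proximal"] <- TRUE
  }
  for (j in seq_len(npair)) for (dir in c("distal", "proximal"))
    if (flag[j, dir])
      emph <- rbind(emph, data.frame(pair = table$pair_counts$pair[j],
                                     direction = dir, stringsAsFactors = FALSE))

  fmt <- function(v) ifelse(v == round(v), format(v, trim = TRUE),
                            sprintf("%.1f", v))
  width <- 2L * n - 1L
  m <- matrix("", nrow = 6L, ncol = width,
              dimnames = list(c("nodal", "distal", "proximal", "ambiguous",
                                "terminal", "n_growing"), NULL))
  loc_col <- 2L * seq_len(n) - 1L
  pair_col <- 2L * seq_len(npair)
  m["nodal", loc_col] <- fmt(table$locus_counts$nodal)
  m["terminal", loc_col] <- fmt(table$locus_counts$terminal)
  m["n_growing", loc_col] <- fmt(table$locus_counts$n_growing)
  m["ambiguous", pair_col] <- fmt(table$pair_counts$ambiguous)
  m["distal", pair_col] <- paste0(fmt(table$pair_counts$distal),
                                  ifelse(flag[, "distal"], "*", ""))
  m["proximal", pair_col] <- paste0(fmt(table$pair_counts$proximal),
                                    ifelse(flag[, "proximal"], "*", ""))
  header <- character(width)
  header[loc_col] <- ch
  structure(list(matrix = m, header = header, emphasis = emph,
                 chain = table$chain, variant = table$variant),
            class = "molt_summary_render")
}

#' @export
print.molt_summary_render <- function(x, ...) {
  tab <- rbind(x$header, x$matrix)
  w <- apply(nchar(tab), 2, max)
  for (r in seq_len(nrow(tab))) {
    lab <- c("", rownames(x$matrix))[r]
    cells <- mapply(formatC, tab[r, ], width = w)
    cat(formatC(lab, width = 10, flag = "-"), paste(cells, collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write / read a molt summary as CSV
#'
#' Long machine-readable layout with columns \code{variant}, \code{chain},
#' \code{measure} (\code{nodal}, \code{terminal}, \code{n_growing},
#' \code{distal}, \code{proximal}, \code{ambiguous}), \code{position} (locus
#' or pair label) and \code{count}.
#'
#' @param table a \code{molt_summary}.
#' @param path CSV file path.
#' @return \code{read_molt_summary} returns a \code{molt_summary}.
#' @export
write_molt_summary <- function(table, path) {
  lc <- table$locus_counts
  pc <- table$pair_counts
  long <- rbind(
    data.frame(measure = "nodal", position = lc$locus, count = lc$nodal),
    data.frame(measure = "terminal", position = lc$locus, count = lc$terminal),
    data.frame(measure = "n_growing", position = lc$locus,
               count = lc$n_growing),
    data.frame(measure = "distal", position = pc$pair, count = pc$distal),
    data.frame(measure = "proximal", position = pc$pair, count = pc$proximal),
    data.frame(measure = "ambiguous", position = pc$pair, count = pc$ambiguous)
  )
  long <- cbind(variant = table$variant, chain = table$chain, long)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_molt_summary
#' @param n_records number of records behind the summary (not stored in the
#'   CSV; optional on read).
#' @export
read_molt_summary <- function(path, n_records = NA_integer_) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant", "chain", "measure", "position", "count")
  if (!all(need %in% names(long)))
    stop("summary CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  chain <- unique(long$chain)
  variant <- unique(long$variant)
  if (length(chain) != 1L || length(variant) != 1L)
    stop("summary CSV must hold a single chain and variant", call. = FALSE)
  out <- empty_molt_summary(chain, variant, n_records)
  for (r in seq_len(nrow(long))) {
    meas <- long$measure[r]; pos <- long$position[r]; cnt <- long$count[r]
    if (meas %in% c("nodal", "terminal", "n_growing")) {
      i <- match(pos, out$locus_counts$locus)
      if (is.na(i)) stop("unknown locus '", pos, "' in summary CSV",
                         call. = FALSE)
      out$locus_counts[i, meas] <- cnt
    } else if (meas %in% c("distal", "proximal", "ambiguous")) {
      j <- pair_index(pos, chain)
      out$pair_counts[j, meas] <- cnt
    } else {
      stop("unknown measure '", meas, "' in summary CSV", call. = FALSE)
    }
  }
  out
}
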
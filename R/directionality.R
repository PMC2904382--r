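# Directionality annotation. Each growing (or missing) feather is compared
# with its chain neighbors: a growing feather with both neighbors old is
# nodal (a wave start), with both neighbors new terminal (a wave end);
# otherwise each adjacent pair with at least one active member receives a
# proximal/distal/ambiguous direction score.

#' Direction score for one adjacent feather pair
#'
#' Implements the pairwise replacement-direction rules.  With both members
#' active (growing or missing; a missing feather counts as growing with
#' fraction 0) the direction runs from the longer feather toward the shorter;
#' equal lengths are ambiguous.  With one active member, a new neighbor
#' implies the wave came from the neighbor's side, an old (or very old)
#' neighbor that the wave is moving toward it.
#'
#' @param scores named numeric score vector for one record (chain order not
#'   required; looked up by name).
#' @param proximal_locus,distal_locus the pair, proximal member first (lower
#'   chain rank).
#' @return \code{"distal"}, \code{"proximal"}, \code{"ambiguous"}, or
#'   \code{NA} when neither member is active.  Unscored members give \code{NA}
#'   with a warning.
#' @examples
#' score_pair(c(P1 = 1, P2 = 0.5), "P1", "P2")    # distal
#' score_pair(c(P4 = 0.6, P5 = 0.6), "P4", "P5")  # ambiguous
#' @export
score_pair <- function(scores, proximal_locus, distal_locus) {
  if (abs(chain_rank(distal_locus) - chain_rank(proximal_locus)) != 1L ||
      locus_chain(proximal_locus) != locus_chain(distal_locus))
    stop("loci are not adjacent on a chain: ", proximal_locus, ", ",
         distal_locus, call. = FALSE)
  sp <- scores[[proximal_locus]]
  sd <- scores[[distal_locus]]
  if (is.na(sp) || is.na(sd)) {
    warning("pair ", proximal_locus, "/", distal_locus,
            " skipped: unscored member", call. = FALSE)
    return(NA_character_)
  }
  ap <- is_active_score(sp); ad <- is_active_score(sd)
  if (ap && ad) {
    fp <- score_fraction(sp); fd <- score_fraction(sd)
    if (fp > fd) "distal" else if (fd > fp) "proximal" else "ambiguous"
  } else if (ap) {
    # distal neighbor fully grown: new => wave arrived from distal side;
    # old => wave moving distally toward it
    if (is_new_score(sd)) "proximal" else "distal"
  } else if (ad) {
    if (is_new_score(sp)) "distal" else "proximal"
  } else {
    NA_character_
  }
}

#' Annotate one record with nodal/terminal feathers and pair directions
#'
#' Classifies every active locus: all scored neighbors old gives nodal, all
#' scored neighbors new gives terminal (an edge locus with its single
#' neighbor old is nodal; with its single neighbor new it contributes a pair
#' score rather than terminal, matching the raw-summary convention — the
#' series-aware reclassification happens during iteration).  All remaining
#' adjacent pairs with both members scored and at least one active receive
#' one direction score each.
#'
#' @param scores named numeric score vector covering one chain (see
#'   [record_scores()]), or a one-row \code{wing_records} table.
#' @param chain \code{"wing"} or \code{"tail"}.
#' @return list with \code{nodal}, \code{terminal} (locus labels),
#'   \code{pairs} (data.frame \code{pair_index}, \code{pair},
#'   \code{direction}), and \code{unclassified} (active loci with no scored
#'   neighbor).
#' @export
annotate_record <- function(scores, chain = "wing") {
  if (is.data.frame(scores)) scores <- record_scores(scores, 1L, chain)
  ch <- chain_loci(chain)
  s <- scores[ch]
  names(s) <- ch
  n <- length(ch)
  active <- is_active_score(s)
  new_ <- is_new_score(s)
  old_ <- is_old_score(s)
  scored <- !is.na(s)

  nodal <- character(0); terminal <- character(0); unclassified <- character(0)
  for (i in which(active)) {
    nb <- c(if (i > 1L) i - 1L, if (i < n) i + 1L)
    nb <- nb[scored[nb]]
    if (length(nb) == 0L) {
      unclassified <- c(unclassified, ch[i])
    } else if (all(old_[nb])) {
      nodal <- c(nodal, ch[i])
    } else if (length(nb) == 2L && all(new_[nb])) {
      terminal <- c(terminal, ch[i])
    }
  }
  if (length(unclassified))
    warning("active loci with no scored neighbor left unclassified: ",
            paste(unclassified, collapse = ", "), call. = FALSE)

  suppressed <- c(nodal, terminal)
  idx <- integer(0); dir <- character(0)
  for (i in seq_len(n - 1L)) {
    a <- ch[i]; b <- ch[i + 1L]
    if (!scored[i] || !scored[i + 1L]) next
    if (!active[i] && !active[i + 1L]) next
    if ((active[i] && a %in% suppressed) ||
        (active[i + 1L] && b %in% suppressed)) next
    d <- score_pair(s, a, b)
    if (!is.na(d)) { idx <- c(idx, i); dir <- c(dir, d) }
  }
  list(nodal = nodal, terminal = terminal,
       pairs = data.frame(pair_index = idx,
                          pair = if (length(idx)) pair_label(chain, idx)
                                 else character(0),
                          direction = dir, stringsAsFactors = FALSE),
       unclassified = unclassified)
}

#' Annotate every record of a table
#'
#' @param records a \code{wing_records} table.
#' @param chain \code{"wing"} or \code{"tail"}.
#' @return long data.frame with columns \code{record_id}, \code{kind}
#'   (\code{"nodal"}, \code{"terminal"}, or \code{"pair"}),
#'   \code{locus_or_pair} and \code{direction} (\code{NA} for nodal/terminal
#'   rows) — the annotated molt summary in export form.
#' @export
annotate_records <- function(records, chain = "wing") {
  out <- lapply(seq_len(nrow(records)), function(i) {
    ann <- annotate_record(record_scores(records, i, chain), chain)
    id <- records$specimen_id[i]
    rbind(
      if (length(ann$nodal))
        data.frame(record_id = id, kind = "nodal", locus_or_pair = ann$nodal,
                   direction = NA_character_, stringsAsFactors = FALSE),
      if (length(ann$terminal))
        data.frame(record_id = id, kind = "terminal",
                   locus_or_pair = ann$terminal,
                   direction = NA_character_, stringsAsFactors = FALSE),
      if (nrow(ann$pairs))
        data.frame(record_id = id, kind = "pair",
                   locus_or_pair = ann$pairs$pair,
                   direction = ann$pairs$direction, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(record_id = character(0), kind = character(0),
                      locus_or_pair = character(0), direction = character(0),
                      stringsAsFactors = FALSE)
  out
}
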
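# Feather locus bookkeeping. Molt scoring works on two adjacency chains:
# the wing chain S11,S10,...,S1,P1,P2,...,P10 (ranks 1-21) and the tail
# chain R1,...,R5 (ranks 1-5). Rank increases distally on both chains.

WING_CHAIN <- c(paste0("S", 11:1), paste0("P", 1:10))
TAIL_CHAIN <- paste0("R", 1:5)
ALL_LOCI <- c(WING_CHAIN, TAIL_CHAIN)

#' Feather adjacency chains
#'
#' The wing chain orders the secondaries and primaries along their anatomical
#' adjacency, from the innermost secondary (S11) through the wrist (S1/P1) to
#' the outermost primary (P10).  The tail chain orders the rectrices from the
#' central pair (R1) to the outermost (R5).  Replacement direction is always
#' reported relative to these chains: \emph{distal} means toward increasing
#' rank (wing tip, tail edge), \emph{proximal} toward decreasing rank.
#'
#' @return Character vector of locus labels in chain order.
#' @examples
#' wing_chain()
#' tail_chain()
#' @export
wing_chain <- function() WING_CHAIN

#' @rdname wing_chain
#' @export
tail_chain <- function() TAIL_CHAIN

chain_loci <- function(chain = c("wing", "tail")) {
  chain <- match.arg(chain)
  if (chain == "wing") WING_CHAIN else TAIL_CHAIN
}

#' Locus components
#'
#' @param locus character vector of locus labels such as \code{"P3"},
#'   \code{"S10"}, \code{"R5"}.
#' @return \code{locus_tract}: one of \code{"primary"}, \code{"secondary"},
#'   \code{"rectrix"}; \code{locus_index}: the within-tract feather number;
#'   \code{locus_chain}: \code{"wing"} or \code{"tail"}.
#' @export
locus_tract <- function(locus) {
  check_locus(locus)
  unname(c(P = "primary", S = "secondary", R = "rectrix")[substr(locus, 1, 1)])
}

#' @rdname locus_tract
#' @export
locus_index <- function(locus) {
  check_locus(locus)
  as.integer(substring(locus, 2))
}

#' @rdname locus_tract
#' @export
locus_chain <- function(locus) {
  ifelse(locus_tract(locus) == "rectrix", "tail", "wing")
}

check_locus <- function(locus) {
  bad <- setdiff(locus, ALL_LOCI)
  if (length(bad))
    stop("unknown feather locus: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(locus)
}

#' Chain rank of a feather locus
#'
#' Position of a locus along its adjacency chain.  On the wing chain the rank
#' of a primary is \code{11 + index} and of a secondary \code{12 - index}
#' (so S11 has rank 1 and P10 rank 21); rectrices have rank equal to their
#' index on the tail chain.
#'
#' @param locus character vector of locus labels.
#' @return integer vector of ranks.
#' @examples
#' chain_rank(c("S11", "S1", "P1", "P10", "R3"))
#' @export
chain_rank <- function(locus) {
  check_locus(locus)
  idx <- locus_index(locus)
  tract <- locus_tract(locus)
  ifelse(tract == "primary", 11L + idx,
         ifelse(tract == "secondary", 12L - idx, idx))
}

#' Neighbors of a locus on its adjacency chain
#'
#' @param locus a single locus label.
#' @return named character vector with elements \code{proximal} and
#'   \code{distal}; an edge locus (S11, P10, R1, R5) has \code{NA} on its
#'   missing side.
#' @examples
#' chain_neighbors("P1")   # S1 proximally, P2 distally
#' chain_neighbors("P10")  # chain edge
#' @export
chain_neighbors <- function(locus) {
  stopifnot(length(locus) == 1L)
  ch <- chain_loci(locus_chain(locus))
  i <- match(locus, ch)
  c(proximal = if (i > 1L) ch[i - 1L] else NA_character_,
    distal = if (i < length(ch)) ch[i + 1L] else NA_character_)
}

#' Label for an adjacent feather pair
#'
#' Pairs within one tract are labelled lowest feather number first
#' (\code{"S1/S2"}, \code{"P9/P10"}); the wrist pair is \code{"P1/S1"}.
#'
#' @param chain \code{"wing"} or \code{"tail"}.
#' @param i pair index: the pair joins the loci with chain ranks \code{i} and
#'   \code{i + 1}.
#' @return character vector of pair labels.
#' @export
pair_label <- function(chain, i) {
  ch <- chain_loci(chain)
  a <- ch[i]; b <- ch[i + 1L]
  ifelse(locus_tract(a) == locus_tract(b),
         ifelse(locus_index(a) < locus_index(b),
                paste0(a, "/", b), paste0(b, "/", a)),
         paste0(b, "/", a))  # wrist pair: P1/S1
}

#' Pair index from a pair label
#'
#' Inverse of [pair_label()]; either member order is accepted
#' (\code{"S11/S10"} and \code{"S10/S11"} name the same pair).
#'
#' @param label pair labels such as \code{"P1/P2"} or \code{"P1/S1"}.
#' @param chain \code{"wing"} or \code{"tail"}.
#' @return integer pair indices (rank of the proximal member).
#' @export
pair_index <- function(label, chain = "wing") {
  parts <- strsplit(label, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L)
      stop("malformed pair label: ", paste(p, collapse = "/"), call. = FALSE)
    check_locus(p)
    if (!all(locus_chain(p) == chain))
      stop("pair ", paste(p, collapse = "/"), " is not on the ", chain,
           " chain", call. = FALSE)
    r <- sort(chain_rank(p))
    if (r[2] - r[1] != 1L)
      stop("loci in pair ", paste(p, collapse = "/"),
           " are not adjacent on the chain", call. = FALSE)
    r[1]
  }, integer(1))
}
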
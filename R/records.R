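# Specimen molt records: one row per specimen, one wide score column per
# feather locus. Sides are not distinguished; the wing and tail chains of a
# record are analyzed separately.

RECORD_META <- c("specimen_id", "age_class", "month", "breeding")
AGE_CLASSES <- c("juvenile", "immature", "adult")

#' Build a validated table of wing records
#'
#' A wing-record table has the metadata columns \code{specimen_id},
#' \code{age_class}, \code{month}, \code{breeding} followed by one numeric
#' score column per feather locus (S11...S1, P1...P10, R1...R5).  \code{NA}
#' means the locus was not examined, which is distinct from a missing feather
#' (score 0.05).  Absent locus columns are created as unscored; columns
#' outside the schema are rejected.
#'
#' @param df data.frame of specimen records.
#' @return \code{df} with class \code{wing_records}, columns in schema order.
#' @examples
#' as_wing_records(data.frame(specimen_id = "x1", age_class = "adult",
#'                            P1 = 1, P2 = 0.5, P3 = 2))
#' @export
as_wing_records <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), c(RECORD_META, ALL_LOCI))
  if (length(unknown))
    stop("unknown columns in record table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!"specimen_id" %in% names(df))
    stop("record table needs a specimen_id column", call. = FALSE)
  df$specimen_id <- as.character(df$specimen_id)
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen ids: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
               collapse = ", "), call. = FALSE)
  if (!"age_class" %in% names(df))
    df$age_class <- rep(NA_character_, nrow(df))
  df$age_class <- as.character(df$age_class)
  bad_age <- !is.na(df$age_class) & !df$age_class %in% AGE_CLASSES
  if (any(bad_age))
    stop("invalid age_class: ", paste(unique(df$age_class[bad_age]),
                                      collapse = ", "), call. = FALSE)
  if (!"month" %in% names(df)) df$month <- rep(NA_integer_, nrow(df))
  df$month <- as.integer(df$month)
  if (any(!is.na(df$month) & (df$month < 1L | df$month > 12L)))
    stop("month must be in 1..12", call. = FALSE)
  if (!"breeding" %in% names(df)) df$breeding <- rep(NA, nrow(df))
  df$breeding <- as.logical(df$breeding)
  for (loc in ALL_LOCI) {
    if (!loc %in% names(df)) {
      df[[loc]] <- rep(NA_real_, nrow(df))
    } else {
      df[[loc]] <- parse_score(df[[loc]], context = paste("column", loc))
    }
  }
  df <- df[, c(RECORD_META, ALL_LOCI)]
  class(df) <- c("wing_records", "data.frame")
  df
}

#' @export
print.wing_records <- function(x, ...) {
  n_act <- vapply(seq_len(nrow(x)), function(i)
    sum(is_active_score(as.numeric(x[i, ALL_LOCI]))), integer(1))
  cat(sprintf("wing records: %d specimens (%d with active molt)\n",
              nrow(x), sum(n_act > 0L)))
  NextMethod()
}

#' Score vector of one record on one chain
#'
#' @param records a \code{wing_records} table.
#' @param i row number or specimen id.
#' @param chain \code{"wing"} or \code{"tail"}.
#' @return named numeric vector of scores in chain order (\code{NA} =
#'   unscored).
#' @export
record_scores <- function(records, i, chain = "wing") {
  if (is.character(i)) {
    i <- match(i, records$specimen_id)
    if (is.na(i)) stop("specimen id not found", call. = FALSE)
  }
  ch <- chain_loci(chain)
  stats::setNames(as.numeric(records[i, ch]), ch)
}

# build a wing_records row from a named score vector (simulator, tests)
scores_to_record <- function(scores, specimen_id = "r1", age_class = "adult",
                             month = NA, breeding = NA) {
  df <- data.frame(specimen_id = specimen_id, age_class = age_class,
                   month = as.integer(month), breeding = breeding,
                   stringsAsFactors = FALSE)
  for (loc in names(scores)) df[[loc]] <- scores[[loc]]
  as_wing_records(df)
}
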
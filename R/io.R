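# File I/O for the standard wide specimen CSV and the small measurement
# tables (growth-band rates, primary lengths, wave tallies).

record_header <- function() c(RECORD_META, ALL_LOCI)

#' Read / write the wide specimen score CSV
#'
#' The schema is fixed: header \code{specimen_id, age_class, month,
#' breeding, S11...S1, P1...P10, R1...R5}; an empty cell is an unscored
#' locus.  Unknown or missing columns, invalid score codes (with row and
#' column named) and duplicate specimen ids are rejected.
#'
#' @param path CSV path.
#' @return \code{read_wing_records}: a \code{wing_records} table.
#' @export
read_wing_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  hdr <- record_header()
  if (!identical(names(raw), hdr)) {
    extra <- setdiff(names(raw), hdr)
    miss <- setdiff(hdr, names(raw))
    stop("malformed header in ", path,
         if (length(extra)) paste0("; unknown columns: ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing columns: ",
                                  paste(miss, collapse = ", ")),
         if (!length(extra) && !length(miss)) "; columns out of order",
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(as_wing_records(data.frame(specimen_id = character(0),
                                      age_class = character(0))))
  }
  for (loc in ALL_LOCI) {
    raw[[loc]] <- vapply(seq_len(nrow(raw)), function(i)
      parse_score(raw[[loc]][i],
                  context = sprintf("row %d, column %s", i, loc)),
      numeric(1))
  }
  raw$month[raw$month == ""] <- NA
  raw$breeding[raw$breeding == ""] <- NA
  raw$age_class[raw$age_class == ""] <- NA
  as_wing_records(raw)
}

#' @rdname read_wing_records
#' @param records a \code{wing_records} table.
#' @export
write_wing_records <- function(records, path) {
  out <- as.data.frame(records)
  for (loc in ALL_LOCI)
    out[[loc]] <- ifelse(is.na(out[[loc]]), "",
                         formatC(out[[loc]], format = "fg"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wave-tally table
#'
#' Two-column CSV (\code{category}, \code{count}) with categories
#' \code{secondary_only}, \code{one_wave}, \code{two_waves},
#' \code{three_waves}, \code{extra_adjacent}.
#'
#' @param path CSV path.
#' @return named numeric vector usable by [mean_growing_per_wing()].
#' @export
read_wave_tallies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "count") %in% names(df)))
    stop("wave-tally CSV needs columns category, count", call. = FALSE)
  stats::setNames(df$count, df$category)
}

#' Bundled example data
#'
#' Paths to the measurement tables shipped with the package: adult primary
#' lengths, growth-band rates, primary-molt wave tallies, stepwise-molt
#' tallies, and the raw wing molt summary for immatures.
#'
#' @param file file name; with \code{NULL}, lists the available files.
#' @return a file path (or a vector of file names).
#' @examples
#' moltwave_example()
#' @export
moltwave_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "moltwave")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file '", file, "'", call. = FALSE)
  path
}
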
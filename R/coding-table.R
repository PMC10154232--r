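#' @keywords internal
"_PACKAGE"

## Canonical ROI coding schema. Column order follows the coding convention
## used during manual lineage annotation; matching is case-insensitive and
## ignores spaces/underscores so both "MotherID" and "mother_id" headers work.
.schema <- data.frame(
  column = c("CellID", "CellType", "UncertaintyCellType", "Timepoint",
             "MotherID", "UncertaintyMotherCell", "SisterID",
             "UncertaintySisterCell", "CellDeath"),
  field  = c("cell_id", "cell_type", "cell_type_uncertain", "timepoint",
             "mother_id", "mother_uncertain", "sister_id",
             "sister_uncertain", "death_flag"),
  stringsAsFactors = FALSE
)

.cell_types <- c("R", "NR", "N")

.norm_header <- function(x) gsub("[ _.]", "", tolower(x))

.parse_flag <- function(x, column) {
  if (is.logical(x)) {
    return(ifelse(is.na(x), FALSE, x))
  }
  x <- trimws(as.character(x))
  out <- rep(FALSE, length(x))
  out[x %in% c("1", "TRUE", "True", "true", "T", "yes", "Y", "y")] <- TRUE
  bad <- !(x %in% c("", "NA", "0", "FALSE", "False", "false", "F", "no",
                    "N", "n", "1", "TRUE", "True", "true", "T", "yes",
                    "Y", "y"))
  if (any(bad)) {
    stop("column '", column, "': cannot interpret value(s) ",
         paste(unique(x[bad]), collapse = ", "), " as TRUE/FALSE",
         call. = FALSE)
  }
  out
}

.parse_id <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "NaN", "<NA>")] <- NA_character_
  x
}

#' Read an ROI coding table
#'
#' Reads a per-cell, per-timepoint coding table as produced during manual
#' lineage annotation of chronic intravital imaging data. The table must
#' contain the nine schema columns `CellID`, `CellType`,
#' `UncertaintyCellType`, `Timepoint`, `MotherID`, `UncertaintyMotherCell`,
#' `SisterID`, `UncertaintySisterCell` and `CellDeath` (header matching is
#' case-insensitive and tolerant of spaces/underscores). An optional
#' `CloneID` column and `x`/`y`/`z` position columns (micrometres) are
#' carried through when present.
#'
#' @param path Path to a CSV file.
#' @param timepoint_units Either `"days"` (timepoints are days post
#'   induction, the default) or `"session"` (integer session indices, which
#'   are converted to days as `first_session_day + (index - 1) *
#'   session_interval`).
#' @param session_interval Days between sessions when
#'   `timepoint_units = "session"`.
#' @param first_session_day Day post induction of the first imaging session
#'   (used only for `"session"` units).
#' @param sep Field separator passed to [utils::read.csv()].
#' @return A `coding_table`: a data frame with one row per cell per
#'   timepoint and columns `cell_id`, `cell_type`, `cell_type_uncertain`,
#'   `timepoint`, `mother_id`, `mother_uncertain`, `sister_id`,
#'   `sister_uncertain`, `death_flag` (plus `clone_id`, `x`, `y`, `z` when
#'   present in the input). Empty mother/sister fields become `NA`.
#' @seealso [assemble_lineage()], [emit_coding_table()]
#' @export
read_coding_table <- function(path, timepoint_units = c("days", "session"),
                              session_interval = 1, first_session_day = 2,
                              sep = ",") {
  timepoint_units <- match.arg(timepoint_units)
  if (!file.exists(path)) {
    stop("coding table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  as_coding_table(raw, timepoint_units = timepoint_units,
                  session_interval = session_interval,
                  first_session_day = first_session_day)
}

#' Coerce a data frame to a validated coding table
#'
#' @param x A data frame with the nine schema columns (any capitalisation).
#' @inheritParams read_coding_table
#' @return A `coding_table` data frame; see [read_coding_table()].
#' @export
as_coding_table <- function(x, timepoint_units = c("days", "session"),
                            session_interval = 1, first_session_day = 2) {
  timepoint_units <- match.arg(timepoint_units)
  if (inherits(x, "coding_table")) {
    return(x)
  }
  stopifnot(is.data.frame(x))
  hdr <- .norm_header(names(x))
  idx <- match(.norm_header(.schema$column), hdr)
  ## also accept the snake_case field names used internally
  alt <- match(.norm_header(.schema$field), hdr)
  idx[is.na(idx)] <- alt[is.na(idx)]
  if (anyNA(idx)) {
    stop("coding table is missing required column(s): ",
         paste(.schema$column[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    cell_id   = .parse_id(x[[idx[1]]]),
    cell_type = toupper(trimws(as.character(x[[idx[2]]]))),
    cell_type_uncertain = .parse_flag(x[[idx[3]]], "UncertaintyCellType"),
    timepoint = rep(NA_real_, nrow(x)),
    mother_id = .parse_id(x[[idx[5]]]),
    mother_uncertain = .parse_flag(x[[idx[6]]], "UncertaintyMotherCell"),
    sister_id = .parse_id(x[[idx[7]]]),
    sister_uncertain = .parse_flag(x[[idx[8]]], "UncertaintySisterCell"),
    death_flag = .parse_flag(x[[idx[9]]], "CellDeath"),
    stringsAsFactors = FALSE
  )
  tp_raw <- trimws(as.character(x[[idx[4]]]))
  tp <- suppressWarnings(as.numeric(tp_raw))
  if (anyNA(tp)) {
    bad <- which(is.na(tp))[1]
    stop("non-numeric Timepoint value '", tp_raw[bad], "' at data line ",
         bad, call. = FALSE)
  }
  if (timepoint_units == "session") {
    if (any(tp != round(tp) | tp < 1)) {
      stop("session-indexed timepoints must be positive integers",
           call. = FALSE)
    }
    tp <- first_session_day + (tp - 1) * session_interval
  }
  out$timepoint <- tp
  for (extra in c("cloneid", "x", "y", "z")) {
    j <- match(extra, hdr)
    if (!is.na(j)) {
      val <- x[[j]]
      name <- if (extra == "cloneid") "clone_id" else extra
      out[[name]] <- if (name == "clone_id") .parse_id(val) else
        suppressWarnings(as.numeric(val))
    }
  }
  if (anyNA(out$cell_id)) {
    stop("CellID must be non-missing on every row", call. = FALSE)
  }
  bad_type <- !(out$cell_type %in% .cell_types)
  if (any(bad_type)) {
    stop("unknown CellType value(s): ",
         paste(unique(out$cell_type[bad_type]), collapse = ", "),
         " (expected R, NR or N)", call. = FALSE)
  }
  if (any(out$timepoint < 0)) {
    stop("timepoints must be non-negative days", call. = FALSE)
  }
  key <- if (is.null(out$clone_id)) out$cell_id else
    paste(out$clone_id, out$cell_id, sep = "/")
  deaths <- tapply(out$death_flag, key, sum)
  if (any(deaths > 1)) {
    stop("CellDeath recorded more than once for cell(s): ",
         paste(names(deaths)[deaths > 1], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("coding_table", "data.frame")
  out
}

#' Write a coding table to CSV
#'
#' Writes with the canonical schema headers so the file round-trips through
#' [read_coding_table()].
#'
#' @param table A `coding_table` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coding_table <- function(table, path) {
  table <- as_coding_table(table)
  out <- table
  names(out)[match(.schema$field, names(out))] <- .schema$column
  names(out)[names(out) == "clone_id"] <- "CloneID"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
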
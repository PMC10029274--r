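#' Read relocation tables into per-individual tracks
#'
#' Reads a delimited text table of telemetry fixes and returns one track per
#' individual. A track is a data frame with columns `individual_id`,
#' `timestamp` (POSIXct, UTC), `x`, `y` (planar projected meters; the study
#' system is Israeli Transverse Mercator, but any planar meter grid works),
#' and `accuracy_std` (meters, may be NA). Fixes are sorted by time and
#' duplicate (individual, timestamp) rows are collapsed to the first
#' occurrence; the number of dropped rows is attached as attribute
#' `"dropped"`.
#'
#' @param path path to a delimited text file.
#' @param config a [dar_config()] list; `config$columns` maps the Fix fields
#'   to file headers and `config$delim` sets the delimiter. Timestamps must
#'   be ISO-8601; they are stored UTC and interpreted in `config$timezone`
#'   by the diel logic downstream.
#' @return A named list of track data frames (one per individual), with
#'   attribute `dropped` (number of duplicate rows removed).
#' @export
read_tracks <- function(path, config = dar_config()) {
  if (!file.exists(path)) stop("track file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = config$delim,
                           stringsAsFactors = FALSE, comment.char = "")
  cols <- config$columns
  need <- unlist(cols[c("id", "time", "x", "y")])
  missing_cols <- setdiff(c(need, cols$std), names(raw))
  if (length(missing_cols))
    stop("column(s) mapped in config but absent from file: ",
         paste(missing_cols, collapse = ", "))
  ts <- parse_timestamps(raw[[cols$time]])
  for (cc in c(cols$x, cols$y)) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]) & nzchar(trimws(raw[[cc]])))
    if (length(bad))
      stop("non-numeric coordinate in column '", cc, "' at row ", bad[1])
    if (anyNA(v)) stop("missing coordinate in column '", cc, "'")
    if (any(!is.finite(v))) stop("non-finite coordinate in column '", cc, "'")
    raw[[cc]] <- v
  }
  std <- if (!is.null(cols$std) && cols$std %in% names(raw)) {
    s <- suppressWarnings(as.numeric(raw[[cols$std]]))
    if (any(s < 0, na.rm = TRUE)) stop("negative accuracy_std")
    s
  } else rep(NA_real_, nrow(raw))

  fixes <- data.frame(individual_id = as.character(raw[[cols$id]]),
                      timestamp = ts,
                      x = raw[[cols$x]], y = raw[[cols$y]],
                      accuracy_std = std,
                      stringsAsFactors = FALSE)
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), ]
  dup <- duplicated(fixes[c("individual_id", "timestamp")])
  dropped <- sum(dup)
  fixes <- fixes[!dup, ]
  rownames(fixes) <- NULL
  tracks <- split(fixes, fixes$individual_id)
  tracks <- lapply(tracks, function(tr) { rownames(tr) <- NULL; tr })
  attr(tracks, "dropped") <- dropped
  tracks
}

parse_timestamps <- function(v) {
  v <- as.character(v)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")
  ts <- tryCatch(as.POSIXct(v, tz = "UTC", tryFormats = fmts),
                 error = function(e) rep(as.POSIXct(NA), length(v)))
  bad <- which(is.na(ts) & !is.na(v))
  if (length(bad))
    stop("unparseable timestamp at row ", bad[1], ": '", v[bad[1]], "'")
  ts
}

#' Read the individual-metadata table
#'
#' Expects a delimited table with a ring/tag identifier, sex and age-class
#' columns (optionally birth/assignment date and family id). Sex tokens
#' f/F/female and m/M/male are normalized; age tokens young/juvenile/j and
#' adult/a likewise (young is at most one year old at assignment). Rows with
#' unrecognized sex or age tokens are rejected with a message and returned in
#' attribute `"rejected"`.
#'
#' @param path path to the metadata file.
#' @param config a [dar_config()] list (`meta_columns`, `delim`).
#' @return A data frame with columns `individual_id`, `sex`, `age_class`,
#'   `birth_date` (Date or NA), `family_id` (character or NA).
#' @export
read_metadata <- function(path, config = dar_config()) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = config$delim,
                           stringsAsFactors = FALSE)
  mc <- config$meta_columns
  for (cc in unlist(mc[c("id", "sex", "age")]))
    if (!cc %in% names(raw)) stop("metadata column missing: ", cc)
  id <- as.character(raw[[mc$id]])
  if (anyDuplicated(id)) stop("duplicate ring ID in metadata: ",
                              id[duplicated(id)][1])
  sex <- normalize_token(raw[[mc$sex]],
                         list(female = c("f", "female"), male = c("m", "male")))
  age <- normalize_token(raw[[mc$age]],
                         list(young = c("y", "young", "j", "juvenile"),
                              adult = c("a", "adult")))
  birth <- if (!is.null(mc$birth_date) && mc$birth_date %in% names(raw))
    as.Date(raw[[mc$birth_date]]) else as.Date(rep(NA, nrow(raw)))
  fam <- if (!is.null(mc$family) && mc$family %in% names(raw))
    as.character(raw[[mc$family]]) else rep(NA_character_, nrow(raw))
  out <- data.frame(individual_id = id, sex = sex, age_class = age,
                    birth_date = birth, family_id = fam,
                    stringsAsFactors = FALSE)
  bad <- is.na(out$sex) | is.na(out$age_class)
  if (any(bad)) {
    message(sum(bad), " metadata row(s) rejected (unrecognized sex/age): ",
            paste(utils::head(id[bad], 5), collapse = ", "))
  }
  rejected <- out[bad, ]
  out <- out[!bad, ]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

normalize_token <- function(v, lexicon) {
  v <- tolower(trimws(as.character(v)))
  out <- rep(NA_character_, length(v))
  for (canon in names(lexicon)) out[v %in% lexicon[[canon]]] <- canon
  out
}

#' Write a tabular artifact to delimited text
#'
#' CSV writer used for all package outputs (metrics tables, cluster labels,
#' summaries). Round-trips losslessly through [utils::read.csv()].
#'
#' @param records a non-empty data frame.
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, delim = ",") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("refusing to write an empty table")
  utils::write.table(records, path, sep = delim, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
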
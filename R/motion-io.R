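#' Motion file column schema
#'
#' The fixed, published column order of motion CSV files: `timestamp` followed
#' by `<joint>_x, <joint>_y, <joint>_z` for each of the 25 joints in
#' [kinect_joints()] order. Coordinates are in meters, timestamps in seconds.
#'
#' @return Character vector of 76 column names.
#' @export
motion_schema <- function() {
  joints <- kinect_joints()
  c("timestamp", paste(rep(joints, each = 3), rep(c("x", "y", "z"), 25), sep = "_"))
}

#' Write a motion sequence to CSV
#'
#' Comma-separated, UTF-8, dot decimal, mandatory header, one row per frame.
#' Values are written with six decimals, so coordinates survive a round-trip
#' to 1e-6 m and two writes of the same sequence are byte-identical.
#'
#' @param seq A `motion_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(seq, path) {
  if (!inherits(seq, "motion_sequence")) {
    s2s_error("seq must be a motion_sequence", "s2s_invalid_sequence")
  }
  joints <- kinect_joints()
  rows <- vapply(seq$frames, function(f) {
    vals <- c(attr(f, "timestamp"), as.vector(t(unclass(f)[joints, c("x", "y", "z")])))
    paste(sprintf("%.6f", vals), collapse = ",")
  }, character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(motion_schema(), collapse = ","), rows), con)
  invisible(path)
}

#' Read a motion sequence from CSV
#'
#' Expects the exact schema of [motion_schema()] (any column order is
#' accepted, but every column must be present). Coordinates are in meters.
#'
#' @param path Input file path.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param cohort Cohort label, `"elderly"` or `"control"`.
#' @return A `motion_sequence` with frames in file order.
#' @export
read_motion <- function(path, subject_id = NULL,
                        cohort = c("elderly", "control")) {
  cohort <- match.arg(cohort)
  if (!file.exists(path)) {
    s2s_error(sprintf("motion file '%s' does not exist", path), "s2s_io_error")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  schema <- motion_schema()
  missing <- setdiff(schema, names(raw))
  if (length(missing) > 0) {
    s2s_error(sprintf("motion file '%s' lacks required column(s): %s", path,
                      paste(missing, collapse = ", ")), "s2s_format_error")
  }
  num <- suppressWarnings(
    vapply(raw[schema], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, schema))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    s2s_error(sprintf("non-numeric value in column '%s', data row %d of '%s'",
                      schema[bad[1, 2]], bad[1, 1], path), "s2s_parse_error")
  }
  joints <- kinect_joints()
  frames <- lapply(seq_len(nrow(num)), function(i) {
    pos <- matrix(num[i, -1], ncol = 3, byrow = TRUE,
                  dimnames = list(joints, c("x", "y", "z")))
    skeleton_frame(num[i, "timestamp"], pos)
  })
  motion_sequence(frames, subject_id = subject_id, cohort = cohort)
}

#' Write anthropometry records to CSV
#'
#' Schema: `subject_id, cohort, L1..L14, Z1..Z14`, values in millimeters.
#'
#' @param records Named list of `anthropometry` objects (names = subject ids),
#'   or a single `anthropometry`.
#' @param cohort Cohort label recycled across records, or a vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anthropometry <- function(records, cohort, path) {
  if (inherits(records, "anthropometry")) records <- list(subject1 = records)
  cohort <- rep_len(cohort, length(records))
  df <- data.frame(subject_id = names(records), cohort = cohort,
                   stringsAsFactors = FALSE)
  meas <- t(vapply(records, function(a) c(a$standing, a$sitting), numeric(28)))
  df <- cbind(df, as.data.frame(meas))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read anthropometry records from CSV
#'
#' @param path File with columns `subject_id, cohort, L1..L14, Z1..Z14` (mm).
#' @return Named list of `anthropometry` objects with a `cohort` attribute
#'   (character vector parallel to the list).
#' @export
read_anthropometry <- function(path) {
  if (!file.exists(path)) {
    s2s_error(sprintf("anthropometry file '%s' does not exist", path), "s2s_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort", paste0("L", 1:14), paste0("Z", 1:14))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    s2s_error(sprintf("anthropometry file lacks column(s): %s",
                      paste(missing, collapse = ", ")), "s2s_format_error")
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    anthropometry(unlist(df[i, paste0("L", 1:14)]),
                  unlist(df[i, paste0("Z", 1:14)]))
  })
  names(recs) <- df$subject_id
  attr(recs, "cohort") <- df$cohort
  recs
}
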
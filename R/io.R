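RAW_COLUMNS <- c("participant_id", "group", "trial_id", "timestamp_ms",
                 "pupil_left_mm", "pupil_right_mm", "validity_left",
                 "validity_right")

# Full-precision numeric formatting so TSV round-trips are bit-exact.
fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v),
                character(1))
  out
}

#' Write raw recordings as tab-separated text
#'
#' Native dialect: header row with columns `participant_id`, `group`,
#' `trial_id`, `timestamp_ms`, `pupil_left_mm`, `pupil_right_mm`,
#' `validity_left`, `validity_right`; missing numeric fields are empty;
#' UTF-8, Unix newlines. Values round-trip bit-exactly through
#' [read_raw_tsv()].
#'
#' @param recordings list of `raw_recording` data frames or one combined
#'   data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raw_tsv <- function(recordings, path) {
  if (!is.data.frame(recordings)) {
    if (length(recordings) == 0)
      stop_pw("no recordings to write", "pw_input_error")
    recordings <- do.call(rbind, unname(recordings))
  }
  df <- recordings[, RAW_COLUMNS]
  out <- data.frame(participant_id = df$participant_id, group = df$group,
                    trial_id = df$trial_id,
                    timestamp_ms = fmt_num(df$timestamp_ms),
                    pupil_left_mm = fmt_num(df$pupil_left_mm),
                    pupil_right_mm = fmt_num(df$pupil_right_mm),
                    validity_left = df$validity_left,
                    validity_right = df$validity_right,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(RAW_COLUMNS, collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(out, sep = "\t")), con, sep = "\n")
  invisible(path)
}

tobii_column_map <- c(ParticipantName = "participant_id",
                      Group = "group",
                      TrialId = "trial_id",
                      RecordingTimestamp = "timestamp_ms",
                      PupilLeft = "pupil_left_mm",
                      PupilRight = "pupil_right_mm",
                      ValidityLeft = "validity_left",
                      ValidityRight = "validity_right")

#' Read raw eye-tracker TSV exports
#'
#' Dialect `"native"` reads the schema written by [write_raw_tsv()]
#' (validity 1 = valid, 0 = invalid). Dialect `"tobii"` reads a Tobii
#' Studio-style text export (`ParticipantName`, `RecordingTimestamp`,
#' `PupilLeft`/`PupilRight`, `ValidityLeft`/`ValidityRight` with 0-4
#' validity codes, of which codes 0-1 count as valid). In both dialects a
#' sample is missing when its validity is bad or the pupil value is absent
#' or non-positive.
#'
#' @param path TSV file.
#' @param dialect `"native"` or `"tobii"`.
#' @return Named list of `raw_recording` data frames, one per participant.
#' @export
read_raw_tsv <- function(path, dialect = c("native", "tobii")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_pw(paste("no such file:", path),
                                  "pw_input_error")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE,
                          showProgress = FALSE)
  if (dialect == "tobii") {
    missing_cols <- setdiff(names(tobii_column_map),
                            c(names(dt), "Group", "TrialId"))
    if (length(missing_cols) > 0)
      stop_pw(paste("tobii export is missing required column(s):",
                    paste(missing_cols, collapse = ", ")), "pw_input_error")
    if (!"Group" %in% names(dt)) dt$Group <- "all"
    if (!"TrialId" %in% names(dt)) dt$TrialId <- 1L
    dt <- dt[, names(tobii_column_map)]
    names(dt) <- unname(tobii_column_map)
    # Tobii validity: 0 = certainly the right eye ... 4 = not found
    dt$validity_left <- as.integer(dt$validity_left <= 1)
    dt$validity_right <- as.integer(dt$validity_right <= 1)
    dt$validity_left[is.na(dt$validity_left)] <- 0L
    dt$validity_right[is.na(dt$validity_right)] <- 0L
  } else {
    missing_cols <- setdiff(RAW_COLUMNS, names(dt))
    if (length(missing_cols) > 0)
      stop_pw(paste("raw TSV is missing required column(s):",
                    paste(missing_cols, collapse = ", ")), "pw_input_error")
    dt <- dt[, RAW_COLUMNS]
  }
  bad_left <- dt$validity_left == 0 | is.na(dt$pupil_left_mm) |
    dt$pupil_left_mm <= 0
  bad_right <- dt$validity_right == 0 | is.na(dt$pupil_right_mm) |
    dt$pupil_right_mm <= 0
  dt$pupil_left_mm[bad_left] <- NA_real_
  dt$pupil_right_mm[bad_right] <- NA_real_
  dt$validity_left <- as.integer(!bad_left)
  dt$validity_right <- as.integer(!bad_right)

  recs <- split(dt, dt$participant_id)
  for (pid in names(recs)) {
    rec <- recs[[pid]]
    for (tid in unique(rec$trial_id)) {
      ts <- rec$timestamp_ms[rec$trial_id == tid]
      if (is.unsorted(ts, strictly = TRUE))
        stop_pw(sprintf("non-monotone timestamps in trial %s of %s", tid, pid),
                "pw_input_error")
    }
    rownames(rec) <- NULL
    class(rec) <- c("raw_recording", "data.frame")
    recs[[pid]] <- rec
  }
  recs
}

#' Write a tidy data frame as CSV (empty field = missing)
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(df, path) {
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}
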
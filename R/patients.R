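# Patient record schema: one row per patient.
PATIENT_COLUMNS <- c("patient_id", "cohort", "age", "new_onset_headache",
                     "jaw_claudication", "aion", "crp", "wall_thickness",
                     "hrtcs_result", "final_diagnosis")

#' Validate a data frame of patient records
#'
#' Checks the column set, value ranges and cross-field consistency (a
#' recorded sonography result must agree with the wall thickness under the
#' positivity rule when both are present).  Extra columns are tolerated and
#' carried through untouched.
#'
#' @param patients Data frame.
#' @param wall_cutoff Positivity cut-off (mm) used for the consistency check.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_patients <- function(patients, wall_cutoff = 0.7) {
  missing_cols <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(missing_cols)) {
    gca_stop("BAD_SCHEMA", paste("missing column(s):",
                                 paste(missing_cols, collapse = ", ")))
  }
  check_row <- function(cond, code, what) {
    bad <- which(cond)
    if (length(bad)) {
      gca_stop(code, sprintf("%s at row %s", what,
                             paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  check_row(!is.na(patients$age) & patients$age < 0,
            "INVALID_VALUE", "age < 0")
  check_row(is.na(patients$age), "MISSING_FIELD", "age missing")
  check_row(!is.na(patients$crp) & patients$crp < 0,
            "INVALID_VALUE", "crp < 0")
  check_row(!is.na(patients$wall_thickness) & patients$wall_thickness < 0,
            "INVALID_VALUE", "wall_thickness < 0")
  aion <- as.character(patients$aion)
  check_row(!aion %in% c("none", "unilateral", "bilateral"),
            "INVALID_VALUE",
            "unknown AION token (accepted: none, unilateral, bilateral)")
  hr <- as.character(patients$hrtcs_result)
  check_row(!is.na(hr) & !hr %in% c("positive", "negative"),
            "INVALID_VALUE", "unknown hrtcs_result token")
  dx <- as.character(patients$final_diagnosis)
  check_row(!is.na(dx) & !dx %in% c("cGCA", "alternative"),
            "INVALID_VALUE", "unknown final_diagnosis token")
  both <- !is.na(hr) & !is.na(patients$wall_thickness)
  implied <- ifelse(hrtcs_positive(patients$wall_thickness, wall_cutoff),
                    "positive", "negative")
  check_row(both & hr != implied, "INCONSISTENT_RECORD",
            "hrtcs_result contradicts wall_thickness under the cut-off")
  invisible(patients)
}

#' Read patient records from CSV
#'
#' Expects the comma-separated, UTF-8, header-first dialect used throughout
#' the package: booleans as 0/1, AION as `none`/`unilateral`/`bilateral`
#' (case-insensitive), missing values as empty strings.  Unknown columns are
#' carried through untouched.
#'
#' @param path Path to a CSV file.
#' @param validate Run [validate_patients()] on the result (default TRUE).
#' @return Data frame of patient records.
#' @export
read_patients <- function(path, validate = TRUE) {
  if (!file.exists(path)) gca_stop("NO_SUCH_FILE", paste("not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), encoding = "UTF-8")
  missing_cols <- setdiff(PATIENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    gca_stop("BAD_SCHEMA", paste("header lacks column(s):",
                                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) return(df)
  for (col in c("aion", "hrtcs_result", "cohort")) {
    df[[col]] <- tolower(as.character(df[[col]]))
    df[[col]][df[[col]] == "na"] <- NA_character_
  }
  # final_diagnosis keeps the cGCA capitalisation regardless of input case
  fd <- tolower(as.character(df$final_diagnosis))
  df$final_diagnosis <- ifelse(is.na(fd), NA_character_,
                               ifelse(fd == "cgca", "cGCA", fd))
  for (col in c("age", "crp", "wall_thickness")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in c("new_onset_headache", "jaw_claudication")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (any(!is.na(v) & !v %in% c(0L, 1L))) {
      gca_stop("INVALID_VALUE", paste("column", col, "must be 0/1"))
    }
    df[[col]] <- v
  }
  if (validate) validate_patients(df)
  df
}

#' Write patient records to CSV
#'
#' Inverse of [read_patients()]: same dialect, missing values as empty
#' strings, LF line endings.
#'
#' @param patients Data frame of patient records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, na = "", eol = "\n",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
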
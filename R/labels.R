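# ADA cut-offs (mmol/L for glucose, % for HbA1c). Lower edge of each
# at-risk band is inclusive.
ADA_CUTOFFS <- list(
  fpg_pre = 5.6, fpg_dm = 7.0,
  g2h_pre = 7.8, g2h_dm = 11.1,
  hba1c_pre = 5.7, hba1c_dm = 6.5
)

#' Assign glycemic status by ADA criteria
#'
#' Diabetes if fasting glucose >= 7.0 mmol/L, 2-hour OGTT glucose >= 11.1
#' mmol/L, or HbA1c >= 6.5 %; otherwise prediabetes if fasting glucose in
#' [5.6, 7.0) (impaired fasting glucose), 2-hour glucose in [7.8, 11.1)
#' (impaired glucose tolerance), or HbA1c in [5.7, 6.5); otherwise
#' normoglycemia. The `via_*` flags record which channel is in its at-risk
#' (or diabetes) range, so a normoglycemic participant has no flag set.
#'
#' @param fpg Fasting plasma glucose, mmol/L (vectorized).
#' @param g2h 2-hour OGTT glucose, mmol/L.
#' @param hba1c HbA1c, percent.
#' @return A tibble with columns `status` (factor: normoglycemia,
#'   prediabetes, diabetes) and logical `via_ifg`, `via_igt`, `via_hba1c`.
#' @export
classify_glycemia <- function(fpg, g2h, hba1c) {
  n <- length(fpg)
  stopifnot(length(g2h) == n, length(hba1c) == n)
  if (any(is.na(fpg)) || any(is.na(g2h)) || any(is.na(hba1c))) {
    stop("classify_glycemia requires fasting, 2-hour and HbA1c values ",
         "for every participant", call. = FALSE)
  }
  co <- ADA_CUTOFFS
  dm <- fpg >= co$fpg_dm | g2h >= co$g2h_dm | hba1c >= co$hba1c_dm
  via_ifg <- fpg >= co$fpg_pre
  via_igt <- g2h >= co$g2h_pre
  via_hba1c <- hba1c >= co$hba1c_pre
  pre <- !dm & (via_ifg | via_igt | via_hba1c)
  status <- factor(
    ifelse(dm, "diabetes", ifelse(pre, "prediabetes", "normoglycemia")),
    levels = c("normoglycemia", "prediabetes", "diabetes")
  )
  tibble::tibble(status = status, via_ifg = via_ifg, via_igt = via_igt,
                 via_hba1c = via_hba1c)
}

#' The single-threshold HbA1c screening rule
#'
#' The benchmark rule: positive iff HbA1c >= threshold (boundary
#' inclusive).
#'
#' @param hba1c HbA1c values, percent (vectorized).
#' @param threshold Threshold in percent, default 5.7.
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
hba1c_rule <- function(hba1c, threshold = 5.7) {
  ifelse(hba1c >= threshold, "positive", "negative")
}

#' Label a clinical table
#'
#' Appends `status` and per-criterion flag columns to a clinical table with
#' columns `fpg`, `g2h`, `hba1c`.
#'
#' @param clinical A clinical tibble (see [read_clinical_csv()]).
#' @return The table with `status`, `via_ifg`, `via_igt`, `via_hba1c`
#'   appended.
#' @export
label_cohort <- function(clinical) {
  lab <- classify_glycemia(clinical$fpg, clinical$g2h, clinical$hba1c)
  dplyr::bind_cols(clinical, lab)
}

CLINICAL_CSV_COLS <- c(participant_id = "participant_id", age = "age",
                       sex = "sex", ethnicity = "ethnicity", bmi = "bmi",
                       whr = "whr", fpg = "fpg_mmol_l", g2h = "g2h_mmol_l",
                       hba1c = "hba1c_pct")

#' Read / write the clinical CSV
#'
#' Header `participant_id,age,sex,ethnicity,bmi,whr,fpg_mmol_l,g2h_mmol_l,
#' hba1c_pct`; internal column names drop the unit suffixes. Label columns
#' (`status` + flags), if present, round-trip unchanged.
#'
#' @param path CSV path.
#' @return A clinical tibble.
#' @export
read_clinical_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(CLINICAL_CSV_COLS), names(df))
  if (length(missing_cols) > 0) {
    stop("clinical CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- match(unname(CLINICAL_CSV_COLS), names(df))
  names(df)[idx] <- names(CLINICAL_CSV_COLS)
  tibble::as_tibble(df)
}

#' @rdname read_clinical_csv
#' @param clinical A clinical tibble.
#' @export
write_clinical_csv <- function(clinical, path) {
  df <- clinical
  idx <- match(names(CLINICAL_CSV_COLS), names(df))
  names(df)[idx[!is.na(idx)]] <- unname(CLINICAL_CSV_COLS)[!is.na(idx)]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
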
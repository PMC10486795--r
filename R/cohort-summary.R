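#' Cohort characteristics summary
#'
#' Builds the standard patient-characteristics panel over the full retained
#' cohort: counts with percentages to one decimal for binary/categorical
#' rows (percentages computed over the whole cohort, missing values counted
#' separately), median (min-max) for continuous rows. An empty category
#' reports 0 (0.0\%).
#'
#' @param table cohort data.frame (the column dictionary of
#'   \code{\link{make_cohort}}; absent columns are skipped).
#' @param ca19_9_cutoff threshold for the elevated CA 19-9 row (default 55).
#' @return Object of class \code{cohort_summary}: a data.frame with columns
#'   characteristic, value (formatted), n, percent, median, min, max,
#'   n_missing.
#' @export
cohort_summary <- function(table, ca19_9_cutoff = 55) {
  stopifnot(is.data.frame(table))
  N <- nrow(table)
  rows <- list()
  add_count <- function(label, x) {
    n <- sum(x, na.rm = TRUE)
    pct <- round(100 * n / N, 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = label,
      value = sprintf("%d (%.1f%%)", n, pct),
      n = n, percent = pct, median = NA_real_, min = NA_real_, max = NA_real_,
      n_missing = sum(is.na(x)))
  }
  add_cont <- function(label, x, digits = 1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = label,
      value = sprintf("%.7g (%.7g-%.7g)",
                      round(stats::median(x, na.rm = TRUE), digits),
                      round(min(x, na.rm = TRUE), digits),
                      round(max(x, na.rm = TRUE), digits)),
      n = NA_integer_, percent = NA_real_,
      median = stats::median(x, na.rm = TRUE),
      min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
      n_missing = sum(is.na(x)))
  }
  has <- function(cc) cc %in% names(table)
  if (has("age")) add_cont("Age, years", table$age)
  if (has("sex")) {
    add_count("Sex, male", table$sex == 1)
    add_count("Sex, female", table$sex == 0)
  }
  if (has("hbv")) add_count("HBV infection", table$hbv == 1)
  if (has("hcv")) add_count("HCV infection", table$hcv == 1)
  if (has("cirrhosis")) add_count("Liver cirrhosis", table$cirrhosis == 1)
  if (has("diameter_mm")) add_cont("Tumor diameter, mm", table$diameter_mm)
  if (has("solitary")) add_count("Solitary tumor", table$solitary == 1)
  if (has("pattern"))
    for (lv in levels(factor(table$pattern)))
      add_count(paste("Tumor pattern, type", lv), table$pattern == lv)
  if (has("ca19_9")) {
    add_cont("Ca 19.9, U/mL", table$ca19_9)
    add_count(sprintf("Ca 19.9 >= %g U/mL", ca19_9_cutoff),
              table$ca19_9 >= ca19_9_cutoff)
  }
  if (has("preop_chemo"))
    add_count("Preoperative chemotherapy", table$preop_chemo == 1)
  if (has("major_hepatectomy"))
    add_count("Major hepatectomy", table$major_hepatectomy == 1)
  if (has("G3")) add_count("Tumor grading, G3", table$G3 == 1)
  if (has("MVI")) add_count("Microscopic vascular invasion", table$MVI == 1)
  out <- do.call(rbind, rows)
  structure(out, class = c("cohort_summary", "data.frame"), n_total = N)
}

#' @exportS3Method
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort characteristics (n = %d)\n", attr(x, "n_total")))
  df <- data.frame(Characteristic = x$characteristic, Value = x$value,
                   Missing = ifelse(x$n_missing > 0, x$n_missing, ""))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
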
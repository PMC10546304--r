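#' Cohort characteristics summary with between-class tests
#'
#' Per-class descriptive statistics in the usual "Table 1" layout: n, sex
#' counts with the male-to-female ratio (rounded to 2 decimals), age mean
#' +/- sd, tumor size median with interquartile range; plus between-class
#' tests - Welch t-test for age, chi-square with continuity correction for
#' sex, Mann-Whitney for size. The test choices are this package's
#' defaults and are flagged in the output.
#'
#' @param patientTable data.frame with columns \code{label}
#'   ("SCN"/"MCN"; required) and optionally \code{sex} ("M"/"F"),
#'   \code{age} (years), \code{tumor_size} (cm).
#' @return List with \code{perClass} (data.frame, one row per class) and
#'   \code{tests} (data.frame with variable, test, p_value).
#' @export
cohortSummary <- function(patientTable) {
  if (!is.data.frame(patientTable) || !("label" %in% names(patientTable))) {
    stop("patientTable must be a data.frame with a 'label' column",
         call. = FALSE)
  }
  if (!all(patientTable$label %in% .LABELS)) {
    stop("labels must be SCN or MCN", call. = FALSE)
  }
  classes <- intersect(.LABELS, unique(patientTable$label))
  perClass <- lapply(classes, function(cl) {
    sub <- patientTable[patientTable$label == cl, , drop = FALSE]
    row <- data.frame(label = cl, n = nrow(sub))
    if ("sex" %in% names(sub)) {
      male <- sum(sub$sex == "M"); female <- sum(sub$sex == "F")
      row$male <- male
      row$female <- female
      row$male_to_female <- if (female > 0) round(male / female, 2) else NA
    }
    if ("age" %in% names(sub)) {
      row$age_mean <- mean(sub$age)
      row$age_sd <- stats::sd(sub$age)
    }
    if ("tumor_size" %in% names(sub)) {
      q <- stats::quantile(sub$tumor_size, c(0.25, 0.5, 0.75), names = FALSE)
      row$size_median <- q[2]
      row$size_q25 <- q[1]
      row$size_q75 <- q[3]
    }
    row
  })
  perClass <- do.call(rbind, perClass)

  tests <- list()
  has2 <- length(classes) == 2L
  if (has2 && "age" %in% names(patientTable)) {
    p <- stats::t.test(age ~ label, data = patientTable,
                       var.equal = FALSE)$p.value
    tests[[length(tests) + 1L]] <- data.frame(
      variable = "age", test = "Welch t-test (package default)", p_value = p)
  }
  if (has2 && "sex" %in% names(patientTable)) {
    tab <- table(patientTable$label, patientTable$sex)
    p <- tryCatch(stats::chisq.test(tab, correct = TRUE)$p.value,
                  warning = function(w)
                    suppressWarnings(stats::chisq.test(tab,
                                                       correct = TRUE)$p.value))
    tests[[length(tests) + 1L]] <- data.frame(
      variable = "sex",
      test = "chi-square with continuity correction (package default)",
      p_value = p)
  }
  if (has2 && "tumor_size" %in% names(patientTable)) {
    p <- suppressWarnings(stats::wilcox.test(
      tumor_size ~ label, data = patientTable)$p.value)
    tests[[length(tests) + 1L]] <- data.frame(
      variable = "tumor_size", test = "Mann-Whitney (package default)",
      p_value = p)
  }
  list(perClass = perClass,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(variable = character(), test = character(),
                    p_value = numeric()))
}
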
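# Cohort-level statistics: quadratic regression of mean T2* on gestational
# age with a group contrast and ethnicity adjustment, linear regression for
# volume and skewness, demographic group comparisons (pooled t / chi-
# squared), and the outcome/histology percentage table.

#' Format a p-value in clinical-report style
#'
#' Values below 0.001 print as `"<0.001"`; otherwise two significant
#' figures (trailing zeros trimmed).
#'
#' @param p numeric p-value(s).
#' @return character.
#' @export
formatPValue <- function(p) {
  out <- ifelse(is.na(p), "",
                ifelse(p < 0.001, "<0.001",
                       vapply(p, function(x)
                         format(signif(x, 2), scientific = FALSE,
                                drop0trailing = TRUE), "")))
  out
}

.prepareModelFrame <- function(table, outcome, ethnicityCoding) {
  need <- c("group", "ga_mri", outcome)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table is missing columns: ", paste(miss, collapse = ", "))
  df <- table[!is.na(table[[outcome]]) & !is.na(table$ga_mri) &
                !is.na(table$group), ]
  if (length(unique(df$group)) < 2L || any(table(df$group) < 2L))
    stop("need at least 2 subjects in each group")
  df$group <- factor(as.character(df$group),
                     levels = c("control", "preterm"))   # control = reference
  df$.y <- df[[outcome]]
  if ("ethnicity" %in% names(table) && !all(is.na(df$ethnicity))) {
    if (ethnicityCoding == "binary")
      df$.eth <- factor(ifelse(as.character(df$ethnicity) == "White",
                               "White", "nonWhite"),
                        levels = c("White", "nonWhite"))
    else
      df$.eth <- factor(as.character(df$ethnicity),
                        levels = .ethnicityLevels)
  } else df$.eth <- NULL
  df
}

.fitGroupModel <- function(table, outcome, quadratic, ethnicityCoding,
                           interaction, transform, shapiroAlpha = 0.05) {
  df <- .prepareModelFrame(table, outcome, ethnicityCoding)
  terms <- c("ga_mri", if (quadratic) "I(ga_mri^2)", "group",
             if (interaction) "ga_mri:group",
             if (!is.null(df$.eth) && nlevels(droplevels(df$.eth)) > 1L)
               ".eth")
  fml <- stats::reformulate(terms, response = ".y")
  dropped <- character()

  fitOnce <- function(d) {
    fit <- stats::lm(fml, data = d)
    # rank deficiency: drop the ethnicity covariate rather than report NA
    if (anyNA(stats::coef(fit)) && ".eth" %in% terms) {
      dropped <<- c(dropped, "ethnicity (collinear)")
      warning("ethnicity covariate is collinear; dropping it")
      fml <<- stats::reformulate(setdiff(terms, ".eth"), response = ".y")
      fit <- stats::lm(fml, data = d)
    }
    fit
  }

  fit <- fitOnce(df)
  transformApplied <- "none"
  res <- stats::residuals(fit)
  swP <- if (length(res) >= 3 && length(res) <= 5000 &&
             stats::sd(res) > 0) stats::shapiro.test(res)$p.value else NA_real_
  if (transform == "log" ||
      (transform == "auto" && !is.na(swP) && swP < shapiroAlpha)) {
    if (all(df$.y > 0)) {
      df$.y <- log(df$.y)
      fit <- fitOnce(df)
      transformApplied <- "log"
      res <- stats::residuals(fit)
      swP <- if (stats::sd(res) > 0) stats::shapiro.test(res)$p.value
             else NA_real_
    } else if (transform == "log") {
      warning("outcome has non-positive values; log transform skipped")
    } else {
      warning("residuals non-normal but outcome has non-positive values; ",
              "no transform applied")
    }
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  gRow <- grep("^grouppreterm$", rownames(ct))
  if (!length(gRow)) stop("group term missing from fit")
  structure(list(
    outcome_name = outcome,
    formula = deparse(fml),
    coefficients = stats::coef(fit),
    standard_errors = ct[, "Std. Error"],
    group_estimate = ct[gRow, "Estimate"],
    group_se = ct[gRow, "Std. Error"],
    group_p = ct[gRow, "Pr(>|t|)"],
    n_used = nrow(df),
    transformation_applied = transformApplied,
    residual_normality_p = swP,
    dropped_covariates = dropped,
    model = fit), class = "GroupModelResult")
}

#' @export
print.GroupModelResult <- function(x, ...) {
  cat("Group model for ", x$outcome_name,
      if (x$transformation_applied != "none")
        paste0(" (", x$transformation_applied, "-transformed)"),
      ": n = ", x$n_used, "\n", sep = "")
  cat("  ", x$formula, "\n", sep = "")
  cat("  group (preterm - control): ",
      format(x$group_estimate, digits = 4), " (SE ",
      format(x$group_se, digits = 3), "), p = ",
      formatPValue(x$group_p), "\n", sep = "")
  invisible(x)
}

#' Quadratic-gestation group model for mean T2*
#'
#' Ordinary least squares of the (possibly log-transformed) outcome on
#' gestational age, its square, a preterm-group indicator and an ethnicity
#' covariate, reporting the group contrast and its two-sided p-value. The
#' outcome is checked for residual normality (Shapiro-Wilk at alpha 0.05)
#' and natural-log-transformed when the check fails, mirroring a
#' transform-if-non-normal analysis policy. Ethnicity is coded
#' White/non-White by default (`"full"` uses all five levels) and is
#' dropped, with a warning, if collinear with the design.
#'
#' @param table a data.frame with `group`, `ga_mri`, `ethnicity` and the
#'   outcome column (e.g. the merge of ROI summaries with the cohort
#'   table, or [simulateSummaryTable()] output).
#' @param outcome outcome column name (default `"mean_t2star"`).
#' @param ethnicityCoding `"binary"` (White/non-White, default) or
#'   `"full"`.
#' @param interaction include a group x gestation interaction
#'   (default FALSE).
#' @param transform `"auto"` (normality-gated, default), `"none"`, or
#'   `"log"`.
#' @return A `GroupModelResult` list: coefficients, standard errors, the
#'   group contrast (`group_estimate`, `group_se`, `group_p`), `n_used`,
#'   `transformation_applied`, `residual_normality_p`, and the underlying
#'   `lm` fit.
#' @export
fitQuadraticGroupModel <- function(table, outcome = "mean_t2star",
                                   ethnicityCoding = c("binary", "full"),
                                   interaction = FALSE,
                                   transform = c("auto", "none", "log")) {
  .fitGroupModel(table, outcome, quadratic = TRUE,
                 ethnicityCoding = match.arg(ethnicityCoding),
                 interaction = interaction, transform = match.arg(transform))
}

#' Linear-gestation group model for volume or skewness
#'
#' As [fitQuadraticGroupModel()] but with gestational age entering linearly
#' (no squared term), the model used for supratentorial brain volume and
#' histogram skewness.
#'
#' @inheritParams fitQuadraticGroupModel
#' @param outcome `"volume"` or `"skewness"` (any numeric column works).
#' @return A `GroupModelResult`.
#' @export
fitLinearGroupModel <- function(table, outcome = c("volume", "skewness"),
                                ethnicityCoding = c("binary", "full"),
                                interaction = FALSE,
                                transform = c("auto", "none", "log")) {
  if (length(outcome) > 1L) outcome <- outcome[1L]
  .fitGroupModel(table, outcome, quadratic = FALSE,
                 ethnicityCoding = match.arg(ethnicityCoding),
                 interaction = interaction, transform = match.arg(transform))
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance computed directly from group sizes,
#' means and standard deviations; the closed form used to cross-check
#' published summary tables.
#'
#' @param n1,mean1,sd1 first group.
#' @param n2,mean2,sd2 second group.
#' @return A list with `t`, `df`, `p` (two-sided).
#' @examples
#' tTestFromSummary(25, 32.2, 5.4, 67, 33.9, 4.1)  # t ~ -1.62, p ~ 0.11
#' @export
tTestFromSummary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

.fmtMeanSd <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                  stats::sd(x, na.rm = TRUE))
.fmtRange <- function(x) sprintf("%.1f-%.1f", min(x, na.rm = TRUE),
                                 max(x, na.rm = TRUE))

#' Compare demographics between groups
#'
#' Continuous variables (maternal age, BMI, gestation at MRI) are compared
#' with the two-sample t-test (pooled-variance Student's t by default,
#' Welch optionally); categorical variables (ethnicity, parity) with the
#' chi-squared test (no continuity correction). Output rows mirror a
#' demographics summary table: means (SD), ranges, and within-category
#' percentages with the category block's denominator.
#'
#' @param table a cohort data.frame (see [readCohortTable()]).
#' @param tTestVariant `"student"` (pooled, default) or `"welch"`.
#' @return A data.frame with columns `label`, `preterm`, `control`
#'   (formatted values), `p` (formatted) and `p_value` (numeric; `NA` on
#'   continuation rows). Chi-squared results with any expected cell count
#'   below 1 carry a small-sample warning.
#' @export
compareDemographics <- function(table, tTestVariant = c("student", "welch")) {
  tTestVariant <- match.arg(tTestVariant)
  g <- as.character(table$group)
  if (!any(g == "preterm") || !any(g == "control"))
    stop("both groups must be nonempty")
  pt <- table[g == "preterm", ]; ct <- table[g == "control", ]
  rows <- list()
  addRow <- function(label, pre, ctl, p = NA_real_, blankP = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, preterm = pre, control = ctl,
      p = if (blankP) "" else formatPValue(p), p_value = p)
  }
  contin <- function(label, col) {
    tt <- stats::t.test(pt[[col]], ct[[col]],
                        var.equal = (tTestVariant == "student"))
    addRow(paste0(label, ", mean (SD)"), .fmtMeanSd(pt[[col]]),
           .fmtMeanSd(ct[[col]]), tt$p.value)
    addRow(paste0(label, ", range"), .fmtRange(pt[[col]]),
           .fmtRange(ct[[col]]), blankP = TRUE)
  }
  categ <- function(label, fp, fc, levels) {
    tp <- table(factor(fp, levels = levels))
    tc <- table(factor(fc, levels = levels))
    keep <- (tp + tc) > 0
    m <- rbind(tp[keep], tc[keep])
    chi <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    if (any(chi$expected < 1))
      warning(label, ": expected cell counts < 1; chi-squared unreliable")
    addRow(paste0(label, " (%)"), "", "", chi$p.value)
    for (lv in levels) {
      addRow(paste0("  ", lv),
             sprintf("%.0f", 100 * tp[[lv]] / max(1, sum(tp))),
             sprintf("%.0f", 100 * tc[[lv]] / max(1, sum(tc))),
             blankP = TRUE)
    }
  }
  contin("Maternal age (years)", "maternal_age")
  contin("BMI", "bmi")
  categ("Ethnicity", as.character(pt$ethnicity), as.character(ct$ethnicity),
        .ethnicityLevels)
  parityBin <- function(p) ifelse(p >= 4, ">3", as.character(p))
  categ("Parity", parityBin(pt$parity), parityBin(ct$parity),
        c("0", "1", "2", "3", ">3"))
  contin("Gestation at MRI (weeks)", "ga_mri")
  do.call(rbind, rows)
}

.pctRow <- function(label, num, den) {
  if (den == 0) {
    warning(label, ": zero denominator")
    return(data.frame(label = label, numerator = num, denominator = den,
                      percent = NA_real_))
  }
  data.frame(label = label, numerator = num, denominator = den,
             percent = round(100 * num / den))
}

#' Outcome and placental-histology percentage table
#'
#' Percentages with the denominators a clinical outcome table uses:
#' delivery outcomes (live to discharge, intrapartum death, neonatal
#' death) over all preterm subjects; neonatal complications (IVH grade
#' 3/4, RDS, BPD, NEC) over liveborn preterm subjects; chorioamnionitis
#' over subjects with histology available; funisitis over subjects with
#' chorioamnionitis. Percentages are rounded to the nearest integer; a
#' zero denominator yields a blank (NA) cell with a warning.
#'
#' @param table a cohort data.frame (see [readCohortTable()]); only the
#'   preterm rows enter the table.
#' @return A data.frame with `label`, `numerator`, `denominator`,
#'   `percent`.
#' @export
summarizeOutcomes <- function(table) {
  pt <- table[as.character(table$group) == "preterm", ]
  n <- nrow(pt)
  s <- function(col, rows = pt) sum(rows[[col]] == 1, na.rm = TRUE)
  live <- pt[!is.na(pt$liveborn) & pt$liveborn == 1, ]
  hist <- pt[!is.na(pt$histology_available) & pt$histology_available == 1, ]
  cho <- pt[!is.na(pt$chorioamnionitis) & pt$chorioamnionitis == 1, ]
  rbind(
    .pctRow("Live to discharge", s("live_to_discharge"), n),
    .pctRow("Intrapartum death", sum(pt$liveborn == 0, na.rm = TRUE), n),
    .pctRow("Neonatal death",
            sum(pt$liveborn == 1 & pt$live_to_discharge == 0,
                na.rm = TRUE), n),
    .pctRow("IVH grade 3/4", s("ivh_grade34", live), nrow(live)),
    .pctRow("Respiratory distress syndrome", s("rds", live), nrow(live)),
    .pctRow("Bronchopulmonary dysplasia", s("bpd", live), nrow(live)),
    .pctRow("Necrotising enterocolitis", s("nec", live), nrow(live)),
    .pctRow("Histology available", nrow(hist), n),
    .pctRow("Chorioamnionitis", s("chorioamnionitis", hist), nrow(hist)),
    .pctRow("Funisitis", s("funisitis", cho), nrow(cho)))
}
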
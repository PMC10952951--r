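test_that("a noiseless quadratic outcome is interpolated exactly with zero group effect", {
  set.seed(1)
  ga <- runif(40, 19.3, 31.7)
  tab <- data.frame(group = rep(c("preterm", "control"), 20), ga_mri = ga,
                    ethnicity = "White",
                    mean_t2star = -0.6 * ga^2 + 26.4 * ga - 110.4)
  m <- fitQuadraticGroupModel(tab, transform = "none")
  expect_equal(unname(m$coefficients["I(ga_mri^2)"]), -0.6, tolerance = 1e-8)
  expect_equal(unname(m$coefficients["ga_mri"]), 26.4, tolerance = 1e-8)
  expect_equal(unname(m$coefficients["(Intercept)"]), -110.4,
               tolerance = 1e-8)
  expect_equal(unname(m$group_estimate), 0, tolerance = 1e-8)
})

test_that("a noiseless linear outcome recovers slope and intercept exactly", {
  set.seed(2)
  ga <- runif(30, 20, 31)
  tab <- data.frame(group = rep(c("preterm", "control"), 15), ga_mri = ga,
                    ethnicity = "White", volume = 2 * ga + 5)
  m <- fitLinearGroupModel(tab, "volume", transform = "none")
  expect_equal(unname(m$coefficients["ga_mri"]), 2, tolerance = 1e-8)
  expect_equal(unname(m$coefficients["(Intercept)"]), 5, tolerance = 1e-8)
  expect_equal(unname(m$group_estimate), 0, tolerance = 1e-8)
})

test_that("the group contrast is invariant to centring gestational age", {
  spec <- cohortSimSpec()
  tab <- simulateSummaryTable(spec, seed = 10L)
  m1 <- fitQuadraticGroupModel(tab, transform = "none")
  tab2 <- tab; tab2$ga_mri <- tab2$ga_mri - 25
  m2 <- fitQuadraticGroupModel(tab2, transform = "none")
  expect_equal(m1$group_estimate, m2$group_estimate, tolerance = 1e-8)
  expect_equal(m1$group_p, m2$group_p, tolerance = 1e-8)
})

test_that("a skewed outcome triggers the log transformation under the normality gate", {
  set.seed(3)
  n <- 200
  tab <- data.frame(group = rep(c("preterm", "control"), n / 2),
                    ga_mri = runif(n, 19.3, 31.7), ethnicity = "White",
                    mean_t2star = exp(rnorm(n, 5, 1.2)))
  m <- fitQuadraticGroupModel(tab)
  expect_equal(m$transformation_applied, "log")
  mNone <- fitQuadraticGroupModel(tab, transform = "none")
  expect_equal(mNone$transformation_applied, "none")
})

test_that("single-level ethnicity collinear with the design is dropped with a warning", {
  set.seed(4)
  # ethnicity perfectly aligned with group -> collinear with the contrast
  tab <- data.frame(group = rep(c("preterm", "control"), each = 20),
                    ga_mri = runif(40, 20, 31),
                    ethnicity = rep(c("Black", "White"), each = 20),
                    mean_t2star = rnorm(40, 160, 5))
  expect_warning(m <- fitQuadraticGroupModel(tab, transform = "none"),
                 "collinear")
  expect_true("ethnicity (collinear)" %in% m$dropped_covariates)
  expect_false(is.na(m$group_p))
})

test_that("power is monotone in the group effect and the null is at nominal level", {
  spec0 <- cohortSimSpec(groupDelta = 0)
  deltas <- c(0, -6, -12)
  nrep <- 150
  rates <- vapply(deltas, function(d) {
    spec <- cohortSimSpec(groupDelta = d)
    mean(vapply(seq_len(nrep), function(r) {
      tab <- simulateSummaryTable(spec, seed = 20000 + 137 * r + round(abs(d)))
      fitQuadraticGroupModel(tab, transform = "none")$group_p < 0.05
    }, TRUE))
  }, 0)
  expect_true(all(diff(rates) > 0))          # power grows with |delta|
  expect_lt(rates[1], 0.12)                  # null near nominal
  expect_gt(rates[3], 0.9)
})

test_that("pooled t and chi-squared match textbook closed forms", {
  r <- tTestFromSummary(25, 32.2, 5.4, 67, 33.9, 4.1)
  expect_equal(r$t, -1.618, tolerance = 0.001)
  expect_equal(r$df, 90)
  expect_equal(r$p, 0.109, tolerance = 0.002)   # consistent with printed 0.1
  # direct-formula oracle on another input
  r2 <- tTestFromSummary(10, 5, 1, 10, 6, 1)
  sp <- sqrt((9 * 1 + 9 * 1) / 18)
  expect_equal(r2$t, -1 / (sp * sqrt(0.2)), tolerance = 1e-12)
  chi <- chisq.test(matrix(c(10, 10, 10, 10), 2), correct = FALSE)
  expect_equal(unname(chi$statistic), 0)
  expect_equal(chi$p.value, 1)
})

test_that("identical duplicated groups give unit p-values and mirrored columns", {
  half <- do.call(rbind, lapply(1:10, function(i)
    cohortRow(sprintf("s%d", i), "preterm", ga_mri = 20 + i,
              maternal_age = 25 + i, bmi = 20 + i / 2,
              ethnicity = c("White", "Asian")[1 + i %% 2], parity = i %% 3)))
  other <- half
  other$group <- "control"
  other$subject_id <- paste0("c", 1:10)
  dem <- compareDemographics(rbind(half, other))
  expect_true(all(dem$p_value[!is.na(dem$p_value)] == 1))
  expect_identical(dem$preterm, dem$control)
})

test_that("outcome percentages use the correct denominators on the packaged fixture", {
  tab <- readCohortTable(fixturePath())
  out <- summarizeOutcomes(tab)
  pct <- function(lbl) out$percent[out$label == lbl]
  expect_equal(pct("Chorioamnionitis"), 81)     # 17 of 21 with histology
  expect_equal(pct("Funisitis"), 88)            # 15 of 17 with chorioamnionitis
  expect_equal(pct("Live to discharge"), 64)
  expect_equal(pct("Intrapartum death"), 24)
  expect_equal(pct("Neonatal death"), 12)
  expect_equal(pct("Respiratory distress syndrome"), 84)
  expect_equal(pct("IVH grade 3/4"), 5)
  expect_equal(pct("Bronchopulmonary dysplasia"), 21)
  expect_equal(pct("Necrotising enterocolitis"), 16)
})

test_that("all-zero adverse flags yield zero percentages and empty denominators warn", {
  zero <- do.call(rbind, lapply(1:5, function(i)
    cohortRow(sprintf("z%d", i), liveborn = 1, live_to_discharge = 1)))
  suppressWarnings(out <- summarizeOutcomes(zero))
  expect_true(all(out$percent[out$label %in%
    c("Intrapartum death", "Neonatal death", "IVH grade 3/4",
      "Respiratory distress syndrome", "Bronchopulmonary dysplasia",
      "Necrotising enterocolitis")] == 0))
  expect_equal(out$percent[out$label == "Live to discharge"], 100)
  # nobody with histology -> blank chorioamnionitis cell with a warning
  expect_true(is.na(out$percent[out$label == "Chorioamnionitis"]))
  expect_warning(summarizeOutcomes(zero), "zero denominator")
})
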
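test_that("mRS recoding groups 2-5 and drops deaths", {
  rec <- recode_mrs(c(0, 1, 2, 3, 4, 5, 6))
  expect_equal(as.character(rec), c("0", "1", "2-5", "2-5", "2-5", "2-5", NA))
  expect_equal(attr(rec, "n_deaths_dropped"), 1L)
  expect_true(is.ordered(rec))
  expect_error(recode_mrs(c(0, 7)), "0..6")
})

test_that("prepare_outcomes applies log10, drops non-positive rows with a count", {
  tab <- data.frame(y = c(1, 10, 100, 0, -2, 5), x = 1:6, age = 60 + 1:6,
                    sex = rep(0:1, 3), systolic_bp = 140 + 1:6)
  sp <- model_spec("y", "x", "linear", covariates = c("age", "sex",
                                                      "systolic_bp"),
                   transform = "log10")
  prep <- prepare_outcomes(tab, sp)
  expect_equal(prep$dropped$log_nonpositive, 2L)
  expect_equal(prep$n_used, 4L)
  expect_equal(prep$frame$y, c(0, 1, 2, log10(5)))   # log10(1) = 0
  # no missing data: n_used = cohort size
  tab2 <- tab[tab$y > 0, ]
  expect_equal(prepare_outcomes(tab2, sp)$n_used, nrow(tab2))
})

test_that("prepare_outcomes recodes mRS outcomes and reports death drops", {
  tab <- data.frame(mrs = c(0, 1, 2, 3, 4, 5, 6, 1), x = stats::rnorm(8),
                    age = 60 + 1:8)
  sp <- model_spec("mrs", "x", "ordinal", covariates = "age")
  prep <- prepare_outcomes(tab, sp)
  expect_equal(prep$dropped$mrs_deaths, 1L)
  expect_equal(prep$n_used, 7L)
  expect_equal(levels(prep$frame$mrs), c("0", "1", "2-5"))
})

test_that("linear fit recovers a planted coefficient with noiseless data", {
  set.seed(4)
  tab <- data.frame(x = stats::rnorm(50), age = stats::rnorm(50, 66, 11))
  tab$y <- 1 + 0.26 * tab$x + 0.01 * tab$age
  sp <- model_spec("y", "x", "linear", covariates = "age")
  # a noiseless fit is "essentially perfect"; the warning is the point here
  fit <- suppressWarnings(fit_model(prepare_outcomes(tab, sp)$frame, sp))
  expect_equal(fit$estimate, 0.26, tolerance = 1e-9)
  expect_equal(fit$family, "linear")
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
})

test_that("fitting is deterministic and invariant to row order", {
  tab <- make_cohort(planted_spec(200, "linear", 0.3, seed = 8))
  sp <- model_spec("y", "x", "linear", covariates = c("age", "sex",
                                                      "systolic_bp"),
                   transform = "log10")
  f1 <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  f2 <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  shuf <- tab[sample(nrow(tab)), ]
  f3 <- fit_model(prepare_outcomes(shuf, sp)$frame, sp)
  expect_equal(f3$estimate, f1$estimate, tolerance = 1e-10)
})

test_that("affine rescaling of a nuisance covariate leaves the estimate alone", {
  tab <- make_cohort(planted_spec(300, "linear", 0.3, seed = 12))
  sp <- model_spec("y", "x", "linear", covariates = c("age", "sex"),
                   transform = "log10")
  f1 <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  tab$age <- 3 * tab$age - 100
  f2 <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-9)
  # rescaling the predictor of interest transforms the coefficient inversely
  tab$x <- tab$x / 2
  f3 <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  expect_equal(f3$estimate, 2 * f1$estimate, tolerance = 1e-9)
})

test_that("exact collinearity raises a rank-deficiency error naming the column", {
  tab <- data.frame(y = stats::rnorm(40), x = stats::rnorm(40))
  tab$dup <- tab$x
  sp <- model_spec("y", "x", "linear", covariates = "dup")
  expect_error(fit_model(tab, sp), "rank-deficient.*dup")
})

test_that("perfect separation in logistic models is a structured error", {
  tab <- data.frame(x = c(stats::rnorm(20, -3), stats::rnorm(20, 3)))
  tab$y <- as.integer(tab$x > 0)
  sp <- model_spec("y", "x", "logistic", covariates = character(0))
  expect_error(fit_model(tab, sp), "separation")
})

test_that("ordinal fits report odds ratios with Wald CIs", {
  tab <- make_cohort(planted_spec(800, "ordinal", 0.9, seed = 21))
  sp <- model_spec("y", "x", "ordinal", covariates = c("age", "sex"),
                   mrs_recode = FALSE)
  fit <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  expect_equal(fit$family, "ordinal")
  expect_true(fit$ci_low < fit$estimate && fit$estimate < fit$ci_high)
  expect_equal(log(fit$estimate), 0.9, tolerance = 0.35)
})

test_that("parameter recovery bias shrinks as n grows", {
  bias_at <- function(n) {
    ests <- vapply(1:8, function(r) {
      tab <- make_cohort(planted_spec(n, "linear", 0.26, seed = 1000 + r))
      sp <- model_spec("y", "x", "linear",
                       covariates = c("age", "sex", "systolic_bp"),
                       transform = "log10")
      fit_model(prepare_outcomes(tab, sp)$frame, sp)$estimate
    }, numeric(1))
    abs(mean(ests) - 0.26)
  }
  expect_lt(bias_at(2000), 0.05)
})

test_that("the suite reproduces a single fit, honours longitudinal contracts", {
  tab <- make_cohort(default_cohort_spec(150, seed = 31))
  grid1 <- data.frame(outcome = "wmh_pct_icv", predictor = "arterial_pi",
                      family = "linear", transform = "log10",
                      longitudinal = FALSE, baseline = NA_character_,
                      stringsAsFactors = FALSE)
  suite <- run_analysis_suite(tab, grid1)
  expect_equal(nrow(suite), 1L)
  sp <- model_spec("wmh_pct_icv", "arterial_pi", "linear",
                   covariates = c("age", "sex", "systolic_bp"),
                   transform = "log10")
  direct <- fit_model(prepare_outcomes(tab, sp)$frame, sp)
  expect_equal(suite$estimate, direct$estimate, tolerance = 1e-12)
  expect_error(run_analysis_suite(tab, grid1[0, ]), "empty")

  grid2 <- data.frame(outcome = "followup_wmh_pct_icv",
                      predictor = "arterial_pi", family = "linear",
                      transform = "log10", longitudinal = TRUE,
                      baseline = "wmh_pct_icv", stringsAsFactors = FALSE)
  suite2 <- run_analysis_suite(tab, grid2)
  fit <- attr(fit_model(prepare_outcomes(
    tab, model_spec("followup_wmh_pct_icv", "arterial_pi", "linear",
                    covariates = c("age", "sex", "systolic_bp"),
                    transform = "log10", longitudinal = TRUE,
                    baseline = "wmh_pct_icv"))$frame,
    model_spec("followup_wmh_pct_icv", "arterial_pi", "linear",
               covariates = c("age", "sex", "systolic_bp"),
               transform = "log10", longitudinal = TRUE,
               baseline = "wmh_pct_icv")), "fit")
  expect_true("wmh_pct_icv" %in% names(stats::coef(fit)))
  expect_false(is.na(suite2$estimate))
})
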
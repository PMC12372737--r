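# Covariate-adjusted cross-sectional and longitudinal association models:
# linear (B, 95% CI), logistic and proportional-odds ordinal (OR, 95% CI),
# with the cohort-analysis preparation rules (log10 transforms, mRS
# regrouping, complete-case per model).

#' Specify one association model
#'
#' @param outcome Outcome column name. For longitudinal models this is the
#'   follow-up column.
#' @param predictor Predictor of interest.
#' @param family `"linear"`, `"logistic"` or `"ordinal"` (proportional odds,
#'   logit link).
#' @param covariates Adjustment covariates. Defaults to age, sex, systolic BP
#'   and baseline WMH %ICV (log10); any covariate equal to the outcome or the
#'   predictor of interest is dropped automatically.
#' @param transform `"none"` or `"log10"` applied to the outcome (and to a
#'   longitudinal baseline covariate of the same quantity).
#' @param longitudinal If `TRUE`, `baseline` is added as a covariate.
#' @param baseline Baseline column for longitudinal models.
#' @param mrs_recode Recode the outcome as mRS categories `{0, 1, 2-5}` and
#'   drop deaths (mRS 6). Defaults to `TRUE` when the outcome name contains
#'   `"mrs"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, predictor,
                       family = c("linear", "logistic", "ordinal"),
                       covariates = c("age", "sex", "systolic_bp",
                                      "log10_wmh_baseline"),
                       transform = c("none", "log10"),
                       longitudinal = FALSE, baseline = NULL,
                       mrs_recode = grepl("mrs", outcome, ignore.case = TRUE)) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (longitudinal && is.null(baseline))
    stop("longitudinal models need a baseline column", call. = FALSE)
  structure(list(outcome = outcome, predictor = predictor, family = family,
                 covariates = covariates, transform = transform,
                 longitudinal = longitudinal, baseline = baseline,
                 mrs_recode = isTRUE(mrs_recode)),
            class = "model_spec")
}

#' Recode modified Rankin Scale scores for ordinal analysis
#'
#' Groups the sparse categories 2-5 and drops deaths (score 6), returning an
#' ordered factor with levels `0 < 1 < 2-5` (6 becomes `NA`).
#'
#' @param x Integer mRS scores in 0..6.
#' @return Ordered factor; attribute `n_deaths_dropped` counts the 6s.
#' @export
#' @examples
#' recode_mrs(c(0, 1, 2, 3, 4, 5, 6))
recode_mrs <- function(x) {
  if (any(!is.na(x) & (x < 0 | x > 6)))
    stop("mRS scores must lie in 0..6", call. = FALSE)
  n6 <- sum(x == 6, na.rm = TRUE)
  out <- ifelse(is.na(x) | x == 6, NA_character_,
                ifelse(x >= 2, "2-5", as.character(x)))
  out <- factor(out, levels = c("0", "1", "2-5"), ordered = TRUE)
  attr(out, "n_deaths_dropped") <- n6
  out
}

#' Prepare the analysis frame for one model
#'
#' Applies the outcome transform (log10 rows with non-positive values are
#' excluded with a logged count, never silently), mRS regrouping, and
#' complete-case restriction to the model's variables.
#'
#' @param table Cohort data frame.
#' @param spec A [model_spec()].
#' @return List with `frame` (ready for [fit_model()]), `n_used`, and
#'   `dropped` (counts: `log_nonpositive`, `mrs_deaths`, `incomplete`).
#' @export
prepare_outcomes <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(c(spec$outcome, spec$predictor, spec$covariates,
                   if (spec$longitudinal) spec$baseline))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("columns absent from cohort table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frame <- table[vars]
  dropped <- list(log_nonpositive = 0L, mrs_deaths = 0L, incomplete = 0L)

  log10_col <- function(col) {
    bad <- !is.na(frame[[col]]) & frame[[col]] <= 0
    dropped$log_nonpositive <<- dropped$log_nonpositive + sum(bad)
    x <- frame[[col]]
    x[bad] <- NA
    log10(x)
  }
  if (spec$transform == "log10") {
    frame[[spec$outcome]] <- log10_col(spec$outcome)
    if (spec$longitudinal) frame[[spec$baseline]] <- log10_col(spec$baseline)
  }
  if (spec$mrs_recode) {
    rec <- recode_mrs(frame[[spec$outcome]])
    dropped$mrs_deaths <- attr(rec, "n_deaths_dropped")
    frame[[spec$outcome]] <- rec
  } else if (spec$family == "ordinal") {
    frame[[spec$outcome]] <- factor(frame[[spec$outcome]], ordered = TRUE)
  }
  complete <- stats::complete.cases(frame)
  dropped$incomplete <- sum(!complete) - dropped$log_nonpositive -
    dropped$mrs_deaths
  frame <- frame[complete, , drop = FALSE]
  if (spec$family == "ordinal")
    frame[[spec$outcome]] <- droplevels(frame[[spec$outcome]])
  list(frame = frame, n_used = nrow(frame), dropped = dropped)
}

# Effective adjustment set: declared covariates minus outcome/predictor/
# baseline collisions and columns absent from the frame are an error upstream.
.effective_covariates <- function(spec) {
  covs <- setdiff(spec$covariates,
                  c(spec$outcome, spec$predictor, spec$baseline))
  if (spec$longitudinal) covs <- c(covs, spec$baseline)
  covs
}

.wald <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = est - z * se, high = est + z * se,
    p = 2 * stats::pnorm(-abs(est / se)))
}

#' Fit one association model
#'
#' Linear models are ordinary least squares with t-based 95% CIs on the
#' coefficient (B) scale; logistic and proportional-odds (logit link,
#' `MASS::polr`) models report Wald 95% CIs exponentiated to odds ratios.
#' Fitting is deterministic given the frame.
#'
#' @param frame Prepared analysis frame from [prepare_outcomes()] (its
#'   `$frame` element) or any data frame holding the model's columns
#'   complete-case.
#' @param spec A [model_spec()].
#' @return A one-row data frame of class `model_result`: `outcome`,
#'   `predictor`, `family`, `estimate` (B or OR), `ci_low`, `ci_high`, `p`,
#'   `n_used`, plus attribute `diagnostics` (residual-normality p and max
#'   variance-inflation factor where applicable) and `fit` (the underlying
#'   model object).
#' @export
fit_model <- function(frame, spec) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(frame))
  covs <- .effective_covariates(spec)
  rhs <- paste(c(spec$predictor, covs), collapse = " + ")
  fml <- stats::as.formula(paste(spec$outcome, "~", rhs))
  n_par <- length(covs) + 2L
  if (nrow(frame) < n_par + 2L)
    stop("too few complete rows (", nrow(frame), ") for ", n_par,
         " parameters", call. = FALSE)
  if (spec$family != "ordinal" &&
      stats::var(as.numeric(frame[[spec$outcome]])) == 0)
    stop("outcome '", spec$outcome, "' has zero variance", call. = FALSE)

  check_rank <- function(cf) {
    if (anyNA(cf))
      stop("rank-deficient model: aliased term(s) ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  mm <- stats::model.matrix(fml, frame)
  vif <- max_vif_of(mm)

  if (spec$family == "linear") {
    fit <- stats::lm(fml, data = frame)
    check_rank(stats::coef(fit))
    est <- stats::coef(fit)[[spec$predictor]]
    ci <- stats::confint(fit, spec$predictor, level = 0.95)
    p <- summary(fit)$coefficients[spec$predictor, "Pr(>|t|)"]
    res <- stats::residuals(fit)
    sh <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
      stats::shapiro.test(res)$p.value else NA_real_
    out <- data.frame(outcome = spec$outcome, predictor = spec$predictor,
                      family = "linear", estimate = est,
                      ci_low = ci[1L], ci_high = ci[2L], p = p,
                      n_used = nrow(frame), stringsAsFactors = FALSE)
    diagnostics <- list(shapiro_p = sh, max_vif = vif)
  } else if (spec$family == "logistic") {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = frame, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    check_rank(stats::coef(fit))
    if (sep_warn)
      stop("possible perfect separation in logistic model for predictor '",
           spec$predictor, "'", call. = FALSE)
    est <- stats::coef(fit)[[spec$predictor]]
    se <- summary(fit)$coefficients[spec$predictor, "Std. Error"]
    w <- .wald(est, se)
    out <- data.frame(outcome = spec$outcome, predictor = spec$predictor,
                      family = "logistic", estimate = exp(est),
                      ci_low = exp(w[["low"]]), ci_high = exp(w[["high"]]),
                      p = w[["p"]], n_used = nrow(frame),
                      stringsAsFactors = FALSE)
    diagnostics <- list(max_vif = vif)
  } else {
    # polr's internal start-value glm emits a separation warning on small
    # sparse tables; the polr fit itself is still informative
    fit <- withCallingHandlers(
      MASS::polr(fml, data = frame, Hess = TRUE),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    if (!spec$predictor %in% rownames(cf))
      stop("rank-deficient model: predictor '", spec$predictor,
           "' dropped from ordinal fit", call. = FALSE)
    est <- cf[spec$predictor, "Value"]
    se <- cf[spec$predictor, "Std. Error"]
    w <- .wald(est, se)
    out <- data.frame(outcome = spec$outcome, predictor = spec$predictor,
                      family = "ordinal", estimate = exp(est),
                      ci_low = exp(w[["low"]]), ci_high = exp(w[["high"]]),
                      p = w[["p"]], n_used = nrow(frame),
                      stringsAsFactors = FALSE)
    diagnostics <- list(max_vif = vif)
  }
  attr(out, "diagnostics") <- diagnostics
  attr(out, "fit") <- fit
  class(out) <- c("model_result", class(out))
  out
}

# Maximum variance-inflation factor across non-intercept model-matrix columns.
max_vif_of <- function(mm) {
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  if (ncol(mm) < 2L) return(1)
  vifs <- vapply(seq_len(ncol(mm)), function(j) {
    y <- mm[, j]
    x <- cbind(1, mm[, -j, drop = FALSE])
    fit <- stats::lm.fit(x, y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1))
  max(vifs)
}

#' Run a grid of association models
#'
#' Fits one model per row of the grid and assembles the results in the
#' B / OR, 95% CI, p reporting format. No multiple-comparison correction is
#' applied; the `nominal_sig` column only marks p < 0.05.
#'
#' @param table Cohort data frame.
#' @param grid Data frame with columns `outcome`, `predictor`, `family`, and
#'   optionally `transform`, `longitudinal`, `baseline`, `label`; see
#'   [default_analysis_grid()].
#' @param covariates Adjustment set passed to every [model_spec()].
#' @return Data frame with one row per model: `label`, `outcome`,
#'   `predictor`, `family`, `estimate`, `ci_low`, `ci_high`, `p`, `n_used`,
#'   `nominal_sig`, `error` (message for models that failed, else `NA`);
#'   attribute `dropped` collects per-model exclusion counts.
#' @export
run_analysis_suite <- function(table, grid,
                               covariates = c("age", "sex", "systolic_bp",
                                              "log10_wmh_baseline")) {
  stopifnot(is.data.frame(table), is.data.frame(grid))
  if (!nrow(grid)) stop("empty model grid", call. = FALSE)
  grid$transform <- grid$transform %||% "none"
  grid$longitudinal <- grid$longitudinal %||% FALSE
  if (is.null(grid$baseline)) grid$baseline <- NA_character_
  if (is.null(grid$label))
    grid$label <- paste(grid$outcome, "~", grid$predictor)

  # ensure the default baseline-WMH covariate exists when requested
  if ("log10_wmh_baseline" %in% covariates) {
    if (!"log10_wmh_baseline" %in% names(table) &&
        "wmh_pct_icv" %in% names(table)) {
      x <- table$wmh_pct_icv
      x[!is.na(x) & x <= 0] <- NA
      table$log10_wmh_baseline <- log10(x)
    } else if (!"log10_wmh_baseline" %in% names(table)) {
      covariates <- setdiff(covariates, "log10_wmh_baseline")
    }
  }

  rows <- vector("list", nrow(grid))
  dropped <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sp <- model_spec(
      outcome = g$outcome, predictor = g$predictor, family = g$family,
      covariates = setdiff(covariates,
                           if (g$outcome == "wmh_pct_icv" ||
                               identical(g$baseline, "wmh_pct_icv"))
                             "log10_wmh_baseline" else character(0)),
      transform = g$transform,
      longitudinal = isTRUE(g$longitudinal),
      baseline = if (isTRUE(g$longitudinal)) g$baseline else NULL)
    res <- tryCatch({
      prep <- prepare_outcomes(table, sp)
      dropped[[i]] <- prep$dropped
      r <- fit_model(prep$frame, sp)
      r$label <- g$label
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(outcome = g$outcome, predictor = g$predictor,
                 family = g$family, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, n_used = NA_integer_,
                 label = g$label, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  out$nominal_sig <- !is.na(out$p) & out$p < 0.05
  rownames(out) <- NULL
  out <- out[c("label", "outcome", "predictor", "family", "estimate",
               "ci_low", "ci_high", "p", "n_used", "nominal_sig", "error")]
  attr(out, "dropped") <- dropped
  out
}

#' Default model grid
#'
#' Mirrors the study's analysis structure on the synthetic cohort columns:
#' (a) determinants of pulsatility — flow measures as outcomes, clinical
#' features as predictors; (b) baseline cross-sectional models — SVD measures
#' (log10) as outcomes with each stiffness measure (PI, RI, PTT, FVP) as a
#' separate predictor; (c) longitudinal models — follow-up outcome with its
#' baseline as covariate, pulsatility entering via PI only.
#'
#' @param flow_measures Stiffness/flow columns available in the table.
#' @param determinants Clinical predictor columns for part (a).
#' @return Grid data frame for [run_analysis_suite()].
#' @export
default_analysis_grid <- function(flow_measures = c("arterial_pi"),
                                  determinants = c("hypertension", "diabetes",
                                                   "hypercholesterolemia",
                                                   "smoking_ever")) {
  a <- expand.grid(outcome = flow_measures, predictor = determinants,
                   stringsAsFactors = FALSE)
  a$family <- "linear"; a$transform <- "none"; a$longitudinal <- FALSE
  a$baseline <- NA_character_

  b <- expand.grid(outcome = c("wmh_pct_icv", "bg_pvs_pct"),
                   predictor = flow_measures, stringsAsFactors = FALSE)
  b$family <- "linear"; b$transform <- "log10"; b$longitudinal <- FALSE
  b$baseline <- NA_character_

  cc <- data.frame(outcome = "followup_wmh_pct_icv",
                   predictor = grep("_pi$", flow_measures, value = TRUE),
                   stringsAsFactors = FALSE)
  if (nrow(cc)) {
    cc$family <- "linear"; cc$transform <- "log10"; cc$longitudinal <- TRUE
    cc$baseline <- "wmh_pct_icv"
  }

  d <- data.frame(outcome = c("svd_score", "mrs", "recurrent_event"),
                  predictor = flow_measures[1L],
                  family = c("ordinal", "ordinal", "logistic"),
                  transform = "none", longitudinal = FALSE,
                  baseline = NA_character_, stringsAsFactors = FALSE)
  out <- rbind(a, b, if (nrow(cc)) cc, d)
  out$label <- paste(out$outcome, "~", out$predictor)
  out
}
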
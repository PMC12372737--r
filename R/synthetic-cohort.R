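# Synthetic per-subject cohort tables with planted linear / logistic /
# proportional-odds effects, for validating the association models.

#' Specify a synthetic cohort
#'
#' Covariates are drawn independently from the given distributions (or taken
#' from supplied flow-metric columns); outcomes are generated from planted
#' linear predictors:
#' * `linear`: `y = intercept + X b + N(0, noise_sd)`; with
#'   `transform = "log10"` the linear model lives on the log10 scale and the
#'   stored column is `10^y` (as for WMH %ICV and PVS %ROI, which the
#'   analysis log-transforms back).
#' * `logistic`: `y ~ Bernoulli(plogis(intercept + X b))`.
#' * `ordinal`: latent `z = X b + Logistic(0, 1)` cut at `thresholds`,
#'   yielding categories `0, 1, ..., K` — a proportional-odds mechanism by
#'   construction.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param covariates Named list; each element is a list whose first element
#'   names the family (`"normal"`, `"lognormal"`, `"binary"`, `"uniform"`)
#'   followed by its parameters (`mean`/`sd`, `meanlog`/`sdlog`, `p`,
#'   `min`/`max`).
#' @param outcomes Named list; each element is a list with `family`
#'   (`"linear"`, `"logistic"`, `"ordinal"`), `coef` (named numeric vector of
#'   planted coefficients; names must be covariate, flow-metric or previously
#'   generated outcome columns, optionally `"log10:<column>"`), and
#'   per-family fields `intercept`, `noise_sd`, `transform`
#'   (`"none"`/`"log10"`), `thresholds`.
#' @param missingness_fraction Fraction of cells (outside `id`) set missing
#'   completely at random, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, covariates = list(), outcomes = list(),
                        missingness_fraction = 0, seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (missingness_fraction < 0 || missingness_fraction >= 1)
    stop("missingness_fraction must lie in [0, 1)", call. = FALSE)
  stopifnot(is.list(covariates), is.list(outcomes))
  structure(list(n_subjects = as.integer(n_subjects),
                 covariates = covariates, outcomes = outcomes,
                 missingness_fraction = as.numeric(missingness_fraction),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.draw_covariate <- function(cv, n) {
  fam <- cv[[1L]]
  g <- function(name, default = NULL) {
    if (!is.null(cv[[name]])) cv[[name]]
    else if (!is.null(default)) default
    else stop("covariate family '", fam, "' needs parameter '", name, "'",
              call. = FALSE)
  }
  switch(fam,
    normal = stats::rnorm(n, g("mean", 0), g("sd", 1)),
    lognormal = stats::rlnorm(n, g("meanlog", 0), g("sdlog", 1)),
    binary = stats::rbinom(n, 1L, g("p", 0.5)),
    uniform = stats::runif(n, g("min", 0), g("max", 1)),
    stop("unknown covariate family '", fam, "'", call. = FALSE))
}

# Resolve planted-coefficient predictor names against available columns,
# supporting a "log10:<col>" prefix.
.linear_predictor <- function(coef, tab) {
  if (!length(coef)) return(rep(0, nrow(tab)))
  lp <- rep(0, nrow(tab))
  valid <- setdiff(names(tab), "id")
  for (nm in names(coef)) {
    col <- sub("^log10:", "", nm)
    if (!col %in% valid)
      stop("unknown predictor '", nm, "' in effect sizes; valid names: ",
           paste(valid, collapse = ", "), call. = FALSE)
    x <- tab[[col]]
    if (startsWith(nm, "log10:")) x <- log10(x)
    lp <- lp + coef[[nm]] * x
  }
  lp
}

#' Generate a synthetic cohort table
#'
#' @param spec A [cohort_spec()].
#' @param flow_metrics Optional data frame of per-subject flow-metric columns
#'   (e.g. measured `arterial_pi`) with `spec$n_subjects` rows, merged in as
#'   predictors before outcomes are generated.
#' @return Data frame with one row per subject (`id` first), covariate,
#'   flow-metric and outcome columns; attribute `planted` stores the true
#'   coefficients, intercepts and thresholds.
#' @export
#' @examples
#' sp <- cohort_spec(100,
#'   covariates = list(age = list("normal", mean = 66, sd = 11)),
#'   outcomes = list(wmh_pct_icv = list(family = "linear", transform = "log10",
#'     intercept = -0.5, coef = c(age = 0.01), noise_sd = 0.3)))
#' head(make_cohort(sp))
make_cohort <- function(spec, flow_metrics = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    tab <- data.frame(id = sprintf("sub%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (nm in names(spec$covariates))
      tab[[nm]] <- .draw_covariate(spec$covariates[[nm]], n)
    if (!is.null(flow_metrics)) {
      flow_metrics <- as.data.frame(flow_metrics)
      if (nrow(flow_metrics) != n)
        stop("flow_metrics must have one row per subject", call. = FALSE)
      for (nm in names(flow_metrics)) tab[[nm]] <- flow_metrics[[nm]]
    }
    planted <- list()
    for (nm in names(spec$outcomes)) {
      oc <- spec$outcomes[[nm]]
      fam <- oc$family %||% "linear"
      coef <- oc$coef %||% numeric(0)
      lp <- .linear_predictor(coef, tab)
      if (fam == "linear") {
        tr <- oc$transform %||% "none"
        y <- (oc$intercept %||% 0) + lp +
          stats::rnorm(n, 0, oc$noise_sd %||% 1)
        tab[[nm]] <- if (tr == "log10") 10^y else y
        planted[[nm]] <- list(family = "linear", transform = tr,
                              intercept = oc$intercept %||% 0, coef = coef,
                              noise_sd = oc$noise_sd %||% 1)
      } else if (fam == "logistic") {
        p <- stats::plogis((oc$intercept %||% 0) + lp)
        tab[[nm]] <- stats::rbinom(n, 1L, p)
        planted[[nm]] <- list(family = "logistic",
                              intercept = oc$intercept %||% 0, coef = coef)
      } else if (fam == "ordinal") {
        th <- oc$thresholds
        if (is.null(th) || !length(th))
          stop("ordinal outcome '", nm, "' needs thresholds", call. = FALSE)
        z <- lp + stats::rlogis(n)
        tab[[nm]] <- as.integer(cut(z, c(-Inf, sort(th), Inf),
                                    labels = FALSE)) - 1L
        planted[[nm]] <- list(family = "ordinal", coef = coef,
                              thresholds = sort(th))
      } else stop("unknown outcome family '", fam, "'", call. = FALSE)
    }
    if (spec$missingness_fraction > 0) {
      cols <- setdiff(names(tab), "id")
      for (cl in cols) {
        miss <- stats::runif(n) < spec$missingness_fraction
        tab[[cl]][miss] <- NA
      }
    }
    attr(tab, "planted") <- planted
    tab
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default study-like cohort specification
#'
#' A cohort emulating the study table: age, sex, blood pressures, vascular
#' risk factors and an arterial-PI flow metric, with a planted effect of
#' arterial PI on baseline log10 WMH of B = 0.26, a logistic recurrent-event
#' outcome, an ordinal SVD score, and follow-up WMH depending on its
#' baseline. Used by the pipeline demo and the recovery simulations.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param b_wmh_pi Planted coefficient of arterial PI on log10 WMH %ICV.
#' @param with_flow_covariates If `TRUE` (default) arterial PI is drawn as a
#'   covariate; set `FALSE` when measured metrics are supplied to
#'   [make_cohort()] instead.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_subjects = 205L, seed = 1L, b_wmh_pi = 0.26,
                                with_flow_covariates = TRUE) {
  covs <- list(
    age = list("normal", mean = 66.4, sd = 11.1),
    sex = list("binary", p = 0.668),
    systolic_bp = list("normal", mean = 145, sd = 18),
    diastolic_bp = list("normal", mean = 82, sd = 10),
    hypertension = list("binary", p = 0.6),
    diabetes = list("binary", p = 0.15),
    hypercholesterolemia = list("binary", p = 0.5),
    smoking_ever = list("binary", p = 0.55),
    brain_volume = list("normal", mean = 1400, sd = 120))
  if (with_flow_covariates) {
    covs$arterial_pi <- list("normal", mean = 1.05, sd = 0.22)
    covs$csf_stroke_volume <- list("normal", mean = 0.55, sd = 0.15)
  }
  cohort_spec(
    n_subjects,
    covariates = covs,
    outcomes = list(
      wmh_pct_icv = list(
        family = "linear", transform = "log10", intercept = -1.1,
        coef = c(arterial_pi = b_wmh_pi, age = 0.012, systolic_bp = 0.002),
        noise_sd = 0.35),
      bg_pvs_pct = list(
        family = "linear", transform = "log10", intercept = -1.4,
        coef = c(arterial_pi = 0.12, age = 0.008), noise_sd = 0.2),
      followup_wmh_pct_icv = list(
        family = "linear", transform = "log10", intercept = 0.02,
        coef = c("log10:wmh_pct_icv" = 0.95), noise_sd = 0.05),
      svd_score = list(
        family = "ordinal", coef = c(arterial_pi = 0.4, age = 0.03),
        thresholds = c(1.4, 2.4, 3.2, 4.0)),
      mrs = list(
        family = "ordinal", coef = c(age = 0.02),
        thresholds = c(0.8, 2.0, 3.0, 3.8, 4.4, 5.0)),
      moca = list(
        family = "linear", intercept = 30.5, coef = c(age = -0.06),
        noise_sd = 2),
      recurrent_event = list(
        family = "logistic", intercept = -2.5,
        coef = c(age = 0.01, hypertension = 0.3))),
    seed = seed)
}
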
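#' Published comparative-regression coefficients
#'
#' The extant-data regression lines used for fossil projection, as published
#' (log10 scale throughout): lifespan ~ body mass per clade, msSMR ~
#' lifespan, growth constant K ~ lifespan, and blood-flow index Qi ~ body
#' mass. `ci95` is the published 95% confidence half-width where reported.
#' These are coefficients taken as given — refitting them requires the
#' underlying extant trait compilations and tree distributions, which this
#' package consumes as user-supplied inputs.
#'
#' @return data.frame with columns `response`, `predictor`, `clade`,
#'   `slope`, `intercept`, `ci95`, `r2`.
#' @export
reference_regressions <- function() {
  data.frame(
    response = c("lifespan_yr", "lifespan_yr", "mssmr", "mssmr",
                 "k_per_day", "k_per_day", "qi", "qi"),
    predictor = c("mass_g", "mass_g", "lifespan_yr", "lifespan_yr",
                  "lifespan_yr", "lifespan_yr", "mass_g", "mass_g"),
    clade = c("mammal", "reptile", "mammal", "reptile",
              "mammal", "reptile", "mammal", "non_varanid_reptile"),
    slope = c(0.26, 0.26, -0.237, -0.83, -0.692, -0.69, 0.513, 0.685),
    intercept = c(0.16, 0.60, -0.083, -0.31, -1.171, -2.523,
                  -6.104, -8.139),
    ci95 = c(0.05, 0.08, 0.07, 0.255, 0.101, 0.339, NA, NA),
    r2 = c(0.69, 0.46, 0.59, 0.43, 0.66, 0.43, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Look up one published regression as a fit object
#'
#' @param response,clade row selectors for [reference_regressions()].
#' @return a [published_fit()].
#' @export
reference_fit <- function(response, clade) {
  rr <- reference_regressions()
  row <- rr[rr$response == response & rr$clade == clade, ]
  if (nrow(row) != 1)
    stop("no published regression for response '", response,
         "', clade '", clade, "'")
  published_fit(slope = row$slope, intercept = row$intercept,
                ci95 = row$ci95, label = paste0(clade, ": log10(", response,
                                                ") ~ log10(", row$predictor, ")"))
}

#' Project a fossil lifespan onto an extant trait regression
#'
#' Evaluates a log10 trait ~ log10 lifespan regression at the fossil's
#' lifespan and back-transforms: `estimate = 10^(a + b * log10(t))`. For
#' fits carrying a coefficient covariance the 95% confidence band of the
#' regression mean at that abscissa is back-transformed into the interval
#' (the prediction-interval variant is available via `interval`); fits built
#' from published coefficients alone yield `NA` intervals.
#'
#' @param fit a `pgls_fit` of log10 trait on log10 lifespan.
#' @param lifespan_yr fossil maximum lifespan(s) in years (> 0).
#' @param interval `"confidence"` (uncertainty of the regression mean,
#'   default) or `"prediction"` (adds residual variance).
#' @param level interval level, default 0.95.
#' @return data.frame with `lifespan_yr`, `estimate`, `lower`, `upper` on
#'   the trait's natural scale.
#' @export
#' @examples
#' project_trait(reference_fit("mssmr", "reptile"), c(14, 9))
project_trait <- function(fit, lifespan_yr,
                          interval = c("confidence", "prediction"),
                          level = 0.95) {
  stopifnot(inherits(fit, "pgls_fit"))
  interval <- match.arg(interval)
  .check_positive(lifespan_yr, "lifespan")
  x0 <- log10(lifespan_yr)
  b <- fit$coefficients
  mu <- b[["intercept"]] + b[["slope"]] * x0
  if (!is.null(fit$cov_beta) && !anyNA(fit$cov_beta)) {
    pr <- predict_with_intervals(fit, x0, level = level)
    lo <- if (interval == "confidence") pr$ci_lower else pr$pi_lower
    hi <- if (interval == "confidence") pr$ci_upper else pr$pi_upper
  } else {
    lo <- hi <- rep(NA_real_, length(x0))
  }
  data.frame(lifespan_yr = lifespan_yr, estimate = 10^mu,
             lower = 10^lo, upper = 10^hi)
}

#' Captive-lifespan adjustment
#'
#' Maximum captive lifespans of small extant amniotes exceed maximum wild
#' lifespans by about 3.43 years (mammals) and 4.38 years (reptiles) per
#' taxon; adding the clade offset to a fossil's wild-type lifespan gives the
#' input for the captive-data sensitivity variant of the projection.
#'
#' @param lifespan_yr lifespan in years (> 0).
#' @param clade `"mammal"` or `"reptile"` (must name an offset).
#' @param offsets named numeric of per-clade offsets in years.
#' @return adjusted lifespan in years.
#' @export
#' @examples
#' captive_adjust(14, "mammal")   # 17.43
captive_adjust <- function(lifespan_yr, clade,
                           offsets = c(mammal = 3.43, reptile = 4.38)) {
  .check_positive(lifespan_yr, "lifespan")
  if (!clade %in% names(offsets))
    stop("unknown clade '", clade, "'; offsets exist for: ",
         paste(names(offsets), collapse = ", "))
  lifespan_yr + offsets[[clade]]
}

#' Classify a fossil against a regression's 95% prediction interval
#'
#' Classifies an observation against the prediction interval of a fitted
#' log10 trait ~ log10 mass regression at the fossil's mass, and reports the
#' signed log10 distance from the regression mean. Values exactly on a PI
#' boundary are classified `"inside"` (closed interval). Vectorized, so
#' passing every extant species' own mass/trait pair yields the per-species
#' distances needed to check "further above the mean than all members"
#' claims.
#'
#' @param fit a full `pgls_fit` (needs a coefficient covariance).
#' @param x0 log10 predictor value(s) (e.g. log10 mass in g).
#' @param y0 log10 observed trait value(s).
#' @param level PI level, default 0.95.
#' @return data.frame with `x0`, `y0`, `status` (inside/above/below) and
#'   `distance` (signed log10 offset from the regression mean).
#' @export
pi_membership <- function(fit, x0, y0, level = 0.95) {
  pr <- predict_with_intervals(fit, x0, level = level)
  status <- ifelse(y0 > pr$pi_upper, "above",
                   ifelse(y0 < pr$pi_lower, "below", "inside"))
  data.frame(x0 = x0, y0 = y0, status = status,
             distance = y0 - pr$fit)
}

#' Assemble a fossil physiological profile
#'
#' Bundles the inference chain for one fossil taxon: cementum-based maximum
#' lifespan, the dentary-derived mass range, reptile- and mammal-derived
#' msSMR and K projections (with intervals where the supplied fits carry
#' covariances), and optionally the femoral blood-flow index.
#'
#' @param taxon taxon name.
#' @param lifespan_yr maximum-lifespan estimate, integer years >= 1.
#' @param dentary_mm dentary length in mm.
#' @param fits named list of projection fits; recognized names are
#'   `mssmr_mammal`, `mssmr_reptile`, `k_mammal`, `k_reptile` (default: the
#'   published coefficients via [reference_fit()]).
#' @param qi optional blood-flow index, mm^3.
#' @return object of class `fossil_profile`.
#' @export
#' @examples
#' fossil_profile("Morganucodon", lifespan_yr = 14, dentary_mm = 20)
fossil_profile <- function(taxon, lifespan_yr, dentary_mm,
                           fits = list(
                             mssmr_mammal = reference_fit("mssmr", "mammal"),
                             mssmr_reptile = reference_fit("mssmr", "reptile"),
                             k_mammal = reference_fit("k_per_day", "mammal"),
                             k_reptile = reference_fit("k_per_day", "reptile")),
                           qi = NULL) {
  if (length(lifespan_yr) != 1 || lifespan_yr < 1 ||
      lifespan_yr != as.integer(lifespan_yr))
    stop("lifespan_yr must be a single integer >= 1")
  mass <- estimate_fossil_mass(taxon, dentary_mm)
  proj <- lapply(fits, project_trait, lifespan_yr = lifespan_yr)
  out <- list(taxon = taxon, lifespan_yr = as.integer(lifespan_yr),
              mass = mass, projections = proj, qi = qi)
  class(out) <- "fossil_profile"
  out
}

#' @export
print.fossil_profile <- function(x, ...) {
  cat("Fossil physiological profile:", x$taxon, "\n")
  cat(sprintf("  max lifespan: %d yr (cementum increment counts)\n",
              x$lifespan_yr))
  m <- x$mass
  cat(sprintf("  body mass: %.1f-%.1f g (mean %.1f g)\n",
              display_grams(m$mass_min_g), display_grams(m$mass_max_g),
              display_grams(m$mass_mean_g)))
  for (nm in names(x$projections)) {
    p <- x$projections[[nm]]
    cat(sprintf("  %s: %.4g", nm, p$estimate))
    if (!is.na(p$lower))
      cat(sprintf(" (95%% CI %.4g-%.4g)", p$lower, p$upper))
    cat("\n")
  }
  if (!is.null(x$qi)) cat(sprintf("  Qi: %.4g mm^3\n", x$qi))
  invisible(x)
}
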
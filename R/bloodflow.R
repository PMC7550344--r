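#' Foramen measurement set for one femur
#'
#' @param specimen specimen identifier.
#' @param femur_length_mm femur length in mm (measured, or reconstructed
#'   via [femur_length_from_diameter()]).
#' @param radii_mm positive vector of nutrient-foramen minimal radii, mm.
#' @param group group label (`"mammal"`, `"non_varanid_reptile"`,
#'   `"varanid"`, `"fossil"`, ...).
#' @return object of class `foramen_set`.
#' @export
foramen_set <- function(specimen, femur_length_mm, radii_mm,
                        group = "unknown") {
  .check_positive(femur_length_mm, "femur length")
  if (!length(radii_mm)) stop("at least one foramen radius is required")
  .check_positive(radii_mm, "foramen radii")
  out <- list(specimen = as.character(specimen), group = as.character(group),
              femur_length_mm = femur_length_mm,
              radii_mm = as.numeric(radii_mm))
  class(out) <- "foramen_set"
  out
}

#' Femoral blood-flow index Qi
#'
#' `Qi = r^4 / L`, the classic nutrient-foramen proxy for maximum metabolic
#' rate, with `r` the foramen radius and `L` the femur length (both mm; Qi
#' in mm^3). When a femur carries multiple foramina the radii are summed
#' *before* raising to the fourth power (`rule = "sum_radii"`, the default,
#' treating the sum as the total entry potential of nutrient circulation);
#' the physically alternative per-foramen rule `sum(r_i^4)/L` is available
#' as `rule = "sum_fourth_powers"`. Qi scales as length^3, so mm inputs and
#' cm inputs differ by exactly 10^3.
#'
#' @param fs a [foramen_set()], or a numeric vector of radii (mm) if
#'   `femur_length_mm` is given.
#' @param femur_length_mm femur length in mm (ignored when `fs` is a
#'   `foramen_set`).
#' @param rule radius aggregation rule, see above.
#' @return Qi in mm^3.
#' @export
#' @examples
#' blood_flow_index(c(0.03, 0.04), femur_length_mm = 15)  # 1.6007e-6 mm^3
blood_flow_index <- function(fs, femur_length_mm = NULL,
                             rule = c("sum_radii", "sum_fourth_powers")) {
  rule <- match.arg(rule)
  if (inherits(fs, "foramen_set")) {
    radii <- fs$radii_mm
    L <- fs$femur_length_mm
  } else {
    radii <- as.numeric(fs)
    L <- femur_length_mm
    if (is.null(L)) stop("femur_length_mm required with raw radii")
    if (!length(radii)) stop("at least one foramen radius is required")
    .check_positive(radii, "foramen radii")
    .check_positive(L, "femur length")
  }
  if (rule == "sum_radii") sum(radii)^4 / L else sum(radii^4) / L
}

#' Per-group blood-flow regressions with ANCOVA
#'
#' Plain (non-phylogenetic) GLS of log10 Qi on log10 body mass within each
#' group, plus the four-model ANCOVA ladder across the first two groups.
#' Non-phylogenetic regression is appropriate here because lambda estimation
#' on such data shows no phylogenetic signal.
#'
#' @param data data.frame with columns `species`, `group`, `mass_g`, `qi`.
#' @return list with `fits` (named per-group `pgls_fit`s) and `ancova`
#'   (an `ancova_ladder` across the first two group levels, or `NULL` if
#'   fewer than two groups).
#' @export
qi_group_regression <- function(data) {
  need <- c("species", "group", "mass_g", "qi")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  .check_positive(data$mass_g, "body mass")
  .check_positive(data$qi, "Qi")
  data$group <- factor(data$group)
  fits <- lapply(levels(data$group), function(g) {
    sub <- data[data$group == g, ]
    if (nrow(sub) < 3) stop("group '", g, "' has fewer than 3 species")
    fit_gls_plain(log10(sub$mass_g), log10(sub$qi))
  })
  names(fits) <- levels(data$group)
  anc <- NULL
  if (nlevels(data$group) >= 2) {
    two <- data[data$group %in% levels(data$group)[1:2], ]
    anc <- fit_gls_plain(log10(two$mass_g), log10(two$qi),
                         group = droplevels(two$group))
  }
  list(fits = fits, ancova = anc)
}

#' Position a fossil relative to group regression lines
#'
#' Signed vertical residual (log10 units) of the fossil's Qi from each
#' group's regression mean at the fossil's body mass: positive means higher
#' Qi for its mass than the group mean predicts. When `extant` is supplied,
#' every extant species' own residual from its group line is also returned,
#' so claims of the form "further above the group mean than all members"
#' are directly checkable.
#'
#' @param fits named list of per-group `pgls_fit`s (as from
#'   [qi_group_regression()]).
#' @param fossil_mass_g fossil body mass, g.
#' @param fossil_qi fossil Qi, mm^3.
#' @param extant optional data.frame `species`, `group`, `mass_g`, `qi`.
#' @return list with `fossil` (data.frame group/residual) and `extant`
#'   (data.frame of per-species residuals, or `NULL`).
#' @export
position_fossil <- function(fits, fossil_mass_g, fossil_qi, extant = NULL) {
  .check_positive(fossil_mass_g, "body mass")
  .check_positive(fossil_qi, "Qi")
  resid_from <- function(fit, mass, qi) {
    b <- fit$coefficients
    log10(qi) - (b[["intercept"]] + b[["slope"]] * log10(mass))
  }
  fossil <- data.frame(
    group = names(fits),
    residual = vapply(fits, resid_from, numeric(1),
                      mass = fossil_mass_g, qi = fossil_qi),
    row.names = NULL)
  ext <- NULL
  if (!is.null(extant)) {
    ext <- extant[extant$group %in% names(fits), ]
    ext$residual <- mapply(function(g, m, q) resid_from(fits[[g]], m, q),
                           as.character(ext$group), ext$mass_g, ext$qi)
  }
  list(fossil = fossil, extant = ext)
}
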
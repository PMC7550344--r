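## Generalized least squares with a phylogenetic covariance structure.
##
## The covariance of the residuals is sigma^2 * V(lambda), where V is the
## shared-path matrix of the tree with off-diagonals scaled by Pagel's
## lambda (see vcv_pagel). Estimation whitens the model through the Cholesky
## factor of V and solves the weighted projection
##   beta = (X' V^-1 X)^-1 X' V^-1 y
## by QR on the whitened design. Lambda, when estimated, maximizes the
## restricted (REML) log-likelihood profiled over sigma^2 by golden-section
## search on [0, 1].

.gls_core <- function(X, y, V) {
  n <- nrow(X); p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e)
    chol(V + diag(1e-10 * mean(diag(V)), n)))
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, as.numeric(y), transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p) stop("singular design matrix")
  beta <- qr.coef(qrX, yw)
  rss <- sum((yw - Xw %*% beta)^2)
  list(beta = beta, rss = rss, XtViX = crossprod(Xw),
       logdetV = 2 * sum(log(diag(R))), n = n, p = p)
}

.reml_ll <- function(g) {
  df <- g$n - g$p
  s2 <- g$rss / df
  ldx <- as.numeric(determinant(g$XtViX, logarithm = TRUE)$modulus)
  -0.5 * (df * log(2 * pi * s2) + g$logdetV + ldx + df)
}

.ml_ll <- function(g) {
  s2 <- g$rss / g$n
  -0.5 * (g$n * log(2 * pi * s2) + g$logdetV + g$n)
}

.pagel_V <- function(V1, lambda) {
  d <- diag(V1)
  V <- V1 * lambda
  diag(V) <- d
  V
}

# golden-section maximization of the profile likelihood over lambda in [0,1]
.optimize_lambda <- function(X, y, V1, criterion = c("REML", "ML"),
                             iter = 40, tol = 1e-6) {
  criterion <- match.arg(criterion)
  llfun <- if (criterion == "REML") .reml_ll else .ml_ll
  obj <- function(lam) llfun(.gls_core(X, y, .pagel_V(V1, lam)))
  phi <- (sqrt(5) - 1) / 2
  a <- 0; b <- 1
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- obj(c1); f2 <- obj(c2)
  for (i in seq_len(iter)) {
    if (b - a < tol) break
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- obj(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- obj(c1)
    }
  }
  cand <- c(0, (a + b) / 2, 1)
  ll <- vapply(cand, obj, numeric(1))
  list(lambda = cand[which.max(ll)], loglik = max(ll))
}

# align named trait vectors with a tree; returns ordered data and V(lambda=1)
.align_with_tree <- function(x, y, tree, group = NULL) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by species")
  names(x) <- normalize_taxa(names(x))
  names(y) <- normalize_taxa(names(y))
  sp <- intersect(names(x), names(y))
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  tr <- if (length(sp) < ape::Ntip(tree))
    suppressWarnings(prune_to_taxa(tree, sp)) else tree
  ord <- tr$tip.label
  out <- list(x = x[ord], y = y[ord], tree = tr,
              V1 = vcv_pagel(tr, 1))
  if (!is.null(group)) {
    if (is.null(names(group))) stop("group must be named by species")
    names(group) <- normalize_taxa(names(group))
    out$group <- factor(group[ord])
  }
  out
}

.new_fit <- function(g, V, lambda, lambda_mode, model, n, tree_id = NA,
                     fallback = FALSE, coef_names = NULL) {
  p <- g$p
  df <- n - p
  sigma2 <- g$rss / df
  cov_beta <- solve(g$XtViX) * sigma2
  se <- sqrt(diag(cov_beta))
  # overall F against the intercept-only GLS model under the same V
  g0 <- .gls_core(matrix(1, n, 1), attr(g, "y"), V)
  Fstat <- ((g0$rss - g$rss) / (p - 1)) / sigma2
  beta <- as.numeric(g$beta)
  names(beta) <- coef_names %||% names(g$beta)
  names(se) <- names(beta)
  fit <- list(
    coefficients = beta, se = se,
    ci95 = stats::qt(0.975, df) * se,
    sigma2 = sigma2, df_residual = df, n = n,
    r_squared = 1 - g$rss / g0$rss,
    f_statistic = Fstat, f_df = c(p - 1, df),
    p_value = stats::pf(Fstat, p - 1, df, lower.tail = FALSE),
    lambda = lambda, lambda_mode = lambda_mode,
    loglik_reml = .reml_ll(g), loglik_ml = .ml_ll(g),
    rss = g$rss, cov_beta = cov_beta,
    tip_variance = mean(diag(V)),
    model = model, tree_id = tree_id, fallback_gls = fallback
  )
  class(fit) <- "pgls_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_with_V <- function(x, y, V, lambda, lambda_mode, model,
                        tree_id = NA, fallback = FALSE) {
  X <- cbind(1, x)
  g <- .gls_core(X, y, V)
  attr(g, "y") <- y
  .new_fit(g, V, lambda, lambda_mode, model, length(y), tree_id,
           fallback, coef_names = c("intercept", "slope"))
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = a + b x` by GLS with residual covariance `sigma^2 * V(lambda)`,
#' where `V(lambda)` is the Pagel-transformed shared-path matrix of the tree.
#' With `lambda = "REML"` (default) lambda is estimated by maximizing the
#' restricted likelihood over `[0, 1]`; a fixed numeric lambda is also
#' accepted. When the estimated lambda falls below `fallback_threshold`
#' (default 0.001) there is no detectable phylogenetic signal and the model
#' is refit as plain GLS with lambda = 0, flagged via `$fallback_gls`.
#'
#' The reported r-squared is `1 - RSS_V / TSS_V` computed in the V-whitened
#' space (the intercept-only GLS model supplies TSS_V); with lambda = 0 on an
#' ultrametric tree this reduces to the ordinary OLS r-squared.
#'
#' @param x,y numeric vectors named by species (log10 scale by convention).
#' @param tree a rooted `phylo` with branch lengths covering the species.
#' @param lambda `"REML"`, `"ML"`, or a fixed value in `[0, 1]`.
#' @param fallback_threshold lambda below which the plain-GLS fallback fires.
#' @param tree_id optional identifier stored in the fit (provenance).
#' @return an object of class `pgls_fit`: coefficients (`intercept`,
#'   `slope`), standard errors, 95% CI half-widths, r-squared, overall F and
#'   p against the intercept-only model, lambda, residual variance, REML/ML
#'   log-likelihoods and the coefficient covariance used for prediction.
#' @export
fit_pgls <- function(x, y, tree, lambda = "REML",
                     fallback_threshold = 0.001, tree_id = NA) {
  al <- .align_with_tree(x, y, tree)
  n <- length(al$y)
  if (n < 3) stop("need at least 3 species")
  X <- cbind(1, al$x)
  if (is.character(lambda)) {
    opt <- .optimize_lambda(X, al$y, al$V1, criterion = lambda)
    lam <- opt$lambda
    mode <- lambda
    if (lam < fallback_threshold) {
      fit <- .fit_with_V(al$x, al$y, diag(n), lambda = 0, lambda_mode = mode,
                         model = "GLS (no phylogenetic signal)",
                         tree_id = tree_id, fallback = TRUE)
      fit$lambda <- lam
      return(fit)
    }
  } else {
    if (lambda < 0 || lambda > 1)
      stop("fixed lambda must lie in [0, 1]")
    lam <- lambda
    mode <- "fixed"
  }
  .fit_with_V(al$x, al$y, .pagel_V(al$V1, lam), lam, mode, "PGLS",
              tree_id = tree_id)
}

#' Plain (non-phylogenetic) GLS regression or ANCOVA
#'
#' The same estimation pipeline as [fit_pgls()] with an identity covariance:
#' appropriate when lambda estimation shows no phylogenetic signal. With a
#' `group` factor the full four-model ANCOVA ladder is returned (see
#' [phylo_ancova()]).
#'
#' @param x,y numeric vectors (names optional; matched positionally when
#'   unnamed).
#' @param group optional factor with two levels for the ANCOVA ladder.
#' @return a `pgls_fit`, or an `ancova_ladder` when `group` is given.
#' @export
fit_gls_plain <- function(x, y, group = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  if (length(x) != n) stop("x and y lengths differ")
  if (is.null(group))
    return(.fit_with_V(as.numeric(x), as.numeric(y), diag(n),
                       lambda = NA_real_, lambda_mode = "none",
                       model = "GLS (identity)"))
  .ancova_with_V(as.numeric(x), as.numeric(y), factor(group), diag(n),
                 lambda = NA_real_, lambda_mode = "none")
}

#' Fit one regression across a distribution of trees
#'
#' Fits [fit_pgls()] on every tree and returns the fit with the largest
#' overall F statistic (ties broken by lowest index). All per-tree F values
#' are retained for audit.
#'
#' @param x,y named numeric vectors as in [fit_pgls()].
#' @param trees a list of `phylo` objects or a `multiPhylo`.
#' @param ... passed to [fit_pgls()].
#' @return list with elements `fit` (the selected `pgls_fit`), `index`, and
#'   `f_values`.
#' @export
fit_over_trees <- function(x, y, trees, ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree list")
  fits <- lapply(seq_along(trees), function(i)
    fit_pgls(x, y, trees[[i]], tree_id = i, ...))
  fv <- vapply(fits, function(f) f$f_statistic, numeric(1))
  idx <- which.max(fv)   # which.max takes the first maximum: lowest index
  list(fit = fits[[idx]], index = idx, f_values = fv)
}

#' Predicted mean with confidence and prediction intervals
#'
#' The confidence interval uses the coefficient covariance of the fit; the
#' prediction interval additionally carries the residual variance of a new,
#' phylogenetically independent observation (`sigma2` times the mean tip
#' variance of the fitted covariance), so PI always contains CI. Intervals
#' use the t distribution on the fit's residual degrees of freedom.
#'
#' @param fit a `pgls_fit` with two coefficients (intercept, slope).
#' @param x0 numeric vector of predictor values (log10 scale).
#' @param level coverage level, default 0.95.
#' @return data.frame with `x0`, `fit`, `ci_lower`, `ci_upper`, `pi_lower`,
#'   `pi_upper`.
#' @export
predict_with_intervals <- function(fit, x0, level = 0.95) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (length(fit$coefficients) != 2)
    stop("prediction requires a simple intercept+slope fit")
  if (is.null(fit$cov_beta) || anyNA(fit$cov_beta))
    stop("fit carries no coefficient covariance (published coefficients?)")
  X0 <- cbind(1, x0)
  mu <- as.numeric(X0 %*% fit$coefficients)
  var_mean <- rowSums((X0 %*% fit$cov_beta) * X0)
  var_pred <- var_mean + fit$sigma2 * fit$tip_variance
  tq <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  data.frame(x0 = x0, fit = mu,
             ci_lower = mu - tq * sqrt(var_mean),
             ci_upper = mu + tq * sqrt(var_mean),
             pi_lower = mu - tq * sqrt(var_pred),
             pi_upper = mu + tq * sqrt(var_pred))
}

.ancova_designs <- function(x, g) {
  gi <- as.numeric(g) - 1
  list(
    common    = cbind(intercept = 1, slope = x),
    slope     = cbind(intercept = 1, slope = x, slope_diff = x * gi),
    intercept = cbind(intercept = 1, slope = x, intercept_diff = gi),
    full      = cbind(intercept = 1, slope = x, intercept_diff = gi,
                      slope_diff = x * gi)
  )
}

.ancova_with_V <- function(x, y, group, V, lambda, lambda_mode,
                           alpha = 0.05, tree_id = NA) {
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  if (any(table(group) < 3)) stop("each group needs at least 3 members")
  designs <- .ancova_designs(x, group)
  n <- length(y)
  fits <- lapply(names(designs), function(m) {
    g <- .gls_core(designs[[m]], y, V)
    attr(g, "y") <- y
    .new_fit(g, V, lambda, lambda_mode, paste0("ancova_", m), n,
             tree_id = tree_id, coef_names = colnames(designs[[m]]))
  })
  names(fits) <- names(designs)
  base <- fits$common
  cmp <- do.call(rbind, lapply(c("slope", "intercept", "full"), function(m) {
    f <- fits[[m]]
    dfe <- length(f$coefficients) - length(base$coefficients)
    Fst <- ((base$rss - f$rss) / dfe) / (f$rss / f$df_residual)
    lrt <- 2 * (f$loglik_ml - base$loglik_ml)
    data.frame(
      model = m, df_extra = dfe,
      F = Fst, df1 = dfe, df2 = f$df_residual,
      p = stats::pf(Fst, dfe, f$df_residual, lower.tail = FALSE),
      lrt = lrt, p_lrt = stats::pchisq(lrt, dfe, lower.tail = FALSE),
      partial_eta_sq = (base$rss - f$rss) / base$rss
    )
  }))
  sig <- cmp[cmp$p < alpha, , drop = FALSE]
  selected <- if (!nrow(sig)) "common" else sig$model[which.min(sig$p)]
  out <- list(fits = fits, comparisons = cmp, selected = selected,
              lambda = lambda, lambda_mode = lambda_mode, alpha = alpha,
              n = n, group_levels = levels(group), tree_id = tree_id)
  class(out) <- "ancova_ladder"
  out
}

#' Phylogenetic analysis of covariance across two clades
#'
#' Fits a ladder of four GLS models of increasing complexity under a shared
#' phylogenetic covariance: a baseline with one slope and one intercept for
#' the whole data set, a varying-slope model, a varying-intercept model, and
#' a model varying both. Each richer model is compared to the baseline by an
#' F test on the drop in weighted residual sum of squares (a likelihood-ratio
#' test is reported alongside but not used for selection). Lambda is
#' estimated once, by REML on the richest model, and held fixed across the
#' ladder so the nested comparisons share one covariance.
#'
#' The reported `partial_eta_sq` is the proportional RSS reduction relative
#' to the baseline; this definition is documented rather than validated
#' against any external convention.
#'
#' @param x,y numeric vectors named by species (log10 scale).
#' @param group two-level factor (e.g. mammal/reptile) named by species.
#' @param tree a rooted `phylo` covering the species (typically a grafted
#'   composite tree).
#' @param lambda `"REML"`, `"ML"` or a fixed value in `[0, 1]`.
#' @param alpha significance level used when picking the selected model.
#' @param fallback_threshold estimated lambda below which the ladder is run
#'   as plain (identity-covariance) GLS ANCOVA.
#' @return an `ancova_ladder`: per-model `pgls_fit`s, a comparison table
#'   against the baseline, and the selected model label.
#' @export
phylo_ancova <- function(x, y, group, tree, lambda = "REML", alpha = 0.05,
                         fallback_threshold = 0.001) {
  al <- .align_with_tree(x, y, tree, group = group)
  n <- length(al$y)
  if (nlevels(al$group) != 2) stop("group must have exactly 2 levels")
  if (any(table(al$group) < 3)) stop("each group needs at least 3 members")
  X_full <- .ancova_designs(al$x, al$group)$full
  if (is.character(lambda)) {
    opt <- .optimize_lambda(X_full, al$y, al$V1, criterion = lambda)
    lam <- opt$lambda
    mode <- lambda
    if (lam < fallback_threshold) {
      out <- .ancova_with_V(al$x, al$y, al$group, diag(n), lambda = lam,
                            lambda_mode = mode, alpha = alpha)
      out$fallback_gls <- TRUE
      return(out)
    }
  } else {
    if (lambda < 0 || lambda > 1) stop("fixed lambda must lie in [0, 1]")
    lam <- lambda
    mode <- "fixed"
  }
  .ancova_with_V(al$x, al$y, al$group, .pagel_V(al$V1, lam), lam, mode,
                 alpha = alpha)
}

#' Construct a fit from published regression coefficients
#'
#' Wraps a printed slope/intercept pair (e.g. from a published comparative
#' regression) as a minimal `pgls_fit` usable by [project_trait()] and
#' [position_fossil()]. No coefficient covariance is available, so interval
#' computations are not possible from such a fit; an optional published 95%
#' CI half-width on the mean can be carried for reporting.
#'
#' @param slope,intercept regression coefficients on the log10 scale.
#' @param ci95 optional published 95% CI half-width (slope), carried as-is.
#' @param label optional model label.
#' @return a `pgls_fit` with `NA` inferential fields.
#' @export
published_fit <- function(slope, intercept, ci95 = NA_real_, label = "published") {
  fit <- list(coefficients = c(intercept = intercept, slope = slope),
              se = c(intercept = NA_real_, slope = NA_real_),
              ci95 = c(intercept = NA_real_, slope = ci95),
              sigma2 = NA_real_, df_residual = NA_integer_, n = NA_integer_,
              r_squared = NA_real_, f_statistic = NA_real_,
              f_df = c(NA_real_, NA_real_), p_value = NA_real_,
              lambda = NA_real_, lambda_mode = "published",
              loglik_reml = NA_real_, loglik_ml = NA_real_, rss = NA_real_,
              cov_beta = NULL, tip_variance = NA_real_,
              model = label, tree_id = NA, fallback_gls = FALSE)
  class(fit) <- "pgls_fit"
  fit
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat(x$model,
      if (!is.na(x$lambda)) sprintf("(lambda = %.3f, %s)", x$lambda,
                                    x$lambda_mode) else "", "\n")
  b <- x$coefficients
  if (all(c("intercept", "slope") %in% names(b)))
    cat(sprintf("  log10(y) = %.*g * log10(x) %+.*g\n",
                digits, b[["slope"]], digits, b[["intercept"]]))
  else
    print(round(b, digits))
  if (!is.na(x$r_squared))
    cat(sprintf("  n = %d, r^2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
                x$n, x$r_squared, x$f_df[1], x$f_df[2], x$f_statistic,
                x$p_value))
  invisible(x)
}

#' @export
print.ancova_ladder <- function(x, ...) {
  cat("GLS ANCOVA ladder",
      if (!is.na(x$lambda)) sprintf("(lambda = %.3f)", x$lambda) else "",
      "\n")
  print(x$comparisons, row.names = FALSE)
  cat("selected model:", x$selected, "\n")
  invisible(x)
}
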
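#' Increment-count table
#'
#' Validates a data.frame of cementum (or dentary LAG) increment counts with
#' columns `specimen`, `element` (tooth position or "Dentary"), `observer`,
#' `section` (virtual thin-section id) and `count`. Counts are positive
#' integers — one thick+thin increment pair corresponds to one year — and
#' each (specimen, element, observer, section) combination appears once.
#'
#' @param df a data.frame with the columns above.
#' @return the validated data.frame with class `increment_table`.
#' @export
increment_table <- function(df) {
  need <- c("specimen", "element", "observer", "section", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("increment table is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("increment table is empty")
  if (any(is.na(df$count)) || any(df$count != as.integer(df$count)) ||
      any(df$count < 1))
    stop("counts must be positive integers (one increment pair = one year)")
  df$count <- as.integer(df$count)
  key <- paste(df$specimen, df$element, df$observer, df$section, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (specimen, element, observer, section) records")
  class(df) <- c("increment_table", "data.frame")
  df
}

#' Read an increment table from CSV
#'
#' @param file path to a CSV with columns `specimen`, `element`, `observer`,
#'   `section`, `count`.
#' @return an [increment_table()].
#' @export
read_increment_table <- function(file) {
  increment_table(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Final increment count of one observer for one specimen
#'
#' An observer's final count for a specimen is the maximum counted across all
#' of that specimen's virtual thin sections (and elements): increments can be
#' locally obscured, so the section showing the most increments is the most
#' complete record.
#'
#' @param table an [increment_table()].
#' @param specimen,observer identifiers present in the table.
#' @return integer final count.
#' @export
observer_final_count <- function(table, specimen, observer) {
  stopifnot(inherits(table, "increment_table"))
  sel <- table$specimen == specimen & table$observer == observer
  if (!any(sel))
    stop("no records for specimen '", specimen, "', observer '", observer, "'")
  max(table$count[sel])
}

# round-half-up at integer resolution, for median consensus over an even
# number of observers
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Taxon-level maximum-lifespan estimate from increment counts
#'
#' Aggregates a multi-observer increment table to a single minimum estimate
#' of maximum lifespan (years): per specimen, each observer's final count is
#' the maximum over sections; observers are combined by a consensus rule
#' (default the median, rounded half up); the taxon estimate is the maximum
#' consensus across specimens. Because counts map 1:1 to years, the result
#' is in years and can only underestimate true maximum lifespan (outer
#' increments may be lost to damage).
#'
#' @param table an [increment_table()].
#' @param consensus `"median"` (default), `"max"`, or `"min"` across
#'   observers.
#' @return integer, estimated maximum lifespan in years.
#' @export
taxon_max_lifespan <- function(table, consensus = c("median", "max", "min")) {
  stopifnot(inherits(table, "increment_table"))
  consensus <- match.arg(consensus)
  per <- specimen_consensus(table, consensus)
  max(per$consensus)
}

#' Per-specimen observer final counts and consensus
#'
#' @inheritParams taxon_max_lifespan
#' @return data.frame with one row per specimen: consensus count plus each
#'   observer's final count retained for audit (long format columns
#'   `specimen`, `observer`, `final`, merged `consensus`).
#' @export
specimen_consensus <- function(table, consensus = c("median", "max", "min")) {
  stopifnot(inherits(table, "increment_table"))
  consensus <- match.arg(consensus)
  finals <- stats::aggregate(count ~ specimen + observer, data = table, max)
  names(finals)[names(finals) == "count"] <- "final"
  rule <- switch(consensus,
                 median = function(v) as.integer(.round_half_up(stats::median(v))),
                 max = function(v) max(v),
                 min = function(v) min(v))
  cons <- stats::aggregate(final ~ specimen, data = finals,
                           FUN = function(v) rule(v))
  names(cons)[names(cons) == "final"] <- "consensus"
  merge(finals, cons, by = "specimen")
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv(c(4, 5))   # 15.713
cv <- function(values) {
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' One-way ANOVA from raw groups or summary statistics
#'
#' Accepts either a list of raw numeric vectors or a data.frame of per-group
#' summaries with columns `n`, `mean`, `sd`. The summary path reconstructs
#' the between-group and within-group sums of squares algebraically
#' (`SSB = sum n_i (m_i - grand)^2`, `SSW = sum (n_i - 1) s_i^2`) and is
#' exactly equivalent to the raw path when the summaries derive from the
#' same data. The raw path is delegated to [stats::aov()].
#'
#' @param groups list of numeric vectors, or a data.frame with columns
#'   `n`, `mean`, `sd`.
#' @return list with `F`, `df` (numerator, denominator), `p`.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("n", "mean", "sd")
    if (!all(need %in% names(groups)))
      stop("summary input needs columns n, mean, sd")
    if (nrow(groups) < 2) stop("need at least 2 groups")
    n <- groups$n; m <- groups$mean; s <- groups$sd
    if (sum(n) - length(n) < 1)
      stop("within-group variance undefined: all groups of size 1")
    grand <- sum(n * m) / sum(n)
    ssb <- sum(n * (m - grand)^2)
    ssw <- sum((n - 1) * s^2)
    df1 <- length(n) - 1
    df2 <- sum(n) - length(n)
    Fst <- (ssb / df1) / (ssw / df2)
  } else {
    if (!is.list(groups) || length(groups) < 2)
      stop("need at least 2 groups")
    val <- unlist(groups, use.names = FALSE)
    grp <- factor(rep(seq_along(groups), lengths(groups)))
    if (length(val) - nlevels(grp) < 1)
      stop("within-group variance undefined: all groups of size 1")
    tab <- stats::anova(stats::aov(val ~ grp))
    Fst <- tab$`F value`[1]
    df1 <- tab$Df[1]; df2 <- tab$Df[2]
  }
  list(F = Fst, df = c(df1, df2),
       p = stats::pf(Fst, df1, df2, lower.tail = FALSE))
}

#' Cohen's d from group summaries
#'
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)` — the unweighted
#' root-mean-variance pooling, appropriate when group sizes are very unequal
#' and the comparison is descriptive.
#'
#' @param mean1,sd1,mean2,sd2 group summary statistics.
#' @return non-negative effect size.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) stop("zero pooled standard deviation")
  abs(mean1 - mean2) / pooled
}

#' Observer-agreement statistics for an increment table
#'
#' Computes, per specimen, the CV across observer final counts
#' (inter-observer agreement) and the mean per-observer CV across sections
#' (intra-observer consistency), plus Shapiro-Wilk normality of the
#' specimen-level CVs when at least 3 specimens are available (smaller
#' samples report `NA`: W is not meaningfully computable below n = 3).
#'
#' @param table an [increment_table()].
#' @return list with `per_specimen` (data.frame: specimen, cv_inter,
#'   cv_intra), `summary` (n, mean, sd of each CV type) and `shapiro`
#'   (W and p for each CV type, or NA).
#' @export
agreement_stats <- function(table) {
  stopifnot(inherits(table, "increment_table"))
  specs <- unique(table$specimen)
  per <- do.call(rbind, lapply(specs, function(s) {
    sub <- table[table$specimen == s, ]
    finals <- tapply(sub$count, sub$observer, max)
    cv_inter <- if (length(finals) >= 2 && mean(finals) != 0)
      cv(as.numeric(finals)) else NA_real_
    by_obs <- vapply(split(sub$count, sub$observer), function(v)
      if (length(v) >= 2 && mean(v) != 0) cv(as.numeric(v)) else NA_real_,
      numeric(1))
    data.frame(specimen = s, cv_inter = cv_inter,
               cv_intra = mean(by_obs, na.rm = TRUE))
  }))
  summ <- function(v) {
    v <- v[is.finite(v)]
    c(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
  shap <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || stats::sd(v) == 0)
      return(c(W = NA_real_, p = NA_real_))
    s <- stats::shapiro.test(v)
    c(W = unname(s$statistic), p = s$p.value)
  }
  list(per_specimen = per,
       summary = rbind(cv_inter = summ(per$cv_inter),
                       cv_intra = summ(per$cv_intra)),
       shapiro = rbind(cv_inter = shap(per$cv_inter),
                       cv_intra = shap(per$cv_intra)))
}

#' Sum-slices z-projection of a greyscale stack
#'
#' Creates a virtual thin section by summing the greyscale values of `n`
#' consecutive transverse slices of a 3-D stack (default 10), increasing
#' increment contrast and reducing noise. The output dynamic range is `n`
#' times the input range: no renormalization is applied.
#'
#' @param stack 3-D numeric array, slices along the third dimension.
#' @param start index of the first slice in the window.
#' @param n number of slices to sum (default 10).
#' @return 2-D matrix of per-pixel sums.
#' @export
zproject_sum <- function(stack, start = 1, n = 10) {
  if (length(dim(stack)) != 3) stop("stack must be a 3-D array")
  depth <- dim(stack)[3]
  if (start < 1 || n < 1 || start + n - 1 > depth)
    stop("projection window [", start, ", ", start + n - 1,
         "] out of bounds for stack of depth ", depth)
  rowSums(stack[, , start:(start + n - 1), drop = FALSE], dims = 2)
}
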
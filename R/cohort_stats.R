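#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk test, restricted to the
#' sample sizes for which the approximation is defined (3 to 5000).
#' Normality is reported descriptively alongside cohort comparisons; it
#' does not gate the nonparametric test.
#'
#' @param values Numeric sample.
#' @return List with `W` (statistic, in (0, 1]) and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (any(!is.finite(values))) stop("values must be finite")
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney U statistic for the first sample from rank
#' sums with midranks for ties, and a two-sided p-value.  The exact null
#' distribution is used when `n_a + n_b <= 14` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.  `U_a + U_b = n_a * n_b` always holds.
#'
#' @param a,b Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   default `NULL` applies the switching rule above.  Forcing `TRUE` with
#'   ties is an error.
#' @return List: `U` (for sample `a`), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  pooled <- c(a, b)
  r <- rank(pooled)                          # midranks for ties
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- (n_a + n_b <= 14) && !ties
  if (exact && ties)
    stop("exact Mann-Whitney p-value is not defined with ties")
  if (exact) {
    # Exact null distribution of U (no ties): two-sided doubling of the
    # smaller tail, capped at 1.
    if (U > n_a * n_b / 2)
      p <- 2 * (1 - stats::pwilcox(U - 1, n_a, n_b))
    else
      p <- 2 * stats::pwilcox(U, n_a, n_b)
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- n_a + n_b
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    mu <- n_a * n_b / 2
    d <- U - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Significance star code for a p-value
#'
#' Thresholds follow the convention used throughout the figure legends:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 1e-3, `****` p < 1e-4,
#' otherwise `ns`.
#'
#' @param p p-value in `[0, 1]`.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

.variable_columns <- c(Emax = "Emax_um", lifetime = "lifetime_min",
                       Ve = "Ve_um_per_min", Vr = "Vr_um_per_min")

variable_values <- function(summaries, variable) {
  col <- .variable_columns[[variable]]
  v <- summaries[[col]]
  v[!is.na(v)]          # Ve/Vr are NA for phase-absent filopodia
}

#' Compare one dynamics variable between two filopodium cohorts
#'
#' Pooled per-filopodium values of the chosen variable are compared between
#' the two groups: descriptive statistics (n, mean, median), a Shapiro-Wilk
#' normality p-value per group (NA when n < 3), the Mann-Whitney-Wilcoxon
#' two-sided test, and the significance star code.  For `Ve`/`Vr` only
#' filopodia with the corresponding phase observed contribute.
#'
#' @param summaries_a,summaries_b Data frames from [summarize_cohort()].
#' @param variable One of `"Emax"`, `"lifetime"`, `"Ve"`, `"Vr"`.
#' @param group_a,group_b Group names for the report; default the
#'   `group_label` of each cohort.
#' @return One-row data frame (class `cohort_comparison`): `variable`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `median_a`,
#'   `median_b`, `shapiro_p_a`, `shapiro_p_b`, `mw_U`, `mw_p`, `stars`.
#' @export
compare_cohorts <- function(summaries_a, summaries_b,
                            variable = c("Emax", "lifetime", "Ve", "Vr"),
                            group_a = NULL, group_b = NULL) {
  variable <- match.arg(variable)
  va <- variable_values(summaries_a, variable)
  vb <- variable_values(summaries_b, variable)
  if (length(va) == 0 || length(vb) == 0)
    stop("no values for variable '", variable,
         "' in one of the groups after phase filtering")
  if (is.null(group_a))
    group_a <- if (nrow(summaries_a)) summaries_a$group_label[1] else "A"
  if (is.null(group_b))
    group_b <- if (nrow(summaries_b)) summaries_b$group_label[1] else "B"
  sw <- function(v) if (length(v) >= 3 && length(v) <= 5000 &&
                        stats::var(v) > 0) shapiro_wilk(v)$p else NA_real_
  mw <- mann_whitney_u(va, vb)
  out <- data.frame(
    variable = variable, group_a = group_a, group_b = group_b,
    n_a = length(va), n_b = length(vb),
    mean_a = mean(va), mean_b = mean(vb),
    median_a = stats::median(va), median_b = stats::median(vb),
    shapiro_p_a = sw(va), shapiro_p_b = sw(vb),
    mw_U = mw$U, mw_p = mw$p, stars = p_stars(mw$p),
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_comparison", class(out))
  out
}

#' Proportions of triangle vs trapezoid dynamics
#'
#' Counts and percentages of each dynamic type, per group label.
#'
#' @param summaries Data frame from [summarize_cohort()].
#' @return Data frame with one row per `group_label`: `group_label`,
#'   `n_triangle`, `n_trapezoid`, `pct_triangle`, `pct_trapezoid`.
#' @export
type_proportions <- function(summaries) {
  if (nrow(summaries) < 1) stop("need at least one summary")
  out <- do.call(rbind, lapply(split(summaries, summaries$group_label),
                               function(g) {
    n_tri <- sum(g$model_label == "triangle")
    n_trap <- sum(g$model_label == "trapezoid")
    n <- n_tri + n_trap
    data.frame(group_label = g$group_label[1],
               n_triangle = n_tri, n_trapezoid = n_trap,
               pct_triangle = 100 * n_tri / n,
               pct_trapezoid = 100 * n_trap / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
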
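#' Remove age, sex and brain-volume effects by OLS
#'
#' Regresses a per-subject measure (or a matrix of measures, one column per
#' item) on intercept + age + sex (coded 0/1, M = 1) + total brain volume,
#' pooled over all subjects supplied, and returns the residuals. All group
#' comparisons and MMSE associations in the package are run on these
#' residuals.
#'
#' @param values Numeric vector (one value per subject) or matrix
#'   (subjects x items).
#' @param covariates data.frame with columns `age`, `sex`, `brain_volume`
#'   (e.g. from [covariate_frame()]); `extra` columns can be appended via
#'   the `extra` argument.
#' @param extra Optional data.frame of additional covariate columns to
#'   regress out (e.g. disease-status indicators for MMSE analyses).
#' @return Residuals with the same shape as `values`; each column sums to
#'   ~0.
#' @export
residualize <- function(values, covariates, extra = NULL) {
  vec <- is.null(dim(values))
  Y <- as.matrix(values)
  need <- c("age", "sex", "brain_volume")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) {
    stop("covariates missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(Y) != nrow(covariates)) {
    stop("values and covariates disagree on the number of subjects",
         call. = FALSE)
  }
  if (nrow(Y) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (anyNA(covariates[need])) {
    stop("covariates must be complete (no missing age/sex/brain_volume)",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             age = as.numeric(covariates$age),
             sex = as.numeric(covariates$sex == "M"),
             brain_volume = as.numeric(covariates$brain_volume))
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qx, Y)
  if (vec) drop(res) else res
}

# Fast two-sided permutation t-test machinery. For a simple regression of
# y on a single regressor x, |t| is a monotone function of |cor(x, y)|, so
# permutation counting can be done on correlations:
#   t = r * sqrt(df / (1 - r^2)),  df = n - 2.
# Y: n x p matrix of (residualized) measures; x: length-n regressor.
# Returns t_obs (length p) and b (strict count of |t_perm| > |t_obs|).
perm_t_engine <- function(Y, x, m, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  df <- n - 2L
  xs <- scale(x)[, 1L]
  sdY <- apply(Y, 2L, stats::sd)
  degenerate <- !is.finite(sdY) | sdY == 0
  Ys <- Y
  Ys[, !degenerate] <- scale(Y[, !degenerate, drop = FALSE])
  Ys[, degenerate] <- 0
  r_obs <- drop(crossprod(Ys, xs)) / (n - 1L)
  perm_idx <- with_seed(seed,
                        replicate(m, sample.int(n), simplify = FALSE))
  Xp <- vapply(perm_idx, function(p) xs[p], numeric(n))   # n x m
  r_perm <- crossprod(Ys, Xp) / (n - 1L)                  # p x m
  b <- rowSums(abs(r_perm) > abs(r_obs) + 1e-12)
  b[degenerate] <- m  # zero-variance measure carries no evidence: p = 1
  r_obs <- pmin(pmax(r_obs, -1), 1)
  t_obs <- r_obs * sqrt(df / pmax(1 - r_obs^2, .Machine$double.eps))
  list(t_obs = t_obs, b = as.integer(b), degenerate = degenerate)
}

perm_result <- function(t_obs, b, m, seed) {
  structure(list(t_obs = t_obs, b = as.integer(b), m = as.integer(m),
                 p_perm = (b + 1) / (m + 1), seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> t_obs = ", format(x$t_obs, digits = 4),
      ", m = ", x$m, ", b = ", x$b,
      ", P_perm = ", format(x$p_perm, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permutation test of a two-group difference on residuals
#'
#' Fits an OLS regression of the residualized measure on the binary group
#' indicator, then permutes the group labels `m` times with a seeded
#' generator. With `b` the number of permuted statistics whose magnitude
#' strictly exceeds the observed one, the permutation-corrected p-value is
#' \deqn{P = (b + 1) / (m + 1),} so the smallest attainable p is
#' `1 / (m + 1)` (1e-4 at the conventional m = 10,000). The test is
#' two-sided and invariant to which group is coded 1.
#'
#' @param residuals Numeric vector of residualized measures (see
#'   [residualize()]).
#' @param group Binary group labels (factor, character or 0/1); both levels
#'   must be present.
#' @param m Number of permutations (default 10,000).
#' @param seed Optional integer seed.
#' @return A `"perm_test"`: list with `t_obs`, `b`, `m`, `p_perm`, `seed`.
#' @export
permutation_group_test <- function(residuals, group, m = 10000L,
                                   seed = NULL) {
  x <- as.numeric(factor(group))
  if (length(unique(x[!is.na(x)])) != 2L) {
    stop("`group` must contain exactly two levels", call. = FALSE)
  }
  if (stats::sd(residuals) == 0) {
    warning("degenerate residuals (zero variance); p = 1")
    return(perm_result(t_obs = 0, b = m, m = m, seed = seed))
  }
  eng <- perm_t_engine(matrix(residuals, ncol = 1L), x, m = m, seed = seed)
  perm_result(eng$t_obs, eng$b, m, seed)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up false discovery rate control at level `q`: with ordered p-values
#' `p_(1) <= ... <= p_(n)`, reject all hypotheses with `p <= p_(i*)` where
#' `i* = max{ i : p_(i) <= (i/n) q }`. The largest rejected p-value is the
#' "FDR critical p" reported alongside each family of tests.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return An object of class `"fdr_result"`: list with `q`, `critical_p`
#'   (`NA` when nothing passes), `reject` (logical mask) and `p_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(structure(list(q = q, critical_p = NA_real_, reject = logical(0),
                          p_values = numeric(0)), class = "fdr_result"))
  }
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  reject <- stats::p.adjust(p_values, method = "BH") <= q
  critical_p <- if (any(reject)) max(p_values[reject]) else NA_real_
  structure(list(q = q, critical_p = critical_p, reject = reject,
                 p_values = p_values), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> ", sum(x$reject), " of ", length(x$reject),
      " rejected at q = ", x$q, sep = "")
  if (!is.na(x$critical_p)) {
    cat("; FDR critical p = ", format(x$critical_p, digits = 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Chi-squared test on affected proportions across edge or node classes
#'
#' Compares the proportion of affected (altered) items across classes
#' (e.g. rich-club / feeder / local edges, or rich-club / non-rich-club
#' nodes) with a Pearson chi-squared test, no continuity correction, on the
#' 2 x C table of affected vs unaffected counts. The "expected" proportions
#' come from the class totals; the "observed" are the affected counts.
#'
#' Classes with zero total are excluded with a warning (reducing the
#' degrees of freedom, df = C - 1).
#'
#' @param affected Named integer vector of affected counts per class.
#' @param totals Integer vector of class totals (`affected <= totals`).
#' @return An object of class `"chi2_test"`: list with `table` (2 x C),
#'   `statistic`, `df`, `p_value`.
#' @examples
#' # equal proportions across classes carry no signal
#' chi2_proportions(c(10, 20), c(100, 200))$p_value  # 1
#' @export
chi2_proportions <- function(affected, totals) {
  if (length(affected) != length(totals)) {
    stop("`affected` and `totals` must have equal length", call. = FALSE)
  }
  if (any(affected > totals)) {
    stop("`affected` cannot exceed `totals`", call. = FALSE)
  }
  if (any(affected < 0) || any(totals < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  keep <- totals > 0
  if (!all(keep)) {
    warning("dropping class(es) with zero total: ",
            paste(which(!keep), collapse = ", "))
    affected <- affected[keep]
    totals <- totals[keep]
  }
  if (length(totals) < 2L) {
    stop("need at least two classes with nonzero totals", call. = FALSE)
  }
  tab <- rbind(affected = affected, unaffected = totals - affected)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab,
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value)),
            class = "chi2_test")
}

#' @export
print.chi2_test <- function(x, ...) {
  cat("<chi2_test> X-squared = ", format(x$statistic, digits = 4),
      ", df = ", x$df, ", p = ", format(x$p_value, digits = 3), "\n",
      sep = "")
  invisible(x)
}
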
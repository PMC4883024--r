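# Shared driver for itemwise (edge / node) group comparisons: residualize
# all items at once on age/sex/brain volume, then run the shared-permutation
# two-sided t test per item and BH-FDR across items. One permutation
# sequence (one seed) is shared across items of a contrast.
itemwise_group_test <- function(Y, covariates, group, contrast,
                                m = 10000L, seed = NULL, q = 0.05) {
  keep <- group %in% contrast
  if (sum(group == contrast[1L]) == 0L || sum(group == contrast[2L]) == 0L) {
    stop("both contrast groups must be present: ",
         paste(contrast, collapse = " vs "), call. = FALSE)
  }
  Y <- Y[keep, , drop = FALSE]
  covariates <- covariates[keep, , drop = FALSE]
  # code first-listed group 1 (the "disease" side), second 0
  x <- as.numeric(group[keep] == contrast[1L])
  R <- residualize(Y, covariates)
  eng <- perm_t_engine(R, x, m = m, seed = seed)
  p_perm <- (eng$b + 1) / (m + 1)
  fdr <- fdr_bh(p_perm, q = q)
  items <- data.frame(item = colnames(Y) %||% seq_len(ncol(Y)),
                      t_obs = eng$t_obs, b = eng$b, p_perm = p_perm,
                      reject = fdr$reject,
                      sign = ifelse(eng$t_obs > 0, 1L,
                                    ifelse(eng$t_obs < 0, -1L, 0L)),
                      stringsAsFactors = FALSE)
  list(items = items, fdr = fdr, n = nrow(Y), m = m, seed = seed,
       contrast = contrast)
}

#' Edgewise group comparison with permutation testing and FDR
#'
#' For every edge in the cohort's support, residualizes the edge weight of
#' the chosen kind on age, sex and brain volume (pooled over the two
#' contrast groups), runs the two-sided label-permutation test (one shared
#' permutation sequence across edges), and applies Benjamini-Hochberg FDR
#' across edges. The sign of the observed statistic records the direction:
#' negative means lower weight in the first-listed (disease) group.
#'
#' @param ch A [cohort()].
#' @param weight_kind One of `"fiber_density"`, `"FA"`, `"MD"`.
#' @param contrast Character pair, disease group first, e.g.
#'   `c("bvFTD", "control")`.
#' @param m Number of permutations (default 10,000).
#' @param seed Optional integer seed.
#' @param q FDR level (default 0.05).
#' @return An object of class `"edgewise_test"`: list with `items`
#'   (data.frame: `i`, `j`, `item`, `t_obs`, `b`, `p_perm`, `reject`,
#'   `sign`), `fdr` (an `"fdr_result"`), `contrast`, `weight_kind`, `m`.
#' @export
edgewise_group_test <- function(ch, weight_kind = c("fiber_density", "FA",
                                                    "MD"),
                                contrast, m = 10000L, seed = NULL,
                                q = 0.05) {
  weight_kind <- match.arg(weight_kind)
  stopifnot(inherits(ch, "cohort"), length(contrast) == 2L)
  Y <- cohort_measure_matrix(ch, "edge", kind = weight_kind)
  pairs <- attr(Y, "pairs")
  cov <- covariate_frame(ch)
  res <- itemwise_group_test(Y, cov, cov$group, contrast, m = m,
                             seed = seed, q = q)
  res$items <- cbind(i = pairs[, 1L], j = pairs[, 2L], res$items)
  res$weight_kind <- weight_kind
  class(res) <- "edgewise_test"
  res
}

#' Nodal-degree group comparison with permutation testing and FDR
#'
#' As [edgewise_group_test()], with the per-node fiber-density degree as
#' the measure (one test per node, FDR across the 68 nodes).
#'
#' @inheritParams edgewise_group_test
#' @return An object of class `"nodal_test"` (same structure as
#'   `"edgewise_test"`, one row per node).
#' @export
nodal_degree_group_test <- function(ch, contrast, m = 10000L, seed = NULL,
                                    q = 0.05) {
  stopifnot(inherits(ch, "cohort"), length(contrast) == 2L)
  Y <- cohort_measure_matrix(ch, "degree")
  cov <- covariate_frame(ch)
  res <- itemwise_group_test(Y, cov, cov$group, contrast, m = m,
                             seed = seed, q = q)
  class(res) <- "nodal_test"
  res
}

#' @export
print.edgewise_test <- function(x, ...) {
  cat("<edgewise_test> ", x$contrast[1L], " vs ", x$contrast[2L], " on ",
      x$weight_kind, ": ", sum(x$items$reject), "/", nrow(x$items),
      " edges FDR-significant", sep = "")
  if (!is.na(x$fdr$critical_p)) {
    cat(" (critical P_perm = ", format(x$fdr$critical_p, digits = 3), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.nodal_test <- function(x, ...) {
  cat("<nodal_test> ", x$contrast[1L], " vs ", x$contrast[2L], ": ",
      sum(x$items$reject), "/", nrow(x$items),
      " nodes FDR-significant", sep = "")
  if (!is.na(x$fdr$critical_p)) {
    cat(" (critical P_perm = ", format(x$fdr$critical_p, digits = 3), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Class enrichment of significantly altered edges
#'
#' Given an edgewise comparison and a rich-node membership, counts the
#' FDR-significant edges falling in each class (rich-club / feeder / local)
#' and tests, by [chi2_proportions()], whether the altered edges are
#' distributed across classes in proportion to the expected class totals.
#' By default the expected totals are each class's mean per-subject edge
#' count in the disease (first-listed) group, rounded to the nearest
#' integer.
#'
#' @param test An `"edgewise_test"`.
#' @param ch The [cohort()] the test was run on.
#' @param rich A `"rich_node_set"` or integer member indices.
#' @param totals Optional expected class totals; computed from the cohort
#'   when omitted.
#' @param direction Count only edges altered in this direction: `-1` for
#'   decreases in the disease group (default for fiber density / FA
#'   degeneration), `1` for increases, `0` for both.
#' @return List with `affected`, `totals`, and `chi2` (a `"chi2_test"`,
#'   or `NULL` when no edge is significant).
#' @export
class_enrichment <- function(test, ch, rich, totals = NULL, direction = 0L) {
  stopifnot(inherits(test, "edgewise_test"))
  members <- if (inherits(rich, "rich_node_set")) rich$members else
    as.integer(rich)
  sig <- test$items$reject
  if (direction != 0L) sig <- sig & test$items$sign == direction
  sig_pairs <- as.matrix(test$items[sig, c("i", "j"), drop = FALSE])
  affected <- c(rich_club = 0L, feeder = 0L, local = 0L)
  if (nrow(sig_pairs)) {
    affected <- edge_class_counts(classify_edges(sig_pairs, members))
  }
  if (is.null(totals)) {
    grp <- cohort_groups(ch)
    counts <- vapply(ch$subjects[grp == test$contrast[1L]],
                     per_subject_class_counts, integer(3), rich = members)
    totals <- as.integer(round(rowMeans(counts)))
    names(totals) <- rownames(counts)
  }
  chi2 <- if (sum(affected) > 0L) chi2_proportions(affected, totals) else
    NULL
  list(affected = affected, totals = totals, chi2 = chi2)
}

#' Association between MMSE and a network measure
#'
#' Residualizes the measure on age, sex, brain volume *and* disease-status
#' indicators, then permutation-tests the MMSE term: MMSE values are
#' permuted across subjects `m` times and the magnitude of the regression
#' t-statistic is compared with the observed one, P = (b+1)/(m+1).
#' Subjects with missing MMSE are dropped; at least 80% of subjects must
#' have a score.
#'
#' @param ch A [cohort()].
#' @param measure Numeric vector (one value per subject, in cohort order)
#'   or a function applied to each [subject_record()] (e.g.
#'   `function(s) edge_count(s$matrices$fiber_density)`).
#' @param m Number of permutations.
#' @param seed Optional integer seed.
#' @return A `"perm_test"`.
#' @export
mmse_association <- function(ch, measure, m = 10000L, seed = NULL) {
  stopifnot(inherits(ch, "cohort"))
  if (is.function(measure)) {
    measure <- vapply(ch$subjects, measure, numeric(1))
  }
  cov <- covariate_frame(ch)
  stopifnot(length(measure) == nrow(cov))
  has <- !is.na(cov$mmse)
  if (!any(has)) stop("MMSE missing for all subjects", call. = FALSE)
  if (mean(has) < 0.8) {
    stop("MMSE present for fewer than 80% of subjects", call. = FALSE)
  }
  cov <- cov[has, , drop = FALSE]
  measure <- measure[has]
  grp <- factor(cov$group)
  extra <- if (nlevels(grp) > 1L) {
    stats::model.matrix(~grp)[, -1L, drop = FALSE]
  } else NULL
  resid <- residualize(measure, cov, extra = extra)
  if (stats::sd(resid) == 0) {
    warning("degenerate residuals (zero variance); p = 1")
    return(perm_result(t_obs = 0, b = m, m = m, seed = seed))
  }
  eng <- perm_t_engine(matrix(resid, ncol = 1L), cov$mmse, m = m,
                       seed = seed)
  perm_result(eng$t_obs, eng$b, m, seed)
}
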
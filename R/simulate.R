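#' Specification of a synthetic connectome cohort
#'
#' Collects every parameter of the synthetic-data generator. The defaults
#' emulate the statistical structure the analysis pipeline assumes in a
#' three-group dementia study design: 37 controls, 20 bvFTD and 23 EOAD
#' subjects; 68 cortical nodes with a fat-tailed strength distribution
#' following an exponentially truncated power law; a densely interconnected
#' heavy-weight core planted on the 26 reported rich-club regions;
#' anticorrelated FA/MD edge weights sharing the fiber-density support;
#' age/sex/brain-volume effects on connectivity; and group-specific
#' multiplicative lesions (EOAD concentrated on rich-club edges, bvFTD on
#' feeder and local edges) whose burden drives a noisy MMSE score.
#'
#' @param n_per_group Named counts of subjects per diagnostic group.
#' @param labels Node labels (default [dk68_labels()]).
#' @param rich_core Labels of the planted core (default
#'   [rich_club_regions()]).
#' @param base_density Expected fraction of present edges (default 0.36,
#'   about 820 of 2278 possible edges, matching typical 68-node
#'   tractography networks).
#' @param strength_law `c(alpha, cutoff)` of the truncated power law
#'   `s^(alpha - 1) exp(-s / cutoff)` node propensities are drawn from
#'   (a Gamma(alpha, cutoff) draw).
#' @param core_boost Multiplier on fiber-density weights of core-core
#'   edges (plants the heavy-weight rich club).
#' @param weight_coupling Parameters linking FA and MD to fiber density per
#'   edge: `fa_slope` and `fa_noise` (FA rises with log fiber density
#'   through a logistic squashed into (0.2, 0.8)), `md_base` and `md_slope`
#'   (MD in mm^2/s falls linearly with FA), `md_noise` (log-normal sd).
#' @param covariate_effects `c(age_slope, sex_offset, volume_power)`
#'   applied multiplicatively to fiber density: `exp(age_slope * (age -
#'   60))`, `exp(sex_offset)` for males, `(volume / 1.15e6)^volume_power`.
#' @param lesions Named list (by group) of lesion lists; each lesion is
#'   `list(classes =, fraction =, effects = c(fiber_density =, FA =,
#'   MD =))`: the named edge classes have `fraction` of their edges scaled
#'   by the per-kind multiplicative effects, before subject noise.
#' @param noise_sd Subject-level multiplicative log-normal noise sd
#'   (default 0.15).
#' @param dropout Per-subject probability that a non-core supported edge is
#'   absent (default 0.05), so subjects differ in support.
#' @param age_mean,age_sd Named per-group age distributions (years).
#' @param volume_mean,volume_sd Brain-volume distribution (mm^3).
#' @param mmse_control `c(mean, sd)` of the control MMSE distribution.
#' @param mmse_slope,mmse_noise_slope Decline of the MMSE mean (and growth
#'   of its sd) per unit square-root lesion burden.
#' @return An object of class `"cohort_spec"` (a list of the above).
#' @export
cohort_spec <- function(n_per_group = c(control = 37, bvFTD = 20,
                                        EOAD = 23),
                        labels = dk68_labels(),
                        rich_core = rich_club_regions(),
                        base_density = 0.36,
                        strength_law = c(alpha = 1.2, cutoff = 12),
                        core_boost = 2,
                        weight_coupling = c(fa_slope = 1, fa_noise = 0.6,
                                            md_base = 9e-4,
                                            md_slope = 3.5e-4,
                                            md_noise = 0.04),
                        covariate_effects = c(age_slope = -0.01,
                                              sex_offset = 0.05,
                                              volume_power = 0.5),
                        lesions = list(
                          bvFTD = list(list(
                            classes = c("feeder", "local"),
                            fraction = 0.5,
                            effects = c(fiber_density = 0.75, FA = 0.9,
                                        MD = 1.1))),
                          EOAD = list(list(
                            classes = "rich_club",
                            fraction = 0.5,
                            effects = c(fiber_density = 0.8, FA = 0.95,
                                        MD = 1.1)))),
                        noise_sd = 0.15,
                        dropout = 0.05,
                        age_mean = c(control = 59.4, bvFTD = 60.7,
                                     EOAD = 59.0),
                        age_sd = c(control = 9.6, bvFTD = 10.7,
                                   EOAD = 5.0),
                        volume_mean = 1.15e6, volume_sd = 1e5,
                        mmse_control = c(mean = 29.1, sd = 0.9),
                        mmse_slope = 10, mmse_noise_slope = 5.5) {
  stopifnot(all(n_per_group >= 0), base_density > 0, base_density <= 1,
            strength_law[["alpha"]] > 0, strength_law[["cutoff"]] > 0,
            core_boost > 0, noise_sd >= 0, dropout >= 0, dropout < 1)
  bad <- setdiff(rich_core, labels)
  if (length(bad)) {
    stop("rich_core labels not in node list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (g in names(lesions)) {
    for (les in lesions[[g]]) {
      stopifnot(les$fraction >= 0, les$fraction <= 1,
                all(les$effects > 0),
                all(les$classes %in% c("rich_club", "feeder", "local")))
    }
  }
  structure(list(n_per_group = n_per_group, labels = labels,
                 rich_core = rich_core, base_density = base_density,
                 strength_law = strength_law, core_boost = core_boost,
                 weight_coupling = weight_coupling,
                 covariate_effects = covariate_effects, lesions = lesions,
                 noise_sd = noise_sd, dropout = dropout,
                 age_mean = age_mean, age_sd = age_sd,
                 volume_mean = volume_mean, volume_sd = volume_sd,
                 mmse_control = mmse_control, mmse_slope = mmse_slope,
                 mmse_noise_slope = mmse_noise_slope),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", length(x$labels), " nodes, groups: ",
      paste(names(x$n_per_group), x$n_per_group, sep = " = ",
            collapse = ", "),
      ", base density ", x$base_density, ", core of ",
      length(x$rich_core), " nodes\n", sep = "")
  invisible(x)
}

# Draw node propensities theta from the truncated power law
# s^(alpha-1) exp(-s/cutoff) (i.e. Gamma(alpha, scale = cutoff)), assigning
# the largest values to the planted core so it tops the degree ranking.
draw_propensities <- function(spec) {
  n <- length(spec$labels)
  core_idx <- match(spec$rich_core, spec$labels)
  theta <- sort(stats::rgamma(n, shape = spec$strength_law[["alpha"]],
                              scale = spec$strength_law[["cutoff"]]),
                decreasing = TRUE)
  out <- numeric(n)
  out[core_idx] <- theta[seq_along(core_idx)][sample(length(core_idx))]
  rest <- setdiff(seq_len(n), core_idx)
  out[rest] <- theta[-seq_along(core_idx)][sample(length(rest))]
  out
}

#' Generate one base connectome triple
#'
#' Draws the group-level "healthy" network a synthetic cohort is built
#' from: a binary support whose expected degrees follow the truncated
#' power law of `spec$strength_law`, with the planted core connected with
#' probability one; fiber-density weights proportional to the geometric
#' mean of endpoint propensities (boosted on core-core edges); per-edge FA
#' in (0.2, 0.8) positively correlated with log fiber density; MD
#' negatively correlated with FA. The three matrices share one support.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return List with `connectome` elements `fiber_density`, `FA`, `MD`,
#'   plus attributes `theta` (propensities) and `core` (core indices).
#' @export
generate_base_connectome <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- length(spec$labels)
    core_idx <- match(spec$rich_core, spec$labels)
    theta <- draw_propensities(spec)
    pairs <- upper_pairs(n)
    th_prod <- theta[pairs[, 1L]] * theta[pairs[, 2L]]
    is_core <- pairs[, 1L] %in% core_idx & pairs[, 2L] %in% core_idx
    target <- spec$base_density * nrow(pairs) - sum(is_core)
    if (target <= 0) {
      stop("infeasible density/core combination: the planted core alone ",
           "exceeds the requested density", call. = FALSE)
    }
    lam <- stats::uniroot(function(l) {
      sum(1 - exp(-l * th_prod[!is_core])) - target
    }, lower = 1e-12, upper = 1, extendInt = "upX", tol = 1e-10)$root
    p_edge <- ifelse(is_core, 1, 1 - exp(-lam * th_prod))
    present <- stats::runif(nrow(pairs)) < p_edge

    w_raw <- sqrt(th_prod) * exp(stats::rnorm(nrow(pairs), 0, 0.4))
    w_raw[is_core] <- w_raw[is_core] * spec$core_boost
    w_raw[!present] <- 0
    w_raw <- w_raw / mean(w_raw[present])  # mean present-edge weight = 1

    wc <- spec$weight_coupling
    z <- rep(0, nrow(pairs))
    z[present] <- scale(log(w_raw[present]))[, 1L]
    fa <- 0.2 + 0.6 * stats::plogis(wc[["fa_slope"]] * z +
                                      stats::rnorm(nrow(pairs), 0,
                                                   wc[["fa_noise"]]))
    md <- (wc[["md_base"]] - wc[["md_slope"]] * (fa - 0.5)) *
      exp(stats::rnorm(nrow(pairs), 0, wc[["md_noise"]]))
    fa[!present] <- 0
    md[!present] <- 0

    to_mat <- function(v) {
      m <- matrix(0, n, n)
      m[pairs] <- v
      m + t(m)
    }
    out <- list(
      fiber_density = connectome(to_mat(w_raw), "fiber_density",
                                 labels = spec$labels),
      FA = connectome(to_mat(fa), "FA", labels = spec$labels),
      MD = connectome(to_mat(md), "MD", labels = spec$labels)
    )
    attr(out, "theta") <- theta
    attr(out, "core") <- core_idx
    out
  })
}

# Apply one group's lesions to the base edge vectors. Returns the scaled
# vectors plus the row indices (into `pairs`) of lesioned edges per class.
apply_lesions <- function(vectors, pairs, class_of, lesions) {
  hit <- integer(0)
  for (les in lesions) {
    in_class <- which(class_of %in% les$classes & vectors$fiber_density > 0)
    n_hit <- round(les$fraction * length(in_class))
    sel <- if (n_hit > 0L) sample(in_class, n_hit) else integer(0)
    for (kind in names(les$effects)) {
      vectors[[kind]][sel] <- vectors[[kind]][sel] * les$effects[[kind]]
    }
    hit <- union(hit, sel)
  }
  list(vectors = vectors, lesioned = sort(hit))
}

#' Generate a synthetic cohort
#'
#' Builds a full cohort from one base connectome: group-specific lesions
#' are applied to the base (before noise, so the effect size is the
#' population mean shift), then every subject receives independent
#' multiplicative log-normal edge noise per weight kind, covariate effects
#' on fiber density, and per-subject dropout of non-core edges. Covariates
#' are drawn per group; MMSE is a noisy decreasing function of the group's
#' total lesion burden, clamped to `[0, 30]`.
#'
#' The generator is fully reproducible: the same `spec` and `seed` give a
#' bit-identical cohort. The exact lesioned edge list per group is kept in
#' the `"ground_truth"` attribute so the sensitivity and specificity of
#' every downstream test can be scored.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A [cohort()] with attribute `ground_truth`: list with `core`
#'   (planted core indices), `lesioned` (per group, data.frame `i`, `j`,
#'   `class` of lesioned edges) and `base` (the unlesioned triple).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    base <- generate_base_connectome(spec)
    n <- length(spec$labels)
    core_idx <- attr(base, "core")
    pairs <- upper_pairs(n)
    base_vec <- lapply(base, function(m) m$weights[pairs])
    names(base_vec) <- weight_kinds()
    present <- base_vec$fiber_density > 0
    cls_map <- classify_edges(cbind(pairs[present, , drop = FALSE]),
                              core_idx)
    class_of <- rep(NA_character_, nrow(pairs))
    class_of[present] <- as.character(cls_map$class)
    is_core_edge <- pairs[, 1L] %in% core_idx & pairs[, 2L] %in% core_idx

    groups <- names(spec$n_per_group)
    group_vec <- list()
    lesioned <- list()
    for (g in groups) {
      les <- spec$lesions[[g]]
      if (is.null(les)) {
        group_vec[[g]] <- base_vec
        lesioned[[g]] <- data.frame(i = integer(0), j = integer(0),
                                    class = character(0))
      } else {
        res <- apply_lesions(base_vec, pairs, class_of, les)
        group_vec[[g]] <- res$vectors
        lesioned[[g]] <- data.frame(i = pairs[res$lesioned, 1L],
                                    j = pairs[res$lesioned, 2L],
                                    class = class_of[res$lesioned])
      }
    }

    burden <- vapply(groups, function(g) {
      les <- spec$lesions[[g]]
      if (is.null(les)) return(0)
      mean(vapply(les, function(l) {
        l$fraction * sum(abs(log2(l$effects)))
      }, numeric(1)))
    }, numeric(1))

    ce <- spec$covariate_effects
    to_mat <- function(v) {
      m <- matrix(0, n, n)
      m[pairs] <- v
      m + t(m)
    }
    subjects <- list()
    idx <- 0L
    for (g in groups) {
      for (s in seq_len(spec$n_per_group[[g]])) {
        idx <- idx + 1L
        age <- stats::rnorm(1, spec$age_mean[[g]], spec$age_sd[[g]])
        sex <- if (s %% 2L == 0L) "M" else "F"
        vol <- stats::rnorm(1, spec$volume_mean, spec$volume_sd)
        keep <- present & (is_core_edge |
                             stats::runif(nrow(pairs)) >= spec$dropout)
        cov_scale <- exp(ce[["age_slope"]] * (age - 60)) *
          exp(ce[["sex_offset"]] * (sex == "M")) *
          (vol / 1.15e6)^ce[["volume_power"]]
        noise <- function() exp(stats::rnorm(nrow(pairs), 0, spec$noise_sd))
        fd <- group_vec[[g]]$fiber_density * cov_scale * noise() * keep
        fa <- pmin(group_vec[[g]]$FA * noise(), 1) * keep
        md <- group_vec[[g]]$MD * noise() * keep
        mm <- stats::rnorm(1,
                           spec$mmse_control[["mean"]] -
                             spec$mmse_slope * sqrt(burden[[g]]),
                           spec$mmse_control[["sd"]] +
                             spec$mmse_noise_slope * sqrt(burden[[g]]))
        mm <- round(min(30, max(0, mm)))
        subjects[[idx]] <- subject_record(
          sprintf("%s_%02d", g, s),
          connectome(to_mat(fd), "fiber_density", labels = spec$labels),
          connectome(to_mat(fa), "FA", labels = spec$labels),
          connectome(to_mat(md), "MD", labels = spec$labels),
          age = age, sex = sex, brain_volume = vol, group = g, mmse = mm)
      }
    }
    ch <- cohort(subjects)
    attr(ch, "ground_truth") <- list(core = core_idx, lesioned = lesioned,
                                     base = base)
    ch
  })
}

#' A matched null cohort: same design, no lesions
#'
#' Convenience wrapper around [generate_cohort()] with all lesion lists
#' removed, so diagnostic groups are exchangeable and every downstream
#' test operates under its null hypothesis.
#'
#' @inheritParams generate_cohort
#' @return A [cohort()].
#' @export
generate_null_cohort <- function(spec = cohort_spec(), seed = NULL) {
  spec$lesions <- list()
  generate_cohort(spec, seed = seed)
}
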
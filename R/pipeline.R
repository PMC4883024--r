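#' Pipeline configuration
#'
#' All tunable parameters of [run_pipeline()], defaulting to the standard
#' analysis settings: rich-club regime threshold k > 15, membership degree
#' floor 30, 500 random networks for rich-club normalization, 10,000 label
#' permutations, FDR level q = 0.05.
#'
#' @param k_threshold Rich-club regime degree threshold.
#' @param degree_floor Minimum group-mean degree for rich-node membership.
#' @param k_max Highest degree level of the rich-club curves.
#' @param n_random Random networks per rich-club normalization.
#' @param permutations Label permutations per test.
#' @param fdr_q FDR level.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param contrasts List of group pairs to compare, disease group first.
#' @param weight_kinds Weight kinds to analyse edgewise.
#' @param rich_nodes `"reported"` to use [rich_club_regions()],
#'   `"derive"` to run [select_rich_nodes()] on the cohort, or a
#'   `"rich_node_set"`.
#' @param curve_tests Run the per-k rich-club curve group comparisons
#'   (the most expensive stage; requires per-subject curves).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(k_threshold = 15L, degree_floor = 30,
                            k_max = 30L, n_random = 500L,
                            permutations = 10000L, fdr_q = 0.05,
                            seed = 1L,
                            contrasts = list(c("bvFTD", "control"),
                                             c("EOAD", "control"),
                                             c("bvFTD", "EOAD")),
                            weight_kinds = c("fiber_density", "FA", "MD"),
                            rich_nodes = "reported",
                            curve_tests = TRUE) {
  stopifnot(n_random >= 1L, permutations >= 1L, fdr_q > 0, fdr_q < 1,
            k_max >= 1L)
  structure(list(k_threshold = k_threshold, degree_floor = degree_floor,
                 k_max = k_max, n_random = n_random,
                 permutations = permutations, fdr_q = fdr_q, seed = seed,
                 contrasts = contrasts, weight_kinds = weight_kinds,
                 rich_nodes = rich_nodes, curve_tests = curve_tests),
            class = "pipeline_config")
}

contrast_name <- function(ct) paste(ct, collapse = "_vs_")

#' Run the full rich-club group-analysis pipeline
#'
#' Executes, on one cohort: rich-node membership -> per-subject edge-class
#' counts -> global permutation tests (edge count E and per-class counts,
#' per contrast) -> per-k rich-club curve comparisons (FDR across k within
#' each weight kind) -> nodal-degree comparisons (FDR across nodes) ->
#' edgewise comparisons per weight kind (FDR across edges) -> chi-squared
#' class-enrichment of the altered edges and nodes -> MMSE associations
#' with the global measures. Randomness at every stage is derived from the
#' single configured seed, so a rerun with the same cohort and
#' configuration is numerically identical.
#'
#' @param ch A [cohort()].
#' @param config A [pipeline_config()].
#' @return An object of class `"richclub_report"`: list with `rich_nodes`,
#'   `class_counts` (per-subject), `global` (per contrast), `curves` (per
#'   weight kind per contrast), `nodal`, `edgewise`, `enrichment`, `mmse`,
#'   and `manifest`.
#' @export
run_pipeline <- function(ch, config = pipeline_config()) {
  stopifnot(inherits(ch, "cohort"), inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6L)
  grp <- cohort_groups(ch)
  cov <- covariate_frame(ch)

  rich <- if (inherits(config$rich_nodes, "rich_node_set")) {
    config$rich_nodes
  } else if (identical(config$rich_nodes, "derive")) {
    select_rich_nodes(ch, k_threshold = config$k_threshold,
                      degree_floor = config$degree_floor)
  } else {
    rich_node_set(rich_club_regions(), all_labels = ch$labels)
  }

  class_counts <- t(vapply(ch$subjects, per_subject_class_counts,
                           integer(3), rich = rich))
  rownames(class_counts) <- cov$subject_id
  E <- vapply(ch$subjects,
              function(s) as.numeric(edge_count(s$matrices$fiber_density)),
              numeric(1))
  global_measures <- cbind(E = E, class_counts)

  # -- global tests: E and per-class edge counts, per contrast ------------
  global <- list()
  for (ct in config$contrasts) {
    res <- itemwise_group_test(global_measures, cov, grp, ct,
                               m = config$permutations,
                               seed = seeds[[1L]], q = config$fdr_q)
    global[[contrast_name(ct)]] <- res$items
  }

  # -- rich-club curves: per-subject curves, per-k tests ------------------
  curves <- NULL
  if (isTRUE(config$curve_tests)) {
    curve_seeds <- with_seed(seeds[[2L]],
                             sample.int(.Machine$integer.max,
                                        length(ch$subjects)))
    curves <- list()
    for (kind in config$weight_kinds) {
      phi <- t(vapply(seq_along(ch$subjects), function(si) {
        rc <- rich_club_curve(ch$subjects[[si]]$matrices[[kind]],
                              k_max = config$k_max,
                              n_random = config$n_random,
                              seed = curve_seeds[[si]])
        rc$phi_norm
      }, numeric(config$k_max)))
      colnames(phi) <- paste0("k", seq_len(config$k_max))
      per_contrast <- list()
      for (ct in config$contrasts) {
        # drop k levels undefined for any subject in the contrast
        keep_sub <- grp %in% ct
        defined <- colSums(is.na(phi[keep_sub, , drop = FALSE])) == 0L
        if (!any(defined)) next
        res <- itemwise_group_test(phi[, defined, drop = FALSE], cov, grp,
                                   ct, m = config$permutations,
                                   seed = seeds[[3L]], q = config$fdr_q)
        per_contrast[[contrast_name(ct)]] <-
          list(items = res$items, fdr = res$fdr)
      }
      curves[[kind]] <- list(phi_norm = phi, tests = per_contrast)
    }
  }

  # -- nodal degree and edgewise tests ------------------------------------
  nodal <- list()
  edgewise <- list()
  enrichment <- list()
  for (ct in config$contrasts) {
    cn <- contrast_name(ct)
    nodal[[cn]] <- nodal_degree_group_test(ch, ct,
                                           m = config$permutations,
                                           seed = seeds[[4L]],
                                           q = config$fdr_q)
    edgewise[[cn]] <- list()
    enrichment[[cn]] <- list()
    for (kind in config$weight_kinds) {
      et <- edgewise_group_test(ch, kind, ct, m = config$permutations,
                                seed = seeds[[5L]], q = config$fdr_q)
      edgewise[[cn]][[kind]] <- et
      enrichment[[cn]][[kind]] <- class_enrichment(et, ch, rich)
    }
    # nodal enrichment: altered rich-club vs non-rich-club nodes
    sig_nodes <- which(nodal[[cn]]$items$reject)
    n_rich <- length(rich$members)
    n_nonrich <- length(ch$labels) - n_rich
    aff <- c(rich_club = sum(sig_nodes %in% rich$members),
             nonrich = sum(!sig_nodes %in% rich$members))
    enrichment[[cn]]$nodes <- list(
      affected = aff, totals = c(rich_club = n_rich, nonrich = n_nonrich),
      chi2 = if (sum(aff) > 0)
        chi2_proportions(aff, c(n_rich, n_nonrich)) else NULL)
  }

  # -- MMSE associations with the global measures -------------------------
  mmse <- NULL
  if (any(!is.na(cov$mmse)) && mean(!is.na(cov$mmse)) >= 0.8) {
    mmse <- lapply(colnames(global_measures), function(nm) {
      mmse_association(ch, global_measures[, nm],
                       m = config$permutations, seed = seeds[[6L]])
    })
    names(mmse) <- colnames(global_measures)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("richclubnet")),
    r_version = R.version.string,
    n_subjects = length(ch$subjects),
    groups = as.list(table(grp)),
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(rich_nodes = rich, class_counts = class_counts,
                 global = global, curves = curves, nodal = nodal,
                 edgewise = edgewise, enrichment = enrichment, mmse = mmse,
                 manifest = manifest),
            class = "richclub_report")
}

#' @export
print.richclub_report <- function(x, ...) {
  cat("<richclub_report> ", x$manifest$n_subjects, " subjects; rich club: ",
      length(x$rich_nodes$members), " nodes\n", sep = "")
  for (cn in names(x$edgewise)) {
    cat("  ", cn, ":\n", sep = "")
    nd <- x$nodal[[cn]]
    cat("    nodal degree: ", sum(nd$items$reject), "/",
        nrow(nd$items), " nodes FDR-significant\n", sep = "")
    for (kind in names(x$edgewise[[cn]])) {
      et <- x$edgewise[[cn]][[kind]]
      en <- x$enrichment[[cn]][[kind]]
      cat("    ", kind, ": ", sum(et$items$reject), "/", nrow(et$items),
          " edges", sep = "")
      if (!is.null(en$chi2)) {
        cat("; class chi2 p = ", format(en$chi2$p_value, digits = 3),
            sep = "")
      }
      cat("\n")
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes one TSV per result family (global tests, per-k curve tests,
#' nodal and edgewise tests, per-subject class counts), the rich-node
#' membership, a JSON summary of the enrichment tables and MMSE
#' associations, and the run manifest (configuration, seed, versions).
#'
#' @param report A `"richclub_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "richclub_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_membership(report$rich_nodes, file.path(dir, "rich_nodes.txt"))
  wt(data.frame(subject_id = rownames(report$class_counts),
                report$class_counts), "class_counts.tsv")
  glob <- do.call(rbind, lapply(names(report$global), function(cn) {
    cbind(contrast = cn, report$global[[cn]])
  }))
  wt(glob, "global_tests.tsv")
  for (cn in names(report$nodal)) {
    wt(report$nodal[[cn]]$items, paste0("nodal_", cn, ".tsv"))
    for (kind in names(report$edgewise[[cn]])) {
      wt(report$edgewise[[cn]][[kind]]$items,
         paste0("edgewise_", cn, "_", kind, ".tsv"))
    }
  }
  if (!is.null(report$curves)) {
    for (kind in names(report$curves)) {
      for (cn in names(report$curves[[kind]]$tests)) {
        wt(report$curves[[kind]]$tests[[cn]]$items,
           paste0("curve_", cn, "_", kind, ".tsv"))
      }
    }
  }
  summary_json <- list(
    enrichment = lapply(report$enrichment, function(per_ct) {
      lapply(per_ct, function(en) {
        list(affected = as.list(en$affected), totals = as.list(en$totals),
             chi2_p = if (!is.null(en$chi2)) en$chi2$p_value else NULL)
      })
    }),
    mmse = lapply(report$mmse, function(pt) {
      list(t_obs = pt$t_obs, p_perm = pt$p_perm, m = pt$m)
    }),
    manifest = report$manifest
  )
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Reported affected/total class counts shipped with the package
#'
#' The published affected-vs-total counts per edge or node class for each
#' diagnostic contrast, as a data.frame. Feeding these directly into
#' [chi2_proportions()] reproduces the published chi-squared p-values.
#'
#' @return data.frame with columns `contrast`, `measure`, `class`,
#'   `affected`, `total`.
#' @export
reported_class_counts <- function() {
  path <- system.file("extdata", "reported_class_counts.tsv",
                      package = "richclubnet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
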
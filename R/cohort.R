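#' Bundle one subject's matrices and covariates
#'
#' A subject record holds the three weighted connectivity matrices (fiber
#' density, FA, MD) together with the covariates used for residualization
#' and the diagnostic group. The three matrices must share an identical
#' binary support: FA and MD along a tract are only defined where at least
#' one fiber was reconstructed, so an edge absent from the fiber-density
#' matrix cannot carry FA or MD weight.
#'
#' @param subject_id Character scalar.
#' @param fiber_density,fa,md `connectome` objects (or symmetric matrices)
#'   of the corresponding weight kinds.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param brain_volume Total brain volume in mm^3.
#' @param group Diagnostic group: `"control"`, `"bvFTD"` or `"EOAD"`.
#' @param mmse Mini Mental State Examination score in `[0, 30]`, or `NA`.
#' @return An object of class `"subject_record"`.
#' @export
subject_record <- function(subject_id, fiber_density, fa, md,
                           age, sex = c("M", "F"),
                           brain_volume,
                           group = c("control", "bvFTD", "EOAD"),
                           mmse = NA_real_) {
  sex <- match.arg(sex)
  group <- match.arg(group)
  if (!inherits(fiber_density, "connectome")) {
    fiber_density <- connectome(fiber_density, "fiber_density")
  }
  if (!inherits(fa, "connectome")) fa <- connectome(fa, "FA")
  if (!inherits(md, "connectome")) md <- connectome(md, "MD")
  stopifnot(fiber_density$weight_kind == "fiber_density",
            fa$weight_kind == "FA", md$weight_kind == "MD")
  supp <- fiber_density$weights > 0
  if (any((fa$weights > 0) & !supp) || any((md$weights > 0) & !supp)) {
    stop("FA/MD weights present on edges with zero fiber density for ",
         "subject ", subject_id, call. = FALSE)
  }
  if (!is.na(mmse) && (mmse < 0 || mmse > 30)) {
    stop("mmse must be in [0, 30] or NA", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 matrices = list(fiber_density = fiber_density,
                                 FA = fa, MD = md),
                 age = as.numeric(age), sex = sex,
                 brain_volume = as.numeric(brain_volume),
                 group = group, mmse = as.numeric(mmse)),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id, " [", x$group, "] age ", x$age,
      ", sex ", x$sex, ", E = ", edge_count(x$matrices$fiber_density),
      "\n", sep = "")
  invisible(x)
}

#' Assemble subjects into a cohort
#'
#' Computes the cohort-wide edge support: the set of node pairs connected in
#' at least one subject's fiber-density matrix. Pairs never connected in any
#' subject are excluded from all edgewise analyses.
#'
#' @param subjects List of [subject_record()] objects sharing one node set.
#' @return An object of class `"cohort"`: list with `subjects`, `labels`,
#'   and `edge_support` (logical symmetric matrix).
#' @export
cohort <- function(subjects) {
  stopifnot(length(subjects) >= 1L,
            all(vapply(subjects, inherits, logical(1), "subject_record")))
  labels <- subjects[[1L]]$matrices$fiber_density$labels
  for (s in subjects) {
    if (!identical(s$matrices$fiber_density$labels, labels)) {
      stop("all subjects must share the same node labels", call. = FALSE)
    }
  }
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicated subject_id", call. = FALSE)
  supp <- Reduce(`|`, lapply(subjects, function(s) {
    s$matrices$fiber_density$weights > 0
  }))
  structure(list(subjects = subjects, labels = labels, edge_support = supp),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(cohort_groups(x))
  cat("<cohort> ", length(x$subjects), " subjects (",
      paste(names(grp), grp, sep = ": ", collapse = ", "), "), ",
      sum(x$edge_support[upper.tri(x$edge_support)]),
      " supported edges\n", sep = "")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$subjects)

cohort_groups <- function(ch) {
  vapply(ch$subjects, `[[`, character(1), "group")
}

#' Extract the covariate table of a cohort
#'
#' @param ch A [cohort()].
#' @return A data.frame with columns `subject_id`, `age`, `sex`,
#'   `brain_volume`, `group`, `mmse`.
#' @export
covariate_frame <- function(ch) {
  stopifnot(inherits(ch, "cohort"))
  data.frame(
    subject_id = vapply(ch$subjects, `[[`, character(1), "subject_id"),
    age = vapply(ch$subjects, `[[`, numeric(1), "age"),
    sex = vapply(ch$subjects, `[[`, character(1), "sex"),
    brain_volume = vapply(ch$subjects, `[[`, numeric(1), "brain_volume"),
    group = cohort_groups(ch),
    mmse = vapply(ch$subjects, `[[`, numeric(1), "mmse"),
    stringsAsFactors = FALSE
  )
}

#' Subset a cohort to given diagnostic groups
#'
#' @param ch A [cohort()].
#' @param groups Character vector of groups to keep.
#' @param recompute_support Recompute `edge_support` from the kept subjects
#'   (default) or keep the full cohort's support.
#' @return A [cohort()].
#' @export
cohort_subset <- function(ch, groups, recompute_support = TRUE) {
  keep <- cohort_groups(ch) %in% groups
  if (!any(keep)) stop("no subjects in groups: ",
                       paste(groups, collapse = ", "), call. = FALSE)
  sub <- cohort(ch$subjects[keep])
  if (!recompute_support) sub$edge_support <- ch$edge_support
  sub
}

# Matrix of one measure across subjects: n_subjects x n_items.
# kind = weight kind for edge weights; measure = "edge" | "degree".
cohort_measure_matrix <- function(ch, measure = c("edge", "degree"),
                                  kind = "fiber_density",
                                  support = ch$edge_support) {
  measure <- match.arg(measure)
  if (measure == "degree") {
    Y <- t(vapply(ch$subjects,
                  function(s) as.numeric(nodal_degree(s$matrices$fiber_density)),
                  numeric(length(ch$labels))))
    colnames(Y) <- ch$labels
    return(Y)
  }
  pairs <- which(upper.tri(support) & support, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  Y <- t(vapply(ch$subjects,
                function(s) s$matrices[[kind]]$weights[pairs],
                numeric(nrow(pairs))))
  colnames(Y) <- paste(ch$labels[pairs[, 1L]], ch$labels[pairs[, 2L]],
                       sep = "--")
  attr(Y, "pairs") <- pairs
  Y
}

# ---- File formats ----------------------------------------------------------

#' Read / write a connectivity matrix as TSV
#'
#' Plain-text tab-separated square matrix, optionally with a header row and
#' leading label column (auto-detected on read).
#'
#' @param path File path.
#' @param weight_kind Weight kind to attach to the matrix on read.
#' @return `read_connectome_tsv()` returns a `connectome`;
#'   `write_connectome_tsv()` returns `path` invisibly.
#' @export
read_connectome_tsv <- function(path,
                                weight_kind = c("fiber_density", "FA", "MD")) {
  weight_kind <- match.arg(weight_kind)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) {
    df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                            check.names = FALSE)
    w <- as.matrix(df)
    labels <- rownames(df)
  } else {
    w <- as.matrix(utils::read.delim(path, header = FALSE))
    labels <- NULL
  }
  storage.mode(w) <- "double"
  dimnames(w) <- NULL
  connectome(w, weight_kind, labels = labels)
}

#' @rdname read_connectome_tsv
#' @param m A `connectome` (or symmetric matrix).
#' @export
write_connectome_tsv <- function(m, path) {
  w <- conn_weights(m)
  df <- as.data.frame(w)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a covariate table
#'
#' CSV with columns `subject_id`, `age`, `sex`, `brain_volume`, `group`,
#' `mmse` (missing MMSE as empty or NA).
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "brain_volume", "group", "mmse")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("covariate table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$mmse <- as.numeric(df$mmse)
  df
}

#' Load a cohort from a directory of matrix TSVs plus a covariate CSV
#'
#' Expects, for every `subject_id` in the covariate table, files
#' `<id>_fiber_density.tsv`, `<id>_FA.tsv` and `<id>_MD.tsv` under `dir`.
#'
#' @param dir Directory containing the per-subject matrix files.
#' @param covariates Path to the covariate CSV (default
#'   `file.path(dir, "covariates.csv")`).
#' @return A [cohort()].
#' @export
read_cohort <- function(dir, covariates = file.path(dir, "covariates.csv")) {
  cov <- read_covariates_csv(covariates)
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    id <- cov$subject_id[i]
    mats <- lapply(weight_kinds(), function(kind) {
      read_connectome_tsv(file.path(dir, paste0(id, "_", kind, ".tsv")),
                          weight_kind = kind)
    })
    names(mats) <- weight_kinds()
    subject_record(id, mats$fiber_density, mats$FA, mats$MD,
                   age = cov$age[i], sex = cov$sex[i],
                   brain_volume = cov$brain_volume[i], group = cov$group[i],
                   mmse = cov$mmse[i])
  })
  cohort(subjects)
}

#' Write a cohort to a directory of matrix TSVs plus a covariate CSV
#'
#' @param ch A [cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ch$subjects) {
    for (kind in weight_kinds()) {
      write_connectome_tsv(
        s$matrices[[kind]],
        file.path(dir, paste0(s$subject_id, "_", kind, ".tsv"))
      )
    }
  }
  utils::write.csv(covariate_frame(ch), file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  invisible(dir)
}
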
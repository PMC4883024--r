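# Homologue of a lh_/rh_ label (NA when the label has no hemisphere prefix).
homologue <- function(labels) {
  ifelse(startsWith(labels, "lh_"), sub("^lh_", "rh_", labels),
         ifelse(startsWith(labels, "rh_"), sub("^rh_", "lh_", labels),
                NA_character_))
}

#' Select rich-club nodes from a cohort
#'
#' Data-driven rich-club membership by a rule cascade: a node qualifies when
#' its group-mean fiber-density degree is at least `degree_floor` in *every*
#' diagnostic group (consistency across groups); the qualifying set is then
#' symmetrized bilaterally (if one hemisphere's region qualifies, its
#' homologue is included too, when `bilateral = TRUE`), and any labels in
#' `overrides` are force-included. The rule parameters, including the
#' rich-club regime threshold `k_threshold` and the nominal `top_fraction`
#' the membership size is compared against, are recorded with the result so
#' a membership is always auditable.
#'
#' Node selection always uses the fiber-density matrices; FA and MD
#' analyses reuse the same membership.
#'
#' @param ch A [cohort()].
#' @param k_threshold Degree level separating the low- and high-degree
#'   rich-club regimes (recorded; default 15).
#' @param degree_floor Minimum group-mean nodal degree for membership
#'   (default 30).
#' @param top_fraction Nominal fraction of most interconnected nodes the
#'   membership aims to cover (recorded; default 0.12).
#' @param overrides Character vector of labels to force-include.
#' @param bilateral Include the hemispheric homologue of every selected
#'   region (default TRUE).
#' @return An object of class `"rich_node_set"`: list with `members`
#'   (sorted node indices), `labels`, and `rule`.
#' @seealso [rich_club_regions()] for the previously reported membership.
#' @export
select_rich_nodes <- function(ch, k_threshold = 15L, degree_floor = 30,
                              top_fraction = 0.12, overrides = NULL,
                              bilateral = TRUE) {
  stopifnot(inherits(ch, "cohort"), length(ch$subjects) >= 1L)
  labels <- ch$labels
  bad <- setdiff(overrides, labels)
  if (length(bad)) {
    stop("override labels not in node list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  deg <- cohort_measure_matrix(ch, "degree")
  grp <- cohort_groups(ch)
  group_means <- vapply(unique(grp), function(g) {
    colMeans(deg[grp == g, , drop = FALSE])
  }, numeric(length(labels)))
  qualifies <- apply(group_means >= degree_floor, 1L, all)
  selected <- labels[qualifies]
  if (bilateral) {
    hom <- homologue(selected)
    selected <- union(selected, hom[!is.na(hom) & hom %in% labels])
  }
  selected <- union(selected, overrides)
  members <- sort(match(selected, labels))
  structure(list(members = members, labels = labels[members],
                 rule = list(k_threshold = k_threshold,
                             degree_floor = degree_floor,
                             top_fraction = top_fraction,
                             bilateral = bilateral,
                             overrides = overrides %||% character(0))),
            class = "rich_node_set")
}

#' Construct a rich-node set from explicit labels
#'
#' @param labels Member labels.
#' @param all_labels Full node label list (default [dk68_labels()]).
#' @param rule Optional record of how the membership was derived.
#' @return A `"rich_node_set"`.
#' @export
rich_node_set <- function(labels, all_labels = dk68_labels(), rule = NULL) {
  bad <- setdiff(labels, all_labels)
  if (length(bad)) {
    stop("labels not in node list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  members <- sort(match(unique(labels), all_labels))
  structure(list(members = members, labels = all_labels[members],
                 rule = rule %||% list(source = "explicit")),
            class = "rich_node_set")
}

#' @export
print.rich_node_set <- function(x, ...) {
  cat("<rich_node_set> ", length(x$members), " members\n", sep = "")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Normalize a support argument (cohort / connectome / logical or numeric
# symmetric matrix) to a 2-column matrix of upper-triangle pairs.
support_pairs <- function(support) {
  if (inherits(support, "cohort")) support <- support$edge_support
  if (inherits(support, "connectome")) support <- support$weights > 0
  if (is.matrix(support) && nrow(support) == ncol(support)) {
    keep <- upper.tri(support) & (support > 0)
    p <- which(keep, arr.ind = TRUE)
    return(p[order(p[, 1L], p[, 2L]), , drop = FALSE])
  }
  if (is.matrix(support) && ncol(support) == 2L) {
    p <- cbind(pmin(support[, 1L], support[, 2L]),
               pmax(support[, 1L], support[, 2L]))
    return(p[order(p[, 1L], p[, 2L]), , drop = FALSE])
  }
  stop("`support` must be a cohort, connectome, square matrix or a ",
       "2-column pair matrix", call. = FALSE)
}

#' Classify edges as rich-club, feeder or local
#'
#' Partitions the present edges by the number of endpoints inside the
#' rich-club node set: both endpoints rich -> `rich_club`, exactly one ->
#' `feeder`, neither -> `local`. Classification depends only on the binary
#' support and the membership, never on weights.
#'
#' @param support A [cohort()] (its `edge_support`), a `connectome`, a
#'   square logical/numeric matrix, or a 2-column matrix of node-index
#'   pairs.
#' @param rich A `"rich_node_set"` or an integer vector of member indices.
#' @return An object of class `"edge_class_map"`: data.frame with columns
#'   `i`, `j`, `class` (factor rich_club/feeder/local), plus a `counts`
#'   attribute with per-class totals summing to E.
#' @examples
#' square <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
#' classify_edges(square, rich = c(1, 2))
#' @export
classify_edges <- function(support, rich) {
  pairs <- support_pairs(support)
  members <- if (inherits(rich, "rich_node_set")) rich$members else
    as.integer(rich)
  in_rich_i <- pairs[, 1L] %in% members
  in_rich_j <- pairs[, 2L] %in% members
  n_rich_ends <- in_rich_i + in_rich_j
  cls <- factor(c("local", "feeder", "rich_club")[n_rich_ends + 1L],
                levels = c("rich_club", "feeder", "local"))
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L], class = cls)
  counts <- table(cls)
  structure(out, counts = stats::setNames(as.integer(counts), names(counts)),
            class = c("edge_class_map", "data.frame"))
}

#' @export
print.edge_class_map <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("<edge_class_map> ", nrow(x), " edges (",
      paste(names(counts), counts, sep = ": ", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Per-class edge counts of a map
#'
#' @param map An `"edge_class_map"`.
#' @return Named integer vector `(rich_club, feeder, local)`; sums to E.
#' @export
edge_class_counts <- function(map) {
  stopifnot(inherits(map, "edge_class_map"))
  attr(map, "counts")
}

#' Rich-club / feeder / local edge counts for one subject
#'
#' Counts the subject's nonzero fiber-density edges in each class. These
#' per-subject counts feed the group means (and SDs) that serve as the
#' expected class totals in the chi-squared enrichment tests.
#'
#' @param subject A [subject_record()].
#' @param rich A `"rich_node_set"` or integer member indices.
#' @return Named integer vector `(rich_club, feeder, local)`.
#' @export
per_subject_class_counts <- function(subject, rich) {
  stopifnot(inherits(subject, "subject_record"))
  w <- subject$matrices$fiber_density$weights
  if (edge_count(w) == 0L) {
    return(c(rich_club = 0L, feeder = 0L, local = 0L))
  }
  edge_class_counts(classify_edges(w, rich))
}

#' Read / write a rich-club membership file (one label per line)
#'
#' @param path File path.
#' @param all_labels Full node label list.
#' @return `read_membership()` returns a `"rich_node_set"`.
#' @export
read_membership <- function(path, all_labels = dk68_labels()) {
  rich_node_set(readLines(path), all_labels = all_labels,
                rule = list(source = path))
}

#' @rdname read_membership
#' @param rich A `"rich_node_set"`.
#' @export
write_membership <- function(rich, path) {
  writeLines(rich$labels, path)
  invisible(path)
}
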
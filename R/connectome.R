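#' Weight kinds for connectome matrices
#'
#' The three edge-weight definitions used throughout the package:
#' streamline-count based fiber density, mean fractional anisotropy (FA)
#' along the connecting tracts, and mean diffusivity (MD) along them.
#'
#' @return Character vector of the three recognised weight kinds.
#' @export
weight_kinds <- function() c("fiber_density", "FA", "MD")

#' Canonical 68-region cortical node labels
#'
#' The Desikan-Killiany cortical parcellation, 34 regions per hemisphere,
#' in the package's canonical order: all left-hemisphere labels
#' (`lh_` prefix, alphabetical) followed by all right-hemisphere labels
#' (`rh_` prefix, alphabetical). Every 68-node matrix in the package is
#' indexed in this order unless labels are supplied explicitly.
#'
#' @return Character vector of length 68.
#' @export
dk68_labels <- function() {
  path <- system.file("extdata", "dk68_labels.txt", package = "richclubnet",
                      mustWork = TRUE)
  readLines(path)
}

#' Previously reported rich-club membership (13 bilateral regions)
#'
#' The 26-node rich-club membership reported for 68-node cortical networks
#' at the k > 15 rich-club regime: precuneus, posterior cingulate, superior
#' parietal, superior frontal and insula (the classical hub epicenters),
#' extended with the isthmus cingulate, fusiform, inferior temporal, lateral
#' orbitofrontal, lingual, parahippocampal, precentral and rostral anterior
#' cingulate, bilaterally. Shipping this membership lets the edge taxonomy
#' and enrichment stages be run exactly as published, independent of any
#' data-driven node selection.
#'
#' @return Character vector of 26 node labels (subset of [dk68_labels()]).
#' @seealso [select_rich_nodes()] for data-driven selection.
#' @export
rich_club_regions <- function() {
  path <- system.file("extdata", "rich_club_regions.txt",
                      package = "richclubnet", mustWork = TRUE)
  readLines(path)
}

#' Construct a connectome matrix
#'
#' Wraps one subject's symmetric nonnegative weighted adjacency matrix for a
#' single weight kind, validating the invariants every downstream stage
#' relies on: square and symmetric (asymmetries up to `tol` are averaged
#' away, larger ones are an error), zero diagonal, nonnegative entries, and
#' FA weights bounded by 1.
#'
#' @param weights Square numeric matrix of edge weights; entry (i, j) is the
#'   weight of the connection between regions i and j.
#' @param weight_kind One of `"fiber_density"`, `"FA"`, `"MD"`.
#' @param labels Character vector of node labels, one per row. Defaults to
#'   the matrix dimnames, or [dk68_labels()] for 68-node matrices, or
#'   `"n1"`, `"n2"`, ... otherwise.
#' @param tol Largest tolerated absolute asymmetry `|w[i,j] - w[j,i]|`.
#' @return An object of class `"connectome"`: a list with elements
#'   `weights` (matrix with label dimnames), `weight_kind` and `labels`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2.5; w[2, 3] <- w[3, 2] <- 2.5
#' m <- connectome(w, "fiber_density", labels = c("a", "b", "c"))
#' nodal_degree(m)
#' @export
connectome <- function(weights,
                       weight_kind = c("fiber_density", "FA", "MD"),
                       labels = NULL, tol = 1e-8) {
  weight_kind <- match.arg(weight_kind)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop("invalid connectome matrix: not square (", n, " x ", ncol(weights),
         ")", call. = FALSE)
  }
  if (anyNA(weights)) {
    stop("invalid connectome matrix: contains missing values", call. = FALSE)
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    stop("invalid connectome matrix: asymmetry ", format(asym),
         " exceeds tolerance ", format(tol), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(weights < 0)) {
    stop("invalid connectome matrix: negative weights", call. = FALSE)
  }
  if (weight_kind == "FA" && any(weights > 1)) {
    stop("FA weights must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(weights) %||%
      (if (n == 68L) dk68_labels() else paste0("n", seq_len(n)))
  }
  if (length(labels) != n) {
    stop("`labels` length (", length(labels),
         ") does not match matrix dimension (", n, ")", call. = FALSE)
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, weight_kind = weight_kind,
                 labels = labels),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", length(x$labels), " nodes, ", edge_count(x),
      " edges, weight kind: ", x$weight_kind, "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.connectome <- function(x, ...) x$weights

# Accept either a connectome or a bare symmetric matrix.
conn_weights <- function(m) {
  if (inherits(m, "connectome")) return(m$weights)
  connectome(m, "fiber_density")$weights
}

#' Nodal degree
#'
#' The degree k of a node is the number of distinct regions it is connected
#' to by at least one reconstructed fiber, i.e. the count of strictly
#' positive incident weights. No minimum-weight threshold is applied.
#'
#' @param m A `connectome` or a symmetric nonnegative matrix.
#' @return Named integer vector, one degree per node, each in `[0, n - 1]`.
#' @export
nodal_degree <- function(m) {
  w <- conn_weights(m)
  deg <- as.integer(rowSums(w > 0))
  names(deg) <- rownames(w)
  deg
}

#' Number of network edges
#'
#' Counts unordered node pairs with a strictly positive weight (the global
#' measure E).
#'
#' @inheritParams nodal_degree
#' @return Integer edge count.
#' @export
edge_count <- function(m) {
  w <- conn_weights(m)
  as.integer(sum(w[upper.tri(w)] > 0))
}

#' Nodal strength
#'
#' The strength of a node is the sum of its incident edge weights. In
#' healthy cortical networks fiber-density strengths are fat-tailed,
#' following an exponentially truncated power law.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector of strengths; their total equals twice the
#'   total edge weight.
#' @export
node_strength <- function(m) {
  w <- conn_weights(m)
  s <- rowSums(w)
  names(s) <- rownames(w)
  s
}
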
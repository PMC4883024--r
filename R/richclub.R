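#' Weighted rich-club coefficient at one degree level
#'
#' For a degree level k, take the subnetwork induced by all nodes of degree
#' strictly greater than k. With `E_k` the number of edges inside that
#' subnetwork and `W_k` the sum of their weights, the weighted rich-club
#' coefficient is
#' \deqn{\Phi^w(k) = W_{>k} / \sum_{l=1}^{E_{>k}} w_l^{ranked},}
#' the ratio of `W_k` to the sum of the `E_k` strongest edge weights found
#' anywhere in the network. It equals 1 when the subnetwork of the high
#' degree nodes carries the strongest connections of the whole network, and
#' is undefined (`NA`) when the subnetwork contains no edges.
#'
#' @param m A `connectome` or symmetric nonnegative matrix.
#' @param k Degree level, a nonnegative integer.
#' @return `Phi^w(k)` in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' w <- matrix(0, 5, 5)
#' w[1, 2] <- 5; w[1, 3] <- 4; w[2, 3] <- 3; w[3, 4] <- 2; w[4, 5] <- 1
#' w <- w + t(w)
#' weighted_rich_club(w, 1)  # 1: the k>1 core carries the 4 strongest edges
#' weighted_rich_club(w, 2)  # NA: the k>2 subnetwork has no edges
#' @export
weighted_rich_club <- function(m, k) {
  if (length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single nonnegative integer", call. = FALSE)
  }
  w <- conn_weights(m)
  deg <- rowSums(w > 0)
  rich <- deg > k
  if (sum(rich) < 2L) return(NA_real_)
  sub <- w[rich, rich, drop = FALSE]
  subw <- sub[upper.tri(sub)]
  subw <- subw[subw > 0]
  e_k <- length(subw)
  if (e_k == 0L) return(NA_real_)
  all_w <- w[upper.tri(w)]
  all_w <- all_w[all_w > 0]
  top <- sort(all_w, decreasing = TRUE)[seq_len(e_k)]
  sum(subw) / sum(top)
}

#' Degree-preserving randomized null networks
#'
#' Generates random networks with exactly the same number of nodes, the same
#' degree sequence and the same multiset of edge weights as `m`: the binary
#' support is rewired by Maslov-Sneppen double-edge swaps (10 x E attempted
#' swaps per replicate), and the original weights are then randomly permuted
#' onto the rewired edges. These are the null networks against which the
#' observed rich-club coefficient is normalized.
#'
#' Networks too sparse to rewire (fewer than two edges) fall back to a
#' weight-reshuffled copy of the original support, with a warning.
#'
#' @param m A `connectome` or symmetric nonnegative matrix.
#' @param n_random Number of replicates (the conventional choice is 500).
#' @param seed Optional integer seed; replicates are reproducible from it.
#' @param swap_multiplier Attempted swaps per replicate, as a multiple of E.
#' @return List of `n_random` weight matrices.
#' @export
randomized_null <- function(m, n_random = 500L, seed = NULL,
                            swap_multiplier = 10) {
  stopifnot(n_random >= 1L)
  w <- conn_weights(m)
  n <- nrow(w)
  pairs <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  wts <- w[pairs]
  n_edge <- length(wts)
  if (n_edge < 2L) {
    warning("network too sparse to rewire; returning weight-reshuffled ",
            "copies of the original support")
    return(with_seed(seed, replicate(n_random, {
      r <- matrix(0, n, n)
      r[pairs] <- wts[sample.int(n_edge)]
      r + t(r)
    }, simplify = FALSE)))
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  with_seed(seed, replicate(n_random, {
    rg <- igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE,
                                niter = ceiling(swap_multiplier * n_edge)))
    el <- igraph::as_edgelist(rg, names = FALSE)
    r <- matrix(0, n, n)
    r[el] <- sample(wts)
    r <- r + t(r)
    r
  }, simplify = FALSE))
}

#' Weighted rich-club curve with random-network normalization
#'
#' Computes the observed weighted rich-club coefficient `Phi^w(k)` for
#' `k = 1..k_max`, the same coefficient on `n_random` degree-preserving null
#' networks (see [randomized_null()]), and the normalized curve
#' `Phi_n(k) = Phi^w(k) / mean(Phi^w_rand(k))`. A rich-club phenomenon is
#' present where `Phi_n > 1` over a range of k. Entries are `NA` wherever
#' the observed or null coefficient is undefined (empty subnetwork) or the
#' null mean is zero; they are never silently set to 0.
#'
#' @inheritParams randomized_null
#' @param k_max Highest degree level evaluated (default 30, covering the
#'   k ranges typically reported for 68-node cortical networks).
#' @return An object of class `"rich_club_curve"`: list with `k`, `phi_w`,
#'   `phi_rand_mean`, `phi_norm`, `phi_rand` (replicates x k matrix),
#'   `weight_kind`, `n_random`.
#' @examples
#' m <- connectome(matrix(1, 8, 8) - diag(8), "fiber_density")
#' rc <- rich_club_curve(m, k_max = 5, n_random = 10, seed = 1)
#' rc$phi_norm  # all 1: a complete unit-weight graph has no rich club
#' @export
rich_club_curve <- function(m, k_max = 30L, n_random = 500L, seed = NULL) {
  w <- conn_weights(m)
  n <- nrow(w)
  if (k_max > n - 1L) {
    stop("`k_max` must be at most n - 1 = ", n - 1L, call. = FALSE)
  }
  kind <- if (inherits(m, "connectome")) m$weight_kind else "fiber_density"
  ks <- seq_len(k_max)
  phi_w <- vapply(ks, function(k) weighted_rich_club(w, k), numeric(1))
  nulls <- randomized_null(w, n_random = n_random, seed = seed)
  phi_rand <- vapply(nulls, function(r) {
    vapply(ks, function(k) weighted_rich_club(r, k), numeric(1))
  }, numeric(k_max))
  phi_rand <- t(matrix(phi_rand, nrow = k_max))  # n_random x k_max
  phi_rand_mean <- colMeans(phi_rand, na.rm = TRUE)
  phi_rand_mean[!is.finite(phi_rand_mean)] <- NA_real_
  phi_norm <- ifelse(!is.na(phi_w) & !is.na(phi_rand_mean) &
                       phi_rand_mean > 0,
                     phi_w / phi_rand_mean, NA_real_)
  structure(list(k = ks, phi_w = phi_w, phi_rand_mean = phi_rand_mean,
                 phi_norm = phi_norm, phi_rand = phi_rand,
                 weight_kind = kind, n_random = n_random),
            class = "rich_club_curve")
}

#' @export
print.rich_club_curve <- function(x, ...) {
  defined <- which(!is.na(x$phi_norm))
  cat("<rich_club_curve> weight kind: ", x$weight_kind, ", k = 1..",
      max(x$k), ", ", x$n_random, " null networks\n", sep = "")
  if (length(defined)) {
    above <- defined[x$phi_norm[defined] > 1]
    cat("  Phi_n defined at k = ", min(defined), "..", max(defined),
        "; Phi_n > 1 at ", length(above), " of ", length(defined),
        " levels\n", sep = "")
  } else {
    cat("  Phi_n undefined at all k\n")
  }
  invisible(x)
}

#' @export
as.data.frame.rich_club_curve <- function(x, ...) {
  data.frame(weight_kind = x$weight_kind, k = x$k, phi_w = x$phi_w,
             phi_rand_mean = x$phi_rand_mean, phi_norm = x$phi_norm)
}

#' @export
summary.rich_club_curve <- function(object, ...) {
  df <- as.data.frame(object)
  qs <- apply(object$phi_rand, 2L, stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  df$null_lo <- qs[1L, ]
  df$null_hi <- qs[2L, ]
  df
}

#' Plot a normalized rich-club curve
#'
#' @param x A `rich_club_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rich_club_curve <- function(x, ...) {
  graphics::plot(x$k, x$phi_norm, type = "b", pch = 16,
                 xlab = "nodal degree level k",
                 ylab = expression(Phi[n]),
                 main = paste0("Normalized weighted rich club (",
                               x$weight_kind, ")"), ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}
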
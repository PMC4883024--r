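# Independent oracles and fixture builders used across the suite.

# Brute-force weighted rich-club coefficient: naive loops only, no shared
# code with the package implementation.
bf_rich_club <- function(w, k) {
  n <- nrow(w)
  deg <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && w[i, j] > 0) deg[i] <- deg[i] + 1L
    }
  }
  rich <- which(deg > k)
  sub_w <- c()
  for (a in rich) {
    for (b in rich) {
      if (a < b && w[a, b] > 0) sub_w <- c(sub_w, w[a, b])
    }
  }
  if (length(sub_w) == 0L) return(NA_real_)
  all_w <- c()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && w[a, b] > 0) all_w <- c(all_w, w[a, b])
    }
  }
  top <- sort(all_w, decreasing = TRUE)[seq_along(sub_w)]
  sum(sub_w) / sum(top)
}

# Brute-force Benjamini-Hochberg: O(n^2) search over candidate thresholds.
bf_bh_reject <- function(p, q) {
  n <- length(p)
  crit <- 0
  for (i in seq_len(n)) {
    n_le <- sum(p <= p[i])
    if (p[i] <= q * n_le / n && p[i] > crit) crit <- p[i]
  }
  p <= crit & crit > 0
}

# Random symmetric integer-weight matrix on n nodes (weights 0..wmax).
random_small_graph <- function(n, density = 0.5, wmax = 5) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < density, sample(wmax, sum(up), TRUE), 0)
  w[up] <- vals
  w + t(w)
}

# Small, fast cohort spec: 16 nodes (8 bilateral regions), 6-node core.
small_spec <- function(...) {
  regions <- c("alpha", "beta", "gamma", "delta", "eps", "zeta", "eta",
               "theta")
  labels <- c(paste0("lh_", regions), paste0("rh_", regions))
  core <- c(paste0("lh_", regions[1:3]), paste0("rh_", regions[1:3]))
  cohort_spec(n_per_group = c(control = 8, bvFTD = 6, EOAD = 6),
              labels = labels, rich_core = core, base_density = 0.55,
              ...)
}

# Covariate table for n synthetic subjects.
fake_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    age = rnorm(n, 60, 9),
    sex = rep(c("M", "F"), length.out = n),
    brain_volume = rnorm(n, 1.15e6, 1e5),
    group = rep(c("control", "bvFTD"), length.out = n),
    mmse = round(runif(n, 20, 30)),
    stringsAsFactors = FALSE
  )
}
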
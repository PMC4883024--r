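test_that("residualization removes exactly the modelled covariates", {
  cov <- fake_covariates(40, seed = 2)
  # values exactly linear in the covariates leave ~zero residuals
  y <- 3 + 0.5 * cov$age - 2 * (cov$sex == "M") + 1e-6 * cov$brain_volume
  expect_lt(max(abs(residualize(y, cov))), 1e-8)

  # values orthogonal to the covariates come back centered
  set.seed(5)
  noise <- rnorm(40)
  X <- cbind(1, cov$age, cov$sex == "M", cov$brain_volume)
  y_orth <- qr.resid(qr(X), noise)
  expect_equal(residualize(y_orth, cov), y_orth, tolerance = 1e-10)
  expect_lt(abs(sum(residualize(noise, cov))), 1e-8)

  # planted age slope is recovered within 2 SE
  set.seed(6)
  beta <- 0.8
  y_age <- beta * cov$age + rnorm(40, 0, 1)
  fit <- summary(lm(y_age ~ age + I(sex == "M") + brain_volume,
                    data = cov))
  expect_lt(abs(fit$coefficients["age", "Estimate"] - beta),
            2 * fit$coefficients["age", "Std. Error"])
  res <- residualize(y_age, cov)
  expect_lt(abs(cor(res, cov$age)), 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  cov <- fake_covariates(20)
  cov$brain_volume <- cov$age * 1000  # collinear with age
  expect_error(residualize(rnorm(20), cov), "brain_volume")
  expect_error(residualize(rnorm(3), fake_covariates(3)), "at least 5")
})

test_that("permutation p follows (b+1)/(m+1) with its floor and ceiling", {
  cov <- fake_covariates(30, seed = 3)
  set.seed(4)
  grp <- rep(c("a", "b"), each = 15)
  # overwhelming group effect: no permutation can beat it -> b = 0
  y <- ifelse(grp == "a", 0, 50) + rnorm(30, 0, 0.01)
  res <- residualize(y, cov)
  pt <- permutation_group_test(res, grp, m = 999, seed = 1)
  expect_identical(pt$b, 0L)
  expect_equal(pt$p_perm, 1 / 1000)

  # degenerate residuals: p = 1 with a warning
  expect_warning(p1 <- permutation_group_test(rep(2, 30), grp, m = 99),
                 "degenerate")
  expect_equal(p1$p_perm, 1)
  expect_identical(p1$b, 99L)
})

test_that("the permutation p is invariant to group relabeling", {
  set.seed(11)
  y <- rnorm(24)
  grp <- rep(c("x", "y"), each = 12)
  a <- permutation_group_test(y, grp, m = 500, seed = 21)
  b <- permutation_group_test(y, rev(grp), m = 500, seed = 21)
  expect_equal(a$p_perm, b$p_perm)
  expect_equal(abs(a$t_obs), abs(b$t_obs))
})

test_that("permutation p matches exhaustive enumeration at small n", {
  set.seed(12)
  y <- rnorm(8)
  grp <- rep(c("a", "b"), each = 4)
  tstat <- function(lab) abs(t.test(y[lab == "a"], y[lab == "b"],
                                    var.equal = TRUE)$statistic)
  t_obs <- tstat(grp)
  # enumerate all C(8,4) assignments
  combs <- combn(8, 4)
  t_all <- apply(combs, 2, function(idx) {
    lab <- rep("b", 8); lab[idx] <- "a"
    tstat(lab)
  })
  p_exact <- mean(t_all >= t_obs - 1e-12)
  m <- 4000
  pt <- permutation_group_test(y, grp, m = m, seed = 13)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / m) + 1 / (m + 1)
  expect_lt(abs(pt$p_perm - p_exact), mc_err + 0.01)
})

test_that("BH step-up matches hand-applied and brute-force rules", {
  r1 <- fdr_bh(rep(0.01, 8), q = 0.05)
  expect_true(all(r1$reject))
  expect_equal(r1$critical_p, 0.01)

  r2 <- fdr_bh(c(0.001, 0.04, 0.9), q = 0.05)
  expect_identical(r2$reject, c(TRUE, FALSE, FALSE))
  expect_equal(r2$critical_p, 0.001)

  r3 <- fdr_bh(numeric(0))
  expect_identical(r3$reject, logical(0))
  expect_true(is.na(r3$critical_p))
  expect_error(fdr_bh(c(0.1, 0)), "p-values")

  set.seed(14)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    p <- runif(n)^sample(c(1, 2, 4), 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- fdr_bh(p, q)
    expect_identical(got$reject, bf_bh_reject(p, q))
  }
})

test_that("chi-squared proportions behave at the boundaries", {
  # identical affected proportions carry zero signal
  flat <- chi2_proportions(c(10, 20, 30), c(100, 200, 300))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # 2x2 agrees with the two-sided two-proportion z-test
  res <- chi2_proportions(c(13, 6), c(26, 42))
  z <- prop.test(c(13, 6), c(26, 42), correct = FALSE)
  expect_equal(res$p_value, z$p.value)
  expect_identical(res$df, 1L)

  # df = 2: upper tail is exactly exp(-chi2 / 2)
  res3 <- chi2_proportions(c(23, 12, 4), c(195, 442, 206))
  expect_identical(res3$df, 2L)
  expect_equal(res3$p_value, exp(-res3$statistic / 2))

  expect_error(chi2_proportions(c(5, 1), c(4, 10)), "exceed")
  expect_warning(zero <- chi2_proportions(c(3, 0, 5), c(10, 0, 20)),
                 "zero total")
  expect_identical(zero$df, 1L)
})

test_that("edgewise testing reduces to the single-measure test", {
  ch <- generate_cohort(small_spec(), seed = 20)
  et <- edgewise_group_test(ch, "fiber_density", c("bvFTD", "control"),
                            m = 300, seed = 30)
  pick <- which.min(et$items$p_perm)
  # recompute that one edge by hand through the scalar path
  cov <- covariate_frame(ch)
  keep <- cov$group %in% c("bvFTD", "control")
  i <- et$items$i[pick]; j <- et$items$j[pick]
  y <- vapply(ch$subjects,
              function(s) s$matrices$fiber_density$weights[i, j],
              numeric(1))[keep]
  res <- residualize(y, cov[keep, ])
  pt <- permutation_group_test(res, cov$group[keep] == "bvFTD",
                               m = 300, seed = 30)
  expect_equal(pt$p_perm, et$items$p_perm[pick])
  expect_equal(abs(pt$t_obs), abs(et$items$t_obs[pick]), tolerance = 1e-8)
})

test_that("MMSE association flags strong signal and validates missingness", {
  ch <- generate_cohort(small_spec(), seed = 21)
  mm <- covariate_frame(ch)$mmse
  # measure proportional to MMSE: association survives covarying for
  # disease status (which itself explains much of the MMSE variance)
  strong <- mmse_association(ch, mm * 2.5, m = 400, seed = 7)
  expect_lt(strong$p_perm, 0.05)

  # missing-MMSE handling
  ch_bad <- ch
  for (i in seq_along(ch_bad$subjects)) ch_bad$subjects[[i]]$mmse <- NA_real_
  expect_error(mmse_association(ch_bad, mm, m = 50), "all subjects")
  ch_some <- ch
  for (i in 1:10) ch_some$subjects[[i]]$mmse <- NA_real_
  expect_error(mmse_association(ch_some, mm, m = 50), "80%")
})

test_that("MMSE permutation p matches exhaustive enumeration at small n", {
  set.seed(22)
  n <- 7
  y <- rnorm(n)
  mm <- sample(20:30, n)
  # no groups, no covariate signal: enumerate all n! permutations of MMSE
  r_obs <- abs(cor(y, mm))
  perms <- NULL
  idx <- seq_len(n)
  allperm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in allperm(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  rs <- vapply(allperm(idx), function(p) abs(cor(y, mm[p])), numeric(1))
  p_exact <- mean(rs >= r_obs - 1e-12)
  eng <- richclubnet:::perm_t_engine(matrix(y), mm, m = 3000, seed = 23)
  p_mc <- (eng$b + 1) / 3001
  expect_lt(abs(p_mc - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 3000) + 0.02)
})
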
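test_that("generation is bit-identical under a fixed seed", {
  a <- generate_cohort(small_spec(), seed = 31)
  b <- generate_cohort(small_spec(), seed = 31)
  c <- generate_cohort(small_spec(), seed = 32)
  expect_identical(covariate_frame(a), covariate_frame(b))
  for (i in c(1, 7, 15)) {
    expect_identical(a$subjects[[i]]$matrices, b$subjects[[i]]$matrices)
  }
  expect_identical(attr(a, "ground_truth")$lesioned,
                   attr(b, "ground_truth")$lesioned)
  expect_false(identical(a$subjects[[1]]$matrices,
                         c$subjects[[1]]$matrices))
})

test_that("base connectomes satisfy the planted structure", {
  spec <- cohort_spec()
  base <- generate_base_connectome(spec, seed = 33)
  fd <- base$fiber_density
  n_pairs <- choose(68, 2)

  # density near target
  expect_lt(abs(edge_count(fd) / n_pairs - spec$base_density), 0.05)

  # identical support across the three kinds
  supp <- fd$weights > 0
  expect_identical(base$FA$weights > 0, supp)
  expect_identical(base$MD$weights > 0, supp)

  # FA in [0,1] on edges, MD positive on edges
  up <- upper.tri(supp) & supp
  expect_true(all(base$FA$weights[up] > 0 & base$FA$weights[up] <= 1))
  expect_true(all(base$MD$weights[up] > 0))

  # planted core is a complete heavy subgraph
  core <- attr(base, "core")
  core_block <- fd$weights[core, core]
  expect_true(all(core_block[upper.tri(core_block)] > 0))

  # FA and MD anticorrelated across edges
  expect_lt(cor(base$FA$weights[up], base$MD$weights[up]), 0)

  # full density spec gives the complete graph; a density budget smaller
  # than the planted core is infeasible
  tiny <- small_spec()
  tiny$base_density <- 1
  full <- generate_base_connectome(tiny, seed = 1)
  expect_identical(edge_count(full$fiber_density), 120L)
  tiny$base_density <- 0.1  # 12 edges < the 15 core edges
  expect_error(generate_base_connectome(tiny, seed = 1), "infeasible")
})

test_that("the planted core occupies the top of the degree ranking", {
  for (seed in 34:38) {
    base <- generate_base_connectome(cohort_spec(), seed = seed)
    deg <- nodal_degree(base$fiber_density)
    core <- attr(base, "core")
    top26 <- order(deg, decreasing = TRUE)[1:26]
    expect_gte(length(intersect(top26, core)), 24)
  }
})

test_that("strengths favour a truncated power law over a pure power law", {
  base <- generate_base_connectome(cohort_spec(), seed = 39)
  s <- node_strength(base$fiber_density)
  s <- s[s > 0]
  s_min <- min(s)
  # both models fitted by maximum likelihood on [s_min, Inf):
  # truncated: f(s) ~ s^(-b) exp(-s/c); pure: f(s) ~ s^(-b)
  nll_trunc <- function(par) {
    b <- par[1]; cc <- exp(par[2])
    z <- stats::integrate(function(x) x^(-b) * exp(-x / cc), s_min, Inf,
                          rel.tol = 1e-9)$value
    -sum(-b * log(s) - s / cc - log(z))
  }
  nll_pure <- function(b) {
    if (b <= 1) return(Inf)
    z <- s_min^(1 - b) / (b - 1)
    -sum(-b * log(s) - log(z))
  }
  fit_t <- optim(c(0.5, log(mean(s))), nll_trunc)
  fit_p <- optimize(nll_pure, c(1.0001, 10))
  expect_lt(fit_t$value, fit_p$objective)
})

test_that("cohorts carry exact lesion ground truth", {
  ch <- generate_cohort(small_spec(), seed = 40)
  gt <- attr(ch, "ground_truth")
  base_supp <- gt$base$fiber_density$weights > 0
  core <- gt$core
  spec <- small_spec()

  for (g in c("bvFTD", "EOAD")) {
    les <- gt$lesioned[[g]]
    expect_gt(nrow(les), 0)
    # lesioned edges lie on the base support with the declared class
    for (r in seq_len(nrow(les))) {
      expect_true(base_supp[les$i[r], les$j[r]])
    }
    allowed <- unlist(lapply(spec$lesions[[g]], `[[`, "classes"))
    expect_true(all(les$class %in% allowed))
    recls <- classify_edges(cbind(les$i, les$j), core)
    expect_identical(as.character(recls$class[order(recls$i, recls$j)]),
                     as.character(les$class[order(les$i, les$j)]))
  }

  # lesion shifts the group mean on lesioned edges (fiber density down)
  grp <- vapply(ch$subjects, `[[`, character(1), "group")
  les <- gt$lesioned$EOAD
  mean_w <- vapply(ch$subjects, function(s) {
    mean(s$matrices$fiber_density$weights[cbind(les$i, les$j)])
  }, numeric(1))
  expect_lt(mean(mean_w[grp == "EOAD"]), mean(mean_w[grp == "control"]))
})

test_that("covariates and MMSE follow the study design", {
  ch <- generate_cohort(cohort_spec(), seed = 41)
  cv <- covariate_frame(ch)
  expect_identical(as.integer(table(cv$group)[c("control", "bvFTD",
                                                "EOAD")]),
                   c(37L, 20L, 23L))
  expect_true(all(cv$mmse >= 0 & cv$mmse <= 30))
  ctrl <- cv$mmse[cv$group == "control"]
  pats <- cv$mmse[cv$group != "control"]
  expect_lt(abs(mean(ctrl) - 29.1), 1)
  expect_lt(mean(pats), mean(ctrl))
  expect_lt(abs(mean(cv$age) - 59.6), 4)
})

test_that("a null cohort has exchangeable groups", {
  ch <- generate_null_cohort(small_spec(), seed = 42)
  gt <- attr(ch, "ground_truth")
  expect_true(all(vapply(gt$lesioned, nrow, integer(1)) == 0L))
  et <- edgewise_group_test(ch, "fiber_density", c("bvFTD", "control"),
                            m = 200, seed = 1)
  expect_identical(sum(et$items$reject), 0L)
})
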
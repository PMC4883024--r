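test_that("constructor enforces matrix invariants", {
  w <- matrix(1, 3, 3) - diag(3)
  m <- connectome(w, "fiber_density", labels = c("a", "b", "c"))
  expect_s3_class(m, "connectome")
  expect_identical(diag(m$weights), c(a = 0, b = 0, c = 0))

  expect_error(connectome(matrix(1, 2, 3)), "not square")
  asym <- w; asym[1, 2] <- 2
  expect_error(connectome(asym), "asymmetry")
  # asymmetries within tolerance are averaged away
  tiny <- w; tiny[1, 2] <- 1 + 1e-10
  m2 <- connectome(tiny)
  expect_equal(m2$weights[1, 2], m2$weights[2, 1])
  expect_error(connectome(-w), "negative")
  expect_error(connectome(w * 2, "FA"), "FA")
  expect_error(connectome(w, labels = c("a", "b")), "labels")
})

test_that("degree, edge count and strength match hand-computed examples", {
  # complete graph on 68 nodes
  n <- 68
  cm <- connectome(matrix(1, n, n) - diag(n), "fiber_density")
  expect_true(all(nodal_degree(cm) == 67L))
  expect_identical(edge_count(cm), 2278L)
  expect_true(all(node_strength(cm) == 67))

  # path a-b-c with weights 2.5
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2.5
  w[2, 3] <- w[3, 2] <- 2.5
  p <- connectome(w, "fiber_density", labels = c("a", "b", "c"))
  expect_identical(unname(nodal_degree(p)), c(1L, 2L, 1L))
  expect_identical(edge_count(p), 2L)
  expect_identical(unname(node_strength(p)), c(2.5, 5.0, 2.5))

  # empty matrix
  expect_identical(edge_count(matrix(0, 5, 5)), 0L)

  # a degree-16 node reaches 24% of the other 67 nodes
  expect_equal(round(16 / 67, 2), 0.24)
})

test_that("edge count equals planted support size", {
  set.seed(42)
  for (rep in 1:5) {
    w <- random_small_graph(20, density = 0.3)
    s <- sum(w[upper.tri(w)] > 0)
    expect_identical(edge_count(w), s)
  }
})

test_that("graph measures obey structural identities", {
  set.seed(7)
  for (rep in 1:10) {
    w <- random_small_graph(15)
    expect_identical(sum(nodal_degree(w)), 2L * edge_count(w))
    # degree of a matrix equals degree of its binarized support
    expect_identical(unname(nodal_degree(w)),
                     unname(nodal_degree((w > 0) * 1)))
    # strengths total twice the total weight
    expect_equal(sum(node_strength(w)), 2 * sum(w[upper.tri(w)]))
    # label-equivariance under node permutation
    perm <- sample(nrow(w))
    expect_identical(unname(nodal_degree(w))[perm],
                     unname(nodal_degree(w[perm, perm])))
    expect_equal(unname(node_strength(w))[perm],
                 unname(node_strength(w[perm, perm])))
  }
})

test_that("matrix TSV round-trips with and without label headers", {
  w <- random_small_graph(6)
  m <- connectome(w / 10, "FA", labels = letters[1:6])  # FA stays in [0, 1]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectome_tsv(m, path)
  back <- read_connectome_tsv(path, "FA")
  expect_equal(back$weights, m$weights)
  expect_identical(back$labels, m$labels)

  # headerless numeric matrix
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(w, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back2 <- read_connectome_tsv(path2)
  expect_equal(unname(back2$weights), unname(w * 1.0))
})

test_that("subject records enforce a shared support across weight kinds", {
  fd <- matrix(0, 4, 4); fd[1, 2] <- fd[2, 1] <- 3
  fa <- matrix(0, 4, 4); fa[1, 2] <- fa[2, 1] <- 0.5
  md <- fa * 2e-3
  s <- subject_record("s1", fd, fa, md, age = 60, sex = "M",
                      brain_volume = 1e6, group = "control", mmse = 29)
  expect_s3_class(s, "subject_record")

  # FA on an edge absent from fiber density is rejected
  fa_bad <- fa; fa_bad[3, 4] <- fa_bad[4, 3] <- 0.4
  expect_error(
    subject_record("s2", fd, fa_bad, md, age = 60, sex = "M",
                   brain_volume = 1e6, group = "control"),
    "zero fiber density")
  expect_error(
    subject_record("s3", fd, fa, md, age = 60, sex = "M",
                   brain_volume = 1e6, group = "control", mmse = 31),
    "mmse")
})

test_that("cohort support excludes never-connected pairs", {
  mk <- function(id, edges) {
    fd <- matrix(0, 4, 4)
    for (e in edges) fd[e[1], e[2]] <- fd[e[2], e[1]] <- 1
    subject_record(id, fd, (fd > 0) * 0.5, (fd > 0) * 1e-3, age = 60,
                   sex = "F", brain_volume = 1e6, group = "control")
  }
  ch <- cohort(list(mk("a", list(c(1, 2))), mk("b", list(c(1, 2), c(2, 3)))))
  expect_true(ch$edge_support[1, 2])
  expect_true(ch$edge_support[2, 3])
  expect_false(ch$edge_support[3, 4])
  expect_identical(sum(ch$edge_support[upper.tri(ch$edge_support)]), 2L)
})

test_that("cohorts round-trip through the directory format", {
  ch <- generate_cohort(small_spec(), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_identical(length(back), length(ch))
  expect_equal(back$subjects[[3]]$matrices$fiber_density$weights,
               ch$subjects[[3]]$matrices$fiber_density$weights,
               tolerance = 1e-6)
  expect_identical(back$subjects[[3]]$group, ch$subjects[[3]]$group)
  expect_error(suppressWarnings(read_covariates_csv(file.path(dir, "missing.csv"))))
})
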
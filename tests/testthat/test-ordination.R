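test_that("pcoa recovers collinear points up to sign", {
  # points at 0, 1, 3 on a line
  x <- c(0, 1, 3)
  d <- stats::dist(matrix(x, ncol = 1))
  ord <- suppressWarnings(pcoa(d, n_axes = 1))
  got <- sort(ord$coordinates[, 1])
  expect_equal(unname(diff(got)), diff(sort(x - mean(x))),
               tolerance = 1e-10)
})

test_that("pcoa on planar configurations has tiny Procrustes residual", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(2 * 9), ncol = 2,
                dimnames = list(paste0("M", 1:9), NULL))
    ord <- pcoa(stats::dist(X), n_axes = 2)
    expect_lt(procrustes_residual(X, ord$coordinates), 1e-6)
    expect_equal(colMeans(ord$coordinates), c(Axis1 = 0, Axis2 = 0),
                 tolerance = 1e-10)
    expect_equal(ord$negative_eigenvalue_mass, 0, tolerance = 1e-10)
  }
})

test_that("pcoa reconstructs Euclidean-embeddable distances exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rbinom(7 * 12, 1, 0.4), nrow = 7,
                dimnames = list(paste0("M", 1:7), NULL))
    d <- euclidean_distances(m)
    ord <- suppressWarnings(pcoa(d, n_axes = 6))
    expect_equal(as.matrix(stats::dist(ord$coordinates)), as.matrix(d),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate and truncated ordinations behave", {
  d0 <- stats::as.dist(matrix(0, 4, 4))
  ord0 <- pcoa(d0)
  expect_true(all(ord0$coordinates == 0))
  expect_equal(ord0$negative_eigenvalue_mass, 0)

  d <- stats::dist(matrix(rnorm(8), ncol = 2))
  expect_warning(pcoa(d, n_axes = 10), "exceeds embedding rank")
  expect_error(pcoa(stats::dist(matrix(1:2, ncol = 1))),
               class = "ethnomarket_dimension_error")
})

test_that("pcoa agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(42)
  m <- matrix(rbinom(6 * 15, 1, 0.4), nrow = 6,
              dimnames = list(paste0("M", 1:6), NULL))
  d <- euclidean_distances(m)
  ours <- pcoa(d, n_axes = 2)
  ref <- ape::pcoa(d)
  expect_lt(procrustes_residual(ref$vectors[, 1:2], ours$coordinates), 1e-6)
})

test_that("group test p matches exact enumeration on 5 markets", {
  set.seed(9)
  X <- matrix(rnorm(10), ncol = 2, dimnames = list(paste0("M", 1:5), NULL))
  d <- stats::dist(X)
  groups <- c(M1 = "A", M2 = "A", M3 = "B", M4 = "B", M5 = "B")
  exact <- exact_group_p(d, groups[labels(d)])
  mc <- permutation_group_test(d, groups, n_permutations = 20000, seed = 4)
  expect_equal(mc$p_value, exact, tolerance = 0.02)
  expect_gte(mc$p_value, 1 / 20001)
})

test_that("Monte-Carlo p converges to exact enumeration on three toys", {
  for (seed in c(2, 5, 8)) {
    set.seed(seed)
    n <- sample(6:7, 1)
    X <- matrix(rnorm(2 * n), ncol = 2,
                dimnames = list(paste0("M", seq_len(n)), NULL))
    d <- stats::dist(X)
    groups <- rep(c("A", "B"), length.out = n)
    names(groups) <- paste0("M", seq_len(n))
    exact <- exact_group_p(d, groups[labels(d)])
    mc <- permutation_group_test(d, groups, n_permutations = 20000,
                                 seed = seed)
    expect_equal(mc$p_value, exact, tolerance = 0.02)
  }
})

test_that("maximal group separation drives p to its floor", {
  # two groups with zero species overlap and large effect
  m <- rbind(
    A1 = c(1, 1, 1, 0, 0, 0), A2 = c(1, 1, 0, 0, 0, 0),
    A3 = c(1, 0, 1, 0, 0, 0),
    B1 = c(0, 0, 0, 1, 1, 1), B2 = c(0, 0, 0, 1, 1, 0),
    B3 = c(0, 0, 0, 1, 0, 1)
  )
  d <- euclidean_distances(m)
  g <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B", B3 = "B")
  out <- permutation_group_test(d, g, n_permutations = 4999, seed = 1)
  # 6 markets in two balanced groups: C(6,3) = 20 label arrangements, of
  # which only the true split and its label swap reach the observed F,
  # so the exact p is 2/20 = 0.1
  expect_lt(abs(out$p_value - 0.1), 0.02)
})

test_that("group test validates its inputs", {
  d <- stats::dist(matrix(rnorm(10), ncol = 2))
  expect_error(permutation_group_test(d, rep("A", 5), seed = 1),
               class = "ethnomarket_parameter_error")
  expect_error(permutation_group_test(d, c("A", "A", "B", "B", "B")),
               class = "ethnomarket_parameter_error")  # missing seed
})

test_that("size test finds constructed perfect association", {
  # enough markets that a random permutation almost surely breaks the
  # correspondence, so the observed r = 1 sits strictly above every
  # permuted statistic and p reaches its floor
  set.seed(10)
  sizes <- sort(sample(5:200, 12))
  names(sizes) <- paste0("M", 1:12)
  dm <- abs(outer(sizes, sizes, "-"))
  out <- size_association_test(stats::as.dist(dm), sizes,
                               n_permutations = 999, seed = 3)
  expect_equal(out$observed, 1, tolerance = 1e-12)
  expect_equal(out$p_value, 1 / 1000, tolerance = 1e-12)
})

test_that("size test rejects degenerate sizes and tiny samples", {
  d <- stats::dist(matrix(rnorm(10), ncol = 2))
  expect_error(size_association_test(d, rep(3, 5), seed = 1),
               class = "ethnomarket_parameter_error")
  d3 <- stats::dist(matrix(rnorm(6), ncol = 2))
  expect_error(size_association_test(d3, 1:3, seed = 1),
               class = "ethnomarket_dimension_error")
})

test_that("size test p-values are roughly uniform under independence", {
  set.seed(31)
  ps <- replicate(120, {
    X <- matrix(rnorm(12), ncol = 2)
    d <- stats::dist(X)
    sizes <- sample(5:50, 6)
    size_association_test(d, sizes, n_permutations = 99,
                          seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps <= 0.05), 0.15)
})

test_that("permutation p-values agree with an independent implementation", {
  skip_if_not_installed("vegan")
  sv <- generate_survey(bogota_preset(seed = 77))
  d <- euclidean_distances(incidence_matrix(sv, "species"))
  g <- rep(c("A", "B", "C"), 8)
  names(g) <- labels(d)
  ours <- permutation_group_test(d, g, n_permutations = 4999, seed = 5)
  ref <- vegan::adonis2(d ~ grp, data = data.frame(grp = g[labels(d)]),
                        permutations = 4999)
  expect_equal(ours$observed, ref$F[1], tolerance = 1e-8)
  expect_lt(abs(ours$p_value - ref$`Pr(>F)`[1]), 0.02)

  sizes <- rowSums(incidence_matrix(sv, "species"))
  ours_m <- size_association_test(d, sizes, n_permutations = 999, seed = 5)
  ref_m <- vegan::mantel(d, stats::dist(sizes, method = "manhattan"),
                         permutations = 999)
  expect_equal(ours_m$observed, unname(ref_m$statistic), tolerance = 1e-8)
})
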
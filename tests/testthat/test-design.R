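test_that("design width follows 1 + q + p + pq across study dimensions", {
  for (p in c(75L, 150L, 300L, 30L)) {
    sim <- simulate_longitudinal(n = 5, k = 2, p = p, q = 3, seed = 1)
    des <- build_design(sim$data)
    expect_identical(des$d, 1L + 3L + p + p * 3L)
    expect_identical(ncol(des$Z), des$d)
    expect_identical(nrow(des$Z), 5L * 2L)
  }
  expect_equal(build_design(simulate_longitudinal(
    n = 4, k = 2, p = 75, q = 3, seed = 1)$data)$d, 304L)
})

test_that("feature-free design degenerates to intercept + dummies", {
  d <- longitudinal_data(y = rnorm(4), X = matrix(0, 4, 0),
                         E = matrix(c(1, 1, 0, 0), 4, 1), id = rep(1:2, each = 2))
  des <- build_design(d)
  expect_identical(des$d, 2L)
  expect_identical(length(des$blocks$inter), 0L)
})

test_that("interaction columns follow feature-major, dummy-minor order", {
  des <- build_design(kron_row_data())
  # X = (2, 3), E = (1, 0, 0): x1:e1..e3 then x2:e1..e3
  expect_equal(unname(des$Z[1, des$blocks$inter]), c(2, 0, 0, 3, 0, 0))
  # intercept column is all ones, first column
  expect_true(all(des$Z[, 1] == 1))
  # column index rule: interaction (h, l) at 1 + q + p + (h-1)q + l
  expect_equal(des$groups$inter[2, 3], 1L + 3L + 2L + 1L * 3L + 3L)
})

test_that("design rejects empty data and q = 0", {
  expect_error(longitudinal_data(numeric(0), matrix(0, 0, 1),
                                 matrix(0, 0, 1), integer(0)), "empty")
  d <- toy_data()
  d$q <- 0L
  d$E <- d$E[, 0, drop = FALSE]
  expect_error(build_design(d), "q = 0")
})

test_that("interaction Gram matrices match direct computation", {
  # 2 subjects, k = 1, q = 2: B_h = [[1, 0], [1, 1]] -> Sigma = [[2,1],[1,1]]/2
  d <- longitudinal_data(y = c(0, 0), X = matrix(c(1, 1), 2, 1),
                         E = matrix(c(1, 1, 0, 1), 2, 2), id = 1:2)
  des <- build_design(d)
  B <- des$Z[, des$groups$inter[1, ]]
  expect_equal(unname(B), matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE))
  grams <- interaction_gram(des)
  expect_equal(grams[[1]], crossprod(B) / 2, ignore_attr = TRUE)
  expect_equal(unname(grams[[1]]), 0.5 * matrix(c(2, 1, 1, 1), 2, 2))
  # observation divisor: k = 1 so identical here
  expect_equal(interaction_gram(des, "observations"), grams)

  # all-zero block -> zero matrix; orthogonal columns of squared norm n -> identity
  dz <- longitudinal_data(y = c(0, 0), X = matrix(0, 2, 1),
                          E = matrix(c(1, 0, 0, 1), 2, 2), id = 1:2)
  expect_true(all(interaction_gram(build_design(dz))[[1]] == 0))
  di <- longitudinal_data(y = c(0, 0), X = matrix(c(sqrt(2), sqrt(2)), 2, 1),
                          E = matrix(c(1, 0, 0, 1), 2, 2), id = 1:2)
  expect_equal(unname(interaction_gram(build_design(di))[[1]]), diag(2))
})

test_that("empirical group norm evaluates the quadratic form", {
  Sig <- 0.5 * matrix(c(2, 1, 1, 1), 2, 2)
  expect_equal(group_empirical_norm(c(1, 2), Sig), sqrt(5))
  expect_equal(group_empirical_norm(c(0, 0), Sig), 0)
  expect_equal(group_empirical_norm(c(3, -4), diag(2)), 5)
  # near-singular numerical negativity clamps at zero
  expect_equal(group_empirical_norm(c(1, -1), matrix(1, 2, 2)), 0)
})

test_that("group norm is bounded by the largest-eigenvalue inequality", {
  set.seed(11)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    Sig <- crossprod(A) / 3
    b <- rnorm(3)
    expect_lte(group_empirical_norm(b, Sig),
               sqrt(sum(b^2)) * sqrt(max(eigen(Sig)$values)) + 1e-12)
  }
})

test_that("design structure is invariant under subject permutation", {
  sim <- simulate_longitudinal(n = 12, k = 3, p = 6, q = 3, seed = 4)
  des <- build_design(sim$data)
  perm <- permute_subjects(sim$data, c(5, 1, 12, 3, 2, 9, 7, 11, 4, 10, 6, 8))
  des2 <- build_design(perm)
  expect_identical(des2$d, des$d)
  expect_identical(des2$groups, des$groups)
  g1 <- interaction_gram(des)
  g2 <- interaction_gram(des2)
  for (h in seq_along(g1)) expect_equal(g2[[h]], g1[[h]])
})
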
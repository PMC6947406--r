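test_that("GEE score vanishes at exact and least-squares solutions", {
  sim <- simulate_longitudinal(n = 30, k = 3, p = 4, q = 3, seed = 21)
  d <- sim$data
  des <- build_design(d)
  # scalar sanity: one subject, k = 1, Z = 1, V = 1, Y = 2, beta = 0 -> U = 2
  d1 <- longitudinal_data(y = 2, X = matrix(0, 1, 0), E = matrix(1, 1, 1),
                          id = 1)
  des1 <- build_design(d1)
  expect_equal(gee_score(c(0, 0), des1, matrix(1), d1$y), c(2, 2), ignore_attr = TRUE)

  # pooled OLS solution under independence working covariance
  beta_ols <- qr.coef(qr(des$Z), d$y)
  U <- gee_score(beta_ols, des, diag(d$k), d$y)
  expect_lt(max(abs(U)), 1e-8)

  # exact interpolation
  beta <- rnorm(des$d)
  y <- drop(des$Z %*% beta)
  expect_lt(max(abs(gee_score(beta, des, build_V_inv("ar1", 0.4, 2, d$k), y))),
            1e-8)
})

test_that("information matrix matches direct blockwise computation", {
  d <- toy_data()
  des <- build_design(d)
  Vi <- build_V_inv("exchangeable", 0.5, 1.3, d$k)
  Tdirect <- matrix(0, des$d, des$d)
  for (i in 1:d$n) {
    rows <- ((i - 1) * d$k + 1):(i * d$k)
    Zi <- des$Z[rows, , drop = FALSE]
    Tdirect <- Tdirect + t(Zi) %*% Vi %*% Zi
  }
  expect_equal(gee_information(des, Vi), Tdirect, ignore_attr = TRUE)
  # independence, phi = 1 -> Z'Z
  expect_equal(gee_information(des, diag(d$k)), crossprod(des$Z),
               ignore_attr = TRUE)
})

test_that("Newton update reproduces closed-form special cases", {
  # scalar: T = 2, n = 1, W = 1, beta = 1, U = 0 -> 1 + (1/3) * (-1) = 2/3
  expect_equal(newton_update(1, 0, matrix(2), 1, 1), 2 / 3)

  # fixed point when U = 0 and W beta = 0
  expect_equal(newton_update(c(1, 2), c(0, 0), diag(2), c(0, 0), 5), c(1, 2))

  # W = 0, start at zero, independence: one step lands on pooled OLS
  d <- simulate_longitudinal(n = 30, k = 3, p = 4, q = 3, seed = 22)$data
  des <- build_design(d)
  U <- gee_score(numeric(des$d), des, diag(d$k), d$y)
  Tm <- gee_information(des, diag(d$k))
  beta1 <- newton_update(numeric(des$d), U, Tm, numeric(des$d), d$n)
  expect_equal(beta1, unname(qr.coef(qr(des$Z), d$y)), tolerance = 1e-8)
  # idempotent: a second step does not move (quadratic objective, fixed V)
  U2 <- gee_score(beta1, des, diag(d$k), d$y)
  beta2 <- newton_update(beta1, U2, Tm, numeric(des$d), d$n)
  expect_equal(beta2, beta1, tolerance = 1e-8)
})

test_that("one W = 0 step from any start reaches GLS under a fixed V", {
  sim <- simulate_longitudinal(n = 30, k = 3, p = 4, q = 3, seed = 8)
  des <- build_design(sim$data)
  Vi <- build_V_inv("ar1", 0.5, 1.7, 3)
  Tm <- gee_information(des, Vi)
  # GLS oracle via weighted least squares on the expanded system
  W_full <- kronecker(diag(sim$data$n), Vi)
  gls <- solve(t(des$Z) %*% W_full %*% des$Z,
               t(des$Z) %*% W_full %*% sim$data$y)
  start <- rnorm(des$d)
  U <- gee_score(start, des, Vi, sim$data$y)
  one_step <- newton_update(start, U, Tm, numeric(des$d), des$n)
  expect_equal(one_step, unname(drop(gls)), tolerance = 1e-8)
})

test_that("lasso initializer handles degenerate and signal cases", {
  # constant response -> intercept only
  d <- toy_data()
  d$y <- rep(5, 4)
  des <- build_design(d)
  b <- geeint:::lasso_initialize(d, des)
  expect_equal(b[1], 5)
  expect_true(all(b[-1] == 0))
  d$y <- rep(0, 4)
  expect_true(all(geeint:::lasso_initialize(d, des) == 0))

  # strong single-column signal is picked up
  sim <- simulate_longitudinal(n = 40, k = 3, p = 6, q = 3,
                               truth_mode = "null", seed = 5)
  des <- build_design(sim$data)
  j <- des$blocks$main[3]
  y <- 2 * des$Z[, j] + rnorm(nrow(des$Z), sd = 0.1)
  dat <- sim$data; dat$y <- y
  b <- geeint:::lasso_initialize(dat, des)
  expect_gt(abs(b[j]), 1)
  expect_gt(abs(b[j]), max(abs(b[des$blocks$main[-3]])))
})

test_that("sparsify zeroes small entries but never protected columns", {
  out <- sparsify(c(0.0005, 0.5), 1e-3)
  expect_equal(out$beta, c(0, 0.5))
  expect_equal(out$selected, 2L)
  expect_equal(sparsify(c(0.0005, 0.5), 0)$beta, c(0.0005, 0.5))
  out2 <- sparsify(c(1e-5, 1e-5, 0.2), 1e-3, protect = 1:2)
  expect_equal(out2$beta, c(1e-5, 1e-5, 0.2))
  expect_setequal(out2$selected, 1:3)
})

test_that("zero-penalty independence fit equals pooled OLS", {
  sim <- simulate_longitudinal(n = 25, k = 3, p = 4, q = 3, seed = 10)
  fit <- pgee(sim$data, method = "A3", lambda1 = 0, lambda2 = 0,
              zero_threshold = 0, tol = 1e-8, max_iter = 100)
  des <- build_design(sim$data)
  ols <- unname(qr.coef(qr(des$Z), sim$data$y))
  expect_equal(unname(coef(fit)), ols, tolerance = 1e-6)
})

test_that("saturating penalties keep only intercept and environment terms", {
  sim <- simulate_longitudinal(n = 30, k = 3, p = 6, q = 3, seed = 12)
  fit <- pgee(sim$data, method = "A1", lambda1 = 50, lambda2 = 50)
  co <- coef(fit)
  expect_true(all(co[fit$blocks$main] == 0))
  expect_true(all(co[fit$blocks$inter] == 0))
  expect_setequal(fit$selected, 1:4)
})

test_that("fits are invariant to subject permutation", {
  sim <- simulate_longitudinal(n = 20, k = 4, p = 6, q = 3, seed = 13)
  fit <- pgee(sim$data, method = "A1", lambda1 = 0.3, lambda2 = 0.2)
  set.seed(99)
  perm <- permute_subjects(sim$data, sample(20))
  fit2 <- pgee(perm, method = "A1", lambda1 = 0.3, lambda2 = 0.2)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("method roster maps labels to structure and grouping", {
  expect_equal(method_spec("A1"), list(structure = "exchangeable", grouped = TRUE))
  expect_equal(method_spec("A2"), list(structure = "ar1", grouped = TRUE))
  expect_equal(method_spec("A3"), list(structure = "independence", grouped = TRUE))
  expect_equal(method_spec("A5"), list(structure = "ar1", grouped = FALSE))
  expect_false(method_spec("A6")$grouped)
})
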
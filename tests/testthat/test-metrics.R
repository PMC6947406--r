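test_that("identification metrics do exact set arithmetic", {
  truth <- simulation_truth(p = 10, q = 3, truth_mode = "interactions",
                            seed = 1)
  # selecting exactly the truth's support
  sel <- truth$beta != 0
  m <- identification_metrics(sel, truth)
  expect_equal(unname(m["TP_inter"]), 9)
  expect_equal(unname(m["FP"]), 0)
  expect_equal(unname(m["TP"]), 13)        # 4 mains + 9 interactions
  expect_equal(unname(m["TP_incl"]), 17)   # + intercept + 3 dummies
  expect_equal(unname(m["FN"]), 0)

  # nothing selected on penalized columns
  m0 <- identification_metrics(logical(truth$d), truth)
  expect_equal(unname(m0[c("TP", "FP")]), c(0, 0))
  expect_equal(unname(m0["FN"]), 13)

  # partial overlap: truth main features vs a shifted selection
  sel2 <- integer(0)
  sel2 <- c(truth$blocks$main[truth$main_features[1]],  # one hit
            truth$blocks$main[10])                      # one miss (feature 10)
  m2 <- identification_metrics(sel2, truth)
  expect_equal(unname(m2[c("TP_main", "FP_main")]), c(1, 1))
})

test_that("TP/FN and FP/TN bookkeeping is exact over random selections", {
  truth <- simulation_truth(p = 12, q = 3, seed = 2)
  pen <- c(truth$blocks$main, truth$blocks$inter)
  n_nz <- sum(truth$beta[pen] != 0)
  set.seed(4)
  for (i in 1:10) {
    sel <- logical(truth$d)
    sel[sample(pen, 20)] <- TRUE
    m <- identification_metrics(sel, truth)
    expect_equal(unname(m["TP"] + m["FN"]), n_nz)
    expect_equal(unname(m["FP"] + m["TN"]), length(pen) - n_nz)
    expect_equal(unname(m["TP"]), unname(m["TP_main"] + m["TP_inter"]))
  }
})

test_that("estimation metrics decompose the squared error", {
  truth <- simulation_truth(p = 75, q = 3, seed = 3)
  expect_equal(estimation_metrics(truth$beta, truth),
               c(MSE = 0, NMSE = 0, TMSE = 0))

  # one coordinate off by 0.5 out of d = 304
  bh <- truth$beta
  bh[truth$nonzero[1]] <- bh[truth$nonzero[1]] + 0.5
  em <- estimation_metrics(bh, truth)
  expect_equal(unname(em["TMSE"]), 0.25 / 304)
  expect_equal(unname(em["MSE"]), 0.25 / 17)
  expect_equal(unname(em["NMSE"]), 0)

  # error only on true zeros
  bh2 <- truth$beta
  zeros <- which(truth$beta == 0)
  bh2[zeros[1:4]] <- 0.1
  em2 <- estimation_metrics(bh2, truth)
  expect_equal(unname(em2["MSE"]), 0)
  expect_gt(em2["NMSE"], 0)

  # replicate averaging
  em3 <- estimation_metrics(rbind(bh, truth$beta), truth)
  expect_equal(unname(em3["TMSE"]), 0.25 / 304 / 2)
})

test_that("metrics are invariant to replicate ordering", {
  truth <- simulation_truth(p = 10, q = 3, seed = 5)
  set.seed(6)
  B <- matrix(rnorm(3 * truth$d, sd = 0.1), 3) +
    matrix(truth$beta, 3, truth$d, byrow = TRUE)
  expect_equal(estimation_metrics(B, truth),
               estimation_metrics(B[c(3, 1, 2), ], truth))
})

test_that("replicate study aggregates per-method tables", {
  st <- replicate_study(methods = c("A3", "A6"), R = 3,
                        sim_args = list(n = 25, k = 3, p = 6),
                        tuning = "fixed", lambda1 = 0.4, lambda2 = 0.4,
                        seed = 11)
  expect_s3_class(st, "pgee_study")
  expect_equal(nrow(st$summary), 2L)
  expect_equal(unique(st$summary$R), 3)
  expect_true(all(c("TP_incl_mean", "FP_sd", "MSE", "TMSE") %in%
                  names(st$summary)))
  expect_equal(nrow(st$replicates), 6L)
  # saturating penalties -> a zero TP/FP row
  st0 <- replicate_study(methods = "A3", R = 1,
                         sim_args = list(n = 25, k = 3, p = 6),
                         tuning = "fixed", lambda1 = 100, lambda2 = 100,
                         seed = 12)
  expect_equal(st0$summary$TP_mean, 0)
  expect_equal(st0$summary$FP_mean, 0)
})

test_that("stability selection proportions are exact counts in [0, 1]", {
  sim <- simulate_longitudinal(n = 30, k = 3, p = 5, q = 3,
                               coef_range = c(1.4, 1.8), seed = 13)
  ss <- stability_selection(sim$data, method = "A3", lambda1 = 0.3,
                            lambda2 = 0.3, subsample_size = 24, B = 8,
                            seed = 2)
  pr <- ss$proportions[!is.na(ss$proportions)]
  expect_true(all(pr >= 0 & pr <= 1))
  # proportions are counts / B exactly
  pen <- which(!is.na(ss$proportions))
  expect_equal(unname(ss$proportions[pen]),
               unname(ss$counts[pen] / ss$used))
  expect_equal(ss$used + ss$failed, 8L)
  expect_error(stability_selection(sim$data, lambda1 = 1, lambda2 = 1,
                                   subsample_size = 30), "subsample_size")
})
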
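#' Identification metrics against a simulation truth
#'
#' Counts true and false positives per individual coefficient (each
#' interaction coefficient separately), split into main-effect and
#' interaction columns.  The intercept and environment columns are never
#' penalized, so they are excluded from the exclusive counts and never
#' contribute false positives; the inclusive convention (`TP_incl`,
#' `TP_main_incl`) additionally counts the truly nonzero unpenalized
#' columns as true positives, matching tabulations where the 17-effect
#' truth includes the intercept and dummies.
#'
#' @param fit a [pgee()] fit, or a logical/integer selection over the `d`
#'   design columns.
#' @param truth a [simulation_truth()] object.
#' @return Named numeric vector with `TP`, `FP` (overall, exclusive),
#'   `TP_main`, `FP_main`, `TP_inter`, `FP_inter`, `FN`, `TN`,
#'   `TP_incl`, `TP_main_incl`.
#' @export
identification_metrics <- function(fit, truth) {
  stopifnot(inherits(truth, "pgee_truth"))
  d <- truth$d
  if (inherits(fit, "pgee")) {
    if (fit$d != d) stop("fit and truth dimensions differ")
    sel <- fit$coefficients != 0
    # unpenalized columns are always in the model
    sel[c(truth$blocks$intercept, truth$blocks$env)] <- TRUE
  } else if (is.logical(fit)) {
    stopifnot(length(fit) == d); sel <- fit
  } else {
    sel <- logical(d); sel[fit] <- TRUE
  }
  nz <- truth$beta != 0
  main <- truth$blocks$main
  inter <- truth$blocks$inter
  unpen <- c(truth$blocks$intercept, truth$blocks$env)

  tp <- function(idx) sum(sel[idx] & nz[idx])
  fp <- function(idx) sum(sel[idx] & !nz[idx])
  TPm <- tp(main); FPm <- fp(main)
  TPi <- tp(inter); FPi <- fp(inter)
  pen <- c(main, inter)
  c(TP = TPm + TPi, FP = FPm + FPi,
    TP_main = TPm, FP_main = FPm, TP_inter = TPi, FP_inter = FPi,
    FN = sum(nz[pen]) - TPm - TPi, TN = sum(!nz[pen]) - FPm - FPi,
    TP_incl = TPm + TPi + sum(nz[unpen]),
    TP_main_incl = TPm + sum(nz[unpen]))
}

#' Estimation accuracy metrics against a simulation truth
#'
#' Squared-error decomposition of coefficient estimates over replicates:
#' `MSE` averages the squared deviation over the truly nonzero coordinates,
#' `NMSE` over the truly zero coordinates, and `TMSE` is the mean of
#' `||beta_hat - beta||^2 / d` over replicates.
#'
#' @param beta_hat numeric vector (one replicate) or matrix with one row per
#'   replicate and `d` columns.
#' @param truth a [simulation_truth()] object (or a numeric truth vector).
#' @return Named numeric vector `c(MSE, NMSE, TMSE)`.
#' @export
estimation_metrics <- function(beta_hat, truth) {
  beta_true <- if (inherits(truth, "pgee_truth")) truth$beta else truth
  if (is.vector(beta_hat)) beta_hat <- matrix(beta_hat, nrow = 1)
  stopifnot(ncol(beta_hat) == length(beta_true))
  D2 <- sweep(beta_hat, 2, beta_true)^2
  nz <- beta_true != 0
  mse <- if (any(nz)) mean(rowMeans(D2[, nz, drop = FALSE])) else 0
  nmse <- if (any(!nz)) mean(rowMeans(D2[, !nz, drop = FALSE])) else 0
  c(MSE = mse, NMSE = nmse, TMSE = mean(rowSums(D2)) / length(beta_true))
}
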
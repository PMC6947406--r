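# first-order autoregressive draws: m independent rows, each a length-len
# stationary AR(1) series with unit marginal variance and correlation rho
ar1_matrix <- function(m, len, rho) {
  Z <- matrix(stats::rnorm(m * len), m, len)
  if (len == 1L || rho == 0) return(Z)
  out <- Z
  for (j in 2:len) out[, j] <- rho * out[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  out
}

#' True coefficient vector for a simulation scenario
#'
#' Lays out the sparse truth on the `d = 1 + q + p + p*q` design columns.
#' In `"interactions"` mode the nonzeros are the intercept, the `q`
#' environment dummies, 4 feature main effects and 3 complete interaction
#' groups (`3 * q` interaction coefficients) — 17 nonzero effects at `q = 3`.
#' `"main_only"` has the intercept, dummies and 8 feature main effects and no
#' interactions; `"null"` has every coefficient zero.  Magnitudes are drawn
#' uniformly from `coef_range` (positive).  Nonzero positions sit at the
#' first eligible features by default so truth indices are stable across
#' replicates; `placement = "random"` draws them without replacement.
#'
#' @param p,q feature and dummy counts.
#' @param truth_mode `"interactions"`, `"main_only"` or `"null"`.
#' @param coef_range length-2 numeric, lower/upper bound of the magnitudes.
#' @param placement `"first"` (default) or `"random"`.
#' @param seed optional seed (only the magnitudes and random placement use
#'   randomness).
#' @return List of class `pgee_truth`: `beta` (length `d`), `d`, `p`, `q`,
#'   `main_features` (feature indices with true main effects),
#'   `group_features` (feature indices with true interaction groups),
#'   `nonzero` (column indices of nonzero coefficients), and the block
#'   index map.
#' @export
simulation_truth <- function(p, q, truth_mode = c("interactions", "main_only",
                                                  "null"),
                             coef_range = c(0.4, 0.8),
                             placement = c("first", "random"), seed = NULL) {
  truth_mode <- match.arg(truth_mode)
  placement <- match.arg(placement)
  d <- 1L + q + p + p * q
  blocks <- list(intercept = 1L, env = 1L + seq_len(q),
                 main = 1L + q + seq_len(p),
                 inter = 1L + q + p + seq_len(p * q))
  beta <- numeric(d)
  main_features <- integer(0)
  group_features <- integer(0)

  with_seed(seed, {
    draw <- function(m) stats::runif(m, coef_range[1], coef_range[2])
    pick <- function(avail, m)
      if (placement == "first") avail[seq_len(m)] else sort(sample(avail, m))
    if (truth_mode == "interactions") {
      if (p < 4L) stop("interactions mode needs p >= 4")
      main_features <- pick(seq_len(p), 4L)
      group_features <- pick(seq_len(p), 3L)
      beta[c(blocks$intercept, blocks$env)] <- draw(1L + q)
      beta[blocks$main[main_features]] <- draw(4L)
      gcols <- as.vector(t(outer(group_features - 1L, seq_len(q),
                                 function(h, l) 1L + q + p + h * q + l)))
      beta[gcols] <- draw(length(gcols))
    } else if (truth_mode == "main_only") {
      if (p < 8L) stop("main_only mode needs p >= 8")
      main_features <- pick(seq_len(p), 8L)
      beta[c(blocks$intercept, blocks$env)] <- draw(1L + q)
      beta[blocks$main[main_features]] <- draw(8L)
    }
  })

  structure(list(beta = beta, d = d, p = p, q = q, blocks = blocks,
                 main_features = main_features,
                 group_features = group_features,
                 nonzero = which(beta != 0), truth_mode = truth_mode),
            class = "pgee_truth")
}

#' Simulate a longitudinal feature-environment interaction dataset
#'
#' Emulates a longitudinal lipidomics-style study.  Each subject receives a
#' single `p`-vector of features drawn from a multivariate normal with mean
#' zero and AR(1) cross-feature correlation `rho_X` (unit marginal
#' variance), held constant over the `k` time points, and a time-invariant
#' environment assignment.  Within-subject errors are `k`-variate normal
#' with AR(1) correlation `rho_error` and unit marginal variance.  Responses
#' follow the linear interaction model `Y = Z beta_true + e`.
#'
#' Environment coding (`E_mode`):
#' * `"quartile4"` (default): a latent standard normal per subject is cut at
#'   its empirical 25th/50th/75th percentiles, giving a 4-level factor whose
#'   lowest level is the baseline; the other `q = 3` levels are one-hot
#'   dummies.  This mirrors a 4-arm treatment assignment and keeps the
#'   design full rank.
#' * `"tertile"`: the latent vector is cut at its 30th/70th percentiles and
#'   all three categories are one-hot coded; with an intercept these
#'   columns are collinear, so a warning is issued.
#'
#' @param n number of subjects.
#' @param k time points per subject.
#' @param p number of features.
#' @param q number of environment dummies (must be 3 for `"tertile"`).
#' @param rho_error within-subject error autocorrelation.
#' @param rho_X cross-feature correlation.
#' @param coef_range bounds of the uniform nonzero coefficient magnitudes
#'   (`c(0.4, 0.8)` for the main study scale, `c(1.4, 1.8)` for the
#'   case-study scale).
#' @param truth_mode,placement passed to [simulation_truth()].
#' @param E_mode environment coding, see above.
#' @param truth optional [simulation_truth()] object to reuse across
#'   replicates of a study (one coefficient vector, fresh data per
#'   replicate); by default a new truth is drawn.
#' @param seed optional integer; the whole draw is reproducible from it.
#' @return List with `data` (a [longitudinal_data()]) and `truth`
#'   (a [simulation_truth()] object).
#' @examples
#' sim <- simulate_longitudinal(n = 20, k = 5, p = 10, seed = 1)
#' sim$data
#' length(sim$truth$nonzero)  # 17
#' @export
simulate_longitudinal <- function(n = 250, k = 5, p = 75, q = 3,
                                  rho_error = 0.5, rho_X = 0.5,
                                  coef_range = c(0.4, 0.8),
                                  truth_mode = "interactions",
                                  placement = "first",
                                  E_mode = c("quartile4", "tertile"),
                                  truth = NULL, seed = NULL) {
  stopifnot(n > 0, k > 0, p >= 0, q > 0,
            rho_error >= 0, rho_error < 1, rho_X >= 0, rho_X < 1)
  E_mode <- match.arg(E_mode)
  if (E_mode == "tertile" && q != 3L)
    stop("E_mode 'tertile' requires q = 3")

  if (!is.null(truth)) {
    stopifnot(inherits(truth, "pgee_truth"))
    if (truth$p != p || truth$q != q)
      stop("supplied truth does not match the requested dimensions")
  }

  with_seed(seed, {
    if (is.null(truth))
      truth <- simulation_truth(p, q, truth_mode, coef_range, placement)

    latent <- stats::rnorm(n)
    if (E_mode == "quartile4") {
      cuts <- stats::quantile(latent, probs = seq_len(q) / (q + 1))
      level <- findInterval(latent, cuts) + 1L          # 1..q+1, 1 = baseline
      Es <- matrix(0, n, q)
      for (l in seq_len(q)) Es[level == l + 1L, l] <- 1
    } else {
      warning("E_mode 'tertile' one-hot codes all 3 categories; ",
              "the design is collinear with the intercept")
      cuts <- stats::quantile(latent, probs = c(0.3, 0.7))
      level <- findInterval(latent, cuts) + 1L          # 1..3
      Es <- matrix(0, n, q)
      for (l in seq_len(q)) Es[level == l, l] <- 1
    }

    Xs <- if (p > 0) ar1_matrix(n, p, rho_X) else matrix(0, n, 0)
    eps <- ar1_matrix(n, k, rho_error)

    rows <- rep(seq_len(n), each = k)
    data <- longitudinal_data(
      y = numeric(n * k),
      X = Xs[rows, , drop = FALSE],
      E = Es[rows, , drop = FALSE],
      id = rows,
      time = rep(seq_len(k), times = n))
    des <- build_design(data)
    data$y <- drop(des$Z %*% truth$beta) + as.vector(t(eps))
    list(data = data, truth = truth)
  })
}
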
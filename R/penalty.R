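#' Minimax concave penalty (MCP)
#'
#' `mcp_value()` evaluates `rho(t; lambda, gamma) = lambda * t - t^2 / (2 *
#' gamma)` for `t <= gamma * lambda` and the saturation constant
#' `gamma * lambda^2 / 2` beyond; `mcp_deriv()` is its derivative
#' `(lambda - t / gamma)_+ * I(t <= gamma * lambda)`.  MCP shrinks like the
#' LASSO near zero and applies no shrinkage beyond the fold point
#' `gamma * lambda`, giving nearly unbiased large estimates.
#'
#' @param t nonnegative magnitude (vectorized).
#' @param lambda tuning parameter `>= 0`.
#' @param gamma regularization parameter `> 1` (default 3).
#' @return Penalty values (or derivative values), same length as `t`.
#' @export
mcp_value <- function(t, lambda, gamma = 3) {
  stopifnot(gamma > 1, lambda >= 0)
  if (any(t < 0)) stop("t must be nonnegative (pass magnitudes)")
  ifelse(t <= gamma * lambda,
         lambda * t - t^2 / (2 * gamma),
         gamma * lambda^2 / 2)
}

#' @rdname mcp_value
#' @export
mcp_deriv <- function(t, lambda, gamma = 3) {
  stopifnot(gamma > 1, lambda >= 0)
  if (any(t < 0)) stop("t must be nonnegative (pass magnitudes)")
  ifelse(t <= gamma * lambda, lambda - t / gamma, 0)
}

#' Diagonal shrinkage matrix of the local quadratic approximation
#'
#' Builds the diagonal of the matrix `W` used by the Newton-Raphson update:
#' zero on the intercept and environment columns (never penalized),
#' `rho'(|beta_h|; lambda1, gamma) / (eps + |beta_h|)` on each main-feature
#' column, and on interaction columns either the group-MCP weight
#' `rho'(||beta_h||_Sigma_h; q * lambda2, gamma) / (eps + ||beta_h||_Sigma_h)`
#' shared by all `q` columns of feature `h`'s group (grouped selection), or
#' the individual-MCP weight with `lambda2` per column (benchmark mode).
#'
#' @param beta coefficient vector of length `design$d`.
#' @param design a [build_design()] result.
#' @param grams [interaction_gram()] list (required when `grouped = TRUE`).
#' @param lambda1,lambda2 individual / group tuning parameters.
#' @param gamma MCP regularization parameter.
#' @param epsilon ridge stabilizer in the denominator (default `1e-6`).
#' @param grouped logical; penalize interactions as groups (`TRUE`) or
#'   individually (`FALSE`).
#' @return Numeric vector of length `d`: the diagonal of `W`.
#' @export
build_shrinkage <- function(beta, design, grams = NULL, lambda1, lambda2,
                            gamma = 3, epsilon = 1e-6, grouped = TRUE) {
  stopifnot(inherits(design, "pgee_design"), epsilon > 0)
  if (length(beta) != design$d)
    stop("beta length ", length(beta), " does not match design width ", design$d)
  w <- numeric(design$d)
  bl <- design$blocks
  if (design$p > 0) {
    tm <- abs(beta[bl$main])
    w[bl$main] <- mcp_deriv(tm, lambda1, gamma) / (epsilon + tm)
    if (grouped) {
      if (is.null(grams)) stop("grams required for grouped interaction penalty")
      for (h in seq_len(design$p)) {
        idx <- design$groups$inter[h, ]
        nrm <- group_empirical_norm(beta[idx], grams[[h]])
        w[idx] <- mcp_deriv(nrm, design$q * lambda2, gamma) / (epsilon + nrm)
      }
    } else {
      ti <- abs(beta[bl$inter])
      w[bl$inter] <- mcp_deriv(ti, lambda2, gamma) / (epsilon + ti)
    }
  }
  w
}
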
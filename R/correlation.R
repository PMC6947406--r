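#' Moment estimator of the dispersion parameter
#'
#' Under the Gaussian identity-link working model the marginal variance is a
#' constant `phi`; its moment estimate is the mean squared raw residual over
#' all `n*k` cells.  No degrees-of-freedom correction is applied because the
#' coefficient dimension can exceed `n*k`.
#'
#' @param residuals numeric vector of raw residuals, subject-major order.
#' @return Scalar `phi >= 0` (exactly 0 only for all-zero residuals; callers
#'   substitute a small floor before inverting).
#' @export
estimate_dispersion <- function(residuals) {
  mean(residuals^2)
}

#' Moment estimator of the working-correlation parameter
#'
#' Liang-Zeger style moment estimators of the nuisance correlation `eta`:
#' for the exchangeable structure, the average standardized cross product
#' over all within-subject pairs `j < j'`; for AR(1), over adjacent pairs
#' only.  The estimate is clipped so the working correlation matrix stays
#' positive definite: to `[-0.99, 0.99]` for AR(1), and to
#' `[-1/(k-1) + 0.01, 0.99]` for exchangeable (whose matrix loses positive
#' definiteness below `-1/(k-1)`).
#'
#' @param residuals numeric vector of raw residuals, subject-major order,
#'   `k` consecutive entries per subject.
#' @param structure `"independence"`, `"exchangeable"` or `"ar1"`.
#' @param k cluster size (times per subject).
#' @param phi dispersion; estimated from `residuals` if omitted.
#' @return Scalar `eta` in `[-0.99, 0.99]`; exactly 0 for independence.
#' @export
estimate_eta <- function(residuals,
                         structure = c("independence", "exchangeable", "ar1"),
                         k, phi = NULL) {
  structure <- match.arg(structure)
  if (structure == "independence") return(0)
  if (k < 2L) stop("structure '", structure, "' requires k >= 2")
  if (length(residuals) %% k != 0L)
    stop("residual length is not a multiple of k")
  n <- length(residuals) %/% k
  if (is.null(phi)) phi <- estimate_dispersion(residuals)
  if (phi <= 0) return(0)
  Rm <- matrix(residuals, nrow = k)            # one column per subject
  eta <- if (structure == "exchangeable") {
    s <- sum((colSums(Rm)^2 - colSums(Rm^2)) / 2)  # sum over pairs j < j'
    s / (n * k * (k - 1) / 2 * phi)
  } else {
    sum(Rm[-k, , drop = FALSE] * Rm[-1L, , drop = FALSE]) / (n * (k - 1) * phi)
  }
  lower <- if (structure == "exchangeable")
    max(-0.99, -1 / (k - 1) + 0.01) else -0.99
  max(lower, min(0.99, eta))
}

#' Working correlation matrix
#'
#' @param structure `"independence"`, `"exchangeable"` or `"ar1"`.
#' @param eta correlation parameter, `|eta| < 1` (ignored for independence).
#' @param k cluster size.
#' @return `k x k` correlation matrix: identity; `eta` off-diagonal; or
#'   `eta^|j - j'|`.
#' @export
build_R <- function(structure = c("independence", "exchangeable", "ar1"),
                    eta, k) {
  structure <- match.arg(structure)
  if (structure == "independence") return(diag(k))
  if (abs(eta) >= 1) stop("|eta| must be < 1")
  j <- seq_len(k)
  if (structure == "exchangeable") {
    R <- matrix(eta, k, k); diag(R) <- 1; R
  } else {
    eta^abs(outer(j, j, "-"))
  }
}

#' Inverse working covariance matrix for one subject
#'
#' Under the Gaussian identity-link model with constant variance the marginal
#' variance matrix is `A = phi * I`, so the working covariance is
#' `V = phi * R(eta)` and all subjects share one `V^{-1}` (balanced design).
#'
#' @param structure,eta,k as in [build_R()].
#' @param phi dispersion, `> 0`.
#' @return Symmetric positive-definite `k x k` matrix `(phi * R)^{-1}`.
#' @export
build_V_inv <- function(structure, eta, phi, k) {
  if (phi <= 0) stop("phi must be positive")
  R <- build_R(structure, eta, k)
  rc <- rcond(R)
  if (rc < 1e-12)
    stop(sprintf("working correlation numerically singular (rcond = %.2e)", rc))
  chol2inv(chol(phi * R))
}
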
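#' Method roster
#'
#' Maps the six benchmark method labels to their working-correlation
#' structure and interaction-penalty mode: A1-A3 penalize each feature's
#' interaction block as a group (exchangeable, AR(1), independence working
#' correlation respectively); A4-A6 penalize interaction coefficients
#' individually under the same three structures.
#'
#' @param method one of `"A1"..."A6"`.
#' @return List with elements `structure` and `grouped`.
#' @export
method_spec <- function(method = c("A1", "A2", "A3", "A4", "A5", "A6")) {
  method <- match.arg(method)
  structure <- c(A1 = "exchangeable", A2 = "ar1", A3 = "independence",
                 A4 = "exchangeable", A5 = "ar1", A6 = "independence")[[method]]
  list(structure = structure, grouped = method %in% c("A1", "A2", "A3"))
}

# apply a k x k matrix to every subject block of a stacked matrix/vector
# (rows subject-major): computes (I_n (x) M) %*% A
kron_apply <- function(M, A, k) {
  if (is.matrix(A)) {
    matrix(M %*% matrix(A, nrow = k), nrow = nrow(A))
  } else {
    as.vector(M %*% matrix(A, nrow = k))
  }
}

#' GEE score vector
#'
#' `U(beta) = sum_i Z_i' V^{-1} (Y_i - Z_i beta)` under the identity link,
#' where all subjects share the inverse working covariance `V^{-1}` of the
#' balanced Gaussian model.
#'
#' @param beta coefficient vector of length `design$d`.
#' @param design a [build_design()] result.
#' @param V_inv `k x k` inverse working covariance from [build_V_inv()].
#' @param y response vector, subject-major order.
#' @return Numeric vector of length `d`.
#' @export
gee_score <- function(beta, design, V_inv, y) {
  r <- y - drop(design$Z %*% beta)
  drop(crossprod(design$Z, kron_apply(V_inv, r, design$k)))
}

#' GEE information-type matrix
#'
#' `T = sum_i Z_i' V^{-1} Z_i`, the negative derivative of the score; under
#' the identity link it does not depend on `beta`.
#'
#' @inheritParams gee_score
#' @return Symmetric positive-semidefinite `d x d` matrix.
#' @export
gee_information <- function(design, V_inv) {
  crossprod(design$Z, kron_apply(V_inv, design$Z, design$k))
}

#' One Newton-Raphson update of the penalized GEE
#'
#' `beta_new = beta + [T + n W]^{-1} [U - n W beta]` with `W` the diagonal
#' shrinkage matrix of the local quadratic approximation.  The system is
#' solved by Cholesky factorization with an escalating diagonal jitter
#' fallback.
#'
#' @param beta current coefficients.
#' @param U score vector at `beta`.
#' @param Tmat information matrix.
#' @param w diagonal of the shrinkage matrix `W`.
#' @param n subject count.
#' @return Updated coefficient vector.
#' @details When `T + nW` is rank deficient — unavoidable when covariates
#'   are time invariant, so the stacked design has at most `n` distinct
#'   rows, and unpenalized-or-saturated coordinates outnumber them — the
#'   solve falls back to an escalating diagonal jitter (from `1e-10` up to
#'   `1e-4` times the mean diagonal), which acts as a vanishing ridge on
#'   the deficient directions.
#' @export
newton_update <- function(beta, U, Tmat, w, n) {
  M <- Tmat
  diag(M) <- diag(M) + n * w
  rhs <- U - n * w * beta
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    scale <- mean(abs(diag(M)))
    for (jit in scale * 10^c(-10, -8, -6, -4)) {
      Mj <- M
      diag(Mj) <- diag(Mj) + jit
      ch <- tryCatch(chol(Mj), error = function(e) NULL)
      if (!is.null(ch)) break
    }
    if (is.null(ch))
      stop("T + nW is numerically singular even after jitter; ",
           "increase the penalties or reduce the dimension")
  }
  beta + drop(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
}

# LASSO initializer on the pooled observations (within-subject correlation
# ignored); intercept and environment columns unpenalized.  Fold ids for the
# internal 5-fold CV are assigned by subject rank so the result is invariant
# to subject-order permutations.
lasso_initialize <- function(data, design) {
  y <- data$y
  d <- design$d
  if (stats::sd(y) == 0) {
    beta0 <- numeric(d)
    beta0[1L] <- mean(y)
    return(beta0)
  }
  Zp <- design$Z[, -1L, drop = FALSE]
  if (ncol(Zp) < 2L) {
    fit <- stats::lm.fit(design$Z, y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(unname(co))
  }
  pf <- c(rep(0, design$q), rep(1, ncol(Zp) - design$q))
  subj_rank <- match(data$id, sort(data$subject_ids))
  foldid <- ((subj_rank - 1L) %% 5L) + 1L
  cv <- glmnet::cv.glmnet(Zp, y, family = "gaussian", penalty.factor = pf,
                          foldid = foldid, standardize = TRUE)
  as.numeric(stats::coef(cv, s = "lambda.min"))
}

#' Zero out near-zero coefficients
#'
#' The epsilon-stabilized Newton update never produces exact zeros; estimates
#' with `|beta| < tau` on penalized columns are declared zero.  Protected
#' (intercept/environment) columns are never thresholded.
#'
#' @param beta coefficient vector.
#' @param tau nonnegative threshold.
#' @param protect integer indices never zeroed (default none).
#' @return List with `beta` (thresholded) and `selected` (integer indices of
#'   nonzero entries).
#' @export
sparsify <- function(beta, tau, protect = integer(0)) {
  stopifnot(tau >= 0)
  drop_idx <- which(abs(beta) < tau)
  drop_idx <- setdiff(drop_idx, protect)
  beta[drop_idx] <- 0
  list(beta = beta, selected = which(beta != 0 | seq_along(beta) %in% protect))
}

# Precomputed cross-product blocks that let T = sum_i Z_i' V^{-1} Z_i be
# assembled in O(d^2) per iteration.  For exchangeable V^{-1} is a I + b J,
# so T = a C0 + b C1 with C1 the Gram of per-subject time sums; for AR(1)
# V^{-1} is tridiagonal, so T uses the interior-row Gram and the
# adjacent-lag cross products.
information_terms <- function(design) {
  k <- design$k; n <- design$n
  Z <- design$Z
  out <- list(C0 = crossprod(Z))
  if (k > 1) {
    subj <- rep(seq_len(n), each = k)
    S <- rowsum(Z, subj, reorder = FALSE)
    out$C1 <- crossprod(S)
    tpos <- rep(seq_len(k), times = n)
    interior <- which(tpos > 1 & tpos < k)
    out$Cint <- if (length(interior)) crossprod(Z[interior, , drop = FALSE])
                else matrix(0, design$d, design$d)
    A <- Z[tpos < k, , drop = FALSE]
    B <- Z[tpos > 1, , drop = FALSE]
    AB <- crossprod(A, B)
    out$Cadj <- AB + t(AB)
  }
  out
}

fast_information <- function(terms, structure, eta, phi, k) {
  if (structure == "independence" || k == 1L || eta == 0)
    return(terms$C0 / phi)
  if (structure == "exchangeable") {
    a <- 1 / (phi * (1 - eta))
    b <- -eta / (phi * (1 - eta) * (1 + (k - 1) * eta))
    a * terms$C0 + b * terms$C1
  } else {
    (terms$C0 + eta^2 * terms$Cint - eta * terms$Cadj) / (phi * (1 - eta^2))
  }
}

#' Fit a penalized generalized estimating equation model
#'
#' Fits the marginal linear interaction model
#' `Y_ij = beta0 + E_ij' beta1 + X_ij' beta2 + (X_ij (x) E_ij)' beta3 + e_ij`
#' by penalized GEE: the score equation is solved by Newton-Raphson with a
#' diagonal local-quadratic shrinkage matrix carrying MCP weights on the
#' main-feature coefficients and (for methods A1-A3) group-MCP weights on
#' each feature's interaction block under its empirical group norm.
#' The intercept and environment coefficients are never penalized.
#' Iterations start from a LASSO solution on the pooled observations and
#' stop when the L1 change of the coefficient vector drops below `tol`;
#' the dispersion `phi` and correlation parameter `eta` are re-estimated
#' from the current residuals at every iteration.
#'
#' @param data a [longitudinal_data()] object.
#' @param method one of `"A1"..."A6"`; see [method_spec()].  Ignored when
#'   both `structure` and `grouped` are supplied.
#' @param lambda1 tuning parameter for the main-feature MCP.
#' @param lambda2 tuning parameter for the interaction penalty (used as
#'   `q * lambda2` in the group MCP).
#' @param gamma MCP regularization parameter (`> 1`, default 3).
#' @param epsilon denominator stabilizer of the shrinkage weights.
#' @param max_iter maximum Newton-Raphson iterations.
#' @param tol L1 convergence tolerance on the coefficient change.
#' @param zero_threshold magnitude below which penalized estimates are
#'   declared zero.
#' @param prune logical (default `FALSE`): apply `zero_threshold` after
#'   every Newton-Raphson step, the classical local-quadratic-approximation
#'   practice of deleting coefficients once they fall below the numerical
#'   threshold.  A deleted coefficient stays at zero (its shrinkage weight
#'   saturates at `lambda/epsilon`), which stabilizes the iteration and
#'   typically halves the iteration count; `FALSE` thresholds only after
#'   convergence.
#' @param structure,grouped optional overrides of the method mapping.
#' @param gram_divisor divisor convention for [interaction_gram()].
#' @param beta_init optional starting coefficient vector (length `d`);
#'   defaults to the LASSO initializer.
#' @param verbose print per-iteration L1 deltas and nuisance estimates.
#' @return An object of class `pgee`: coefficients (thresholded), the raw
#'   final iterate, selection indices, convergence trace, final `eta` and
#'   `phi`, fitted values and residuals, and the design metadata needed by
#'   `predict()`.
#' @examples
#' sim <- simulate_longitudinal(n = 30, k = 4, p = 8, q = 3, seed = 7)
#' fit <- pgee(sim$data, method = "A1", lambda1 = 0.2, lambda2 = 0.2)
#' fit
#' head(coef(fit)[coef(fit) != 0])
#' @export
pgee <- function(data, method = "A1", lambda1, lambda2, gamma = 3,
                 epsilon = 1e-6, max_iter = 50L, tol = 1e-3,
                 zero_threshold = 1e-3, prune = FALSE, structure = NULL,
                 grouped = NULL, gram_divisor = "subjects",
                 beta_init = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "longitudinal_data"),
            lambda1 >= 0, lambda2 >= 0, gamma > 1, tol > 0,
            zero_threshold >= 0)
  spec <- method_spec(method)
  if (is.null(structure)) structure <- spec$structure
  if (is.null(grouped)) grouped <- spec$grouped

  design <- build_design(data)
  grams <- if (grouped && design$p > 0)
    interaction_gram(design, divisor = gram_divisor) else NULL

  beta <- if (is.null(beta_init)) lasso_initialize(data, design) else beta_init
  if (length(beta) != design$d) stop("beta_init has wrong length")

  n <- design$n; k <- design$k; y <- data$y
  terms <- information_terms(design)
  protect <- c(design$blocks$intercept, design$blocks$env)
  deltas <- numeric(0)
  eta <- 0; phi <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - drop(design$Z %*% beta)
    phi <- max(estimate_dispersion(r), 1e-8)
    eta <- estimate_eta(r, structure, k = k, phi = phi)
    V_inv <- build_V_inv(structure, eta, phi, k)
    U <- drop(crossprod(design$Z, kron_apply(V_inv, r, k)))
    Tmat <- fast_information(terms, structure, eta, phi, k)
    w <- build_shrinkage(beta, design, grams, lambda1, lambda2,
                         gamma = gamma, epsilon = epsilon, grouped = grouped)
    beta_new <- newton_update(beta, U, Tmat, w, n)
    if (prune) beta_new <- sparsify(beta_new, zero_threshold, protect)$beta
    delta <- sum(abs(beta_new - beta))
    deltas <- c(deltas, delta)
    if (verbose)
      message(sprintf("iter %2d: L1 delta %.6g, eta %.4f, phi %.4f",
                      iter, delta, eta, phi))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  sp <- sparsify(beta, zero_threshold, protect = protect)
  coefs <- sp$beta
  names(coefs) <- colnames(design$Z)
  fitted <- drop(design$Z %*% coefs)

  structure(list(
    coefficients = coefs, beta_raw = beta, selected = sp$selected,
    iterations = iter, converged = converged, deltas = deltas,
    eta = eta, phi = phi,
    method = method, structure = structure, grouped = grouped,
    lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
    epsilon = epsilon, tol = tol, zero_threshold = zero_threshold,
    d = design$d, n = n, k = k, p = design$p, q = design$q,
    blocks = design$blocks, groups = design$groups,
    fitted.values = fitted, residuals = data$y - fitted,
    call = match.call()
  ), class = "pgee")
}

#' @export
print.pgee <- function(x, ...) {
  cat("Penalized GEE fit (", x$method, ": ", x$structure,
      if (x$grouped) ", grouped interactions" else ", individual interactions",
      ")\n", sep = "")
  cat(sprintf("  n = %d subjects, k = %d times, p = %d features, d = %d\n",
              x$n, x$k, x$p, x$d))
  cat(sprintf("  lambda1 = %.4g, lambda2 = %.4g, gamma = %.3g\n",
              x$lambda1, x$lambda2, x$gamma))
  cat(sprintf("  %s in %d iteration(s); eta = %.3f, phi = %.3f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$eta, x$phi))
  nm <- sum(x$coefficients[x$blocks$main] != 0)
  ni <- sum(x$coefficients[x$blocks$inter] != 0)
  cat(sprintf("  selected: %d main effect(s), %d interaction coefficient(s)\n",
              nm, ni))
  invisible(x)
}

#' @export
coef.pgee <- function(object, ...) object$coefficients

#' @export
residuals.pgee <- function(object, ...) object$residuals

#' @export
fitted.pgee <- function(object, ...) object$fitted.values

#' Predict from a penalized GEE fit
#'
#' @param object a [pgee()] fit.
#' @param newdata a [longitudinal_data()] with the same `p` and `q` as the
#'   training data; omitted returns fitted values.
#' @param ... unused.
#' @return Numeric vector of linear predictions, subject-major order.
#' @export
predict.pgee <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  stopifnot(inherits(newdata, "longitudinal_data"))
  if (newdata$p != object$p || newdata$q != object$q)
    stop("newdata dimensions (p, q) do not match the fit")
  des <- build_design(newdata)
  drop(des$Z %*% object$coefficients)
}

#' @export
summary.pgee <- function(object, ...) {
  co <- object$coefficients
  sel_main <- which(co[object$blocks$main] != 0)
  sel_int <- which(co[object$blocks$inter] != 0)
  grp_sel <- if (object$p > 0)
    which(vapply(seq_len(object$p), function(h)
      any(co[object$groups$inter[h, ]] != 0), logical(1))) else integer(0)
  out <- list(fit = object,
              selected_main = object$blocks$main[sel_main],
              selected_inter = object$blocks$inter[sel_int],
              selected_groups = grp_sel)
  class(out) <- "summary.pgee"
  out
}

#' @export
print.summary.pgee <- function(x, ...) {
  print(x$fit)
  co <- x$fit$coefficients
  keep <- co != 0
  cat("\nNonzero coefficients:\n")
  print(round(co[keep], 4))
  if (length(x$selected_groups))
    cat("\nSelected interaction groups (feature indices): ",
        paste(x$selected_groups, collapse = ", "), "\n", sep = "")
  invisible(x)
}
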
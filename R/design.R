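#' Build the stacked interaction design matrix
#'
#' Stacks one row per (subject, time) observation with columns
#' `[1 | E | X | X (x) E]`: intercept, the `q` environment dummies, the `p`
#' features, and the `p*q` Kronecker interaction columns ordered
#' feature-major, dummy-minor (`x1:e1, x1:e2, ..., x1:eq, x2:e1, ...`).
#' Total width is `d = 1 + q + p + p*q`.
#'
#' @param data a [longitudinal_data()] object with `q >= 1`.
#' @return An object of class `pgee_design`: list with the stacked matrix
#'   `Z` (`n*k` rows, `d` columns), `d`, the dimensions `n, k, p, q`, a
#'   `blocks` list of column indices (`intercept`, `env`, `main`, `inter`),
#'   and a `groups` list mapping each feature `h` to its main-effect column
#'   (`groups$main[h]`) and its `q` interaction columns (`groups$inter[h, ]`).
#' @examples
#' sim <- simulate_longitudinal(n = 4, k = 2, p = 3, q = 3, seed = 1)
#' des <- build_design(sim$data)
#' des$d  # 1 + 3 + 3 + 9
#' @export
build_design <- function(data) {
  stopifnot(inherits(data, "longitudinal_data"))
  if (length(data$y) == 0L) stop("empty dataset")
  p <- data$p; q <- data$q
  if (q == 0L) stop("q = 0: interaction design undefined without environment dummies")
  d <- 1L + q + p + p * q
  xn <- colnames(data$X); en <- colnames(data$E)
  if (p > 0) {
    inter <- data$X[, rep(seq_len(p), each = q), drop = FALSE] *
      data$E[, rep(seq_len(q), times = p), drop = FALSE]
    colnames(inter) <- paste(rep(xn, each = q), rep(en, times = p), sep = ":")
    Z <- cbind("(Intercept)" = 1, data$E, data$X, inter)
  } else {
    Z <- cbind("(Intercept)" = 1, data$E)
  }
  blocks <- list(intercept = 1L,
                 env = seq_len(q) + 1L,
                 main = if (p > 0) 1L + q + seq_len(p) else integer(0),
                 inter = if (p > 0) 1L + q + p + seq_len(p * q) else integer(0))
  groups <- list(
    main = blocks$main,
    inter = if (p > 0)
      matrix(blocks$inter, nrow = p, ncol = q, byrow = TRUE) else
      matrix(integer(0), 0, q)
  )
  structure(list(Z = Z, d = d, n = data$n, k = data$k, p = p, q = q,
                 blocks = blocks, groups = groups),
            class = "pgee_design")
}

#' @export
print.pgee_design <- function(x, ...) {
  cat("pGEE design:", nrow(x$Z), "rows x", x$d, "columns",
      sprintf("(1 + q=%d + p=%d + pq=%d)\n", x$q, x$p, x$p * x$q))
  invisible(x)
}

#' Empirical Gram matrices of the interaction groups
#'
#' For each feature `h`, computes `Sigma_h = B_h' B_h / n` where `B_h` is the
#' `q`-column block of the design holding feature `h`'s interactions with the
#' environment dummies.  The divisor is the subject count `n` by default (the
#' literal definition), with the observation count `n*k` available for
#' sensitivity checks.
#'
#' @param design a [build_design()] result.
#' @param divisor `"subjects"` (`n`, default) or `"observations"` (`n*k`).
#' @return A list of `p` symmetric nonnegative-definite `q x q` matrices.
#' @export
interaction_gram <- function(design, divisor = c("subjects", "observations")) {
  stopifnot(inherits(design, "pgee_design"))
  divisor <- match.arg(divisor)
  den <- if (divisor == "subjects") design$n else design$n * design$k
  lapply(seq_len(design$p), function(h) {
    B <- design$Z[, design$groups$inter[h, ], drop = FALSE]
    crossprod(B) / den
  })
}

#' Empirical group norm of an interaction coefficient block
#'
#' Computes `sqrt(beta' Sigma beta)` for one feature's interaction
#' coefficients under its empirical Gram matrix.  Numerically negative
#' quadratic forms are clamped at zero with a warning.
#'
#' @param beta numeric vector of length `q`.
#' @param gram symmetric nonnegative-definite `q x q` matrix.
#' @return Nonnegative scalar.
#' @export
group_empirical_norm <- function(beta, gram) {
  v <- drop(crossprod(beta, gram %*% beta))
  if (v < 0) {
    if (v < -sqrt(.Machine$double.eps))
      warning("negative quadratic form clamped to zero")
    v <- 0
  }
  sqrt(v)
}
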
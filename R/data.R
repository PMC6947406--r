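#' Construct a balanced longitudinal dataset
#'
#' Bundles a continuous repeated-measures response together with feature
#' (e.g. lipid species) and environment-dummy covariates into the long-format
#' container used by all fitting and simulation functions.  Rows are stored
#' subject-major (all `k` time points of a subject contiguous, times
#' ascending); subjects keep their order of first appearance.
#'
#' @param y numeric response, one value per (subject, time) row.
#' @param X numeric matrix of feature values, `length(y)` rows, `p` columns.
#'   `p = 0` is allowed (feature-free designs).
#' @param E numeric matrix of environment dummy variables in `{0, 1}`,
#'   `length(y)` rows, `q >= 1` columns.
#' @param id subject identifier per row (any atomic type).
#' @param time within-subject time index per row; defaults to the observation
#'   order within each subject.
#' @return An object of class `longitudinal_data`: a list with elements
#'   `y`, `X`, `E`, `id`, `time`, `n` (subjects), `k` (times per subject),
#'   `p`, `q`, and `subject_ids`.
#' @examples
#' d <- longitudinal_data(y = rnorm(6), X = matrix(rnorm(12), 6, 2),
#'                        E = matrix(rep(c(1, 0), each = 3), 6, 1),
#'                        id = rep(1:2, each = 3))
#' d$n; d$k
#' @export
longitudinal_data <- function(y, X, E, id, time = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  E <- as.matrix(E)
  m <- length(y)
  if (m == 0L) stop("empty dataset")
  if (nrow(X) != m || nrow(E) != m || length(id) != m)
    stop("y, X, E and id must have the same number of rows")
  if (ncol(E) < 1L) stop("at least one environment dummy column is required")
  if (anyNA(y) || anyNA(X) || anyNA(E) || anyNA(id))
    stop("missing values are not supported; remove or impute before loading")
  if (!all(E %in% c(0, 1)))
    stop("environment dummies must be coded 0/1")

  subject_ids <- unique(id)
  n <- length(subject_ids)
  counts <- table(factor(id, levels = subject_ids))
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced design: all subjects must have the same number of rows ",
         "(counts ", paste(range(counts), collapse = "-"), ")")
  k <- as.integer(counts[1L])

  if (is.null(time)) {
    time <- stats::ave(seq_len(m), match(id, subject_ids), FUN = seq_along)
  }
  if (anyDuplicated(cbind(match(id, subject_ids), time)))
    stop("duplicated (id, time) pair")

  ord <- order(match(id, subject_ids), time)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(E))) colnames(E) <- paste0("e", seq_len(ncol(E)))

  structure(list(
    y = y[ord], X = X[ord, , drop = FALSE], E = E[ord, , drop = FALSE],
    id = id[ord], time = time[ord],
    n = n, k = k, p = ncol(X), q = ncol(E),
    subject_ids = subject_ids
  ), class = "longitudinal_data")
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat("Longitudinal dataset:", x$n, "subjects x", x$k, "times,",
      x$p, "features,", x$q, "environment dummies\n")
  invisible(x)
}

#' Subset a longitudinal dataset by subject
#'
#' @param data a [longitudinal_data()] object.
#' @param ids subject identifiers to keep (order preserved as given).
#' @return A `longitudinal_data` with the selected subjects.
#' @export
subset_subjects <- function(data, ids) {
  stopifnot(inherits(data, "longitudinal_data"))
  if (!all(ids %in% data$subject_ids)) stop("unknown subject id")
  rows <- unlist(lapply(ids, function(s) which(data$id == s)), use.names = FALSE)
  longitudinal_data(data$y[rows], data$X[rows, , drop = FALSE],
                    data$E[rows, , drop = FALSE], data$id[rows],
                    data$time[rows])
}

#' Read a long-format repeated-measures CSV
#'
#' Expects one row per (subject, time) with columns `id`, `time`, `y`,
#' environment dummies `e1..eq` and features `x1..xp` (names overridable via
#' `column_map`).  Validation mirrors [longitudinal_data()]: balance, 0/1
#' dummies and completeness are enforced, with row-level diagnostics.
#'
#' @param path CSV file path.
#' @param column_map optional named list with entries `id`, `time`, `y` and
#'   regular expressions `e_pattern`, `x_pattern` matching the dummy and
#'   feature columns.
#' @return A [longitudinal_data()] object.
#' @export
read_long_data <- function(path, column_map = NULL) {
  cm <- list(id = "id", time = "time", y = "y",
             e_pattern = "^e[0-9]+$", x_pattern = "^x[0-9]+$")
  cm[names(column_map)] <- column_map
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(cm$id, cm$time, cm$y)
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  ecols <- grep(cm$e_pattern, names(df), value = TRUE)
  xcols <- grep(cm$x_pattern, names(df), value = TRUE)
  if (length(ecols) == 0L) stop("no environment dummy columns matched")
  bad <- which(!stats::complete.cases(df[c(need, ecols, xcols)]))
  if (length(bad))
    stop("missing value(s) in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  longitudinal_data(df[[cm$y]],
                    as.matrix(df[xcols]),
                    as.matrix(df[ecols]),
                    df[[cm$id]], df[[cm$time]])
}

#' Write a longitudinal dataset as a long-format CSV
#'
#' @param data a [longitudinal_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_data <- function(data, path) {
  stopifnot(inherits(data, "longitudinal_data"))
  df <- data.frame(id = data$id, time = data$time, y = data$y,
                   check.names = FALSE)
  E <- data$E; colnames(E) <- paste0("e", seq_len(ncol(E)))
  df <- cbind(df, E)
  if (data$p > 0) {
    X <- data$X; colnames(X) <- paste0("x", seq_len(ncol(X)))
    df <- cbind(df, X)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# run an expression under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
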
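#' Replicate simulation study
#'
#' Runs the simulate / tune / fit / score pipeline for one or more methods
#' over `R` independent replicates of a scenario and aggregates
#' identification (TP/FP) and estimation (MSE/NMSE/TMSE) metrics into a
#' table shaped like the usual mean (sd) comparison tables.
#'
#' Tuning modes:
#' * `"pilot"` (default): `(lambda1, lambda2)` is chosen by subject-level CV
#'   on replicate 1 and then held fixed for all replicates of that method —
#'   the fixed-tuning timing mode of replicate benchmarks.
#' * `"per_replicate"`: CV is rerun on every replicate.
#' * `"fixed"`: use the supplied `lambda1`/`lambda2` without CV.
#'
#' @param methods character subset of `"A1"..."A6"`.
#' @param R number of replicates.
#' @param sim_args list of arguments for [simulate_longitudinal()]
#'   (everything but `seed`).
#' @param tuning `"pilot"`, `"per_replicate"` or `"fixed"`.
#' @param lambda1,lambda2 grids for CV modes (passed to [cv_pgee()]), or the
#'   fixed scalar pair for `tuning = "fixed"`.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param fit_args extra arguments for [pgee()] (e.g. `gamma`).
#' @return Object of class `pgee_study`: `summary` data frame (one row per
#'   method: means and sds of the identification metrics plus
#'   MSE/NMSE/TMSE), `replicates` (per-replicate metric rows), `tuning`
#'   (the pair used per method), `failures` (count of non-converged or
#'   failed fits, excluded from the aggregates), and the scenario.
#' @examples
#' \donttest{
#' st <- replicate_study(methods = c("A1", "A4"), R = 3,
#'                       sim_args = list(n = 40, k = 4, p = 10),
#'                       tuning = "fixed", lambda1 = 0.3, lambda2 = 0.3,
#'                       seed = 1)
#' st
#' }
#' @export
replicate_study <- function(methods = c("A1", "A4"), R = 30,
                            sim_args = list(), tuning = c("pilot",
                                                          "per_replicate",
                                                          "fixed"),
                            lambda1 = NULL, lambda2 = NULL, seed = 1,
                            fit_args = list()) {
  tuning <- match.arg(tuning)
  stopifnot(R >= 1)
  methods <- match.arg(methods, c("A1", "A2", "A3", "A4", "A5", "A6"),
                       several.ok = TRUE)

  # one truth for the whole study (the TMSE formula compares every
  # replicate's estimate against a single coefficient vector); data are
  # re-drawn per replicate
  truth <- do.call(simulate_longitudinal,
                   c(sim_args, list(seed = seed)))$truth
  sims <- lapply(seq_len(R), function(r)
    do.call(simulate_longitudinal,
            c(sim_args, list(truth = truth, seed = seed + r))))

  pairs <- list()
  for (m in methods) {
    pairs[[m]] <- switch(tuning,
      fixed = list(lambda1 = lambda1, lambda2 = lambda2),
      pilot = {
        cv <- cv_pgee(sims[[1]]$data, method = m, lambda1 = lambda1,
                      lambda2 = lambda2, seed = seed)
        list(lambda1 = cv$best$lambda1, lambda2 = cv$best$lambda2)
      },
      per_replicate = NULL)
  }

  rows <- list()
  betas <- stats::setNames(vector("list", length(methods)), methods)
  failures <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(R)) {
    sim <- sims[[r]]
    for (m in methods) {
      pr <- pairs[[m]]
      if (is.null(pr)) {
        cv <- cv_pgee(sim$data, method = m, lambda1 = lambda1,
                      lambda2 = lambda2, seed = seed + r)
        pr <- list(lambda1 = cv$best$lambda1, lambda2 = cv$best$lambda2)
      }
      fit <- tryCatch(
        do.call(pgee, c(list(data = sim$data, method = m,
                             lambda1 = pr$lambda1, lambda2 = pr$lambda2),
                        fit_args)),
        error = function(e) NULL)
      if (is.null(fit)) {
        failures[m] <- failures[m] + 1L
        next
      }
      im <- identification_metrics(fit, sim$truth)
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, replicate = r, t(im),
                   converged = fit$converged)
      betas[[m]] <- rbind(betas[[m]], fit$coefficients)
    }
  }
  reps <- do.call(rbind, rows)

  metric_cols <- c("TP", "FP", "TP_main", "FP_main", "TP_inter", "FP_inter",
                   "TP_incl", "TP_main_incl")
  summ <- do.call(rbind, lapply(methods, function(m) {
    sub <- reps[reps$method == m, , drop = FALSE]
    est <- estimation_metrics(betas[[m]], sims[[1]]$truth)
    out <- data.frame(method = m, R = nrow(sub))
    for (cl in metric_cols) {
      out[[paste0(cl, "_mean")]] <- mean(sub[[cl]])
      out[[paste0(cl, "_sd")]] <- stats::sd(sub[[cl]])
    }
    out$MSE <- est[["MSE"]]; out$NMSE <- est[["NMSE"]]; out$TMSE <- est[["TMSE"]]
    out
  }))

  structure(list(summary = summ, replicates = reps, tuning = pairs,
                 tuning_mode = tuning, failures = failures,
                 sim_args = sim_args, R = R, seed = seed,
                 truth = sims[[1]]$truth),
            class = "pgee_study")
}

#' @export
print.pgee_study <- function(x, digits = 2, ...) {
  cat("Replicate pGEE study:", x$R, "replicates, tuning =", x$tuning_mode, "\n")
  s <- x$summary
  fmt <- function(m, sdv) sprintf(paste0("%.", digits, "f(%.", digits, "f)"),
                                  m, sdv)
  tab <- data.frame(
    method = s$method,
    TP = fmt(s$TP_incl_mean, s$TP_incl_sd),
    FP = fmt(s$FP_mean, s$FP_sd),
    TP.main = fmt(s$TP_main_incl_mean, s$TP_main_incl_sd),
    FP.main = fmt(s$FP_main_mean, s$FP_main_sd),
    TP.inter = fmt(s$TP_inter_mean, s$TP_inter_sd),
    FP.inter = fmt(s$FP_inter_mean, s$FP_inter_sd),
    MSE = round(s$MSE, 4), NMSE = round(s$NMSE, 4), TMSE = round(s$TMSE, 4))
  print(tab, row.names = FALSE)
  if (any(x$failures > 0))
    cat("failed/skipped fits:",
        paste(names(x$failures), x$failures, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write replicate-study tables to disk
#'
#' Emits `summary.csv`, `replicates.csv` and a JSON `manifest.json` (seed,
#' scenario, tuning mode and selected pairs) for exact rerun.
#'
#' @param study a [replicate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(study, dir) {
  stopifnot(inherits(study, "pgee_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  manifest <- list(seed = study$seed, R = study$R,
                   tuning_mode = study$tuning_mode,
                   tuning = study$tuning, sim_args = study$sim_args,
                   failures = as.list(study$failures))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Stability selection by subject subsampling
#'
#' Repeatedly draws subsamples of subjects without replacement, refits the
#' penalized GEE at fixed tuning, and reports the fraction of subsamples in
#' which each penalized coefficient was selected.  Large proportions flag
#' effects whose selection is stable rather than a one-off artifact of a
#' particular sample.
#'
#' @param data a [longitudinal_data()] object.
#' @param method one of `"A1"..."A6"`.
#' @param lambda1,lambda2 fixed tuning parameters.
#' @param subsample_size subjects per subsample (`< n`).
#' @param B number of subsamples.
#' @param seed base seed; subsample `b` uses `seed + b`.
#' @param ... extra arguments for [pgee()].
#' @return Object of class `pgee_stability`: `proportions` (named, one per
#'   design column, `NA` for the unpenalized intercept/environment
#'   columns), `counts`, `B`, and the number of failed fits.
#' @export
stability_selection <- function(data, method = "A1", lambda1, lambda2,
                                subsample_size, B = 100, seed = 1, ...) {
  stopifnot(inherits(data, "longitudinal_data"),
            subsample_size < data$n, subsample_size >= 1, B >= 1)
  des <- build_design(data)
  counts <- numeric(des$d)
  used <- 0L
  for (b in seq_len(B)) {
    ids <- with_seed(seed + b,
                     sample(data$subject_ids, subsample_size, replace = FALSE))
    sub <- subset_subjects(data, ids)
    fit <- tryCatch(pgee(sub, method = method, lambda1 = lambda1,
                         lambda2 = lambda2, ...),
                    error = function(e) NULL)
    if (is.null(fit)) next
    used <- used + 1L
    counts <- counts + (fit$coefficients != 0)
  }
  if (used == 0L) stop("all subsample fits failed")
  prop <- counts / used
  names(prop) <- colnames(des$Z)
  prop[c(des$blocks$intercept, des$blocks$env)] <- NA_real_
  structure(list(proportions = prop, counts = counts, B = B, used = used,
                 failed = B - used, method = method,
                 lambda1 = lambda1, lambda2 = lambda2,
                 subsample_size = subsample_size),
            class = "pgee_stability")
}

#' @export
print.pgee_stability <- function(x, top = 10, ...) {
  cat("Stability selection (", x$method, "): ", x$used, "/", x$B,
      " subsamples of ", x$subsample_size, " subjects\n", sep = "")
  pr <- sort(x$proportions[!is.na(x$proportions)], decreasing = TRUE)
  cat("Top selection proportions:\n")
  print(round(utils::head(pr, top), 2))
  invisible(x)
}
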
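#' Write fit results to disk
#'
#' Writes a coefficient table (`<prefix>_coefficients.csv`: column name,
#' block, estimate, selected flag) and a JSON run manifest
#' (`<prefix>_manifest.json`) holding the method, tuning parameters,
#' tolerances and nuisance estimates needed for an exact rerun.
#'
#' @param fit a [pgee()] fit.
#' @param prefix output path prefix (directories must exist).
#' @param seed optional seed to record in the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_fit_results <- function(fit, prefix, seed = NULL) {
  stopifnot(inherits(fit, "pgee"))
  block <- rep("intercept", fit$d)
  block[fit$blocks$env] <- "environment"
  block[fit$blocks$main] <- "main"
  block[fit$blocks$inter] <- "interaction"
  tab <- data.frame(column = names(fit$coefficients),
                    block = block,
                    estimate = unname(fit$coefficients),
                    selected = seq_len(fit$d) %in% fit$selected)
  coef_path <- paste0(prefix, "_coefficients.csv")
  utils::write.csv(tab, coef_path, row.names = FALSE)

  manifest <- list(method = fit$method, structure = fit$structure,
                   grouped = fit$grouped,
                   lambda1 = fit$lambda1, lambda2 = fit$lambda2,
                   gamma = fit$gamma, epsilon = fit$epsilon,
                   tol = fit$tol, zero_threshold = fit$zero_threshold,
                   max_iterations_used = fit$iterations,
                   converged = fit$converged,
                   eta = fit$eta, phi = fit$phi,
                   n = fit$n, k = fit$k, p = fit$p, q = fit$q,
                   seed = seed)
  man_path <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(coef_path, man_path))
}
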
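# Configuration serialisation, run comparison and result reports.

#' Write a run configuration to a YAML file
#' @param config a `neo_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' A serialised configuration reloads to an identical run setup.
#'
#' @param path YAML file written by [write_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- neo_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$scf_thresh <- stats::setNames(as.numeric(cfg$scf_thresh), c("e", "d", "g"))
  cfg
}

#' Compare two NEO results
#'
#' Absolute and per-term energy differences in Hartree, kcal/mol and
#' cal/mol, machine-readable.  Errors if the two runs refer to different
#' systems.
#'
#' @param a,b `neo_result` objects on the same system and electronic basis.
#' @return a `neo_comparison` list.
#' @export
compare_runs <- function(a, b) {
  same <- identical(a$system$elements, b$system$elements) &&
    isTRUE(all.equal(a$system$coords, b$system$coords, tolerance = 1e-12)) &&
    identical(a$system$quantum, b$system$quantum)
  if (!same) stop("results refer to different systems")
  dh <- a$E_total - b$E_total
  terms <- c("electronic", "nuclear_pair", "coupling", "classical")
  per_term <- vapply(terms, function(t)
    sum(a$components[[t]]) - sum(b$components[[t]]), numeric(1))
  per_term <- c(per_term,
                nuclear = sum(a$components$nuclear) - sum(b$components$nuclear))
  structure(list(
    dE_hartree = dh,
    dE_kcal = dh * HARTREE_TO_KCALMOL,
    dE_cal = dh * HARTREE_TO_KCALMOL * 1000,
    abs_dE_kcal = abs(dh) * HARTREE_TO_KCALMOL,
    per_term_hartree = per_term,
    modes = c(a = a$config$mode, b = b$config$mode)
  ), class = "neo_comparison")
}

#' @export
print.neo_comparison <- function(x, ...) {
  cat(sprintf("run comparison (%s vs %s):\n", x$modes["a"], x$modes["b"]))
  cat(sprintf("  dE = %+.12f Eh = %+.6f kcal/mol = %+.3f cal/mol\n",
              x$dE_hartree, x$dE_kcal, x$dE_cal))
  invisible(x)
}

#' Write a machine-readable result report (JSON)
#'
#' Energies in Hartree to 12 digits, component breakdown, iteration counts,
#' thresholds and basis hashes.
#'
#' @param result a `neo_result`.
#' @param path output path.
#' @export
write_result_json <- function(result, path) {
  rep <- list(
    E_total = round(result$E_total, 12),
    components = lapply(result$components, function(x) round(unname(x), 12)),
    converged = result$converged,
    macro_cycles = nrow(result$macro_trace),
    electronic_iterations = result$electronic$iterations,
    nuclear_iterations = if (!is.null(result$nuclear))
      vapply(result$nuclear, function(s) s$iterations, numeric(1)) else NULL,
    nao = result$nao,
    mode = result$config$mode,
    thresholds = list(scf = as.list(result$config$scf_thresh),
                      macro = result$config$macro_thresh),
    basis_hash = result$basis_hash,
    seconds = round(result$seconds, 3)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
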
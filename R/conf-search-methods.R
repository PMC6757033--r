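# S3 methods for conf_search result objects.

#' @export
print.conf_search <- function(x, ...) {
  cat(sprintf("<conf_search> %s on %s (%d torsions)\n", toupper(x$method),
              x$molecule, x$n_torsions))
  cat(sprintf("  best energy : %.6f kcal/mol\n", x$best_energy))
  cat(sprintf("  iterations  : %d (%s)\n", x$iterations, x$stop_reason))
  cat(sprintf("  energy evals: %s\n", format(x$n_evals, big.mark = ",")))
  invisible(x)
}

#' @export
summary.conf_search <- function(object, ...) {
  cat(sprintf("%s conformational search on %s\n", toupper(object$method),
              object$molecule))
  cat(sprintf("  atoms %d, torsions %d\n", object$n_atoms, object$n_torsions))
  cat(sprintf("  best energy %.6f kcal/mol after %d iterations (%s)\n",
              object$best_energy, object$iterations, object$stop_reason))
  cat(sprintf("  energy evaluations %s, wall time %.2f s\n",
              format(object$n_evals, big.mark = ","), object$elapsed))
  cat("  best torsion vector (deg):",
      paste(round(object$best_t * 180 / pi, 1), collapse = ", "), "\n")
  cat("  accepted-energy trace:",
      paste(round(utils::head(object$trace, 10), 3), collapse = ", "),
      if (length(object$trace) > 10) "...\n" else "\n")
  invisible(object)
}

#' @export
coef.conf_search <- function(object, ...) object$best_t

#' Plot the accepted-energy trace of a search
#'
#' @param x a `conf_search` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.conf_search <- function(x, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "s",
                 xlab = "iteration", ylab = "best energy (kcal/mol)",
                 main = sprintf("%s on %s", toupper(x$method), x$molecule), ...)
  invisible(x)
}

#' @export
as.data.frame.conf_search <- function(x, ...) {
  data.frame(method = x$method, molecule = x$molecule,
             best_energy = x$best_energy, iterations = x$iterations,
             n_evals = x$n_evals, stop_reason = x$stop_reason,
             elapsed = x$elapsed)
}
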
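#' Energy-evaluation ledger
#'
#' A mutable counter of energy-term evaluations. One unit is charged per
#' full molecular energy evaluation and per QUBO coefficient (`U_i` or
#' `U_ij` grid term) pre-evaluated, matching the accounting used to report
#' "number of energy evaluations" in benchmark tables.
#'
#' @return An object of class `energy_ledger`.
#' @export
#' @examples
#' led <- energy_ledger()
#' ledger_add(led, 5)
#' ledger_count(led)
energy_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$count <- 0
  class(env) <- "energy_ledger"
  env
}

#' @param ledger an [energy_ledger()].
#' @param n number of evaluation units to add (non-negative).
#' @rdname energy_ledger
#' @export
ledger_add <- function(ledger, n = 1) {
  if (is.null(ledger)) return(invisible(NULL))
  stopifnot(inherits(ledger, "energy_ledger"), n >= 0)
  ledger$count <- ledger$count + n
  invisible(ledger)
}

#' @rdname energy_ledger
#' @export
ledger_count <- function(ledger) {
  stopifnot(inherits(ledger, "energy_ledger"))
  ledger$count
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat("<energy_ledger>", format(x$count, big.mark = ","), "evaluations\n")
  invisible(x)
}
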
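#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssr_invalid_parameter", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssr_schema_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_invalid("`", name, "` = ", x, " is outside the allowed range")
  invisible(x)
}

#' Canonical sensillum type codes
#'
#' The six antennal sensillum types, as ASCII tokens used in all files and
#' matrix columns: `Da`, `Db`, `Dg` (the three smooth-peg D subtypes,
#' displayed as D-alpha/beta/gamma), `C` (grooved peg), `E1` and `E2`
#' (hair-like). Display names carry the Greek letters.
#'
#' @return Named character vector mapping codes to display names.
#' @export
#' @examples
#' sensillum_types()
sensillum_types <- function() {
  c(Da = "Dα", Db = "Dβ", Dg = "Dγ",
    C = "C", E1 = "E1", E2 = "E2")
}

#' The 11 chemical classes of the odorant panel
#'
#' @return Character vector of class labels.
#' @export
odorant_classes <- function() {
  c("carboxylic_acid", "ester", "aldehyde", "alcohol", "ketone",
    "aromatic_aliphatic", "halide", "heterocyclic", "amine",
    "sulfide", "urea")
}
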
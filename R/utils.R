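# shared internal helpers

Z95 <- stats::qnorm(0.975)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_mr <- function(..., class = "mrmediate_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "mrmediate_error")))
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL runs against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# two-sided normal p-value from an estimate and its SE
normal_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# canonical complement map for strand flips
ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
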
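# Small shared helpers: deterministic rounding, scoped RNG, seed derivation.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; printed tables in this field are
#' conventionally rounded half-up, so percentage reporting uses this rule.
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Hierarchical seeding: every stochastic stage draws its own seed from the
# run seed plus a stage offset, so stages can be regenerated independently.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 1048573) * 2039 + as.numeric(offset)
  as.integer(s %% 2147483629 + 1)
}

rowVars_ <- function(x) {
  if (ncol(x) < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
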
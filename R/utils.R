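#' @keywords internal
"_PACKAGE"

# Canonical 23-feature blood-panel schema (plus the `label` outcome column).
PANEL_FEATURES <- c(
  "Age", "WBC", "RBC", "HGB", "HCT", "MCV", "MCH", "MCHC",
  "RDW-SD", "RDW-CV", "PLT", "MPV", "PDW", "PCT", "BA", "EO", "LY", "MO",
  "NEU", "NEU/LY", "PLT/LY", "MPV/LY", "LY/MO"
)

# ratio column -> c(numerator, denominator)
RATIO_DEFS <- list(
  "NEU/LY" = c("NEU", "LY"),
  "PLT/LY" = c("PLT", "LY"),
  "MPV/LY" = c("MPV", "LY"),
  "LY/MO"  = c("LY", "MO")
)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) stats::plogis(x)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# consistent "named scalar check" used by config validators
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
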
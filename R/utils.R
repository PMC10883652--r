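#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats median p.adjust qwilcox rnbinom rgamma rmultinom rbinom
#'   runif sd shapiro.test t.test wilcox.test kruskal.test cmdscale dist
#'   predict ave setNames as.dist
#' @importFrom utils read.delim write.table combn packageVersion
NULL

stop2 <- function(...) stop(..., call. = FALSE)

# Derive `n` reproducible sub-seeds from a master seed without leaking more
# than one set.seed() call into the global stream. Kept below 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) <= tol, na.rm = TRUE)
}

# Validate a single compositional vector: non-negative, sums to one.
check_composition <- function(p, tol = 1e-9, what = "composition") {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p))
    stop2("invalid ", what, ": must be a numeric vector without NA")
  if (any(p < -tol))
    stop2("invalid ", what, ": negative entries")
  if (abs(sum(p) - 1) > tol)
    stop2("invalid ", what, ": entries must sum to 1 (got ", format(sum(p)), ")")
  invisible(pmax(p, 0))
}
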
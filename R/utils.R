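# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library functions never perturb the
#' caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically combine small integers into one 31-bit seed.
# Multipliers are < 2^21 so products stay exactly representable in doubles.
derive_seed <- function(...) {
  parts <- c(...)
  stopifnot(all(is.finite(parts)))
  m <- 2147483563 # large prime < 2^31
  s <- 11
  for (p in parts) s <- (s * 1048573 + (as.numeric(p) %% m)) %% m
  as.integer(s) + 1L
}

# Column standard deviations without apply() overhead (denominator n - 1).
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - mu^2, 0) * n / (n - 1))
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_f("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_f("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_f("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_number(x, name, lower = lower)
  if (x != round(x)) stop_f("`%s` must be a whole number", name)
  invisible(as.integer(x))
}

match_matrix_type <- function(matrix) {
  if (!is.character(matrix) || length(matrix) != 1L ||
      !matrix %in% c("plasma", "brain"))
    stop_f("unknown matrix type \"%s\": must be \"plasma\" or \"brain\"",
           paste(as.character(matrix), collapse = ","))
  matrix
}
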
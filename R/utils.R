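# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# scalar checks -------------------------------------------------------------

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_scalar_num(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# matrix coercions ----------------------------------------------------------

as_dgc <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  if (is.matrix(x)) return(methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"))
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# dense copy of a (possibly sparse) genes x cells matrix
as_dense <- function(x) {
  if (is.matrix(x)) x else as.matrix(x)
}
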
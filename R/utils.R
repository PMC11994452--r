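#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# dgCMatrix coercion that tolerates base matrices and keeps dimnames.
as_sparse <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

check_count_matrix <- function(m, what = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("%s must carry observation and feature ids as dimnames", what)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stopf("%s has duplicated observation or feature ids", what)
  if (any(m@x < 0)) stopf("%s contains negative entries", what)
  invisible(m)
}
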
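# Internal helpers shared across modules.

# Deterministic small-integer hash of a string (polynomial rolling hash).
# Used to derive per-method and per-pool seeds from the run seed without
# coupling the RNG streams of different clusterers.
.stable_hash <- function(s) {
  ints <- utf8ToInt(s)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 1000003
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' that seeded components (simulation, base clusterers) do not perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Validate a genes x cells count matrix (base matrix or Matrix sparse class).
# Returns the matrix invisibly; stops with an informative message otherwise.
.validate_counts <- function(counts) {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix"))) {
    stop("`counts` must be a genes x cells matrix (base matrix or Matrix class)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene ids as rownames and cell ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in `counts`")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids in `counts`")
  v <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(v) && any(!is.finite(v))) stop("`counts` contains non-finite values")
  if (length(v) && any(v < 0)) stop("`counts` contains negative values")
  if (length(v) && any(v != floor(v))) stop("`counts` contains non-integral values")
  invisible(counts)
}
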
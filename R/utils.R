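#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' then restores the caller's RNG state, so that seeded package functions
#' never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed
#'
#' One master seed reproduces the whole pipeline: stage seeds (data split,
#' GA, simulation) are derived by fixed offsets. Kept below 2^31 - 1 so the
#' result is always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param offset Integer stage offset.
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  as.integer((abs(as.double(master)) * 1000 + abs(as.double(offset))) %%
               2147483647)
}

# shared column order for treatment coordinates
.treatment_cols <- c("naocl", "h2o2", "time")

# coerce a treatment data.frame/matrix/vector to a numeric matrix with the
# canonical column order, validating finiteness and non-negativity
as_treatment_matrix <- function(x, require_nonneg = TRUE) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 3L) {
      stop("a single treatment must have 3 coordinates (naocl, h2o2, time)")
    }
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, .treatment_cols))
  }
  if (is.data.frame(x)) {
    missing <- setdiff(.treatment_cols, names(x))
    if (length(missing)) {
      stop("missing treatment column(s): ", paste(missing, collapse = ", "))
    }
    x <- as.matrix(x[, .treatment_cols, drop = FALSE])
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop("treatment matrix must have 3 columns")
    if (is.null(colnames(x))) colnames(x) <- .treatment_cols
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("treatment coordinates must be finite")
  if (require_nonneg && any(x < 0)) {
    stop("treatment coordinates must be non-negative")
  }
  x
}
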
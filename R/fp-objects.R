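#' Binary fingerprint
#'
#' A binary fingerprint is the set of its set feature keys over a named key
#' space. Folded spaces (`maccs166`, `ecfp4_2048`, or a synthetic
#' `synth<L>` space) use integer positions in `[0, length)`; the unfolded
#' MOLPRINT2D space (`umop2d_unfolded`) uses canonical atom-environment
#' strings, so no global vector length exists.
#'
#' @param keys integer vector (folded space) or character vector (unfolded
#'   space) of set keys; duplicates are collapsed.
#' @param space key-space name: `"maccs166"`, `"ecfp4_2048"`,
#'   `"umop2d_unfolded"` or `"synth<L>"` for a synthetic folded space of
#'   length `L`.
#' @return An object of class `bit_fp` with elements `keys` (sorted, unique)
#'   and `space`.
#' @examples
#' a <- bit_fp(c(1L, 2L, 3L), "maccs166")
#' b <- bit_fp(c(2L, 3L, 4L), "maccs166")
#' tanimoto_binary(a, b) # 0.5
#' @export
bit_fp <- function(keys, space) {
  stopifnot(is.character(space), length(space) == 1L)
  len <- fp_space_length(space)
  if (is.na(len)) {
    keys <- sort(unique(as.character(keys)))
  } else {
    keys <- sort(unique(as.integer(keys)))
    if (length(keys) && (min(keys) < 0L || max(keys) >= len))
      stop("keys outside [0, ", len, ") for space '", space, "'")
  }
  structure(list(keys = keys, space = space), class = "bit_fp")
}

#' Real-valued fingerprint
#'
#' Sparse non-negative weight vector over the same key spaces as [bit_fp()].
#' Realist and knowledgeable consensus fingerprints are `float_fp` objects
#' with weights in \[0, 1\] (per-bit frequencies among the query actives).
#'
#' @param weights named numeric vector; names are keys (integer positions as
#'   strings for folded spaces, environment strings for the unfolded space),
#'   values are non-negative weights. Zero weights are dropped.
#' @param space key-space name, as for [bit_fp()].
#' @return An object of class `float_fp` with elements `weights` and `space`.
#' @export
float_fp <- function(weights, space) {
  stopifnot(is.numeric(weights))
  if (length(weights) && is.null(names(weights)))
    stop("float_fp weights must be named by key")
  if (any(weights < 0)) stop("negative fingerprint weight")
  if (!length(weights)) names(weights) <- character(0)
  weights <- weights[weights > 0]
  weights <- weights[order(names(weights))]
  structure(list(weights = weights, space = space), class = "float_fp")
}

#' Lift a binary fingerprint to a 0/1-valued real fingerprint
#'
#' @param fp a `bit_fp`.
#' @return A `float_fp` with weight 1 on every set key.
#' @export
as_float_fp <- function(fp) {
  stopifnot(inherits(fp, "bit_fp"))
  w <- rep(1, length(fp$keys))
  names(w) <- as.character(fp$keys)
  float_fp(w, fp$space)
}

#' Length of a folded fingerprint key space
#'
#' @param space key-space name.
#' @return Integer length for folded spaces (166 for `maccs166`, 2048 for
#'   `ecfp4_2048`, `L` for `synth<L>`), `NA` for the unfolded space.
#' @export
fp_space_length <- function(space) {
  switch(space,
    maccs166 = 166L,
    ecfp4_2048 = 2048L,
    umop2d_unfolded = NA_integer_,
    {
      if (grepl("^synth[0-9]+$", space))
        as.integer(sub("^synth", "", space))
      else stop("unknown fingerprint space: ", space)
    }
  )
}

#' @export
print.bit_fp <- function(x, ...) {
  cat("<bit_fp> space=", x$space, " |keys|=", length(x$keys), "\n", sep = "")
  invisible(x)
}

#' @export
print.float_fp <- function(x, ...) {
  cat("<float_fp> space=", x$space, " |keys|=", length(x$weights), "\n",
      sep = "")
  invisible(x)
}

check_same_space <- function(a, b) {
  if (!identical(a$space, b$space))
    stop("fingerprint space mismatch: '", a$space, "' vs '", b$space, "'")
  invisible(TRUE)
}

#' Pack a list of binary fingerprints into a sparse incidence matrix
#'
#' Rows are molecules, columns are keys. For folded spaces the matrix has
#' exactly `fp_space_length(space)` columns (named by 0-based position); for
#' the unfolded space, columns are the union of environment keys observed.
#' Screening functions use this representation to score whole candidate
#' databases with sparse linear algebra.
#'
#' @param fps named list of `bit_fp` objects sharing one space.
#' @return A `dgCMatrix` with one row per fingerprint (named by molecule id)
#'   and an attribute `space`.
#' @export
fp_matrix <- function(fps) {
  stopifnot(length(fps) > 0L, !is.null(names(fps)))
  space <- fps[[1L]]$space
  ok <- vapply(fps, function(f) identical(f$space, space), logical(1))
  if (!all(ok)) stop("fingerprint space mismatch in fp_matrix")
  len <- fp_space_length(space)
  if (is.na(len)) {
    vocab <- sort(unique(unlist(lapply(fps, `[[`, "keys"))))
  } else {
    vocab <- as.character(seq_len(len) - 1L)
  }
  nk <- vapply(fps, function(f) length(f$keys), integer(1))
  i <- rep(seq_along(fps), nk)
  j <- match(as.character(unlist(lapply(fps, `[[`, "keys"))), vocab)
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(fps), length(vocab)),
    dimnames = list(names(fps), vocab)
  )
  attr(m, "space") <- space
  m
}
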
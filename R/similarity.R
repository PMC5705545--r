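#' Tanimoto coefficient for binary fingerprints
#'
#' `Tani(A, B) = |A intersect B| / |A union B|` over the set of set keys.
#' When both key sets are empty the union is empty and the coefficient is
#' defined as 0: a featureless query matches nothing.
#'
#' @param a,b `bit_fp` objects in the same key space.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto_binary(bit_fp(1:3, "maccs166"), bit_fp(2:4, "maccs166")) # 2/4
#' @export
tanimoto_binary <- function(a, b) {
  stopifnot(inherits(a, "bit_fp"), inherits(b, "bit_fp"))
  check_same_space(a, b)
  ni <- length(intersect(a$keys, b$keys))
  nu <- length(a$keys) + length(b$keys) - ni
  if (nu == 0L) return(0)
  ni / nu
}

#' Tanimoto coefficient for real-valued fingerprints
#'
#' `Tani(X, Y) = sum(x_i * y_i) / sum(x_i^2 + y_i^2 - x_i * y_i)`.
#' Evaluation is sparse, over the union of keys present in either vector;
#' absent keys contribute zero to every sum, which recovers the dense
#' fixed-length formulation and extends it to the unfolded key space.
#' Both-all-zero input returns 0 by the same convention as
#' [tanimoto_binary()]. On 0/1-valued vectors this reduces exactly to the
#' binary coefficient of the support sets.
#'
#' @param x,y `float_fp` objects (or `bit_fp`, lifted via [as_float_fp()])
#'   in the same key space.
#' @return Similarity in \[0, 1\] for non-negative weights.
#' @export
tanimoto_float <- function(x, y) {
  if (inherits(x, "bit_fp")) x <- as_float_fp(x)
  if (inherits(y, "bit_fp")) y <- as_float_fp(y)
  stopifnot(inherits(x, "float_fp"), inherits(y, "float_fp"))
  check_same_space(x, y)
  xs <- sum(x$weights^2)
  ys <- sum(y$weights^2)
  common <- intersect(names(x$weights), names(y$weights))
  xy <- sum(x$weights[common] * y$weights[common])
  den <- xs + ys - xy
  if (den == 0) return(0)
  xy / den
}
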
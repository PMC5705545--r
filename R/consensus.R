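# Consensus queries: the five policies and potency scaling.

POLICIES <- c("single", "oppo", "pess", "opti", "real", "know")

# Full names or 4-letter abbreviations are accepted ("sing" -> "single").
normalize_policy <- function(policy) {
  p <- tolower(policy)
  if (p == "sing") p <- "single"
  full <- c(oppo = "opportunist", pess = "pessimist", opti = "optimist",
            real = "realist", know = "knowledgeable")
  hit <- names(full)[match(p, full)]
  if (!is.na(hit)) p <- hit
  if (!p %in% POLICIES) stop("unknown consensus policy: ", policy)
  p
}

#' Potency weights for query actives
#'
#' Logarithmic IC50-based weighting: `w_i = log10(IC50_worst) -
#' log10(IC50_i) + 1`, where `IC50_worst` is the largest IC50 among the
#' queries (the least active molecule). The scheme is linear over the whole
#' potency range: the least active query gets weight exactly 1 and a query
#' 10x more potent gets one unit more. Base-10 logarithms follow the pIC50
#' convention; any base only rescales `w - 1` and preserves the ordering.
#' All IC50s must be in one consistent unit (only their ratios matter).
#'
#' @param queries data frame of query actives with columns `mol_id` and
#'   `ic50` (all strictly positive).
#' @return Named numeric vector of weights `>= 1`, minimum exactly 1.
#' @examples
#' potency_weights(data.frame(mol_id = c("a", "b", "c"),
#'                            ic50 = c(100, 10, 1))) # 1, 2, 3
#' @export
potency_weights <- function(queries) {
  stopifnot(is.data.frame(queries),
            all(c("mol_id", "ic50") %in% names(queries)))
  ic50 <- queries$ic50
  if (anyNA(ic50) || any(ic50 <= 0))
    stop("every query needs a strictly positive IC50 for potency scaling")
  w <- log10(max(ic50)) - log10(ic50) + 1.0
  names(w) <- queries$mol_id
  w
}

#' Build a consensus query
#'
#' Combines the fingerprints of the query actives under a consensus policy:
#' * `single` - exactly one query, kept as-is;
#' * `oppo` (opportunist) - the member fingerprints are kept verbatim and
#'   fused at scoring time by the max-of-scores rule;
#' * `pess` (pessimist) - bitwise AND (intersection of key sets);
#' * `opti` (optimist) - bitwise OR (union of key sets);
#' * `real` (realist) - real-valued fingerprint whose value at key `k` is
#'   the fraction of queries that set `k`;
#' * `know` (knowledgeable) - realist with each query weighted by its
#'   potency weight: value at `k` is `sum(w_i, i sets k) / sum(w_i)`, which
#'   stays in \[0, 1\] and reduces to realist when all weights are equal.
#'
#' @param policy policy name, full or 4-letter abbreviation.
#' @param query_fps list of `bit_fp` sharing one space.
#' @param potency named weight vector from [potency_weights()], covering
#'   every query; required for `know`, ignored otherwise.
#' @return A `consensus_query` object.
#' @export
build_consensus <- function(policy, query_fps, potency = NULL) {
  policy <- normalize_policy(policy)
  if (!length(query_fps)) stop("empty query list")
  space <- query_fps[[1L]]$space
  for (fp in query_fps) {
    stopifnot(inherits(fp, "bit_fp"))
    if (!identical(fp$space, space)) stop("mixed fingerprint spaces")
  }
  n <- length(query_fps)
  if (policy == "single" && n != 1L)
    stop("the single policy takes exactly one query")
  payload <- switch(policy,
    single = ,
    oppo = list(members = query_fps),
    pess = list(fused = bit_fp(Reduce(intersect,
                                      lapply(query_fps, `[[`, "keys")),
                               space)),
    opti = list(fused = bit_fp(unlist(lapply(query_fps, `[[`, "keys")),
                               space)),
    real = list(fused = freq_fusion(query_fps, rep(1, n), space)),
    know = {
      if (is.null(potency)) stop("knowledgeable policy needs potency weights")
      ids <- names(query_fps)
      if (is.null(ids) || !all(ids %in% names(potency)))
        stop("potency weights must cover every query fingerprint")
      freq <- freq_fusion(query_fps, unname(potency[ids]), space)
      list(fused = freq)
    }
  )
  structure(c(list(policy = policy, space = space), payload),
            class = "consensus_query")
}

# Weighted bit-frequency fusion: value(k) = sum(w_i; k in q_i) / sum(w_i).
freq_fusion <- function(query_fps, w, space) {
  keys <- unlist(lapply(query_fps, `[[`, "keys"))
  wk <- rep(w, vapply(query_fps, function(f) length(f$keys), integer(1)))
  agg <- tapply(wk, as.character(keys), sum) / sum(w)
  v <- as.numeric(agg)
  names(v) <- names(agg)
  float_fp(v, space)
}

#' @export
print.consensus_query <- function(x, ...) {
  n <- if (!is.null(x$members)) length(x$members) else 1L
  cat("<consensus_query> policy=", x$policy, " space=", x$space,
      if (!is.null(x$members)) paste0(" members=", n) else " (fused)",
      "\n", sep = "")
  invisible(x)
}

#' Score a candidate against a consensus query
#'
#' `single` scores by plain binary Tanimoto against the one query; `oppo`
#' takes the maximum Tanimoto over all members (max-of-scores fusion);
#' `pess`/`opti` score the fused binary fingerprint; `real`/`know` score the
#' fused real-valued fingerprint against the candidate lifted to 0/1 weights
#' with the real-valued Tanimoto.
#'
#' @param consensus a `consensus_query`.
#' @param candidate a `bit_fp` in the same space.
#' @return Similarity in \[0, 1\].
#' @export
cscore <- function(consensus, candidate) {
  stopifnot(inherits(consensus, "consensus_query"),
            inherits(candidate, "bit_fp"))
  if (!identical(consensus$space, candidate$space))
    stop("fingerprint space mismatch between consensus and candidate")
  switch(consensus$policy,
    single = tanimoto_binary(consensus$members[[1L]], candidate),
    oppo = max(vapply(consensus$members, tanimoto_binary, numeric(1),
                      b = candidate)),
    pess = ,
    opti = tanimoto_binary(consensus$fused, candidate),
    real = ,
    know = tanimoto_float(consensus$fused, as_float_fp(candidate))
  )
}
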
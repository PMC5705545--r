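# Retrospective screening experiments: rank a candidate database under a
# consensus query, repeat over random query draws, and the CPU-bounded and
# potency delta-rank comparison protocols.

#' Bundle fingerprints and labels into a screening dataset
#'
#' @param fps named list of `bit_fp` sharing one space (names are molecule
#'   ids).
#' @param labels character vector (`active`/`inactive`/`unknown`) aligned
#'   with `fps`.
#' @param ic50 optional numeric vector aligned with `fps` (NA allowed for
#'   inactives).
#' @param target_id free-form dataset identifier.
#' @return An `fp_dataset`: molecule ids, labels, IC50s and a sparse
#'   incidence matrix of the fingerprints.
#' @export
fp_dataset <- function(fps, labels, ic50 = NULL, target_id = "target") {
  stopifnot(length(fps) == length(labels), !is.null(names(fps)))
  if (is.null(ic50)) ic50 <- rep(NA_real_, length(fps))
  if (anyDuplicated(names(fps))) stop("duplicate mol_id in dataset")
  structure(list(
    mol_id = names(fps),
    label = as.character(labels),
    ic50 = as.numeric(ic50),
    fpmat = fp_matrix(fps),
    space = fps[[1L]]$space,
    target_id = target_id
  ), class = "fp_dataset")
}

#' @export
print.fp_dataset <- function(x, ...) {
  cat("<fp_dataset> '", x$target_id, "': ", length(x$mol_id),
      " molecules (", sum(x$label == "active"), " active, ",
      sum(x$label == "inactive"), " inactive), space=", x$space, "\n",
      sep = "")
  invisible(x)
}

# Extract one matrix row as a bit_fp.
row_fp <- function(dataset, id) {
  r <- dataset$fpmat[id, ]
  keys <- colnames(dataset$fpmat)[which(r != 0)]
  bit_fp(keys, dataset$space)
}

# Run the RNG at `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Score every row of a sparse 0/1 candidate matrix against a consensus.
score_candidates <- function(consensus, m) {
  vocab <- colnames(m)
  rs <- Matrix::rowSums(m)
  key_vec <- function(keys, values) {
    v <- numeric(ncol(m))
    idx <- match(as.character(keys), vocab)
    ok <- !is.na(idx)
    v[idx[ok]] <- values[ok]
    v
  }
  if (consensus$policy %in% c("single", "oppo")) {
    members <- consensus$members
    scores <- matrix(0, nrow(m), length(members))
    for (j in seq_along(members)) {
      keys <- members[[j]]$keys
      inter <- as.numeric(m %*% key_vec(keys, rep(1, length(keys))))
      union <- rs + length(keys) - inter
      scores[, j] <- ifelse(union == 0, 0, inter / union)
    }
    apply(scores, 1L, max)
  } else if (consensus$policy %in% c("pess", "opti")) {
    keys <- consensus$fused$keys
    inter <- as.numeric(m %*% key_vec(keys, rep(1, length(keys))))
    union <- rs + length(keys) - inter
    ifelse(union == 0, 0, inter / union)
  } else {
    w <- consensus$fused$weights
    xs <- sum(w^2)
    num <- as.numeric(m %*% key_vec(names(w), w))
    den <- xs + rs - num
    ifelse(den == 0, 0, num / den)
  }
}

#' Rank a candidate database under a consensus query
#'
#' Every candidate is scored with [cscore()] semantics (sparse-matrix fast
#' path) and sorted by descending score; ties keep their input order, so the
#' ranking is deterministic and seed-free. Labels travel along but are never
#' consulted during scoring.
#'
#' @param consensus a `consensus_query`.
#' @param candidates an `fp_dataset`, or a named list of `bit_fp`.
#' @param labels labels aligned with `candidates` when it is a plain list.
#' @param subset optional vector of molecule ids restricting the database
#'   (used by the experiment protocols to drop query actives).
#' @return Ranked list: data frame `rank`, `mol_id`, `score`, `label`.
#' @export
rank_database <- function(consensus, candidates, labels = NULL,
                          subset = NULL) {
  if (inherits(candidates, "fp_dataset")) {
    ids <- candidates$mol_id
    labels <- candidates$label
    if (!is.null(subset)) {
      keep <- ids %in% subset
      ids <- ids[keep]; labels <- labels[keep]
    }
    if (!length(ids)) stop("empty candidate set")
    if (!identical(consensus$space, candidates$space))
      stop("fingerprint space mismatch between consensus and candidates")
    m <- candidates$fpmat[ids, , drop = FALSE]
  } else {
    stopifnot(is.list(candidates), length(candidates) > 0L)
    if (is.null(labels)) labels <- rep("unknown", length(candidates))
    ids <- names(candidates)
    if (is.null(ids)) ids <- paste0("cand", seq_along(candidates))
    names(candidates) <- ids
    for (fp in candidates)
      if (!identical(consensus$space, fp$space))
        stop("fingerprint space mismatch between consensus and candidates")
    m <- fp_matrix(candidates)
  }
  score <- score_candidates(consensus, m)
  o <- order(-score, seq_along(score))
  data.frame(rank = seq_along(o), mol_id = ids[o], score = score[o],
             label = labels[o], stringsAsFactors = FALSE)
}

#' Experiment configuration
#'
#' @param policy consensus policy (full name or 4-letter abbreviation).
#' @param csize consensus size `N`: number of actives drawn per repetition.
#'   Consensus policies use 2..20; `csize = 1` is reserved for (and implied
#'   by) the `single` policy.
#' @param repetitions number of random query draws.
#' @param seed integer seed controlling every random draw.
#' @param pm_percent power-metric threshold (percent of the database).
#' @param single_mode for the `single` policy: `"enumerate"` uses each
#'   active in turn (cycling), `"sample"` draws one active uniformly per
#'   repetition, `"auto"` (default) enumerates when the actives fit in the
#'   repetition budget and samples otherwise.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(policy, csize = 10L, repetitions = 100L,
                              seed = 1L, pm_percent = 10,
                              single_mode = c("auto", "enumerate",
                                              "sample")) {
  policy <- normalize_policy(policy)
  csize <- as.integer(csize)
  if (policy == "single") {
    if (csize != 1L) stop("the single policy implies csize = 1")
  } else if (csize < 2L || csize > 20L) {
    stop("consensus size must be in 2..20 (got ", csize, ")")
  }
  structure(list(policy = policy, csize = csize,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), pm_percent = pm_percent,
                 single_mode = match.arg(single_mode)),
            class = "experiment_config")
}

draw_queries <- function(config, active_ids, rep_index) {
  n_act <- length(active_ids)
  if (config$policy == "single") {
    mode <- config$single_mode
    if (mode == "auto")
      mode <- if (n_act <= config$repetitions) "enumerate" else "sample"
    if (mode == "enumerate")
      active_ids[(rep_index - 1L) %% n_act + 1L]
    else sample(active_ids, 1L)
  } else {
    sample(active_ids, config$csize)
  }
}

build_rep_consensus <- function(dataset, config, q_ids) {
  q_fps <- lapply(q_ids, row_fp, dataset = dataset)
  names(q_fps) <- q_ids
  potency <- NULL
  if (config$policy == "know") {
    idx <- match(q_ids, dataset$mol_id)
    potency <- potency_weights(data.frame(mol_id = q_ids,
                                          ic50 = dataset$ic50[idx]))
  }
  build_consensus(config$policy, q_fps, potency)
}

#' Retrospective consensus-query screening experiment
#'
#' Per repetition: draw the query set uniformly without replacement from the
#' actives, remove those actives from the database to screen (so benchmarks
#' do not get artificially easier as the consensus grows), build the
#' consensus, rank the remaining molecules and compute AUC and the power
#' metric. Results are aggregated as median +/- MAD and as the median
#' accumulated-actives curve.
#'
#' @param dataset an `fp_dataset` with at least `csize + 1` actives and one
#'   inactive.
#' @param config an [experiment_config()].
#' @return An `experiment_result` with per-repetition `auc` and `pm`
#'   vectors, `auc_summary`/`pm_summary` (median and raw MAD) and
#'   `median_curve`.
#' @export
retrospective_experiment <- function(dataset, config) {
  stopifnot(inherits(dataset, "fp_dataset"),
            inherits(config, "experiment_config"))
  active_ids <- dataset$mol_id[dataset$label == "active"]
  n_act <- length(active_ids)
  if (n_act <= config$csize)
    stop("dataset needs more than csize actives (", n_act, " <= ",
         config$csize, ")")
  if (config$policy != "single" && config$csize > n_act / 2)
    warning("consensus size exceeds half the actives (", config$csize,
            " > ", n_act, "/2)")
  if (!any(dataset$label == "inactive"))
    stop("dataset needs at least one inactive")
  reps <- config$repetitions
  with_seed(config$seed, {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    auc <- pm <- numeric(reps)
    curves <- vector("list", reps)
    for (r in seq_len(reps)) {
      set.seed(rep_seeds[r])
      q_ids <- draw_queries(config, active_ids, r)
      cons <- build_rep_consensus(dataset, config, q_ids)
      ranked <- rank_database(cons, dataset,
                              subset = setdiff(dataset$mol_id, q_ids))
      auc[r] <- roc_auc(ranked)
      pm[r] <- power_metric(ranked, config$pm_percent)
      curves[[r]] <- accumulated_actives(ranked)
    }
    structure(list(auc = auc, pm = pm,
                   auc_summary = median_and_mad(auc),
                   pm_summary = median_and_mad(pm),
                   median_curve = median_curve(curves),
                   config = config),
              class = "experiment_result")
  })
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> policy=", x$config$policy, " N=", x$config$csize,
      " reps=", x$config$repetitions, "\n  AUC ",
      sprintf("%.3f +/- %.3f", x$auc_summary[1], x$auc_summary[2]),
      "   PM_", x$config$pm_percent, "% ",
      sprintf("%.3f +/- %.3f", x$pm_summary[1], x$pm_summary[2]), "\n",
      sep = "")
  invisible(x)
}

#' CPU-bounded comparison of two consensus policies
#'
#' Models a screen with a fixed time budget over an effectively unbounded
#' library: the faster policy screens the whole candidate database while the
#' slower one only screens a uniformly random `1/speedup` fraction
#' (`floor(|C|/speedup)` molecules, so the budget is never exceeded). Both
#' policies share the same query draw in each repetition; the returned
#' accumulated-actives curves (medians over repetitions) live on a common
#' rank axis, and dominance is judged by the caller.
#'
#' @param dataset an `fp_dataset`.
#' @param config_fast,config_slow [experiment_config()]s for the faster and
#'   slower policy; `config_fast` supplies repetitions and seed.
#' @param speedup how many times faster the fast policy is (`>= 1`).
#' @return List with median curves `fast` and `slow`, and `speedup`.
#' @export
cpu_bounded_compare <- function(dataset, config_fast, config_slow,
                                speedup = 2) {
  if (speedup < 1) stop("speedup must be >= 1")
  stopifnot(config_fast$csize == config_slow$csize)
  active_ids <- dataset$mol_id[dataset$label == "active"]
  reps <- config_fast$repetitions
  with_seed(config_fast$seed, {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    fast_curves <- slow_curves <- vector("list", reps)
    for (r in seq_len(reps)) {
      set.seed(rep_seeds[r])
      q_ids <- draw_queries(config_fast, active_ids, r)
      candidates <- setdiff(dataset$mol_id, q_ids)
      n_slow <- floor(length(candidates) / speedup)
      slow_ids <- if (n_slow > 0L) sample(candidates, n_slow)
                  else character(0)
      cons_fast <- build_rep_consensus(dataset, config_fast, q_ids)
      cons_slow <- build_rep_consensus(dataset, config_slow, q_ids)
      fast_curves[[r]] <-
        accumulated_actives(rank_database(cons_fast, dataset,
                                          subset = candidates))
      slow_curves[[r]] <- if (n_slow > 0L)
        accumulated_actives(rank_database(cons_slow, dataset,
                                          subset = slow_ids))
      else data.frame(x = integer(0), y = integer(0))
    }
    list(fast = median_curve(fast_curves),
         slow = if (n_slow_ok(slow_curves)) median_curve(slow_curves)
                else slow_curves[[1L]],
         speedup = speedup)
  })
}

n_slow_ok <- function(curves) all(vapply(curves, nrow, integer(1)) > 0L)

#' Potency delta-rank comparison of two policies
#'
#' For each active molecule, the median rank it obtains in the screened
#' database under each policy is recorded across repetitions (only
#' repetitions where that active was not drawn into the query set count: a
#' query molecule has no rank). The delta rank is `median rank under
#' policy_a - median rank under policy_b`; a negative delta means policy_a
#' retrieves the molecule earlier. Both policies share the query draw of
#' each repetition. The output is ordered by decreasing IC50, i.e. from
#' least to most potent.
#'
#' @param dataset an `fp_dataset` whose actives all carry an IC50.
#' @param policy_a,policy_b policy names.
#' @param csize consensus size.
#' @param repetitions,seed experiment controls.
#' @return Data frame `mol_id`, `ic50`, `delta_rank` (one row per active
#'   that was rankable at least once).
#' @export
delta_rank_analysis <- function(dataset, policy_a, policy_b, csize = 10L,
                                repetitions = 100L, seed = 1L) {
  active_ids <- dataset$mol_id[dataset$label == "active"]
  act_idx <- match(active_ids, dataset$mol_id)
  if (anyNA(dataset$ic50[act_idx]))
    stop("delta-rank analysis needs an IC50 for every active")
  cfg_a <- experiment_config(policy_a, csize, repetitions, seed)
  cfg_b <- experiment_config(policy_b, csize, repetitions, seed)
  with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, repetitions)
    ranks_a <- ranks_b <- matrix(NA_real_, length(active_ids), repetitions,
                                 dimnames = list(active_ids, NULL))
    for (r in seq_len(repetitions)) {
      set.seed(rep_seeds[r])
      q_ids <- draw_queries(cfg_a, active_ids, r)
      candidates <- setdiff(dataset$mol_id, q_ids)
      for (side in c("a", "b")) {
        cfg <- if (side == "a") cfg_a else cfg_b
        cons <- build_rep_consensus(dataset, cfg, q_ids)
        ranked <- rank_database(cons, dataset, subset = candidates)
        pos <- match(active_ids, ranked$mol_id)
        if (side == "a") ranks_a[, r] <- ranked$rank[pos]
        else ranks_b[, r] <- ranked$rank[pos]
      }
    }
    med_a <- apply(ranks_a, 1L, stats::median, na.rm = TRUE)
    med_b <- apply(ranks_b, 1L, stats::median, na.rm = TRUE)
    out <- data.frame(mol_id = active_ids,
                      ic50 = dataset$ic50[act_idx],
                      delta_rank = med_a - med_b,
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$delta_rank), , drop = FALSE]
    out[order(-out$ic50), , drop = FALSE]
  })
}
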
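# Synthetic labeled fingerprint datasets with controllable signal, so every
# policy, metric and experiment protocol is testable without external
# downloads or a chemistry toolkit.

#' Synthetic dataset configuration
#'
#' The generator emulates a decoy-free screening target: a few active
#' "chemotypes" (mode template fingerprints) plus experimentally tested
#' inactives drawn from a background bit distribution at matched density.
#' Each active copies a uniformly chosen template bit-by-bit with
#' probability `mode_fidelity`, and draws the bit from the background
#' (Bernoulli `density`) otherwise; `mode_fidelity = 1` makes every active
#' identical to its template, `mode_fidelity = 0` makes actives and
#' inactives exactly exchangeable (the signal-free null). Because templates
#' are themselves drawn at `density`, expected bit counts match
#' `density * space_length` at every fidelity.
#'
#' @param n_actives,n_inactives molecule counts.
#' @param space_length folded key-space length (166 emulates a MACCS-like
#'   space, 2048 an ECFP4-like one).
#' @param n_modes number of active chemotypes (template fingerprints).
#' @param density expected fraction of set bits, in (0, 1).
#' @param mode_fidelity probability an active copies its template's bit
#'   rather than drawing from background, in \[0, 1\].
#' @param potency_range_logs IC50 spread of the actives in orders of
#'   magnitude (log-uniform; activity values of real targets span several
#'   orders of magnitude).
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_actives = 50L, n_inactives = 1950L,
                         space_length = 2048L, n_modes = 3L,
                         density = 0.025, mode_fidelity = 0.8,
                         potency_range_logs = 3, seed = 1L) {
  stopifnot(n_actives > 0L, n_inactives > 0L, space_length > 0L,
            n_modes >= 1L, mode_fidelity >= 0, mode_fidelity <= 1,
            potency_range_logs >= 0)
  if (density <= 0 || density >= 1)
    stop("density must lie strictly inside (0, 1)")
  structure(list(n_actives = as.integer(n_actives),
                 n_inactives = as.integer(n_inactives),
                 space_length = as.integer(space_length),
                 n_modes = as.integer(n_modes), density = density,
                 mode_fidelity = mode_fidelity,
                 potency_range_logs = potency_range_logs,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic screening target
#'
#' See [synth_config()] for the generative model. Actives receive
#' log-uniform IC50s spanning `potency_range_logs` orders of magnitude
#' (arbitrary but consistent unit); inactives carry no IC50. Fully
#' deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return An `fp_dataset` with `n_actives + n_inactives` molecules in the
#'   folded space `synth<space_length>`.
#' @export
generate_target <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  L <- config$space_length
  space <- paste0("synth", L)
  with_seed(config$seed, {
    # Templates are exact-size random subsets (round(density*L) bits): with
    # Bernoulli templates, template-count luck would give actives a
    # systematic set-bit-count offset against the inactives, leaking a rank
    # signal through saturated (e.g. optimist) consensus fingerprints that
    # real matched-density benchmarks do not carry.
    n_bits <- max(1L, round(config$density * L))
    templates <- matrix(FALSE, config$n_modes, L)
    for (m in seq_len(config$n_modes))
      templates[m, sample.int(L, n_bits)] <- TRUE
    draw_active <- function() {
      mode <- sample.int(config$n_modes, 1L)
      copy <- stats::runif(L) < config$mode_fidelity
      bits <- ifelse(copy, templates[mode, ],
                     stats::runif(L) < config$density)
      which(bits) - 1L
    }
    fps <- c(
      lapply(seq_len(config$n_actives), function(i)
        bit_fp(draw_active(), space)),
      lapply(seq_len(config$n_inactives), function(i)
        bit_fp(which(stats::runif(L) < config$density) - 1L, space))
    )
    names(fps) <- c(sprintf("act%03d", seq_len(config$n_actives)),
                    sprintf("inact%05d", seq_len(config$n_inactives)))
    labels <- rep(c("active", "inactive"),
                  c(config$n_actives, config$n_inactives))
    ic50 <- c(10^stats::runif(config$n_actives, 0,
                              config$potency_range_logs),
              rep(NA_real_, config$n_inactives))
    fp_dataset(fps, labels, ic50,
               target_id = sprintf("synthetic_L%d_m%d_seed%d", L,
                                   config$n_modes, config$seed))
  })
}

#' Built-in SMILES fixture set
#'
#' A hard-coded list of 20 small drug-like (and deliberately tiny) molecules
#' with hand-assigned activity labels and IC50s, used to exercise real
#' fingerprint computation end-to-end. It contains ethanol, benzene and
#' propane (the worked examples for the unfolded MOLPRINT2D keys) and eight
#' actives with distinct IC50s, enabling the knowledgeable policy. The
#' labels are synthetic bookkeeping for tests, not experimental data.
#'
#' @return Data frame of molecule records (`mol_id`, `smiles`, `label`,
#'   `ic50`).
#' @export
fixture_smiles <- function() {
  rec <- function(id, smi, label, ic50 = NA_real_)
    data.frame(mol_id = id, smiles = smi, label = label, ic50 = ic50,
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    rec("ethanol",      "CCO",                          "inactive"),
    rec("benzene",      "c1ccccc1",                     "inactive"),
    rec("propane",      "CCC",                          "inactive"),
    rec("aspirin",      "CC(=O)Oc1ccccc1C(=O)O",        "active", 120),
    rec("salicylate",   "OC(=O)c1ccccc1O",              "active", 45),
    rec("paracetamol",  "CC(=O)Nc1ccc(O)cc1",           "active", 8.2),
    rec("ibuprofen",    "CC(C)Cc1ccc(cc1)C(C)C(=O)O",   "active", 3.5),
    rec("naproxen",     "COc1ccc2cc(ccc2c1)C(C)C(=O)O", "active", 1.1),
    rec("caffeine",     "Cn1cnc2c1c(=O)n(C)c(=O)n2C",   "active", 950),
    rec("benzamide",    "NC(=O)c1ccccc1",               "active", 300),
    rec("toluate",      "Cc1ccccc1C(=O)O",              "active", 75),
    rec("phenol",       "Oc1ccccc1",                    "inactive"),
    rec("aniline",      "Nc1ccccc1",                    "inactive"),
    rec("pyridine",     "c1ccncc1",                     "inactive"),
    rec("cyclohexane",  "C1CCCCC1",                     "inactive"),
    rec("acetone",      "CC(C)=O",                      "inactive"),
    rec("acetic_acid",  "CC(=O)O",                      "inactive"),
    rec("thiophene",    "c1ccsc1",                      "inactive"),
    rec("furan",        "c1ccoc1",                      "inactive"),
    rec("glycerol",     "OCC(O)CO",                     "inactive")
  ))
}
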
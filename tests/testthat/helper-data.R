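# Shared fixtures: random fingerprints, random ranked lists, and the
# brute-force metric oracles used to validate the fast implementations.

# Random bit_fp in a folded space.
rand_fp <- function(space = "synth64", k = NULL) {
  L <- fp_space_length(space)
  if (is.null(k)) k <- sample.int(L %/% 2, 1L)
  bit_fp(sample.int(L, k) - 1L, space)
}

# Random labeled score table for metric tests.
rand_ranked <- function(n = 50L, tie_prob = 0.3) {
  scores <- round(stats::runif(n), digits = sample(1:3, 1L))
  if (stats::runif(1) < tie_prob) scores <- round(scores, 1L)
  labels <- sample(c("active", "inactive"), n, replace = TRUE)
  # guarantee both classes
  labels[1L] <- "active"; labels[2L] <- "inactive"
  o <- order(-scores)
  data.frame(rank = seq_len(n), mol_id = paste0("m", o),
             score = scores[o], label = labels[o],
             stringsAsFactors = FALSE)
}

# All-pairs concordance oracle for the ROC AUC (ties count one half).
auc_bruteforce <- function(ranked) {
  sa <- ranked$score[ranked$label == "active"]
  si <- ranked$score[ranked$label == "inactive"]
  d <- outer(sa, si, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(sa) * length(si))
}

# Brute-force sup-difference of two empirical CDFs.
ks_bruteforce <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

# Tiny synthetic dataset for screening tests.
toy_dataset <- function(n_act = 8L, n_inact = 40L, L = 64L, seed = 7L) {
  generate_target(synth_config(n_actives = n_act, n_inactives = n_inact,
                               space_length = L, n_modes = 2L,
                               density = 0.15, mode_fidelity = 0.8,
                               seed = seed))
}
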
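#' Summary of the nine PubChem HTS benchmark targets
#'
#' Per-target molecule counts of the validated high-throughput-screening
#' benchmark compilation (PubChem summary assay ids with confirmed actives
#' and inactives; no decoys). Shipped as plain TSV under `extdata`; the
#' largest target (SAID 485290, 281 actives + 341,084 inactives = 341,365
#' molecules) is the one used for throughput experiments.
#'
#' @return Data frame with columns `target_class`, `said`, `n_actives`,
#'   `n_inactives`.
#' @export
hts_dataset_summary <- function() {
  path <- system.file("extdata", "pubchem_hts_summary.tsv",
                      package = "consensr", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
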
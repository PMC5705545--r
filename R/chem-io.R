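# File formats: .smi molecule lists, activity tables, ranked screen output.

#' Read a SMILES file
#'
#' One molecule per line, `SMILES<whitespace>id`; the id is optional
#' (`mol<line#>` is generated when absent) and lines starting with `#` are
#' ignored. Unparseable SMILES are skipped with a message giving the line
#' number; a running count of skips is reported at the end.
#'
#' @param path path to a .smi file.
#' @param validate check each SMILES with the chemistry toolkit and skip the
#'   ones that do not parse (default `TRUE`).
#' @return Data frame of molecule records: `mol_id`, `smiles`,
#'   `label` (all `"unknown"`), `ic50` (all `NA`).
#' @export
read_smiles_file <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (!length(lines))
    return(data.frame(mol_id = character(0), smiles = character(0),
                      label = character(0), ic50 = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\\s+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L]
    else paste0("mol", lineno[i])
  }, character(1))
  if (validate) {
    ok <- vapply(smiles, smiles_parses, logical(1), USE.NAMES = FALSE)
    if (any(!ok)) {
      for (i in which(!ok))
        message("skipping unparseable SMILES at line ", lineno[i],
                ": ", smiles[i])
      message(sum(!ok), " line(s) skipped, ", sum(ok), " molecule(s) read")
    }
    smiles <- smiles[ok]; ids <- ids[ok]
  }
  if (anyDuplicated(ids)) stop("duplicate mol_id in SMILES file")
  data.frame(mol_id = ids, smiles = smiles, label = "unknown",
             ic50 = NA_real_, stringsAsFactors = FALSE)
}

smiles_parses <- function(s) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(s, "\tx\n"))),
    error = function(e) "")
  nzchar(trimws(out))
}

#' Merge an activity table onto a molecule set
#'
#' Tab-separated columns `mol_id`, `label`, optional `ic50`. Label tokens
#' `active`/`1` and `inactive`/`0` are accepted. IC50 values are taken as-is
#' in whatever single concentration unit the dataset uses; only ratios of
#' IC50s ever enter the potency weights, so no unit conversion is needed (or
#' attempted).
#'
#' @param path activity TSV (no header, or a header line starting with
#'   `mol_id`).
#' @param dataset data frame of molecule records (from [read_smiles_file()]
#'   or built directly).
#' @return The dataset with `label` and `ic50` filled in for matching
#'   `mol_id`s. Table rows whose id is absent from the dataset produce a
#'   warning; duplicate ids or non-positive IC50s are errors.
#' @export
read_activity_table <- function(path, dataset) {
  if (!file.exists(path)) stop("cannot read activity table: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           col.names = c("mol_id", "label", "ic50"),
                           colClasses = c("character", "character",
                                          "character"))
  if (nrow(tab) && tab$mol_id[1L] == "mol_id") tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab$mol_id))
    stop("duplicate mol_id rows in activity table")
  lab <- ifelse(tab$label %in% c("active", "1"), "active",
         ifelse(tab$label %in% c("inactive", "0"), "inactive", NA))
  if (anyNA(lab)) stop("unrecognized label token in activity table")
  ic50 <- suppressWarnings(as.numeric(tab$ic50))
  bad <- !is.na(ic50) & ic50 <= 0
  if (any(bad)) stop("non-positive IC50 for: ",
                     paste(tab$mol_id[bad], collapse = ", "))
  hit <- match(tab$mol_id, dataset$mol_id)
  if (anyNA(hit))
    warning("activity rows for unknown molecules: ",
            paste(tab$mol_id[is.na(hit)], collapse = ", "))
  ok <- !is.na(hit)
  dataset$label[hit[ok]] <- lab[ok]
  dataset$ic50[hit[ok]] <- ic50[ok]
  dataset
}

#' Write a ranked screening result
#'
#' TSV with header `rank`, `mol_id`, `score`, `label`; scores printed with 6
#' decimal places.
#'
#' @param ranked a ranked list (data frame with `mol_id`, `score`, `label`,
#'   as produced by [rank_database()]).
#' @param path output file.
#' @export
write_ranked_output <- function(ranked, path) {
  stopifnot(is.data.frame(ranked))
  if (!nrow(ranked)) stop("refusing to write an empty ranked list")
  out <- data.frame(rank = seq_len(nrow(ranked)),
                    mol_id = ranked$mol_id,
                    score = sprintf("%.6f", ranked$score),
                    label = ranked$label)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ranked output to: ", path)
  invisible(NULL)
}

#' Read a ranked screening result back
#'
#' @param path file written by [write_ranked_output()].
#' @return Data frame `rank`, `mol_id`, `score`, `label`.
#' @export
read_ranked_output <- function(path) {
  if (!file.exists(path)) stop("cannot read ranked output: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "numeric",
                                   "character"))
}
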
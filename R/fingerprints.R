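# Fingerprint adapters and the unfolded MOLPRINT2D implementation.
#
# MACCS and ECFP4 are adapters over Open Babel (via ChemmineOB): MACCS is the
# toolkit's 166-key set, ECFP4 the circular radius-2 fingerprint folded to
# 2048 positions. UMOP2D is computed here from the molecular graph: one
# canonical atom-environment key per heavy atom, built on SYBYL atom types
# and the type composition of the 1- and 2-bond shells, kept unfolded (sparse
# string keys, no hashing).

record_smiles <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  stopifnot(!is.null(record$smiles), !is.null(record$mol_id))
  record
}

ob_fingerprint_matrix <- function(smiles, ids, name) {
  src <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  m <- ChemmineOB::fingerprint_OB(mols, name)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (nrow(m) != length(smiles))
    stop("fingerprint computation returned ", nrow(m), " rows for ",
         length(smiles), " molecules")
  rownames(m) <- ids
  m
}

#' MACCS 166-key fingerprint
#'
#' Adapter over Open Babel's MACCS implementation. Set keys are 0-based
#' positions in `[0, 166)`; the function errors if the backend ever reports
#' a position outside that range.
#'
#' @param record a molecule record (one-row data frame or list with at least
#'   `mol_id` and `smiles`).
#' @return A `bit_fp` in space `maccs166`.
#' @export
maccs_fingerprint <- function(record) {
  record <- record_smiles(record)
  fingerprint_molecules(data.frame(mol_id = record$mol_id,
                                   smiles = record$smiles),
                        "maccs166")[[1L]]
}

#' ECFP4 2048-bit fingerprint
#'
#' Circular fingerprint of radius 2 (ECFP4 family) computed by Open Babel
#' and folded modulo 2048 to the conventional 2048 positions.
#'
#' @inheritParams maccs_fingerprint
#' @return A `bit_fp` in space `ecfp4_2048`.
#' @export
ecfp4_fingerprint <- function(record) {
  record <- record_smiles(record)
  fingerprint_molecules(data.frame(mol_id = record$mol_id,
                                   smiles = record$smiles),
                        "ecfp4_2048")[[1L]]
}

#' Unfolded MOLPRINT2D fingerprint
#'
#' One feature key per heavy atom: the canonical string
#' `"T0|d1:c1xt1+c2xt2+...|d2:..."` where `T0` is the central atom's SYBYL
#' type and each shell lists `count x type` pairs for the heavy atoms at bond
#' distance 1 and 2 (shortest path over heavy atoms), types sorted
#' lexicographically within a shell. The fingerprint is the set of distinct
#' keys; per-molecule multiplicity is dropped, so the key count never exceeds
#' the heavy-atom count.
#'
#' @inheritParams maccs_fingerprint
#' @return A `bit_fp` in space `umop2d_unfolded`.
#' @examples
#' \donttest{
#' umop2d_fingerprint(list(mol_id = "ethane", smiles = "CC"))
#' # single key "C.3|d1:1xC.3|d2:"
#' }
#' @export
umop2d_fingerprint <- function(record) {
  record <- record_smiles(record)
  g <- molecule_graphs(record$smiles, record$mol_id)[[1L]]
  bit_fp(umop2d_keys(g), "umop2d_unfolded")
}

# Environment keys of one molecule graph.
umop2d_keys <- function(graph) {
  n <- length(graph$elements)
  if (n == 0L) stop("molecule with no heavy atom")
  types <- sybyl_types(graph)
  adj <- vector("list", n)
  for (r in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[r]; b <- graph$bonds$b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  shell_str <- function(idx) {
    if (!length(idx)) return("")
    tab <- table(types[idx])
    paste(paste0(as.integer(tab), "x", names(tab)), collapse = "+")
  }
  keys <- vapply(seq_len(n), function(i) {
    d1 <- unique(adj[[i]])
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    paste0(types[i], "|d1:", shell_str(d1), "|d2:", shell_str(d2))
  }, character(1))
  unique(keys)
}

#' Fingerprint a set of molecules
#'
#' Batch interface over the three fingerprint types. Molecules whose
#' fingerprint cannot be computed are skipped with a warning naming the
#' molecule, as in routine screening practice; an error is raised only when
#' no molecule survives.
#'
#' @param records data frame with columns `mol_id` and `smiles`.
#' @param space `"maccs166"`, `"ecfp4_2048"` or `"umop2d_unfolded"`.
#' @return Named list of `bit_fp`, one per successfully fingerprinted
#'   molecule, in input order.
#' @export
fingerprint_molecules <- function(records, space) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("mol_id", "smiles") %in% names(records)))
  ids <- as.character(records$mol_id)
  smiles <- as.character(records$smiles)
  if (space == "umop2d_unfolded") {
    graphs <- molecule_graphs(smiles, ids)
    fps <- lapply(graphs, function(g) {
      tryCatch(bit_fp(umop2d_keys(g), space), error = function(e) NULL)
    })
  } else {
    name <- switch(space, maccs166 = "MACCS", ecfp4_2048 = "ECFP4",
                   stop("unknown fingerprint space: ", space))
    m <- ob_fingerprint_matrix(smiles, ids, name)
    fps <- lapply(seq_len(nrow(m)), function(i) {
      bits <- which(m[i, ] == 1) - 1L
      if (space == "ecfp4_2048") bits <- unique(bits %% 2048L)
      if (space == "maccs166" && length(bits) && max(bits) >= 166L)
        stop("MACCS backend set a key >= 166 for molecule ", ids[i])
      bit_fp(bits, space)
    })
    names(fps) <- ids
  }
  failed <- vapply(fps, is.null, logical(1))
  if (any(failed))
    warning("fingerprint skipped for: ", paste(ids[failed], collapse = ", "))
  fps <- fps[!failed]
  if (!length(fps)) stop("no molecule could be fingerprinted")
  fps
}

#' Write a fingerprint cache file
#'
#' Plain TSV `mol_id<TAB>space<TAB>comma-separated keys`, so screening runs
#' can reuse fingerprints without a chemistry toolkit present.
#'
#' @param fps named list of `bit_fp` sharing one space.
#' @param path output file.
#' @export
write_fp_cache <- function(fps, path) {
  stopifnot(length(fps) > 0L, !is.null(names(fps)))
  lines <- vapply(names(fps), function(id) {
    fp <- fps[[id]]
    paste(id, fp$space, paste(fp$keys, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a fingerprint cache file
#'
#' @param path file written by [write_fp_cache()].
#' @return Named list of `bit_fp`.
#' @export
read_fp_cache <- function(path) {
  if (!file.exists(path)) stop("cannot read fingerprint cache: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  fps <- lapply(parts, function(p) {
    keys <- if (length(p) < 3L || !nzchar(p[3L])) character(0)
            else strsplit(p[3L], ",", fixed = TRUE)[[1L]]
    bit_fp(keys, p[2L])
  })
  names(fps) <- vapply(parts, `[[`, character(1), 1L)
  fps
}
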
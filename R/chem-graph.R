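# Molecule graphs and SYBYL atom typing.
#
# Structures come in as SMILES, are converted by Open Babel to MOL2 (heavy
# atoms only; Open Babel does not add hydrogens on this route), and the MOL2
# atom/bond blocks are parsed into a light graph object. SYBYL typing is then
# an explicit rules table over element, aromatic-ring membership and incident
# bond orders -- not a pass-through of the toolkit's type column -- so the
# unfolded MOLPRINT2D keys are reproducible and auditable. The toolkit's own
# MOL2 types remain available in `$ob_types` for cross-checking.

#' Parse molecules into heavy-atom graphs
#'
#' @param smiles character vector of SMILES.
#' @param ids optional molecule ids (defaults to `mol1..moln`).
#' @return A list of `mol_graph` objects, each with `elements` (character),
#'   `bonds` (data.frame `a`, `b`, `type` with MOL2 bond types
#'   `1`,`2`,`3`,`am`,`ar`), `aromatic` (logical per atom: member of an
#'   aromatic ring), and `ob_types` (the toolkit's own SYBYL column, kept for
#'   cross-checks only).
#' @export
molecule_graphs <- function(smiles, ids = NULL) {
  stopifnot(length(smiles) > 0L)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  txt <- ChemmineOB::convertFormat("SMI", "MOL2", paste0(src, "\n"))
  graphs <- parse_mol2(txt)
  if (length(graphs) != length(smiles))
    stop("MOL2 conversion returned ", length(graphs), " molecules for ",
         length(smiles), " SMILES (unparseable input?)")
  names(graphs) <- ids
  graphs
}

# Split concatenated MOL2 text into mol_graph objects.
parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) return(list())
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    parse_mol2_block(block)
  })
}

mol2_section <- function(block, tag) {
  at <- grep(paste0("^@<TRIPOS>", tag, "$"), block)
  if (!length(at)) return(character(0))
  from <- at[1L] + 1L
  if (from > length(block)) return(character(0))
  rest <- block[from:length(block)]
  nxt <- grep("^@<TRIPOS>", rest)
  to <- if (length(nxt)) nxt[1L] - 1L else length(rest)
  if (to < 1L) return(character(0))
  out <- trimws(rest[seq_len(to)])
  out[nzchar(out)]
}

parse_mol2_block <- function(block) {
  atom_lines <- mol2_section(block, "ATOM")
  bond_lines <- mol2_section(block, "BOND")
  atoms <- strsplit(atom_lines, "\\s+")
  ob_types <- vapply(atoms, `[[`, character(1), 6L)
  elements <- sub("\\..*$", "", ob_types)
  if (length(bond_lines)) {
    bf <- strsplit(bond_lines, "\\s+")
    bonds <- data.frame(
      a = vapply(bf, function(v) as.integer(v[2L]), integer(1)),
      b = vapply(bf, function(v) as.integer(v[3L]), integer(1)),
      type = vapply(bf, `[[`, character(1), 4L),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0),
                        type = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    elements = elements,
    bonds = bonds,
    aromatic = aromatic_ring_atoms(length(elements), bonds),
    ob_types = ob_types
  ), class = "mol_graph")
}

# An atom is aromatic iff it lies on a cycle of 'ar' bonds: iteratively prune
# degree<=1 vertices of the ar-bond subgraph (its 2-core). This keeps ring
# atoms of benzene/pyridine aromatic while the delocalised-but-acyclic 'ar'
# bonds Open Babel writes for e.g. carboxylates do not mark their atoms.
aromatic_ring_atoms <- function(n_atoms, bonds) {
  ar <- bonds[bonds$type == "ar", , drop = FALSE]
  alive <- rep(TRUE, n_atoms)
  keep <- rep(TRUE, nrow(ar))
  repeat {
    deg <- tabulate(c(ar$a[keep], ar$b[keep]), nbins = n_atoms)
    prune <- alive & deg <= 1L
    if (!any(prune)) break
    alive[prune] <- FALSE
    keep <- keep & !(prune[ar$a] | prune[ar$b])
  }
  deg <- tabulate(c(ar$a[keep], ar$b[keep]), nbins = n_atoms)
  deg >= 2L
}

#' SYBYL atom type of a heavy atom
#'
#' Rules-table implementation of SYBYL-style typing (element plus
#' hybridization state): aromatic ring atoms give `C.ar`/`N.ar` (`O.2`/`S.2`
#' for ring oxygen and sulfur, which SYBYL does not give an `.ar` type);
#' triple bonds or cumulated doubles give `.1`; a double or delocalised
#' (`ar`/`am`) bond gives `.2`; otherwise `.3`. Amide nitrogen is `N.am`,
#' carboxylate-style oxygen `O.co2`, sulfoxide/sulfone sulfur `S.o`/`S.o2`,
#' phosphorus `P.3`, and halogens type as their bare element symbol. Formal
#' charges are not modelled, so `N.4`/`C.cat` are not distinguished from
#' their neutral types.
#'
#' @param graph a `mol_graph` from [molecule_graphs()].
#' @param i atom index (1-based, heavy atoms only).
#' @return Type string such as `"C.3"`, `"C.ar"`, `"O.2"`.
#' @export
sybyl_atom_type <- function(graph, i) {
  stopifnot(inherits(graph, "mol_graph"))
  el <- graph$elements[i]
  if (el == "H") stop("hydrogen atom: SYBYL typing covers heavy atoms only")
  b <- graph$bonds
  inc <- b[b$a == i | b$b == i, , drop = FALSE]
  nbr <- ifelse(inc$a == i, inc$b, inc$a)
  n_triple <- sum(inc$type == "3")
  n_double <- sum(inc$type == "2")
  n_ar <- sum(inc$type == "ar")
  n_am <- sum(inc$type == "am")
  arom <- graph$aromatic[i]
  dbl_o_nbrs <- function(j) {
    jb <- b[(b$a == j | b$b == j) & b$type %in% c("2", "ar"), , drop = FALSE]
    jn <- ifelse(jb$a == j, jb$b, jb$a)
    sum(graph$elements[jn] == "O" & jn != i)
  }
  switch(el,
    C = {
      if (arom) "C.ar"
      else if (n_triple >= 1L || n_double >= 2L) "C.1"
      else if (n_double >= 1L || n_ar >= 1L || n_am >= 1L) "C.2"
      else "C.3"
    },
    N = {
      if (arom) "N.ar"
      else if (n_triple >= 1L) "N.1"
      else if (n_am >= 1L) "N.am"
      else if (n_double >= 1L || n_ar >= 1L) "N.2"
      else "N.3"
    },
    O = {
      if (n_double >= 1L) "O.2"
      else if (arom) "O.2"
      else if (length(nbr) == 1L && n_ar == 0L &&
               any(graph$elements[nbr] %in% c("C", "N") &
                   vapply(nbr, dbl_o_nbrs, numeric(1)) >= 1)) "O.co2"
      else if (n_ar >= 1L) "O.co2"
      else "O.3"
    },
    S = {
      sb <- inc[inc$type == "2", , drop = FALSE]
      sn <- ifelse(sb$a == i, sb$b, sb$a)
      n_oxo <- sum(graph$elements[sn] == "O")
      if (n_oxo >= 2L) "S.o2"
      else if (n_oxo == 1L) "S.o"
      else if (arom || n_double >= 1L) "S.2"
      else "S.3"
    },
    P = "P.3",
    el
  )
}

#' SYBYL types of all heavy atoms of a molecule
#'
#' @param graph a `mol_graph`.
#' @return Character vector of SYBYL types, one per heavy atom.
#' @export
sybyl_types <- function(graph) {
  vapply(seq_along(graph$elements), function(i) sybyl_atom_type(graph, i),
         character(1))
}
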
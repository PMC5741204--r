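#' Tag a structure string with its dialect
#'
#' A `raw_structure` is the unit of structure input everywhere in the package:
#' the text of an InChI or SMILES string together with an explicit dialect tag.
#' The dialect is never guessed from ambiguous content; strings starting with
#' `"InChI="` may be tagged automatically, anything else must be declared.
#'
#' @param text non-empty structure string.
#' @param dialect `"InChI"`, `"SMILES"`, or `NA` to auto-tag only the
#'   unambiguous `InChI=` prefix (anything else errors).
#' @return An object of class `raw_structure`.
#' @examples
#' raw_structure("CCO", "SMILES")
#' raw_structure("InChI=1S/H2O/h1H2")
#' @export
raw_structure <- function(text, dialect = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("structure text must be non-empty", call. = FALSE)
  if (is.na(dialect)) {
    if (startsWith(text, "InChI=")) {
      dialect <- "InChI"
    } else {
      stop("dialect must be given explicitly for non-InChI input: ",
           substr(text, 1, 40), call. = FALSE)
    }
  }
  dialect <- match.arg(dialect, c("InChI", "SMILES"))
  structure(list(text = text, dialect = dialect), class = "raw_structure")
}

.as_raw_structure <- function(x, dialect = NA_character_) {
  if (inherits(x, "raw_structure")) return(x)
  raw_structure(x, dialect)
}

.mol_graph_from_py <- function(res, provenance, normalized) {
  if (!isTRUE(res$ok)) {
    stop("structure parse error [", provenance$dialect, " '",
         provenance$text, "']: ", res$error, call. = FALSE)
  }
  atoms <- data.frame(
    element  = vapply(res$atoms, `[[`, character(1), "element"),
    aromatic = vapply(res$atoms, `[[`, logical(1), "aromatic"),
    charge   = vapply(res$atoms, function(a) as.integer(a$charge), integer(1)),
    stereo   = vapply(res$atoms, `[[`, character(1), "stereo"),
    stringsAsFactors = FALSE
  )
  if (length(res$bonds)) {
    bonds <- data.frame(
      from  = vapply(res$bonds, function(b) as.integer(b$from), integer(1)),
      to    = vapply(res$bonds, function(b) as.integer(b$to), integer(1)),
      order = vapply(res$bonds, function(b) as.character(b$order),
                     character(1)),
      stringsAsFactors = FALSE
    )
    swap <- bonds$from > bonds$to
    tmp <- bonds$from[swap]
    bonds$from[swap] <- bonds$to[swap]
    bonds$to[swap] <- tmp
    bonds <- bonds[order(bonds$from, bonds$to), , drop = FALSE]
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(from = integer(), to = integer(),
                        order = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(atoms = atoms, bonds = bonds, provenance = provenance,
         normalized = normalized),
    class = "mol_graph"
  )
}

#' Parse a structure string into a heavy-atom molecular graph
#'
#' Delegates InChI/SMILES decoding to RDKit through the bundled Python helper
#' and returns the bonded graph of heavy atoms (explicit hydrogens as given by
#' the toolkit's standard parse, i.e. already implicit for SMILES/InChI input).
#' The returned graph is *not* normalized; see [normalize_mol()].
#'
#' @param raw a [raw_structure()], or a bare string (dialect auto-tagged only
#'   for `InChI=`-prefixed text).
#' @param dialect used when `raw` is a bare string.
#' @return A `mol_graph`: list with `atoms` (element, aromatic, charge, stereo),
#'   `bonds` (from, to, order in `"1"/"2"/"3"/"a"`, undirected, `from < to`),
#'   `provenance`, `normalized`.
#' @examples
#' \dontrun{
#' mol <- parse_structure("CCO", dialect = "SMILES")
#' n_heavy_atoms(mol)
#' }
#' @export
parse_structure <- function(raw, dialect = NA_character_) {
  raw <- .as_raw_structure(raw, dialect)
  res <- .py_parse_batch(raw$text, raw$dialect, normalize = FALSE)[[1]]
  .mol_graph_from_py(res, raw, normalized = FALSE)
}

#' Normalize a molecular graph for signature encoding
#'
#' Applies the canonical normalization used throughout the knowledge base:
#' compounds are reduced to their largest covalent fragment, formal charges are
#' neutralized (implicit hydrogen counts re-derived), aromaticity is perceived
#' so Kekule rings are rewritten in aromatic form, explicit hydrogens are
#' stripped, and stereo descriptors are retained on the structure. The
#' operation is idempotent.
#'
#' @param mol a `mol_graph` (or a `raw_structure`/string, parsed first).
#' @param dialect used when `mol` is a bare string.
#' @return A normalized `mol_graph` (all charges zero, no explicit H).
#' @export
normalize_mol <- function(mol, dialect = NA_character_) {
  if (inherits(mol, "mol_graph")) {
    if (isTRUE(mol$normalized)) return(mol)
    raw <- mol$provenance
  } else {
    raw <- .as_raw_structure(mol, dialect)
  }
  res <- .py_parse_batch(raw$text, raw$dialect, normalize = TRUE)[[1]]
  .mol_graph_from_py(res, raw, normalized = TRUE)
}

#' Number of heavy atoms in a molecular graph
#' @param mol a `mol_graph`.
#' @return integer atom count.
#' @export
n_heavy_atoms <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  nrow(mol$atoms)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds", if (isTRUE(x$normalized)) " (normalized)", "\n", sep = "")
  cat("  formula: ", paste0(names(table(x$atoms$element)),
                            table(x$atoms$element), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# Atom label used for graph identity and signatures: element plus aromatic
# flag (lowercase marks aromatic, SMILES-style). Charges are gone after
# normalization; stereo is deliberately excluded (constitution-based encoding).
.atom_labels <- function(mol) {
  ifelse(mol$atoms$aromatic, tolower(mol$atoms$element), mol$atoms$element)
}

# Internal: igraph with one dummy vertex per bond so that bond orders become
# vertex colors (igraph canonization/isomorphism are vertex-colored only).
.colored_igraph <- function(mol, root = NA_integer_) {
  n <- nrow(mol$atoms)
  labels <- .atom_labels(mol)
  atom_color <- match(labels, sort(unique(labels)))
  if (!is.na(root)) atom_color <- atom_color + 1L  # reserve color 1 for root
  nb <- nrow(mol$bonds)
  edges <- integer(0)
  bond_color <- integer(0)
  if (nb) {
    dummy <- n + seq_len(nb)
    edges <- as.vector(rbind(mol$bonds$from, dummy, dummy, mol$bonds$to))
    bond_color <- max(atom_color) + 1L +
      match(mol$bonds$order, c("1", "2", "3", "a"))
  }
  colors <- c(atom_color, bond_color)
  if (!is.na(root)) colors[root] <- 1L
  g <- igraph::make_empty_graph(n + nb, directed = FALSE)
  if (nb) g <- igraph::add_edges(g, edges)
  list(graph = g, colors = colors, n_atoms = n)
}

#' Canonical structure key of a normalized molecule
#'
#' Deterministic string identical for isomorphic normalized graphs and
#' different for non-isomorphic ones; used to deduplicate compounds and to
#' decide detectable-compound membership by structure rather than by id.
#' Stereochemistry does not enter the key (two stereoisomers collide), matching
#' the constitution-based fragment encoding.
#'
#' @param mol a normalized `mol_graph`.
#' @return character scalar.
#' @export
canonical_key <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  if (!isTRUE(mol$normalized)) {
    stop("canonical_key requires a normalized mol_graph", call. = FALSE)
  }
  cg <- .colored_igraph(mol)
  perm <- igraph::canonical_permutation(cg$graph, colors = cg$colors)$labeling
  # perm maps old vertex -> canonical position; invert for atom ordering.
  atom_pos <- perm[seq_len(cg$n_atoms)]
  ord <- order(atom_pos)                    # atoms by canonical position
  newidx <- integer(cg$n_atoms)
  newidx[ord] <- seq_len(cg$n_atoms)
  labels <- .atom_labels(mol)[ord]
  if (nrow(mol$bonds)) {
    a <- newidx[mol$bonds$from]
    b <- newidx[mol$bonds$to]
    lo <- pmin(a, b); hi <- pmax(a, b)
    eord <- order(lo, hi)
    estr <- paste0(lo[eord], "-", hi[eord], ":", mol$bonds$order[eord])
  } else {
    estr <- character(0)
  }
  paste0(paste(labels, collapse = ","), "|", paste(estr, collapse = ","))
}
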
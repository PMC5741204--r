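# Signature encoding: every compound is a multiset of canonical atomic
# environments ("atomic signatures") at an even bond diameter d; a reaction is
# the signed difference of its product and substrate multisets. The diameter
# controls how specific a reaction signature is, i.e. how much enzymatic
# promiscuity the matching step will admit (low d = coarse = promiscuous).

.mol_adj <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- rep(list(list(nbr = integer(0), bond = character(0))), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$from[k]; j <- b$to[k]; o <- b$order[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$bond <- c(adj[[i]]$bond, o)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$bond <- c(adj[[j]]$bond, o)
  }
  adj
}

.bfs_within <- function(adj, root, radius) {
  dist <- rep(NA_integer_, length(adj))
  dist[root] <- 0L
  frontier <- root
  depth <- 0L
  while (length(frontier) && depth < radius) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]$nbr) {
        if (is.na(dist[w])) {
          dist[w] <- depth
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  which(!is.na(dist))
}

# Canonical serialization of a rooted, atom- and bond-labelled graph by
# colour refinement with full branching on ties: exact (the lexicographically
# smallest serialization over all refinement-compatible orderings), fast on
# the small environments this package sees. The root is marked in its label,
# which both individualizes it and keeps the root position in the string.
.canon_rooted <- function(labels, adj, root) {
  n <- length(labels)
  labels[root] <- paste0(labels[root], "*")
  pad <- function(x) formatC(x, width = 4, flag = "0")

  refine <- function(colors) {
    repeat {
      keys <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        paste0(pad(colors[i]), "(",
               paste(sort(paste0(nb$bond, pad(colors[nb$nbr]))),
                     collapse = ","), ")")
      }, character(1))
      new <- match(keys, sort(unique(keys)))
      if (identical(new, colors)) return(colors)
      colors <- new
    }
  }

  serialize <- function(ord) {
    pos <- integer(n); pos[ord] <- seq_len(n)
    estr <- character(0)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      keep <- nb$nbr > i
      if (any(keep)) {
        a <- pos[i]; bpos <- pos[nb$nbr[keep]]
        lo <- pmin(a, bpos); hi <- pmax(a, bpos)
        estr <- c(estr, paste0(lo, "-", hi, ":", nb$bond[keep]))
      }
    }
    paste0(paste(labels[ord], collapse = ","), "|",
           paste(sort_edge_str(estr), collapse = ","))
  }

  recurse <- function(colors) {
    colors <- refine(colors)
    tab <- tabulate(colors)
    if (all(tab[colors] == 1L)) return(serialize(order(colors)))
    cell_color <- which(tab > 1L)[1]
    members <- which(colors == cell_color)
    best <- NULL
    for (m in members) {
      c2 <- colors * 2L
      c2[m] <- c2[m] - 1L
      c2 <- match(c2, sort(unique(c2)))
      s <- recurse(c2)
      if (is.null(best) || s < best) best <- s
    }
    best
  }

  init <- match(labels, sort(unique(labels)))
  recurse(init)
}

sort_edge_str <- function(estr) {
  if (!length(estr)) return(estr)
  parts <- regmatches(estr, regexec("^(\\d+)-(\\d+):(.+)$", estr))
  lo <- as.integer(vapply(parts, `[`, character(1), 2))
  hi <- as.integer(vapply(parts, `[`, character(1), 3))
  estr[order(lo, hi)]
}

.check_diameter <- function(diameter) {
  if (length(diameter) != 1L || is.na(diameter) || diameter < 0 ||
      diameter %% 2 != 0) {
    stop("signature diameter must be a single even non-negative integer, got ",
         deparse(diameter), call. = FALSE)
  }
  as.integer(diameter)
}

#' Canonical atomic signature of one atom's environment
#'
#' Extracts the subgraph induced by all atoms within `diameter/2` bonds of the
#' root atom and serializes it canonically (colour refinement with exhaustive
#' tie-branching; root marked). Environments truncated by the molecule
#' boundary are encoded as-is, so small and large molecules never collide.
#'
#' @param mol a normalized `mol_graph`.
#' @param atom_index root atom, 1-based.
#' @param diameter even non-negative bond diameter (environment radius is
#'   `diameter/2`).
#' @return An `atomic_signature`: list with `string` and `diameter`.
#' @export
atomic_signature <- function(mol, atom_index, diameter) {
  stopifnot(inherits(mol, "mol_graph"))
  diameter <- .check_diameter(diameter)
  n <- nrow(mol$atoms)
  if (atom_index < 1L || atom_index > n) {
    stop("atom_index ", atom_index, " out of range 1..", n, call. = FALSE)
  }
  adj <- .mol_adj(mol)
  structure(
    list(string = .atomic_sig_string(mol, adj, atom_index, diameter %/% 2L),
         diameter = diameter),
    class = "atomic_signature"
  )
}

.atomic_sig_string <- function(mol, adj, root, radius) {
  keep <- .bfs_within(adj, root, radius)
  labels <- .atom_labels(mol)[keep]
  remap <- integer(nrow(mol$atoms))
  remap[keep] <- seq_along(keep)
  sub_adj <- lapply(keep, function(v) {
    inside <- adj[[v]]$nbr %in% keep
    list(nbr = remap[adj[[v]]$nbr[inside]], bond = adj[[v]]$bond[inside])
  })
  .canon_rooted(labels, sub_adj, remap[root])
}

#' Molecular signature: the fragment multiset of a compound
#'
#' One atomic signature per heavy atom, aggregated into a multiset. The sum of
#' counts always equals the heavy-atom count.
#'
#' @param mol a normalized `mol_graph`.
#' @param diameter even bond diameter (default 12, radius 6).
#' @return A `mol_signature`: named integer vector (fragment string -> count),
#'   sorted by fragment, with attribute `diameter`.
#' @export
molecular_signature <- function(mol, diameter = 12L) {
  stopifnot(inherits(mol, "mol_graph"))
  if (!isTRUE(mol$normalized)) {
    stop("molecular_signature requires a normalized mol_graph", call. = FALSE)
  }
  diameter <- .check_diameter(diameter)
  adj <- .mol_adj(mol)
  radius <- diameter %/% 2L
  frags <- vapply(seq_len(nrow(mol$atoms)), function(i) {
    .atomic_sig_string(mol, adj, i, radius)
  }, character(1))
  counts <- table(frags)
  sig <- stats::setNames(as.integer(counts), names(counts))
  sig <- sig[order(names(sig))]
  structure(sig, diameter = diameter, class = "mol_signature")
}

.sig_diameter <- function(sig) attr(sig, "diameter")

# Signed named-vector sum over fragment multisets; zero entries dropped.
.frag_sum <- function(...) {
  vecs <- list(...)
  vecs <- Filter(function(v) length(v) > 0, vecs)
  if (!length(vecs)) return(stats::setNames(integer(0), character(0)))
  all_names <- sort(unique(unlist(lapply(vecs, names))))
  out <- stats::setNames(integer(length(all_names)), all_names)
  for (v in vecs) out[names(v)] <- out[names(v)] + as.integer(v)
  out[out != 0L]
}

#' Reaction signature: products minus substrates
#'
#' The signed fragment multiset obtained by subtracting the summed molecular
#' signatures of the substrates from those of the products. Its negative part
#' is what a query compound (plus co-substrates) must embed to match the
#' reaction; adding the signature to a matching substrate set yields the
#' product fragments.
#'
#' @param substrates,products lists of `mol_signature`s sharing one diameter.
#' @return A `rxn_signature`: named non-zero integer vector with attribute
#'   `diameter`.
#' @export
reaction_signature <- function(substrates, products) {
  all_sigs <- c(substrates, products)
  if (!length(all_sigs)) stop("empty reaction", call. = FALSE)
  ds <- unique(vapply(all_sigs, .sig_diameter, integer(1)))
  if (length(ds) != 1L) {
    stop("mixed signature diameters: ", paste(ds, collapse = ", "),
         call. = FALSE)
  }
  neg <- lapply(substrates, function(s) -unclass(s))
  pos <- lapply(products, unclass)
  delta <- do.call(.frag_sum, c(pos, neg))
  delta <- delta[order(names(delta))]
  structure(delta, diameter = ds, class = "rxn_signature")
}

#' Check a signature's stored diameter against an expectation
#' @param sig a `mol_signature` or `rxn_signature`.
#' @param expected integer diameter.
#' @return `TRUE` iff the stored diameter equals `expected`.
#' @export
signature_diameter_check <- function(sig, expected) {
  identical(as.integer(.sig_diameter(sig)), as.integer(expected))
}

#' @export
print.mol_signature <- function(x, ...) {
  cat("<mol_signature> diameter ", .sig_diameter(x), ", ",
      length(x), " distinct fragments, ", sum(x), " atoms\n", sep = "")
  invisible(x)
}

#' @export
print.rxn_signature <- function(x, ...) {
  cat("<rxn_signature> diameter ", .sig_diameter(x), ", ",
      sum(unclass(x) < 0), " consumed / ", sum(unclass(x) > 0),
      " created fragment kinds\n", sep = "")
  invisible(x)
}

#' Serialize a signature to the tab-separated text block used by KB caches
#' @param sig a `mol_signature` or `rxn_signature`.
#' @return character scalar, lines `fragment<TAB>count` sorted by fragment.
#' @export
signature_to_text <- function(sig) {
  v <- unclass(sig)
  v <- v[order(names(v))]
  paste(paste0(names(v), "\t", v), collapse = "\n")
}

#' Parse a signature text block
#' @param text as produced by [signature_to_text()].
#' @param diameter the diameter to stamp on the result.
#' @param kind `"mol"` or `"rxn"`.
#' @return the signature object.
#' @export
signature_from_text <- function(text, diameter, kind = c("mol", "rxn")) {
  kind <- match.arg(kind)
  diameter <- .check_diameter(diameter)
  if (!nzchar(text)) {
    v <- stats::setNames(integer(0), character(0))
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    v <- stats::setNames(
      vapply(parts, function(p) as.integer(p[2]), integer(1)),
      vapply(parts, `[`, character(1), 1)
    )
    v <- v[order(names(v))]
  }
  structure(v, diameter = diameter,
            class = if (kind == "mol") "mol_signature" else "rxn_signature")
}
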
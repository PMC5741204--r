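# Hashed circular fingerprint over this package's own atomic signatures at
# diameters {0, 2, 4} (an ECFP4 analogue: radius <= 2) and Jaccard-Tanimoto
# similarity. Bit assignment uses a stable polynomial string hash so
# fingerprints are identical across runs and platforms.

# Polynomial hash over UTF-8 bytes, modulus < 2^25 so every intermediate
# product stays exactly representable in a double.
.HASH_MOD <- 33554393

.stable_hash <- function(strings) {
  vapply(strings, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 5381
    for (b in bytes) h <- (h * 31 + b) %% .HASH_MOD
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hashed circular fingerprint of a molecule
#'
#' Distinct atomic-signature fragments at diameters 0, 2 and 4 are hashed
#' into a fixed-width bitset. Identical normalized structures always yield
#' identical fingerprints; the set-bit count is at most the number of
#' distinct fragments.
#'
#' @param mol a normalized `mol_graph`.
#' @param width bitset width (default 2048).
#' @return A `fingerprint`: sorted integer vector of set bit positions
#'   (0-based) with attribute `width`.
#' @export
fingerprint <- function(mol, width = 2048L) {
  stopifnot(inherits(mol, "mol_graph"), isTRUE(mol$normalized))
  width <- as.integer(width)
  frags <- unlist(lapply(c(0L, 2L, 4L), function(d) {
    names(molecular_signature(mol, d))
  }))
  # diameter-tag fragments so e.g. a bare-atom fragment and an identical
  # truncated environment at a larger diameter hash independently
  tags <- rep(c(0L, 2L, 4L), vapply(c(0L, 2L, 4L), function(d) {
    length(molecular_signature(mol, d))
  }, integer(1)))
  bits <- sort(unique(as.integer(.stable_hash(paste0(tags, "#", frags)) %%
                                   width)))
  structure(bits, width = width, class = "fingerprint")
}

#' Jaccard-Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`; 1 means identical bitsets ("a perfect match"), and
#' two empty fingerprints are defined as similarity 1 (degenerate case).
#'
#' @param a,b `fingerprint`s of equal width.
#' @return numeric in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(attr(a, "width"), attr(b, "width"))) {
    stop("fingerprint width mismatch: ", attr(a, "width"), " vs ",
         attr(b, "width"), call. = FALSE)
  }
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Precompute compound-vs-detectable similarities for a knowledge base
#'
#' @param kb a `knowledge_base`.
#' @return numeric matrix, rows = compound ids, columns = detectable compound
#'   ids; rebuildable bit-for-bit.
#' @export
precompute_similarity <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  cids <- names(kb$compounds)
  dids <- names(kb$detectables)
  m <- matrix(0, nrow = length(cids), ncol = length(dids),
              dimnames = list(cids, dids))
  for (ci in cids) {
    for (di in dids) {
      m[ci, di] <- tanimoto(kb$fingerprints[[ci]], kb$fingerprints[[di]])
    }
  }
  m
}

#' Write a similarity table to TSV
#' @param m matrix from [precompute_similarity()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(m, path) {
  rows <- c("compound_id\tdetectable_id\tscore")
  for (ci in rownames(m)) {
    for (di in colnames(m)) {
      rows <- c(rows, paste(ci, di, format(m[ci, di], digits = 15),
                            sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
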
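# Forward matching: a query compound matches a reaction if, together with the
# reaction's declared co-substrates, it embeds the negative (consumed) part of
# the reaction signature and itself covers at least one consumed fragment
# (i.e. participates in the reaction centre). Adding the signature to the
# substrate-side fragments yields the putative product fragments, which are
# accepted only if they resolve exactly into known compounds.

.assert_same_diameter <- function(...) {
  ds <- unique(vapply(list(...), .sig_diameter, integer(1)))
  if (length(ds) != 1L) {
    stop("signature diameter mismatch: ", paste(ds, collapse = " vs "),
         call. = FALSE)
  }
  ds
}

#' Does a compound (plus co-substrates) embed a reaction's substrate fragments?
#'
#' @param compound_sig `mol_signature` of the query compound.
#' @param rxn_sig `rxn_signature` at the same diameter.
#' @param co_substrate_sigs list of `mol_signature`s for the reaction's
#'   non-primary substrates (possibly empty).
#' @return `TRUE` iff every consumed fragment is available in the combined
#'   query + co-substrate multiset and the query covers at least one consumed
#'   fragment itself.
#' @export
embeds <- function(compound_sig, rxn_sig, co_substrate_sigs = list()) {
  do.call(.assert_same_diameter,
          c(list(compound_sig, rxn_sig), co_substrate_sigs))
  delta <- unclass(rxn_sig)
  neg <- -delta[delta < 0L]
  if (!length(neg)) return(FALSE)  # nothing consumed: no reaction centre
  pool <- do.call(.frag_sum, c(list(unclass(compound_sig)),
                               lapply(co_substrate_sigs, unclass)))
  avail <- pool[names(neg)]
  avail[is.na(avail)] <- 0L
  if (any(avail < neg)) return(FALSE)
  any(names(neg) %in% names(compound_sig))
}

#' Apply a reaction signature to a matching substrate set
#'
#' Computes `(compound + co-substrates) + rxn_sig`; all resulting counts are
#' non-negative when [embeds()] holds (checked), and zero entries are dropped.
#'
#' @inheritParams embeds
#' @return The putative product fragment multiset as a `mol_signature`-like
#'   named integer vector with attribute `diameter`.
#' @export
apply_signature <- function(compound_sig, rxn_sig, co_substrate_sigs = list()) {
  d <- do.call(.assert_same_diameter,
               c(list(compound_sig, rxn_sig), co_substrate_sigs))
  pool <- do.call(.frag_sum, c(list(unclass(compound_sig)),
                               lapply(co_substrate_sigs, unclass)))
  out <- .frag_sum(pool, unclass(rxn_sig))
  if (any(out < 0L)) {
    bad <- names(out)[out < 0L]
    stop("apply_signature called on a non-embedding substrate; deficient ",
         "fragment(s): ", paste(bad, collapse = "; "), call. = FALSE)
  }
  out <- out[order(names(out))]
  structure(out, diameter = d, class = "mol_signature")
}

#' Resolve a positive fragment multiset into sets of known compounds
#'
#' Finds every multiset of at most `max_set_size` knowledge-base compounds
#' whose molecular signatures sum exactly to `P` (no remainder). Backtracking
#' branches on the rarest unexplained fragment, using the KB fragment index;
#' compound choices are non-decreasing by id so each multiset is produced
#' once. Results are sorted lexicographically by their sorted id vectors.
#'
#' @param P positive fragment multiset (named integer vector or
#'   `mol_signature`).
#' @param kb a `knowledge_base` (for its fragment index and cached
#'   signatures).
#' @param max_set_size cap on compounds per product set (default 3).
#' @param max_results cap on returned product sets (default 100).
#' @return list of character vectors of compound ids; `list(character(0))`
#'   for an empty `P`; `list()` when unresolvable.
#' @export
resolve_products <- function(P, kb, max_set_size = 3L, max_results = 100L) {
  stopifnot(inherits(kb, "knowledge_base"))
  P <- unclass(P)
  if (any(P < 0L)) stop("resolve_products requires positive counts",
                        call. = FALSE)
  P <- P[P > 0L]
  if (!length(P)) return(list(character(0)))
  results <- list()
  sigs <- kb$signatures
  index <- kb$fragment_index

  candidates_for <- function(frag) {
    ids <- index[[frag]]
    if (is.null(ids)) character(0) else ids
  }

  seen <- character(0)
  search <- function(remaining, chosen) {
    if (length(results) >= max_results) return(invisible())
    if (!length(remaining)) {
      key <- paste(sort(chosen), collapse = "\r")
      if (!key %in% seen) {
        seen <<- c(seen, key)
        results[[length(results) + 1L]] <<- sort(chosen)
      }
      return(invisible())
    }
    if (length(chosen) >= max_set_size) return(invisible())
    # branch on the unexplained fragment with the fewest candidate compounds;
    # permutation duplicates are filtered via the sorted-set key above
    n_cand <- vapply(names(remaining),
                     function(f) length(candidates_for(f)), integer(1))
    if (any(n_cand == 0L)) return(invisible())
    frag <- names(remaining)[which.min(n_cand)]
    for (cid in candidates_for(frag)) {
      csig <- unclass(sigs[[cid]])
      rem <- .frag_sum(remaining, -csig)
      if (any(rem < 0L)) next
      search(rem, c(chosen, cid))
    }
    invisible()
  }

  search(P, character(0))
  unique(results[order(vapply(results, paste, character(1), collapse = "\r"))])
}

#' Match one compound against one reaction and resolve the products
#'
#' Composition of [embeds()], [apply_signature()] and [resolve_products()]
#' for a reaction record in a knowledge base. A match whose product fragments
#' do not resolve into known compounds is reported with empty
#' `resolved_products` (the application is rejected, but recorded for
#' diagnostics).
#'
#' @param compound_sig `mol_signature` of the query compound.
#' @param reaction a reaction record from `kb$reactions` (or its id).
#' @param kb a `knowledge_base`.
#' @param direction `"forward"` or `"reverse"` (reverse only if the reaction
#'   is reversible).
#' @param max_set_size,max_results passed to [resolve_products()].
#' @return A `match_result`: list with `reaction_id`, `direction`, `matched`,
#'   `consumed`, `produced_fragments`, `resolved_products`.
#' @export
match_reaction <- function(compound_sig, reaction, kb,
                           direction = c("forward", "reverse"),
                           max_set_size = 3L, max_results = 100L) {
  direction <- match.arg(direction)
  if (is.character(reaction)) reaction <- kb$reactions[[reaction]]
  if (is.null(reaction)) stop("unknown reaction", call. = FALSE)
  if (direction == "reverse" && !isTRUE(reaction$reversible)) {
    stop("reaction ", reaction$id, " is not reversible", call. = FALSE)
  }
  rsig <- if (direction == "forward") reaction$sig_fwd else reaction$sig_rev
  co_ids <- if (direction == "forward") {
    setdiff_keep(reaction$substrates, reaction$primary)
  } else {
    setdiff_keep(reaction$products, reaction$primary_rev)
  }
  co_sigs <- lapply(co_ids, function(id) kb$signatures[[id]])
  empty <- structure(list(
    reaction_id = reaction$id, direction = direction, matched = FALSE,
    consumed = stats::setNames(integer(0), character(0)),
    produced_fragments = stats::setNames(integer(0), character(0)),
    resolved_products = list()
  ), class = "match_result")
  if (!embeds(compound_sig, rsig, co_sigs)) return(empty)
  delta <- unclass(rsig)
  P <- apply_signature(compound_sig, rsig, co_sigs)
  structure(list(
    reaction_id = reaction$id, direction = direction, matched = TRUE,
    consumed = -delta[delta < 0L],
    produced_fragments = P,
    resolved_products = resolve_products(P, kb, max_set_size, max_results)
  ), class = "match_result")
}

# setdiff dropping one occurrence per element of `drop`, preserving order.
setdiff_keep <- function(x, drop) {
  for (d in drop) {
    hit <- match(d, x)
    if (!is.na(hit)) x <- x[-hit]
  }
  x
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$reaction_id, " (", x$direction, "): ",
      if (!x$matched) "no match" else if (!length(x$resolved_products))
        "matched, unresolved (rejected)" else
          paste0(length(x$resolved_products), " product set(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Serialize match results to a TSV diagnostic log
#' @param results list of `match_result`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_match_log <- function(results, path) {
  rows <- vapply(results, function(m) {
    status <- if (!m$matched) "no_match" else if
    (!length(m$resolved_products)) "unresolved" else "accepted"
    prods <- paste(vapply(m$resolved_products, paste, character(1),
                          collapse = "+"), collapse = ";")
    paste(m$reaction_id, m$direction, status, prods, sep = "\t")
  }, character(1))
  writeLines(c("reaction_id\tdirection\tstatus\tproduct_sets", rows), path)
  invisible(path)
}
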
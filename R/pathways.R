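# Expansion of the metabolic graph around a target compound: breadth-first
# application of every knowledge-base reaction signature to the frontier,
# depth-bounded at 1 or 2 enzymatic steps; detectable endpoints are annotated
# by fingerprint similarity against the detectable-compound registry and
# sensing-enabling metabolic pathways (SEMPs) are read off the graph.

#' Expand the metabolic graph around a target compound
#'
#' Applies [match_reaction()] for every reaction (both directions when the
#' reaction is reversible and the config allows) to each frontier compound,
#' breadth-first, up to `max_steps` enzymatic steps. Every compound of every
#' resolved product set becomes a node and one edge per (reaction
#' application, product) is added, so multi-product reactions contribute
#' duplicated edges. Cofactors become nodes but are never expanded further.
#'
#' @param target a compound record (see [kb_resolve_compound()]), a KB
#'   compound id, or a structure string.
#' @param kb a `knowledge_base`.
#' @param max_steps 1 or 2.
#' @param dialect used if `target` is a bare non-InChI structure string.
#' @return An `expansion_graph`: list with `target`, `max_steps`, `nodes`
#'   (data frame: id, is_target, is_cofactor, in_kb, step), `edges` (data
#'   frame: from, to, reaction, direction, step, product_set), `records`
#'   (off-KB compound records, e.g. a novel target).
#' @export
expand <- function(target, kb, max_steps = 2L, dialect = NA_character_) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!max_steps %in% c(1L, 2L)) {
    stop("max_steps must be 1 or 2", call. = FALSE)
  }
  if (is.character(target)) target <- kb_resolve_compound(kb, target, dialect)
  records <- list()
  sig_of <- function(id) {
    if (!is.null(kb$signatures[[id]])) kb$signatures[[id]]
    else molecular_signature(records[[id]]$mol, kb$config$diameter)
  }
  tid <- target$id
  if (is.null(kb$compounds[[tid]])) records[[tid]] <- target

  node_step <- stats::setNames(0L, tid)
  edges <- data.frame(from = character(), to = character(),
                      reaction = character(), direction = character(),
                      step = integer(), product_set = character(),
                      stringsAsFactors = FALSE)
  seen_edges <- character(0)
  frontier <- tid
  expanded <- character(0)
  rxn_ids <- sort(names(kb$reactions))

  for (step in seq_len(max_steps)) {
    nxt <- character(0)
    for (cid in sort(frontier)) {
      if (cid %in% expanded) next
      expanded <- c(expanded, cid)
      csig <- sig_of(cid)
      for (rid in rxn_ids) {
        rxn <- kb$reactions[[rid]]
        dirs <- "forward"
        if (kb$config$bidirectional && isTRUE(rxn$reversible)) {
          dirs <- c(dirs, "reverse")
        }
        for (dn in dirs) {
          m <- match_reaction(csig, rxn, kb, direction = dn,
                              max_set_size = kb$config$max_set_size,
                              max_results = kb$config$max_results)
          if (!m$matched || !length(m$resolved_products)) next
          for (pset in m$resolved_products) {
            pkey <- paste(pset, collapse = "+")
            for (pid in pset) {
              ekey <- paste(cid, rid, dn, pkey, pid, sep = "\r")
              if (ekey %in% seen_edges) next
              seen_edges <- c(seen_edges, ekey)
              edges[nrow(edges) + 1L, ] <-
                list(cid, pid, rid, dn, step, pkey)
              if (is.na(node_step[pid])) {
                node_step[pid] <- step
                if (!pid %in% kb$cofactors) nxt <- c(nxt, pid)
              }
            }
          }
        }
      }
    }
    frontier <- unique(nxt)
  }

  ids <- names(node_step)
  ids <- c(tid, sort(setdiff(ids, tid)))
  nodes <- data.frame(
    id = ids,
    is_target = ids == tid,
    is_cofactor = ids %in% kb$cofactors,
    in_kb = vapply(ids, function(i) !is.null(kb$compounds[[i]]), logical(1)),
    step = unname(node_step[ids]),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(target = tid, max_steps = max_steps, nodes = nodes,
                 edges = edges, records = records, annotated = FALSE),
            class = "expansion_graph")
}

#' Annotate graph nodes with their best detectable-compound similarity
#'
#' Every node receives the maximum Tanimoto similarity against the
#' detectable-compound registry and the identity of that best detectable;
#' exact structural identity (equal canonical key) always scores 1. A node is
#' flagged detectable iff its score reaches `threshold` and it is not a
#' cofactor; `near_threshold` marks advisory near-matches.
#'
#' @param graph an `expansion_graph`.
#' @param kb the `knowledge_base` it was expanded against.
#' @param threshold similarity in `[0,1]` for the detectable flag (default 1:
#'   exact match).
#' @param near_threshold advisory near-match threshold (default 0.9).
#' @return the graph, with a `detect` data frame (id, best_detectable,
#'   effector, transcription_factors, similarity, flagged, near) and
#'   `annotated = TRUE`.
#' @export
annotate_detectables <- function(graph, kb, threshold = 1.0,
                                 near_threshold = 0.9) {
  stopifnot(inherits(graph, "expansion_graph"))
  dids <- sort(names(kb$detectables))
  fp_of <- function(id) {
    if (!is.null(kb$fingerprints[[id]])) kb$fingerprints[[id]]
    else fingerprint(graph$records[[id]]$mol, kb$config$fp_width)
  }
  key_of <- function(id) {
    if (!is.null(kb$compounds[[id]])) kb$compounds[[id]]$key
    else graph$records[[id]]$key
  }
  n <- nrow(graph$nodes)
  best_id <- character(n); best_score <- numeric(n)
  eff <- character(n); tfs <- character(n)
  for (i in seq_len(n)) {
    id <- graph$nodes$id[i]
    bs <- 0; bi <- NA_character_
    for (di in dids) {
      s <- if (identical(key_of(id), kb$detectables[[di]]$key)) 1
      else tanimoto(fp_of(id), fp_of(di))
      if (s > bs) { bs <- s; bi <- di }
    }
    best_id[i] <- bi; best_score[i] <- bs
    eff[i] <- if (is.na(bi)) NA_character_ else kb$detectables[[bi]]$effector
    tfs[i] <- if (is.na(bi)) NA_character_ else
      paste(kb$detectables[[bi]]$transcription_factors, collapse = "|")
  }
  graph$detect <- data.frame(
    id = graph$nodes$id, best_detectable = best_id,
    effector = eff, transcription_factors = tfs,
    similarity = best_score,
    flagged = best_score >= threshold & !graph$nodes$is_cofactor,
    near = best_score >= near_threshold & !graph$nodes$is_cofactor,
    stringsAsFactors = FALSE
  )
  graph$threshold <- threshold
  graph$near_threshold <- near_threshold
  graph$annotated <- TRUE
  graph
}

#' Extract sensing-enabling metabolic pathways from an annotated graph
#'
#' Enumerates all simple paths of length 1 or 2 from the target to a node
#' flagged detectable, grouped by endpoint and sorted by (length, similarity
#' descending, reaction ids). A target that is itself flagged is reported via
#' the `target_directly_detectable` attribute, not as a SEMP.
#'
#' @param graph an annotated `expansion_graph`.
#' @return list of `semp` records (pathway_id, endpoint, effector,
#'   transcription_factors, similarity, length, steps); attribute
#'   `target_directly_detectable` is `TRUE`/`FALSE`.
#' @export
find_semps <- function(graph) {
  stopifnot(inherits(graph, "expansion_graph"))
  if (!isTRUE(graph$annotated)) {
    stop("find_semps requires an annotated graph; run annotate_detectables",
         call. = FALSE)
  }
  det <- graph$detect
  flagged <- det$id[det$flagged]
  tid <- graph$target
  e <- graph$edges
  paths <- list()
  add_path <- function(steps, endpoint) {
    drow <- det[det$id == endpoint, ]
    paths[[length(paths) + 1L]] <<- list(
      endpoint = endpoint, effector = drow$effector,
      transcription_factors = drow$transcription_factors,
      similarity = drow$similarity, length = length(steps), steps = steps
    )
  }
  e1 <- e[e$from == tid & e$step == 1L, , drop = FALSE]
  for (i in seq_len(nrow(e1))) {
    if (e1$to[i] %in% flagged && e1$to[i] != tid) {
      add_path(list(list(reaction = e1$reaction[i],
                         direction = e1$direction[i],
                         product_set = e1$product_set[i],
                         product = e1$to[i])), e1$to[i])
    }
  }
  if (graph$max_steps >= 2L) {
    for (i in seq_len(nrow(e1))) {
      mid <- e1$to[i]
      if (mid == tid) next
      e2 <- e[e$from == mid & e$step == 2L, , drop = FALSE]
      for (j in seq_len(nrow(e2))) {
        endp <- e2$to[j]
        if (endp %in% flagged && endp != tid && endp != mid) {
          add_path(list(
            list(reaction = e1$reaction[i], direction = e1$direction[i],
                 product_set = e1$product_set[i], product = mid),
            list(reaction = e2$reaction[j], direction = e2$direction[j],
                 product_set = e2$product_set[j], product = endp)
          ), endp)
        }
      }
    }
  }
  if (length(paths)) {
    key <- vapply(paths, function(p) {
      paste(p$endpoint,
            p$length,
            format(1 - p$similarity, digits = 15),
            paste(vapply(p$steps, `[[`, character(1), "reaction"),
                  collapse = ","),
            paste(vapply(p$steps, `[[`, character(1), "product"),
                  collapse = ","),
            sep = "\r")
    }, character(1))
    paths <- paths[order(key)]
  }
  for (k in seq_along(paths)) {
    paths[[k]]$pathway_id <- sprintf("SEMP%03d", k)
    class(paths[[k]]) <- "semp"
  }
  structure(paths,
            target_directly_detectable = tid %in% flagged)
}

#' @export
print.semp <- function(x, ...) {
  cat("<", x$pathway_id, "> ",
      paste(vapply(x$steps, `[[`, character(1), "product"),
            collapse = " -> "),
      " [", x$length, " step(s), endpoint ", x$endpoint,
      ", similarity ", format(x$similarity, digits = 3),
      ", TFs: ", x$transcription_factors, "]\n", sep = "")
  invisible(x)
}

.fmt_gml_num <- function(x) {
  if (is.logical(x)) return(as.character(as.integer(x)))
  if (x == round(x) && abs(x) < 1e15) return(format(as.integer(x)))
  format(x, digits = 15)
}

.gml_quote <- function(s) {
  paste0('"', gsub('"', "'", s), '"')
}

# Uniform tabular view of a graph for GML export: works for a (possibly
# annotated) expansion_graph and for the output of read_gml.
.graph_tables <- function(x, kb = NULL) {
  if (inherits(x, "gml_graph")) return(x)
  stopifnot(inherits(x, "expansion_graph"))
  det <- if (isTRUE(x$annotated)) x$detect else
    data.frame(id = x$nodes$id, best_detectable = NA_character_,
               similarity = 0, flagged = FALSE, stringsAsFactors = FALSE)
  xrefs <- vapply(x$nodes$id, function(id) {
    if (!is.null(kb) && !is.null(kb$compounds[[id]])) {
      paste(kb$compounds[[id]]$xrefs, collapse = "|")
    } else ""
  }, character(1))
  rxrefs <- vapply(x$edges$reaction, function(rid) {
    if (!is.null(kb) && !is.null(kb$reactions[[rid]])) {
      paste(kb$reactions[[rid]]$xrefs, collapse = "|")
    } else ""
  }, character(1))
  nodes <- data.frame(
    id = x$nodes$id, is_target = x$nodes$is_target,
    is_cofactor = x$nodes$is_cofactor,
    is_detectable = det$flagged[match(x$nodes$id, det$id)],
    similarity = det$similarity[match(x$nodes$id, det$id)],
    xrefs = unname(xrefs), stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = x$edges$from, to = x$edges$to, reaction = x$edges$reaction,
    direction = x$edges$direction, step = x$edges$step,
    product_set = x$edges$product_set, xrefs = unname(rxrefs),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "gml_graph")
}

#' Export a graph to Graph Markup Language (GML)
#'
#' Writes a plain-text GML file with node attributes (label, is_target,
#' is_cofactor, is_detectable, similarity, xrefs) and edge attributes
#' (reaction, direction, step, products, xrefs). [read_gml()] round-trips the
#' node and edge sets exactly, and export-parse-export is byte-identical.
#'
#' @param x an `expansion_graph` (annotated or not) or a `gml_graph` from
#'   [read_gml()].
#' @param path output file path.
#' @param kb optional `knowledge_base` used to attach cross-references.
#' @return `path`, invisibly.
#' @export
export_gml <- function(x, path, kb = NULL) {
  g <- .graph_tables(x, kb)
  idx <- stats::setNames(seq_len(nrow(g$nodes)) - 1L, g$nodes$id)
  lines <- c("graph [", "  directed 1")
  for (i in seq_len(nrow(g$nodes))) {
    n <- g$nodes[i, ]
    lines <- c(lines, "  node [",
               paste0("    id ", idx[[n$id]]),
               paste0("    label ", .gml_quote(n$id)),
               paste0("    is_target ", .fmt_gml_num(n$is_target)),
               paste0("    is_cofactor ", .fmt_gml_num(n$is_cofactor)),
               paste0("    is_detectable ", .fmt_gml_num(n$is_detectable)),
               paste0("    similarity ", .fmt_gml_num(n$similarity)),
               paste0("    xrefs ", .gml_quote(n$xrefs)),
               "  ]")
  }
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    lines <- c(lines, "  edge [",
               paste0("    source ", idx[[e$from]]),
               paste0("    target ", idx[[e$to]]),
               paste0("    reaction ", .gml_quote(e$reaction)),
               paste0("    direction ", .gml_quote(e$direction)),
               paste0("    step ", .fmt_gml_num(e$step)),
               paste0("    products ", .gml_quote(e$product_set)),
               paste0("    xrefs ", .gml_quote(e$xrefs)),
               "  ]")
  }
  lines <- c(lines, "]")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a GML file written by [export_gml()]
#'
#' @param path GML file path.
#' @return A `gml_graph`: list of `nodes` and `edges` data frames.
#' @export
read_gml <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  toks <- .gml_tokens(lines)
  nodes <- list(); edges <- list()
  i <- 1L
  get_block <- function(start) {
    depth <- 0L; kv <- list(); j <- start
    repeat {
      t <- toks[[j]]
      if (identical(t, "[")) depth <- depth + 1L
      else if (identical(t, "]")) {
        depth <- depth - 1L
        if (depth == 0L) return(list(kv = kv, next_i = j + 1L))
      } else if (depth == 1L && j + 1L <= length(toks)) {
        kv[[t]] <- toks[[j + 1L]]
        j <- j + 1L
      }
      j <- j + 1L
    }
  }
  while (i <= length(toks)) {
    t <- toks[[i]]
    if (identical(t, "node")) {
      b <- get_block(i + 1L); nodes[[length(nodes) + 1L]] <- b$kv
      i <- b$next_i
    } else if (identical(t, "edge")) {
      b <- get_block(i + 1L); edges[[length(edges) + 1L]] <- b$kv
      i <- b$next_i
    } else i <- i + 1L
  }
  unq <- function(s) gsub('^"|"$', "", s)
  ndf <- data.frame(
    id = vapply(nodes, function(n) unq(n$label), character(1)),
    is_target = vapply(nodes, function(n) n$is_target == "1", logical(1)),
    is_cofactor = vapply(nodes, function(n) n$is_cofactor == "1",
                         logical(1)),
    is_detectable = vapply(nodes, function(n) n$is_detectable == "1",
                           logical(1)),
    similarity = vapply(nodes, function(n) as.numeric(n$similarity),
                        numeric(1)),
    xrefs = vapply(nodes, function(n) unq(n$xrefs), character(1)),
    stringsAsFactors = FALSE
  )
  num_id <- vapply(nodes, function(n) n$id, character(1))
  lab_of <- stats::setNames(ndf$id, num_id)
  if (length(edges)) {
    edf <- data.frame(
      from = unname(lab_of[vapply(edges, function(e) e$source,
                                  character(1))]),
      to = unname(lab_of[vapply(edges, function(e) e$target, character(1))]),
      reaction = vapply(edges, function(e) unq(e$reaction), character(1)),
      direction = vapply(edges, function(e) unq(e$direction), character(1)),
      step = vapply(edges, function(e) as.integer(e$step), integer(1)),
      product_set = vapply(edges, function(e) unq(e$products), character(1)),
      xrefs = vapply(edges, function(e) unq(e$xrefs), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    edf <- data.frame(from = character(), to = character(),
                      reaction = character(), direction = character(),
                      step = integer(), product_set = character(),
                      xrefs = character(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = ndf, edges = edf), class = "gml_graph")
}

.gml_tokens <- function(lines) {
  text <- paste(lines, collapse = "\n")
  toks <- regmatches(text, gregexpr('"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+', text,
                                    perl = TRUE))[[1]]
  as.list(toks)
}

#' Export SEMPs to the tabular pathway view
#'
#' One row per pathway step: pathway id, step index, reaction id and
#' cross-references, direction, full product set, the product followed on the
#' path, endpoint, effector and transcription-factor names, similarity.
#'
#' @param semps list from [find_semps()].
#' @param path output TSV path.
#' @param kb optional `knowledge_base` for reaction cross-references.
#' @return `path`, invisibly.
#' @export
export_pathways <- function(semps, path, kb = NULL) {
  header <- paste("pathway_id", "step", "reaction_id", "reaction_xrefs",
                  "direction", "product_set", "product", "endpoint",
                  "effector", "transcription_factors", "similarity",
                  sep = "\t")
  rows <- character(0)
  for (p in semps) {
    for (k in seq_along(p$steps)) {
      s <- p$steps[[k]]
      rx <- if (!is.null(kb) && !is.null(kb$reactions[[s$reaction]])) {
        paste(kb$reactions[[s$reaction]]$xrefs, collapse = "|")
      } else ""
      rows <- c(rows, paste(p$pathway_id, k, s$reaction, rx, s$direction,
                            s$product_set, s$product, p$endpoint,
                            p$effector, p$transcription_factors,
                            format(p$similarity, digits = 15), sep = "\t"))
    }
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @export
print.expansion_graph <- function(x, ...) {
  cat("<expansion_graph> target ", x$target, ": ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " edges (max ", x$max_steps, " steps",
      if (isTRUE(x$annotated)) paste0(", ", sum(x$detect$flagged),
                                      " detectable"),
      ")\n", sep = "")
  invisible(x)
}
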
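# Independent oracles, deliberately on different algorithmic routes from the
# implementation (which uses colour refinement with tie-branching).

# Environment extraction shared with the oracles: plain BFS on the bond list.
oracle_environment <- function(mol, root, radius) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist <- rep(Inf, n); dist[root] <- 0
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (dist[v] >= radius) next
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
    }
  }
  keep <- which(is.finite(dist))
  labels <- ifelse(mol$atoms$aromatic[keep], tolower(mol$atoms$element[keep]),
                   mol$atoms$element[keep])
  inb <- mol$bonds$from %in% keep & mol$bonds$to %in% keep
  remap <- integer(n); remap[keep] <- seq_along(keep)
  list(labels = labels,
       bonds = data.frame(from = remap[mol$bonds$from[inb]],
                          to = remap[mol$bonds$to[inb]],
                          order = mol$bonds$order[inb],
                          stringsAsFactors = FALSE),
       root = remap[root], n = length(keep))
}

# Exhaustive-permutation canonization: the minimum serialization over ALL
# orderings with the root fixed first. Exact for any rooted labelled graph;
# usable up to ~8 atoms. Equal oracle strings <=> isomorphic rooted envs.
oracle_canon_exhaustive <- function(env) {
  stopifnot(env$n <= 8)
  others <- setdiff(seq_len(env$n), env$root)
  perms <- if (length(others)) .all_perms(others) else list(integer(0))
  best <- NULL
  for (p in perms) {
    ord <- c(env$root, p)            # ord[k] = original index at position k
    pos <- integer(env$n); pos[ord] <- seq_len(env$n)
    lab <- paste(env$labels[ord], collapse = ",")
    if (nrow(env$bonds)) {
      a <- pos[env$bonds$from]; b <- pos[env$bonds$to]
      lo <- pmin(a, b); hi <- pmax(a, b)
      o <- order(lo, hi)
      estr <- paste(sprintf("%02d-%02d:%s", lo[o], hi[o], env$bonds$order[o]),
                    collapse = ",")
    } else estr <- ""
    s <- paste0(lab, "|", estr)
    if (is.null(best) || s < best) best <- s
  }
  best
}

.all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# VF2 rooted-environment isomorphism (igraph), for environments too large for
# the permutation oracle: bond orders become colored dummy vertices; the root
# gets a reserved color.
oracle_env_isomorphic <- function(env_a, env_b) {
  if (env_a$n != env_b$n) return(FALSE)
  if (!identical(sort(env_a$labels), sort(env_b$labels))) return(FALSE)
  palette <- sort(unique(c(env_a$labels, env_b$labels)))
  build <- function(env) {
    col <- match(env$labels, palette) + 1L
    col[env$root] <- 1L
    nb <- nrow(env$bonds)
    edges <- integer(0); bcol <- integer(0)
    if (nb) {
      dummy <- env$n + seq_len(nb)
      edges <- as.vector(rbind(env$bonds$from, dummy, dummy, env$bonds$to))
      bcol <- length(palette) + 1L + match(env$bonds$order,
                                           c("1", "2", "3", "a"))
    }
    g <- igraph::make_empty_graph(env$n + nb, directed = FALSE)
    if (nb) g <- igraph::add_edges(g, edges)
    list(g = g, col = c(col, bcol))
  }
  ga <- build(env_a); gb <- build(env_b)
  igraph::isomorphic(ga$g, gb$g, method = "vf2",
                     vertex.color1 = ga$col, vertex.color2 = gb$col)
}

# Serialized multiset sum of molecular signatures, for the brute-force
# product-resolution oracle.
oracle_sig_sum_key <- function(sigs) {
  v <- integer(0)
  for (s in sigs) {
    s <- unclass(s)
    all_n <- union(names(v), names(s))
    out <- stats::setNames(integer(length(all_n)), all_n)
    out[names(v)] <- out[names(v)] + v
    out[names(s)] <- out[names(s)] + s
    v <- out
  }
  v <- v[v != 0L]
  v <- v[order(names(v))]
  paste(names(v), v, sep = "=", collapse = ";")
}
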
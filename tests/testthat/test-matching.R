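test_that("closure: every fixture reaction regenerates its recorded products", {
  for (name in c("cocaine", "parathion", "random")) {
    kb <- fixture_kb(name)
    for (rxn in kb$reactions) {
      m <- match_reaction(kb$signatures[[rxn$primary]], rxn, kb)
      expect_true(m$matched, info = paste(name, rxn$id))
      expected <- sort(rxn$products)
      hit <- any(vapply(m$resolved_products, function(ps) {
        identical(sort(ps), expected)
      }, logical(1)))
      expect_true(hit, info = paste(name, rxn$id, "products"))
      if (rxn$reversible) {
        mr <- match_reaction(kb$signatures[[rxn$primary_rev]], rxn, kb,
                             direction = "reverse")
        expect_true(mr$matched, info = paste(name, rxn$id, "reverse"))
        hit_r <- any(vapply(mr$resolved_products, function(ps) {
          identical(sort(ps), sort(rxn$substrates))
        }, logical(1)))
        expect_true(hit_r, info = paste(name, rxn$id, "reverse products"))
      }
    }
  }
})

test_that("non-substrates do not embed a specific reaction signature", {
  kb <- fixture_kb("cocaine")
  esterase <- kb$reactions$r_cocaine_esterase
  co <- list(kb$signatures$water)
  expect_false(embeds(kb$signatures$ethanol, esterase$sig_fwd, co))
  benzene <- molecular_signature(nmol("c1ccccc1"), 12L)
  m <- match_reaction(benzene, esterase, kb)
  expect_false(m$matched)
  expect_length(m$resolved_products, 0L)
})

test_that("cocaine embeds the esterase signature with water as co-substrate", {
  kb <- fixture_kb("cocaine")
  esterase <- kb$reactions$r_cocaine_esterase
  expect_true(embeds(kb$signatures$cocaine, esterase$sig_fwd,
                     list(kb$signatures$water)))
  # but not without the co-substrate's fragments
  expect_false(embeds(kb$signatures$cocaine, esterase$sig_fwd, list()))
})

test_that("apply_signature reproduces the combined product signature", {
  kb <- fixture_kb("cocaine")
  esterase <- kb$reactions$r_cocaine_esterase
  P <- apply_signature(kb$signatures$cocaine, esterase$sig_fwd,
                       list(kb$signatures$water))
  both <- sempfinder:::.frag_sum(
    bare(kb$signatures$benzoate),
    bare(kb$signatures$ecgonine_methyl_ester))
  expect_identical(bare(P), both[order(names(both))])
  # called without embedding -> error naming a deficient fragment
  expect_error(
    apply_signature(kb$signatures$ethanol, esterase$sig_fwd, list()),
    "deficient")
})

test_that("resolve_products handles degenerate inputs", {
  kb <- fixture_kb("cocaine")
  empty <- structure(stats::setNames(integer(0), character(0)),
                     diameter = 12L, class = "mol_signature")
  expect_identical(resolve_products(empty, kb), list(character(0)))
  orphan <- stats::setNames(1L, "Zz*|")
  expect_identical(resolve_products(orphan, kb), list())
  expect_error(resolve_products(stats::setNames(-1L, "C*|"), kb), "positive")
})

test_that("resolve_products matches the brute-force partition oracle", {
  kb <- fixture_kb("random", seed = 7L)  # esterification net, ~17 compounds
  ids <- names(kb$signatures)
  # oracle: enumerate every multiset of size <= 2 once, key by summed sig
  oracle_map <- new.env(parent = emptyenv())
  put <- function(key, set) {
    oracle_map[[key]] <- c(oracle_map[[key]], list(sort(set)))
  }
  for (i in seq_along(ids)) {
    put(oracle_sig_sum_key(kb$signatures[ids[i]]), ids[i])
    for (j in i:length(ids)) {
      put(oracle_sig_sum_key(kb$signatures[c(ids[i], ids[j])]),
          c(ids[i], ids[j]))
    }
  }
  set.seed(2024)
  for (trial in 1:100) {
    pick <- sample(ids, 2L, replace = TRUE)
    P <- sempfinder:::.frag_sum(unclass(kb$signatures[[pick[1]]]),
                                unclass(kb$signatures[[pick[2]]]))
    got <- resolve_products(structure(P, diameter = 12L), kb,
                            max_set_size = 2L)
    want <- oracle_map[[oracle_sig_sum_key(kb$signatures[pick])]]
    want <- unique(want[order(vapply(want, paste, character(1),
                                     collapse = "\r"))])
    expect_identical(got, want, info = paste(pick, collapse = "+"))
  }
})

test_that("resolution is independent of index insertion order", {
  # two loads of the same directory must give identical indices and results
  dir <- fixture_dir("cocaine")
  kb1 <- fixture_kb("cocaine")
  kb2 <- load_kb(dir, kb_config())
  expect_identical(kb1$fragment_index, kb2$fragment_index)
  esterase <- kb1$reactions$r_cocaine_esterase
  P <- apply_signature(kb1$signatures$cocaine, esterase$sig_fwd,
                       list(kb1$signatures$water))
  expect_identical(resolve_products(P, kb1), resolve_products(P, kb2))
})

test_that("lower diameters never shrink the set of matching compounds", {
  for (d_pair in list(c(12L, 8L), c(8L, 4L))) {
    kb_hi <- fixture_kb("cocaine", diameter = d_pair[1])
    kb_lo <- fixture_kb("cocaine", diameter = d_pair[2])
    for (rid in names(kb_hi$reactions)) {
      matchers <- function(kb) {
        rxn <- kb$reactions[[rid]]
        co <- lapply(sempfinder:::setdiff_keep(rxn$substrates, rxn$primary),
                     function(i) kb$signatures[[i]])
        names(Filter(function(s) embeds(s, rxn$sig_fwd, co), kb$signatures))
      }
      expect_true(all(matchers(kb_hi) %in% matchers(kb_lo)),
                  info = paste(rid, paste(d_pair, collapse = ">")))
    }
  }
})

test_that("match results are deterministic and serializable", {
  kb <- fixture_kb("cocaine")
  m1 <- match_reaction(kb$signatures$cocaine, "r_cocaine_esterase", kb)
  m2 <- match_reaction(kb$signatures$cocaine, "r_cocaine_esterase", kb)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  expect_identical(m1$resolved_products,
                   list(c("benzoate", "ecgonine_methyl_ester")))
  log <- tempfile(fileext = ".tsv")
  write_match_log(list(m1), log)
  lines <- readLines(log)
  expect_length(lines, 2L)
  expect_match(lines[2], "accepted.*benzoate\\+ecgonine_methyl_ester")
})
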
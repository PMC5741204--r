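cocaine_graph <- local({
  g <- NULL
  function(steps = 1L) {
    key <- paste0("g", steps)
    if (is.null(.kb_cache[[key]])) {
      kb <- fixture_kb("cocaine")
      .kb_cache[[key]] <- annotate_detectables(
        expand("cocaine", kb, max_steps = steps), kb)
    }
    .kb_cache[[key]]
  }
})

test_that("one-step expansion of cocaine yields the esterase edge pair", {
  g <- cocaine_graph(1L)
  expect_setequal(g$nodes$id, c("cocaine", "benzoate",
                                "ecgonine_methyl_ester"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(unique(g$edges$reaction), "r_cocaine_esterase")
  expect_setequal(g$edges$to, c("benzoate", "ecgonine_methyl_ester"))
  expect_equal(unique(g$edges$product_set),
               "benzoate+ecgonine_methyl_ester")
})

test_that("two-step parathion expansion reaches nitrite via 4-nitrophenol", {
  kb <- fixture_kb("parathion")
  g1 <- expand("parathion", kb, max_steps = 1L)
  g2 <- expand("parathion", kb, max_steps = 2L)
  expect_true(all(g1$nodes$id %in% g2$nodes$id))  # monotone in depth
  expect_false("nitrite" %in% g1$nodes$id)
  expect_true("nitrite" %in% g2$nodes$id)
  path_edge <- g2$edges[g2$edges$to == "nitrite", ]
  expect_equal(path_edge$from, "nitrophenol_4")
  expect_equal(path_edge$step, 2L)
  # depth bound: no node farther than max_steps
  expect_true(all(g2$nodes$step <= 2L))
  expect_true(all(g1$nodes$step <= 1L))
  # cofactors become nodes but are never expanded
  expect_true("water" %in% g2$nodes$id)
  expect_false(any(g2$edges$from %in% kb$cofactors))
})

test_that("a target matching nothing gives a single-node graph", {
  kb <- fixture_kb("cocaine")
  g <- expand("c1ccccc1", kb, max_steps = 2L, dialect = "SMILES")
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$target, "query")
})

test_that("annotation flags exact detectables and records best scores", {
  g <- cocaine_graph(1L)
  det <- g$detect
  expect_identical(det$similarity[det$id == "benzoate"], 1)
  expect_true(det$flagged[det$id == "benzoate"])
  eme <- det[det$id == "ecgonine_methyl_ester", ]
  expect_false(eme$flagged)
  expect_gte(eme$similarity, 0)  # best score recorded even when unflagged
  expect_false(is.na(eme$best_detectable))
  # threshold 0 flags every non-cofactor node
  kb <- fixture_kb("cocaine")
  g0 <- annotate_detectables(expand("cocaine", kb, 1L), kb, threshold = 0)
  expect_true(all(g0$detect$flagged | g0$nodes$is_cofactor))
})

test_that("find_semps enumerates, groups and sorts pathways", {
  g <- cocaine_graph(1L)
  semps <- find_semps(g)
  expect_length(semps, 1L)
  expect_equal(semps[[1]]$endpoint, "benzoate")
  expect_equal(semps[[1]]$length, 1L)
  expect_false(attr(semps, "target_directly_detectable"))

  kb <- fixture_kb("parathion")
  g2 <- annotate_detectables(expand("parathion", kb, 2L), kb)
  s2 <- find_semps(g2)
  endpoints <- vapply(s2, `[[`, character(1), "endpoint")
  lens <- vapply(s2, `[[`, integer(1), "length")
  expect_setequal(endpoints, c("nitrophenol_4", "nitrite"))
  expect_equal(lens[endpoints == "nitrophenol_4"], 1L)
  expect_equal(lens[endpoints == "nitrite"], 2L)
  # every flagged reachable node is an endpoint of at least one SEMP
  flagged <- g2$detect$id[g2$detect$flagged & g2$detect$id != g2$target]
  expect_setequal(intersect(flagged, g2$nodes$id), unique(endpoints))
  # every endpoint is flagged
  expect_true(all(endpoints %in% g2$detect$id[g2$detect$flagged]))

  expect_error(find_semps(expand("parathion", kb, 1L)), "annotate")
})

test_that("an unannotatable graph yields no SEMPs", {
  kb <- fixture_kb("cocaine")
  g <- annotate_detectables(expand("ethanol", kb, 1L), kb)
  expect_length(find_semps(g), 0L)
})

test_that("GML export round-trips and is byte-stable", {
  g <- cocaine_graph(1L)
  kb <- fixture_kb("cocaine")
  f1 <- tempfile(fileext = ".gml"); f2 <- tempfile(fileext = ".gml")
  export_gml(g, f1, kb)
  parsed <- read_gml(f1)
  expect_setequal(parsed$nodes$id, g$nodes$id)
  expect_equal(nrow(parsed$edges), nrow(g$edges))
  expect_equal(unique(parsed$edges$reaction), "r_cocaine_esterase")
  export_gml(parsed, f2)
  expect_identical(readLines(f1), readLines(f2))

  # single-node graph
  g1 <- annotate_detectables(
    expand("c1ccccc1", kb, 1L, dialect = "SMILES"), kb)
  f3 <- tempfile(fileext = ".gml")
  export_gml(g1, f3, kb)
  p3 <- read_gml(f3)
  expect_equal(nrow(p3$nodes), 1L)
  expect_equal(nrow(p3$edges), 0L)
})

test_that("pathway TSV export contains effectors and shared pathway ids", {
  kb <- fixture_kb("cocaine")
  semps <- find_semps(cocaine_graph(1L))
  f <- tempfile(fileext = ".tsv")
  export_pathways(semps, f, kb)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 1L)
  expect_match(tab$transcription_factors, "BenR")
  expect_match(tab$transcription_factors, "XylS")
  expect_equal(tab$endpoint, "benzoate")

  export_pathways(list(), f)
  expect_length(readLines(f), 1L)  # header only

  kbp <- fixture_kb("parathion")
  sp <- find_semps(annotate_detectables(expand("parathion", kbp, 2L), kbp))
  export_pathways(sp, f, kbp)
  tabp <- utils::read.delim(f)
  two_step <- tabp[tabp$endpoint == "nitrite", ]
  expect_equal(nrow(two_step), 2L)
  expect_length(unique(two_step$pathway_id), 1L)
  expect_equal(two_step$step, c(1L, 2L))
})

test_that("expansion and exports are deterministic end to end", {
  kb <- fixture_kb("parathion")
  r1 <- run_search("parathion", kb, steps = 2,
                   out_gml = tempfile(), out_pathways = tempfile())
  r2 <- run_search("parathion", kb, steps = 2,
                   out_gml = tempfile(), out_pathways = tempfile())
  expect_identical(serialize(r1$graph, NULL), serialize(r2$graph, NULL))
  expect_identical(r1$summary, r2$summary)
})
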
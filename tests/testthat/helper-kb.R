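# Memoised fixture knowledge bases: each (name, diameter) pair is built and
# loaded at most once per test run.

.kb_cache <- new.env(parent = emptyenv())

fixture_dir <- function(name, seed = 1L) {
  key <- paste0("dir_", name, "_", seed)
  if (is.null(.kb_cache[[key]])) {
    .kb_cache[[key]] <- build_fixture_kb(name, seed = seed)
  }
  .kb_cache[[key]]
}

fixture_kb <- function(name, diameter = 12L, seed = 1L) {
  key <- paste0("kb_", name, "_", diameter, "_", seed)
  if (is.null(.kb_cache[[key]])) {
    .kb_cache[[key]] <- load_kb(fixture_dir(name, seed),
                                kb_config(diameter = diameter))
  }
  .kb_cache[[key]]
}

nmol <- function(text, dialect = "SMILES") normalize_mol(text, dialect)

# strip class and signature attributes, keeping only names: for comparing
# fragment multisets as plain named integer vectors
bare <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(names = names(x))
  x
}

COCAINE_INCHI <- paste0(
  "InChI=1S/C17H21NO4/c1-18-12-8-9-13(18)15(17(20)21-2)14(10-12)",
  "22-16(19)11-6-4-3-5-7-11/h3-7,12-15H,8-10H2,1-2H3/",
  "t12-,13+,14-,15+/m0/s1")
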
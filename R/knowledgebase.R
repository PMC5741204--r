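# Tabular knowledge base: compounds.tsv, reactions.tsv, detectables.tsv,
# cofactors.tsv (UTF-8, header row, tab-delimited). Compounds are parsed,
# normalized and deduplicated by canonical structure key; reactions referencing
# unknown or invalid compounds are rejected into a report, never silently
# dropped. Signatures and fingerprints are cached on the loaded object.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = NULL, comment.char = "")
}

.split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, "|", fixed = TRUE)[[1]]
}

#' Knowledge-base configuration
#'
#' @param diameter signature bond diameter (default 12 = radius 6; lower
#'   values make reaction signatures coarser and matching more promiscuous).
#' @param fp_width fingerprint width in bits (default 2048).
#' @param bidirectional treat reactions not flagged irreversible as usable in
#'   both directions (default `TRUE`).
#' @param max_set_size cap on compounds per resolved product set.
#' @param max_results cap on product sets per reaction application.
#' @return A `kb_config` list.
#' @export
kb_config <- function(diameter = 12L, fp_width = 2048L, bidirectional = TRUE,
                      max_set_size = 3L, max_results = 100L) {
  diameter <- .check_diameter(diameter)
  stopifnot(fp_width >= 8L, max_set_size >= 1L, max_results >= 1L)
  structure(list(diameter = diameter, fp_width = as.integer(fp_width),
                 bidirectional = isTRUE(bidirectional),
                 max_set_size = as.integer(max_set_size),
                 max_results = as.integer(max_results)),
            class = "kb_config")
}

#' Load a knowledge base from a directory of tabular files
#'
#' Expects `compounds.tsv` (id, structure, dialect, xrefs), `reactions.tsv`
#' (id, substrates, products, reversible, xrefs; member lists pipe-separated,
#' primary substrate first), `detectables.tsv` (compound_id, effector,
#' transcription_factors, source) and `cofactors.tsv` (compound_id). Invalid
#' rows are collected into `kb$rejections` with a reason.
#'
#' @param dir directory path.
#' @param config a [kb_config()].
#' @return A `knowledge_base` object.
#' @export
load_kb <- function(dir, config = kb_config()) {
  stopifnot(inherits(config, "kb_config"))
  for (f in c("compounds.tsv", "reactions.tsv", "detectables.tsv",
              "cofactors.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop("knowledge base missing ", f, " in ", dir, call. = FALSE)
    }
  }
  rejections <- data.frame(kind = character(), id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  reject <- function(kind, id, reason) {
    rejections[nrow(rejections) + 1L, ] <<- list(kind, id, reason)
  }

  ## compounds ----------------------------------------------------------
  ctab <- .read_tsv(file.path(dir, "compounds.tsv"))
  if (anyDuplicated(ctab$id)) {
    stop("duplicate compound ids in compounds.tsv: ",
         paste(unique(ctab$id[duplicated(ctab$id)]), collapse = ", "),
         call. = FALSE)
  }
  parsed <- .py_parse_batch(ctab$structure, ctab$dialect, normalize = TRUE)
  compounds <- list()
  aliases <- character(0)   # original id -> canonical record id
  key_to_id <- character(0) # canonical key -> record id
  for (i in seq_len(nrow(ctab))) {
    row <- ctab[i, ]
    res <- parsed[[i]]
    if (!isTRUE(res$ok)) {
      reject("compound", row$id, paste0("parse/normalize failed: ",
                                        res$error))
      next
    }
    raw <- raw_structure(row$structure, row$dialect)
    mol <- .mol_graph_from_py(res, raw, normalized = TRUE)
    key <- canonical_key(mol)
    xrefs <- .split_pipe(row$xrefs)
    if (!is.na(hit <- key_to_id[key])) {
      rec <- compounds[[hit]]
      rec$xrefs <- union(rec$xrefs, c(row$id, xrefs))
      compounds[[hit]] <- rec
      aliases[row$id] <- hit
    } else {
      compounds[[row$id]] <- list(id = row$id, structure = raw, mol = mol,
                                  key = key, xrefs = xrefs)
      key_to_id[key] <- row$id
      aliases[row$id] <- row$id
    }
  }

  signatures <- lapply(compounds, function(rec) {
    molecular_signature(rec$mol, config$diameter)
  })
  fingerprints <- lapply(compounds, function(rec) {
    fingerprint(rec$mol, config$fp_width)
  })

  fragment_index <- list()
  for (cid in names(signatures)) {
    for (frag in names(signatures[[cid]])) {
      fragment_index[[frag]] <- c(fragment_index[[frag]], cid)
    }
  }
  fragment_index <- lapply(fragment_index, function(ids) sort(unique(ids)))

  resolve_id <- function(id) {
    out <- aliases[id]
    if (is.na(out)) NA_character_ else unname(out)
  }

  ## reactions ----------------------------------------------------------
  rtab <- .read_tsv(file.path(dir, "reactions.tsv"))
  reactions <- list()
  for (i in seq_len(nrow(rtab))) {
    row <- rtab[i, ]
    subs <- .split_pipe(row$substrates)
    prods <- .split_pipe(row$products)
    if (!length(subs) || !length(prods)) {
      reject("reaction", row$id, "empty substrate or product list")
      next
    }
    subs_c <- vapply(subs, resolve_id, character(1))
    prods_c <- vapply(prods, resolve_id, character(1))
    missing <- c(subs, prods)[is.na(c(subs_c, prods_c))]
    if (length(missing)) {
      reject("reaction", row$id,
             paste0("unknown/invalid compound reference: ",
                    paste(unique(missing), collapse = ", ")))
      next
    }
    sub_sigs <- lapply(subs_c, function(id) signatures[[id]])
    prod_sigs <- lapply(prods_c, function(id) signatures[[id]])
    sig_fwd <- reaction_signature(sub_sigs, prod_sigs)
    if (!length(sig_fwd)) {
      reject("reaction", row$id,
             "degenerate reaction signature (products identical to substrates)")
      next
    }
    reactions[[row$id]] <- list(
      id = row$id,
      substrates = unname(subs_c), primary = unname(subs_c[1]),
      products = unname(prods_c), primary_rev = unname(prods_c[1]),
      reversible = tolower(row$reversible) %in% c("true", "1", "yes"),
      xrefs = .split_pipe(row$xrefs),
      sig_fwd = sig_fwd,
      sig_rev = reaction_signature(prod_sigs, sub_sigs)
    )
  }

  ## detectables --------------------------------------------------------
  dtab <- .read_tsv(file.path(dir, "detectables.tsv"))
  detectables <- list()
  for (i in seq_len(nrow(dtab))) {
    row <- dtab[i, ]
    cid <- resolve_id(row$compound_id)
    if (is.na(cid)) {
      reject("detectable", row$compound_id, "unresolvable compound id")
      next
    }
    if (!is.null(detectables[[cid]])) {
      rec <- detectables[[cid]]
      rec$transcription_factors <-
        union(rec$transcription_factors,
              .split_pipe(row$transcription_factors))
      detectables[[cid]] <- rec
    } else {
      detectables[[cid]] <- list(
        compound_id = cid, effector = row$effector,
        transcription_factors = .split_pipe(row$transcription_factors),
        source = row$source, key = compounds[[cid]]$key
      )
    }
  }

  ## cofactors ----------------------------------------------------------
  ftab <- .read_tsv(file.path(dir, "cofactors.tsv"))
  cofactors <- character(0)
  for (id in ftab$compound_id) {
    cid <- resolve_id(id)
    if (is.na(cid)) reject("cofactor", id, "unresolvable compound id")
    else cofactors <- union(cofactors, cid)
  }

  structure(list(
    dir = normalizePath(dir), config = config,
    compounds = compounds, aliases = aliases,
    signatures = signatures, fingerprints = fingerprints,
    fragment_index = fragment_index,
    reactions = reactions, detectables = detectables,
    cofactors = cofactors, rejections = rejections
  ), class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> ", length(x$compounds), " compounds, ",
      length(x$reactions), " reactions, ", length(x$detectables),
      " detectables, ", length(x$cofactors), " cofactors",
      " (diameter ", x$config$diameter, ")\n", sep = "")
  if (nrow(x$rejections)) {
    cat("  ", nrow(x$rejections), " rejected record(s); see $rejections\n",
        sep = "")
  }
  invisible(x)
}

#' Find a knowledge-base compound by id, alias, or structure
#'
#' Resolution order mirrors the query flow: id/alias lookup first, then parse
#' the text as a structure and look it up by canonical key; an unknown
#' structure returns an ad-hoc record (usable as an expansion target).
#'
#' @param kb a `knowledge_base`.
#' @param query compound id, xref, InChI, or SMILES (with `dialect`).
#' @param dialect used when the query must be parsed as a structure.
#' @return a compound record; its `id` is the KB id when known, else `"query"`.
#' @export
kb_resolve_compound <- function(kb, query, dialect = NA_character_) {
  hit <- kb$aliases[query]
  if (!is.na(hit)) return(kb$compounds[[unname(hit)]])
  for (rec in kb$compounds) {
    if (query %in% rec$xrefs) return(rec)
  }
  mol <- normalize_mol(query, dialect)
  key <- canonical_key(mol)
  for (rec in kb$compounds) {
    if (identical(rec$key, key)) return(rec)
  }
  list(id = "query", structure = mol$provenance, mol = mol, key = key,
       xrefs = character(0))
}

.fixture_names <- c("cocaine", "parathion", "random")

#' Write a self-contained fixture knowledge base
#'
#' `"cocaine"`: cocaine, water, benzoate and ecgonine methyl ester with the
#' cocaine-esterase hydrolysis, benzoate flagged detectable (BenM, BenR, CbdS,
#' PcaR, TcbR, CatR, BadR, XylS), plus distractor compounds/reactions.
#' `"parathion"`: the phosphotriesterase step parathion -> 4-nitrophenol and
#' the monooxygenase step 4-nitrophenol -> benzoquinone + nitrite, with
#' 4-nitrophenol (DmpR) and nitrite (NarL) detectable, plus distractors.
#' `"random"`: a seed-reproducible esterification network (acid + alcohol ->
#' ester + water) over a small alkyl pool.
#'
#' @param name one of `"cocaine"`, `"parathion"`, `"random"`.
#' @param dir output directory (created; default a fresh tempdir).
#' @param seed integer seed (used by `"random"` only).
#' @param n_reactions number of esterification reactions in `"random"`.
#' @return the directory path, invisibly usable with [load_kb()].
#' @export
build_fixture_kb <- function(name = .fixture_names, dir = tempfile("kb_"),
                             seed = 1L, n_reactions = 6L) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(file, header, rows) {
    writeLines(c(header, rows), file.path(dir, file))
  }
  distract_compounds <- c(
    "ethanol\tCCO\tSMILES\tCHEBI:16236",
    "acetaldehyde\tCC=O\tSMILES\tCHEBI:15343",
    "acetate\tCC(=O)O\tSMILES\tCHEBI:30089",
    "toluene\tCc1ccccc1\tSMILES\tCHEBI:17578",
    "benzyl_alcohol\tOCc1ccccc1\tSMILES\tCHEBI:17987",
    "benzaldehyde\tO=Cc1ccccc1\tSMILES\tCHEBI:17169",
    "phenol\tOc1ccccc1\tSMILES\tCHEBI:15882",
    "catechol\tOc1ccccc1O\tSMILES\tCHEBI:18135"
  )
  distract_reactions <- c(
    "r_adh\tethanol\tacetaldehyde\ttrue\tEC:1.1.1.1",
    "r_aldh\tacetaldehyde|water\tacetate\ttrue\tEC:1.2.1.3",
    "r_tol_mo\ttoluene|dioxygen\tbenzyl_alcohol|water\tfalse\tEC:1.14.13.243",
    "r_badh\tbenzyl_alcohol\tbenzaldehyde\ttrue\tEC:1.1.1.90",
    "r_phe_mo\tphenol|dioxygen\tcatechol|water\tfalse\tEC:1.14.13.7"
  )
  comp_header <- "id\tstructure\tdialect\txrefs"
  rxn_header <- "id\tsubstrates\tproducts\treversible\txrefs"
  det_header <- "compound_id\teffector\ttranscription_factors\tsource"
  cof_header <- "compound_id"

  if (name == "cocaine") {
    cocaine_inchi <- paste0(
      "InChI=1S/C17H21NO4/c1-18-12-8-9-13(18)15(17(20)21-2)14(10-12)",
      "22-16(19)11-6-4-3-5-7-11/h3-7,12-15H,8-10H2,1-2H3/",
      "t12-,13+,14-,15+/m0/s1")
    tsv("compounds.tsv", comp_header, c(
      paste0("cocaine\t", cocaine_inchi, "\tInChI\tCHEBI:60056"),
      "water\tO\tSMILES\tCHEBI:15377",
      "dioxygen\tO=O\tSMILES\tCHEBI:15379",
      "benzoate\tOC(=O)c1ccccc1\tSMILES\tCHEBI:30746",
      "ecgonine_methyl_ester\tCN1C2CCC1C(C(=O)OC)C(O)C2\tSMILES\tCHEBI:32034",
      distract_compounds
    ))
    tsv("reactions.tsv", rxn_header, c(
      paste0("r_cocaine_esterase\tcocaine|water\t",
             "benzoate|ecgonine_methyl_ester\ttrue\tEC:3.1.1.84|RHEA:28690"),
      distract_reactions
    ))
    tsv("detectables.tsv", det_header, c(
      "benzoate\tbenzoate\tBenM|BenR|CbdS|PcaR|TcbR|CatR|BadR|XylS\tfixture",
      "catechol\tcatechol\tCatM|CatR\tfixture"
    ))
    tsv("cofactors.tsv", cof_header, c("water", "dioxygen"))
  } else if (name == "parathion") {
    tsv("compounds.tsv", comp_header, c(
      "parathion\tCCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]\tSMILES\tCHEBI:27928",
      "water\tO\tSMILES\tCHEBI:15377",
      "dioxygen\tO=O\tSMILES\tCHEBI:15379",
      "nitrophenol_4\tOc1ccc(cc1)[N+](=O)[O-]\tSMILES\tCHEBI:16836",
      "diethyl_thiophosphate\tCCOP(=S)(O)OCC\tSMILES\tCHEBI:62616",
      "benzoquinone_14\tO=C1C=CC(=O)C=C1\tSMILES\tCHEBI:16509",
      "nitrite\t[O-]N=O\tSMILES\tCHEBI:16301",
      distract_compounds
    ))
    tsv("reactions.tsv", rxn_header, c(
      paste0("r_phosphotriesterase\tparathion|water\t",
             "nitrophenol_4|diethyl_thiophosphate\tfalse\tEC:3.1.8.1"),
      paste0("r_nitrophenol_monooxygenase\tnitrophenol_4|dioxygen\t",
             "benzoquinone_14|nitrite|water\tfalse\tEC:1.14.13.29"),
      distract_reactions
    ))
    tsv("detectables.tsv", det_header, c(
      "nitrophenol_4\t4-nitrophenol\tDmpR\tfixture",
      "nitrite\tnitrite\tNarL\tfixture",
      "catechol\tcatechol\tCatM|CatR\tfixture"
    ))
    tsv("cofactors.tsv", cof_header, c("water", "dioxygen"))
  } else {
    acids <- list(
      acetic    = list(smiles = "CC(=O)O",            prefix = "CC(=O)O"),
      propanoic = list(smiles = "CCC(=O)O",           prefix = "CCC(=O)O"),
      butanoic  = list(smiles = "CCCC(=O)O",          prefix = "CCCC(=O)O"),
      benzoic   = list(smiles = "OC(=O)c1ccccc1",     prefix = "c1ccccc1C(=O)O")
    )
    alcohols <- list(
      methanol    = list(smiles = "CO",           alkyl = "C"),
      ethanol     = list(smiles = "CCO",          alkyl = "CC"),
      propan_1_ol = list(smiles = "CCCO",         alkyl = "CCC"),
      propan_2_ol = list(smiles = "CC(C)O",       alkyl = "C(C)C"),
      benzylic    = list(smiles = "OCc1ccccc1",   alkyl = "Cc1ccccc1")
    )
    pairs <- expand.grid(acid = names(acids), alcohol = names(alcohols),
                         stringsAsFactors = FALSE)
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(as.integer(seed))
    pick <- sort(sample(nrow(pairs), min(n_reactions, nrow(pairs))))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    comp_rows <- c(
      "water\tO\tSMILES\tCHEBI:15377",
      vapply(names(acids), function(a) {
        paste0(a, "\t", acids[[a]]$smiles, "\tSMILES\t")
      }, character(1)),
      vapply(names(alcohols), function(a) {
        paste0(a, "\t", alcohols[[a]]$smiles, "\tSMILES\t")
      }, character(1))
    )
    rxn_rows <- character(0)
    for (k in pick) {
      a <- pairs$acid[k]; b <- pairs$alcohol[k]
      ester_id <- paste0("ester_", a, "_", b)
      ester_smiles <- paste0(acids[[a]]$prefix, alcohols[[b]]$alkyl)
      comp_rows <- c(comp_rows,
                     paste0(ester_id, "\t", ester_smiles, "\tSMILES\t"))
      rxn_rows <- c(rxn_rows,
                    paste0("r_", a, "_", b, "\t", a, "|", b, "\t",
                           ester_id, "|water\ttrue\tEC:3.1.1.x"))
    }
    tsv("compounds.tsv", comp_header, comp_rows)
    tsv("reactions.tsv", rxn_header, rxn_rows)
    tsv("detectables.tsv", det_header,
        "benzoic\tbenzoate\tBenR|XylS\tfixture")
    tsv("cofactors.tsv", cof_header, "water")
  }
  invisible(dir)
}
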
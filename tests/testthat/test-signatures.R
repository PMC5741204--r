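test_that("diameter-0 signatures are bare atom-type counts", {
  s <- molecular_signature(nmol("CCO"), 0L)
  expect_equal(unname(unclass(s)[order(names(s))]), c(2L, 1L))
  expect_setequal(names(s), c("C*|", "O*|"))
})

test_that("symmetric molecules collapse to one fragment", {
  s <- molecular_signature(nmol("c1ccccc1"), 12L)
  expect_length(s, 1L)
  expect_equal(unname(bare(s)), 6L)
})

test_that("fragment counts always sum to the heavy-atom count", {
  kb_compounds <- fixture_kb("cocaine")$compounds
  for (rec in kb_compounds) {
    for (d in c(0L, 2L, 4L, 6L, 12L)) {
      s <- molecular_signature(rec$mol, d)
      expect_equal(sum(s), n_heavy_atoms(rec$mol),
                   info = paste(rec$id, "d =", d))
      expect_true(all(unclass(s) >= 1L))
      expect_true(signature_diameter_check(s, d))
    }
  }
})

test_that("ethanol central-carbon environment at diameter 2 is as forced", {
  eth <- nmol("CCO")
  # the central carbon is the one bonded to both others
  deg <- tabulate(c(eth$bonds$from, eth$bonds$to), nbins = 3)
  central <- which(deg == 2L)
  a <- atomic_signature(eth, central, 2L)
  expect_equal(a$string, "C,C*,O|1-2:1,2-3:1")
  expect_equal(a$diameter, 2L)
  # a lone root at any diameter is a root-only signature
  lone <- atomic_signature(eth, central, 0L)
  expect_equal(lone$string, "C*|")
})

test_that("atomic_signature validates its arguments", {
  eth <- nmol("CCO")
  expect_error(atomic_signature(eth, 1L, 3L), "even")
  expect_error(atomic_signature(eth, 9L, 2L), "out of range")
})

test_that("canonical signatures agree with the brute-force oracles", {
  mols <- list(nmol("CCO"), nmol("CC(C)CO"), nmol("c1ccccc1O"),
               nmol("CC(=O)OCC"), nmol("Oc1ccc(cc1)C"), nmol("OCC(O)CO"),
               nmol("CC1CCC1"), nmol("N#CCO"))
  for (d in c(2L, 4L)) {
    radius <- d %/% 2L
    for (mol in mols) {
      n <- n_heavy_atoms(mol)
      sigs <- vapply(seq_len(n), function(i) {
        atomic_signature(mol, i, d)$string
      }, character(1))
      envs <- lapply(seq_len(n), function(i) {
        oracle_environment(mol, i, radius)
      })
      small <- vapply(envs, function(e) e$n <= 8L, logical(1))
      # exhaustive-permutation oracle where feasible: equal canonical
      # signatures must coincide exactly with equal oracle strings
      if (any(small)) {
        ostr <- vapply(envs[small], oracle_canon_exhaustive, character(1))
        expect_identical(outer(sigs[small], sigs[small], "=="),
                         outer(ostr, ostr, "=="))
      }
      # VF2 isomorphism oracle for every pair (covers environments > 8 atoms)
      for (i in seq_len(n)) {
        for (j in seq_len(n)[-seq_len(i)]) {
          expect_identical(sigs[i] == sigs[j],
                           as.logical(oracle_env_isomorphic(envs[[i]],
                                                            envs[[j]])),
                           info = paste("atoms", i, j, "d", d))
        }
      }
    }
  }
})

test_that("increasing the diameter refines the induced atom partition", {
  mols <- list(nmol("CC(C)CO"), nmol("Oc1ccc(cc1)C"), nmol("CC(=O)OCC"),
               nmol("OCC(O)CO"))
  for (mol in mols) {
    n <- n_heavy_atoms(mol)
    for (d in c(0L, 2L, 4L)) {
      coarse <- vapply(seq_len(n), function(i) {
        atomic_signature(mol, i, d)$string
      }, character(1))
      fine <- vapply(seq_len(n), function(i) {
        atomic_signature(mol, i, d + 2L)$string
      }, character(1))
      # same fine fragment implies same coarse fragment
      for (f in unique(fine)) {
        expect_length(unique(coarse[fine == f]), 1L)
      }
    }
  }
})

test_that("reaction signatures: identity is empty, antisymmetry holds", {
  eth <- molecular_signature(nmol("CCO"), 4L)
  idn <- reaction_signature(list(eth), list(eth))
  expect_length(idn, 0L)

  kb <- fixture_kb("cocaine")
  for (rxn in kb$reactions) {
    fwd <- bare(rxn$sig_fwd)
    expect_identical(bare(rxn$sig_rev), -fwd[order(names(fwd))])
    expect_true(all(fwd != 0L))
  }
})

test_that("ethanol -> acetaldehyde at diameter 0 cancels (same atom types)", {
  s <- reaction_signature(list(molecular_signature(nmol("CCO"), 0L)),
                          list(molecular_signature(nmol("CC=O"), 0L)))
  expect_length(s, 0L)
  # but at diameter 2 the bond-order change is visible
  s2 <- reaction_signature(list(molecular_signature(nmol("CCO"), 2L)),
                           list(molecular_signature(nmol("CC=O"), 2L)))
  expect_gt(length(s2), 0L)
})

test_that("hydrolysis signature consumes the ester linkage of cocaine", {
  kb <- fixture_kb("cocaine")
  delta <- unclass(kb$reactions$r_cocaine_esterase$sig_fwd)
  neg <- names(delta)[delta < 0]
  csig <- kb$signatures$cocaine
  expect_gt(length(neg), 0L)
  expect_true(any(neg %in% names(csig)))
})

test_that("mixed diameters are rejected", {
  a <- molecular_signature(nmol("CCO"), 2L)
  b <- molecular_signature(nmol("CC=O"), 4L)
  expect_error(reaction_signature(list(a), list(b)), "diameter")
  expect_false(signature_diameter_check(a, 4L))
  expect_true(signature_diameter_check(a, 2L))
})

test_that("two-step reaction signatures telescope to the net transformation", {
  kb <- fixture_kb("parathion")
  s <- kb$signatures
  net <- reaction_signature(
    list(s$parathion, s$water, s$dioxygen),
    list(s$diethyl_thiophosphate, s$benzoquinone_14, s$nitrite, s$water)
  )
  two_step <- sempfinder:::.frag_sum(
    bare(kb$reactions$r_phosphotriesterase$sig_fwd),
    bare(kb$reactions$r_nitrophenol_monooxygenase$sig_fwd)
  )
  expect_identical(two_step[order(names(two_step))], bare(net))
})

test_that("signature text serialization round-trips", {
  s <- molecular_signature(nmol("CC(=O)OCC"), 4L)
  txt <- signature_to_text(s)
  back <- signature_from_text(txt, 4L, "mol")
  expect_identical(unclass(back), unclass(s))
  r <- fixture_kb("cocaine")$reactions$r_adh$sig_fwd
  expect_identical(unclass(signature_from_text(signature_to_text(r), 12L,
                                               "rxn")),
                   unclass(r))
})
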
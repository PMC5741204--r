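---
title: "Signature-based design of sensing-enabling metabolic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based design of sensing-enabling metabolic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sempfinder)
```

## The method

A whole-cell biosensor senses a small molecule through an allosteric
transcription factor (TF) whose effector it is. Most compounds of interest
have no known effector/TF pair, but many are one or two enzymatic steps away
from one. `sempfinder` searches a knowledge base of enzymatic reactions for
such *sensing-enabling metabolic pathways* (SEMPs): short transformation
chains from a query compound to a registered detectable compound.

### Compound encoding

Structures (InChI or SMILES) are normalized before encoding: the largest
covalent fragment is kept, formal charges are neutralized where a valid
valence model permits, aromaticity is perceived (Kekulé rings become aromatic
bonds), explicit hydrogens are removed, and stereo descriptors are retained
on the stored structure. Charge removal unifies protonation states — acetate
and acetic acid map to the same record — which matters because matching and
deduplication operate on structures, not on database identifiers.
Charge-separated groups that cannot be neutralized without a valence
violation (the nitro group is the canonical case) keep their formal charges;
since the fragment alphabet below ignores charge, this has no effect on
encoding, only on the stored structure.

The normalized heavy-atom graph is encoded as a **molecular signature**: for
each atom, the subgraph induced by all atoms within `diameter/2` bonds is
serialized canonically (atom label = element + aromatic flag; bond label =
order; the root is marked), and the molecule is the multiset of these
**atomic signatures**. The sum of multiset counts always equals the
heavy-atom count. Environments truncated by the molecule boundary are encoded
as-is, unpadded, so fragments from small molecules never collide with
truncated views of larger ones.

Canonicalization uses colour refinement (Morgan-style, with the root
individualized) plus exhaustive branching on residual ties, taking the
lexicographically smallest serialization. This is exact — equal strings if
and only if the rooted environments are isomorphic — and fast at the
environment sizes that occur here; the test suite pins it against two
independent oracles (exhaustive-permutation canonization up to 8 atoms, and
colored VF2 isomorphism up to 12).

Stereochemistry is deliberately excluded from fragment labels and from the
canonical structure key even though it is retained in stored structures: the
encoding is constitution-based, like ECFP, and nothing downstream (matching,
resolution, dedup) distinguishes stereoisomers. This is the package's
resolution of a genuinely open design point; making dedup stereo-aware would
require stereo-aware fragments to stay consistent.

### Reaction encoding and matching

A reaction with substrate signatures σ(S_j) and product signatures σ(P_i) is
the signed multiset σ(R) = Σσ(P_i) − Σσ(S_j) at a shared diameter. A query
compound *C* matches *R* when

1. every fragment consumed by σ(R) (its negative part) is available in the
   multiset union of *C* and *R*'s co-substrates, and
2. *C* itself covers at least one consumed fragment (it participates in the
   reaction centre rather than free-riding on co-substrates).

The putative products are then *P = C ⊎ co-substrates + σ(R)*, a positive
fragment multiset. The application is accepted only if *P* resolves into an
exact multiset partition over known compounds' signatures — de novo structure
generation from fragments is out of scope, matching the reference method.

The diameter is the promiscuity dial: at diameter 12 (radius 6, the default)
a reaction signature nearly pins down its canonical substrate; lower
diameters encode only the reaction centre's vicinity and admit structurally
similar substrates. Lowering the diameter never shrinks the set of matching
compounds (tested as a property).

### Design choices in matching

* **Co-substrates.** The source method matches single query compounds
  against multi-reactant signatures without stating how the other reactants
  are handled. Here each reaction record designates a primary substrate
  (first in the file); the rest are co-substrates whose signatures are taken
  from the knowledge base and assumed available (water, O₂, etc. — typically
  also declared cofactors). A query is tested in the primary role.
* **Directionality.** Enzymatic reactions are treated as reversible unless
  flagged otherwise (`--forward-only` disables reverse use globally). The
  reverse signature is the negation; the first product acts as the reverse
  primary.
* **Resolution caps.** Product resolution backtracks over candidates indexed
  by the rarest unexplained fragment, with at most 3 compounds per product
  set and 100 product sets per application. These bounds exist to tame
  pathological inputs; correctness within the bounds is pinned by a
  brute-force partition oracle at small scale. Partial resolution (leftover
  fragments) is never accepted.
* **Diagnostics.** A match whose products do not resolve is recorded (it can
  be logged via `write_match_log`) but contributes no graph edge.

### Graph expansion and SEMP extraction

Expansion is breadth-first from the target, depth-bounded at 1 or 2 steps.
Every compound of every resolved product set becomes a node; each (reaction
application, product) pair becomes its own directed edge, so a two-product
hydrolysis shows two edges sharing a reaction id. Cofactors (water, O₂, …)
become nodes but are never expanded and never count as detectable endpoints —
otherwise every hydrolysis would "detect" water.

Detectability is annotated per node as the maximum Jaccard–Tanimoto
similarity against the detectable registry, computed on hashed circular
fingerprints built from this package's own fragments at diameters {0, 2, 4}
(an ECFP4 analogue; 2048 bits; stable polynomial string hash, so fingerprints
are identical across runs and platforms). Exact structural identity
(canonical-key equality) scores 1 regardless of hashing. Two thresholds
apply:

* `threshold` (default **1.0**): a node is a SEMP endpoint only on an exact
  structural match. The reference annotates "identical or highly similar"
  structures but warns that promiscuous detection must be checked in the
  literature, so near-matches are advisory by default.
* `near_threshold` (default **0.9**): near-detectables are reported in the
  search summary but do not form pathways.

A SEMP is a simple path of length ≤ 2 from the target to a flagged node,
grouped by endpoint and ordered by (length, similarity descending, reaction
ids); a target that is itself detectable is reported separately rather than
as a zero-step pathway.

## The knowledge base and its fixtures

The registry is four UTF-8 TSV files (compounds, reactions, detectables,
cofactors). Compounds are deduplicated by canonical structure key with
cross-references unioned; reactions referencing unknown or unparsable
compounds are rejected into a report, never silently dropped; detectable
membership follows the canonical structure, not the id string. The full
corpus behind the original service (10⁵ compounds, 8.7 × 10⁴ reactions, 504
detectables from Rhea/MetaCyc/BRENDA/BBD and four regulation databases) is
out of scope; `build_fixture_kb()` generates self-contained knowledge bases
instead:

* **cocaine** — cocaine (by its standard InChI), water, benzoate and ecgonine
  methyl ester with the esterase hydrolysis, benzoate detectable via its
  eight known TFs, plus five distractor reactions over eight distractor
  compounds (alcohol/aldehyde oxidations, aromatic hydroxylations).
* **parathion** — the phosphotriesterase step to 4-nitrophenol (DmpR) and the
  monooxygenase step to benzoquinone + nitrite (NarL), with the same
  distractor set. NAD(P)H is omitted from the monooxygenase: after
  charge/hydrogen removal NADP⁺ and NADPH have identical heavy-atom graphs,
  so the pair cancels in the reaction signature anyway.
* **random** — a seed-reproducible esterification network (acid + alcohol →
  ester + water over a small alkyl pool). Esterifications were chosen
  because they are heavy-atom balanced by construction, giving chemically
  sane synthetic reactions whose closure is guaranteed; the seed only picks
  which acid/alcohol pairs are included.

All fixture reactions are written heavy-atom balanced, so the closure
property (a reaction applied to its own substrates resolves exactly to its
recorded products) holds by construction and is regression-tested for every
reaction. What a green fixture suite does **not** establish: behaviour on
curated-database noise (unbalanced or generic reactions, polymer stubs,
missing structures beyond the rejection path), multi-thousand-compound index
performance, or the biological validity of any predicted pathway — the
method proposes candidates; enzyme availability, toxicity and TF dose
response remain user-side checks.

## Numerical and degenerate-case choices

* Diameter must be even and non-negative; odd values are errors, not rounded.
* An empty reaction signature (products ≡ substrates after normalization,
  e.g. ethanol → acetaldehyde at diameter 0) is rejected at load time: it
  would match everything and produce identity applications.
* `resolve_products` of an empty multiset returns one empty product set
  (degenerate acceptance); an unresolvable multiset returns an empty list
  (rejection), which is a result, not an error.
* Tanimoto of two empty fingerprints is defined as 1 (both "moleculeless").
* Ties everywhere (product sets, SEMP ordering, GML node order) break
  lexicographically by id, which is what makes repeated runs byte-identical.
* The fingerprint hash is a fixed-seed polynomial hash modulo a prime below
  2²⁵ so all arithmetic is exact in doubles; collisions only ever inflate
  similarity, never break the self-similarity identity, and exact identity
  is decided by canonical key before hashing.

## A worked search

```{r example, eval = FALSE}
kb_dir <- build_fixture_kb("parathion")
res <- run_search("parathion", kb_dir, steps = 2,
                  out_gml = "parathion.gml",
                  out_pathways = "parathion_pathways.tsv")
cat(res$summary, sep = "\n")
```

The summary reports the knowledge-base sizes, the graph size, and one
pathway per detectable endpoint: a 1-step SEMP to 4-nitrophenol and a 2-step
SEMP to nitrite through 4-nitrophenol (the quantities recomputed by
`scripts/acceptance.R`). The GML file round-trips through `read_gml()` and
re-export byte-identically.

## Limitations

* Product resolution only ever returns known compounds: a transformation
  whose true product is absent from the knowledge base is rejected, which is
  conservative by design.
* Matching at the default diameter 12 assumes low enzymatic promiscuity;
  promiscuity modelling requires deliberately lowering the diameter, which
  also raises false-positive matches.
* Stereochemistry never distinguishes compounds during matching or dedup.
* Charge handling follows a valence-safe neutralization; exotic zwitterions
  are kept as drawn, so two resonance drawings that RDKit does not unify
  would be distinct records.
* The Python/RDKit subprocess is a hard runtime dependency for parsing; no
  pure-R fallback exists.
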
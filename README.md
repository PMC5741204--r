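# sempfinder

Design of **sensing-enabling metabolic pathways (SEMPs)** for whole-cell
biosensors.

## The problem

Genetically encoded biosensors — typically an allosteric transcription factor
(TF) wired to a reporter promoter — can only detect the limited set of small
molecules for which a natural effector/TF pair is known. When a target
compound has no direct biosensor, it may still be detectable *indirectly*: one
or two enzymatic steps can convert it into a known TF effector, and the
enzymes plus the sensing circuit can be assembled in a chassis such as
*E. coli*. `sempfinder` screens a knowledge base of enzymatic reactions for
exactly such short transformations.

## The model

Compounds are normalized (aromatic form, charges and hydrogens removed,
stereochemistry retained) and encoded as **molecular signatures**: multisets
of canonical atomic environments ("atomic signatures", one per heavy atom, an
unhashed circular-fingerprint analogue) at a configurable bond diameter *d*
(default 12, i.e. radius 6). A reaction *R* with substrates *S_j* and products
*P_i* is encoded as the signed fragment difference

    σ_d(R) = Σ_i σ_d(P_i) − Σ_j σ_d(S_j)

A query compound *C* **matches** *R* when *C* (together with *R*'s declared
co-substrates) embeds the negative part of σ_d(R); then *C + σ_d(R)* is a
positive fragment multiset of putative products, and the application is
**accepted** only if that multiset resolves exactly into known compounds of
the knowledge base. Because a low diameter encodes only the reaction centre's
neighbourhood, this models enzymatic promiscuity: the smaller *d*, the more
substrates a reaction signature admits. Breadth-first application of all
reaction signatures around the target (depth ≤ 2) yields a metabolic graph;
nodes structurally identical or similar (Jaccard–Tanimoto over hashed
circular fingerprints, ECFP4-style) to a registered detectable compound are
flagged, and every simple path from the target to a flagged node is reported
as a SEMP.

Structure parsing/normalization is delegated to RDKit through a bundled
Python helper (`python` with `rdkit` must be on `PATH`); everything else —
signatures, matching, expansion, similarity, exports — is plain R.

## Worked example

The packaged cocaine fixture contains the cocaine-esterase hydrolysis
(cocaine + H₂O → benzoate + ecgonine methyl ester), benzoate registered as a
TF effector, and several distractor compounds and reactions:

```r
library(sempfinder)
kb_dir <- build_fixture_kb("cocaine")
res <- run_search("CHEBI:60056", kb_dir, steps = 1)
cat(res$summary, sep = "\n")
for (p in res$semps) print(p)
```

```
config: steps=1 diameter=12 threshold=1 near=0.9 width=2048 bidirectional
knowledge base: 13 compounds, 6 reactions, 2 detectables, 0 rejected rows
target: cocaine
graph: 3 nodes, 2 edges
SEMPs found: 1
  endpoint benzoate: 1 pathway(s)
<SEMP001> benzoate [1 step(s), endpoint benzoate, similarity 1, TFs: BenM|BenR|CbdS|PcaR|TcbR|CatR|BadR|XylS]
```

The graph has one reaction application with two duplicated product edges
(benzoate, ecgonine methyl ester); benzoate scores Tanimoto 1 against the
detectable registry, so the hydrolysis is a one-step SEMP and any of the
listed benzoate-responsive transcription factors (e.g. BenR with its pBen
promoter) can serve as the sensing module. On the parathion fixture the same
search at `steps = 2` finds the phosphotriesterase step to 4-nitrophenol
(DmpR) and, through a monooxygenase, a two-step pathway to nitrite (NarL):

```
SEMPs found: 2
  endpoint nitrite: 1 pathway(s)
  endpoint nitrophenol_4: 1 pathway(s)
```

The same flow is available from the shell:

```sh
Rscript inst/cli/sempfinder.R fixture --name parathion --out /tmp/kb
Rscript inst/cli/sempfinder.R search --target parathion --kb /tmp/kb \
    --steps 2 --out-gml /tmp/graph.gml --out-pathways /tmp/pathways.tsv
```

`--out-gml` writes the whole expansion graph as a standard Graph Markup
Language file; `--out-pathways` writes the pathway table (one row per step,
with reaction cross-references, effectors and TF names).

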
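---
title: "Knowledge-based candidate ligand prediction with ligscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based candidate ligand prediction with ligscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligscout)
```

## The problem

Crystallographers and structural biologists routinely need plausible
small-molecule binding partners for a protein before running expensive
co-crystallization or soaking experiments. When homologous protein–ligand
complexes exist, their bound ligands — together with literature-derived
compound associations — are a rich, underused source of candidates.
`ligscout` automates that mining step from sequence alone: it requires no
structure of the query, only a local library of PDB-format complexes,
per-chain domain annotations, and optional compound-source tables
(ChEMBL/ChEBI/KEGG-style exports).

The output is not a binding-site prediction and not a docking score: it is
a ranked, clustered list of candidate molecules, where the ranking encodes
how well each ligand's observed protein contacts are conserved in the
query sequence.

## The workflow

1. **Homolog search.** The query is aligned against every polymer chain of
   the library by optimal local (Smith–Waterman) alignment under BLOSUM62
   with affine gap penalties (open 11, extend 1 — the de facto protein
   search defaults; configurable). The top 20 hits are retained.
2. **Compound sources.** Records associated with those homologs are kept,
   then filtered: ChEMBL-style records must carry a binding constant and
   an IC50 of at most 100 nM (strictly "more than 100 nM" is excluded);
   ChEBI-style records must have at least 4 atoms *and* at least 50 Da.
   KEGG-style records pass unfiltered. The union is deduplicated by exact
   graph identity, the record with the most metadata surviving a
   collision (binding constant beats cross-reference count beats
   first-seen).
3. **Domain partition.** Homolog domain annotations are transferred to the
   query through the pairwise alignments, most similar homolog first, and
   accepted only if they do not overlap a previously assigned domain.
   Unassigned runs of more than 100 residues become domains of unknown
   type; internal linkers are split at their midpoint between the
   flanking domains; terminal runs merge into their single neighbour, so
   the partition always covers the query exactly once.
4. **Per-domain structure search.** Each predicted domain is searched
   against a database holding both full-chain sequences and per-domain
   sequences (a split domain contributes one concatenated entry, so
   discontinuous domains remain findable). The best-scoring hit structure
   is the reference; all other hits are superposed onto it.
5. **Superposition.** Rigid-body least-squares (Kabsch) fitting on the
   main-chain atoms (N, CA, C, O) of residues equivalenced through the
   query-anchored multiple alignment. While the RMSD is at or above the
   cutoff (12 Å by default), the worst 10% of residue pairs (at least
   one) are removed and the fit repeated; fewer than 3 surviving pairs is
   reported as failure. This absorbs alignment errors; the RMSD is
   non-increasing across iterations by construction.
6. **Interaction scoring.** For every ligand of every hit structure,
   hydrogen bonds (polar N/O/S heavy-atom pairs within 3.35 Å) and
   nonbonded contacts (any heavy-atom pair within 3.9 Å, at most one per
   protein residue, and never for a residue that already hydrogen-bonds
   the ligand) are detected in the complex's own frame. Each interaction
   is weighted by the conservation of the contacted residue relative to
   the query through the alignment: hydrogen bonds score 3/2/1/−1 for
   identical/similar/other/gap, contacts 2/1/0/−1. The ligand's
   *achieved* score is the weighted sum; its *maximum* is the ceiling the
   same interactions would reach were every contacted residue identical
   (3 per hydrogen bond, 2 per contacted residue). Scores from separate
   domain searches of the same ligand instance are merged so each residue
   counts once, keeping the best conservation class seen for each
   interaction — a residue aligns in the domain that owns it and shows as
   a gap from every other domain's search.
7. **Clustering and ranking.** All candidates (structure-derived ligands
   plus surviving source compounds) are clustered by
   maximum-common-subgraph Tanimoto similarity, |MCS| / (|A| + |B| −
   |MCS|) over heavy atoms, with complete linkage at a 0.4 cutoff — every
   pair inside an emitted cluster is at least 0.4 similar. Clusters with
   structure-derived members rank first by their best achieved score;
   within a cluster, structure-derived ligands come first by achieved
   score, and source compounds follow by associated-protein identity,
   then cross-reference count. All ties break deterministically by
   identifier.

```{r example}
ss <- makeStudySet(seed = 1)
res <- runPipeline(ss$query, ss$structures, ss$annotations, ss$compounds)
head(resultTable(res)[, c("cluster_rank", "ligand_id", "source",
                          "score_achieved", "score_max",
                          "assoc_identity_pct")])
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `topN` | 20 | homolog hits retained by the sequence search |
| `rmsdCutoff` | 12 Å | superposition convergence threshold |
| `clusterCutoff` | 0.4 | minimum intra-cluster pairwise similarity |
| `hbondMaxDist` | 3.35 Å | polar-pair hydrogen-bond distance |
| `contactMaxDist` | 3.9 Å | heavy-atom contact distance |
| `unknownDomainMin` | 100 | unassigned run length that forms an unknown domain |
| `minMappedDomain` | 20 | minimum mapped residues for a transferred domain segment |
| gap penalties | 11 / 1 | affine gap open / extend (BLOSUM62) |

The 12 Å RMSD threshold is unusually permissive for a convergence
criterion; it is kept as the method's stated default and exposed through
`PipelineConfig` so stricter values (e.g. 1.2 Å) can be used. The
hydrogen-bond criterion is distance-only between polar heavy atoms:
deposited crystal structures rarely include hydrogens, so no angle term is
applied, mirroring common distance-based practice.

## Design choices where the method left room

* **Conservation classes.** "Similar" means a positive BLOSUM62 score and
  not identical; "gap" means the contacted hit residue aligns to no query
  position.
* **Score reading.** The score pair is reported as achieved/maximum; a
  hit identical to the query attains its ceiling by construction, which
  is the anchor for interpreting the pair.
* **Contact bookkeeping.** Each hydrogen bond counts individually; several
  contacts to one residue count once (closest pair kept); a residue with
  a hydrogen bond accrues no additional contact score, preventing double
  counting.
* **MCS semantics.** The maximum common *connected induced* subgraph
  under element and bond-order matching (aromatic is its own order;
  formal charge ignored), computed exactly by branch-and-bound up to 60
  heavy atoms per molecule and by a flagged node-budgeted fallback above
  that. Single-atom metal ions cluster like any other graph.
* **Complete linkage.** The "most distant members ≥ 0.4" criterion is
  exactly complete-linkage agglomeration; average or single linkage would
  violate it. Merges happen in decreasing complete-link similarity with
  lexicographic tie-breaks, so the clustering is fully deterministic.
* **Domain transfer.** Annotation coordinates transfer through the
  pairwise alignment as the minimal query interval covering each mapped
  segment; fragments mapping fewer than 20 residues are dropped as noise.
  Overlap with an already-assigned domain rejects the whole domain
  (strict zero overlap). Odd linkers give their extra residue to the
  N-terminal side. Terminal unassigned runs of 100 residues or fewer
  merge into their single neighbour — the midpoint rule only defines
  internal linkers, and leaving terminal residues unowned would break
  the exact-cover invariant. A query with nothing assigned and 100 or
  fewer residues still becomes one unknown-type domain for the same
  reason.
* **Structure-derived ligand graphs.** HETATM groups carry no connection
  table, so bonds are inferred from covalent radii (r1 + r2 + 0.45 Å,
  order 1). Bond orders are therefore unknown for structure-derived
  ligands, which slightly depresses their similarity to source compounds
  with explicit double/aromatic bonds.
* **Identity reported per candidate** is the full-chain identity of its
  source structure's alignment to the query (over aligned, gap-free
  columns, the natural local-alignment reading) rather than the identity
  of a possibly very short domain alignment.

## What the synthetic generator emulates — and what it does not

`makeComplex` builds an idealized extended chain (3.8 Å CA spacing, fixed
N/C/O offsets) and places ligand atoms to realize each planted hydrogen
bond or contact at its stated distance; the geometry guarantees that a
planted interaction at one residue creates no accidental interaction at
any other residue. `makeHomolog` mutates a sequence to a target identity
(within 2 points) outside declared conserved positions, recording each
substitution's matrix sign so conservation classes are part of the ground
truth. `makeMoleculeSeries` deletes one removable atom per step, giving a
series whose Tanimoto similarity to the base is exactly (n−k)/n.
`makeStudySet` combines these into the package's standard study
conditions: a 120-residue query, homologs at 90/60/30% identity sharing a
conserved five-residue binding site (three hydrogen bonds, two contacts —
score ceiling 13), one homolog rigid-body transformed, one carrying a
split domain annotation, and a six-compound source table with one
cross-source duplicate, one too-weak affinity and one sub-50 Da record.

These fixtures are *not* realistic proteins: no side chains, no secondary
structure, no crystallographic noise, no alternate conformations beyond
what the parser handles, and planted interactions are geometrically
isolated. Passing tests therefore demonstrate the correctness of the
bookkeeping — detection thresholds, conservation transfer, score
arithmetic, trimming, clustering and ranking — not the biological hit
rate on real data, which depends on library depth and homolog coverage.
The sparse planted-interaction atoms also mean that a fixture ligand
re-read from PDB text yields a bond-less point cloud, so graph identity
of structure-derived fixture ligands is only preserved when the generator
attaches the molecule graph explicitly (as `makeStudySet` does).

## Numerical choices

Coordinates are compared at 1e-3 Å through PDB round-trips (the format's
own precision). Kabsch fitting uses the SVD construction with the
determinant sign correction, so reflections are never returned; rotation
recovery is tested to 1e-6. The outlier-trimming schedule (worst 10% per
iteration, at least one pair, floor of three) guarantees termination.
Alternate locations keep the highest-occupancy conformer, first-seen on
ties. Percent identity is computed over aligned columns and reported to
one decimal. All orderings (hits, clusters, members) end in an identifier
comparison, so the whole pipeline is byte-deterministic: two runs on
identical inputs produce identical TSVs.

Problem sizes used in the shipped tests and acceptance script — a
120-residue query over a four-structure library with ~10 heavy-atom
molecules, alignment oracles at ≤15-mers (100 trials), MCS oracles at ≤8
atoms (200 trials), fitting oracles at 1000 trials, 500 random partition
scenarios — were chosen so each oracle comparison runs exhaustively while
the whole suite stays comfortably interactive.

## Known limitations

* Hit-structure residue numbering is assumed consistent with the chain's
  sequence order (true of the generator and most deposited entries);
  heavily renumbered chains would need an explicit position map, which
  `classifyConservation` accepts as a function argument.
* Only the first NMR model is read; mmCIF is not parsed.
* No E-value statistics: ranking is by raw Smith–Waterman score, so hit
  lists of very different database sizes are not directly comparable.
* logP and polar surface area are delegated to OpenBabel when available
  and reported as NA otherwise; they do not enter the ranking.
* The interaction score rewards larger ligands (more interactions, higher
  ceiling); the achieved/maximum pair should be read together.
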
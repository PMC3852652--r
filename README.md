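# ligscout

Knowledge-based prediction of candidate ligands for a protein target,
from sequence alone.

Given a query protein sequence (or a structure, from which the sequence
is extracted), a local library of PDB-format protein–ligand complexes,
per-chain domain annotations and optional compound-source tables
(ChEMBL/ChEBI/KEGG-style exports), `ligscout` returns a ranked, clustered
list of small molecules likely to bind the query. It is aimed at
structural biologists assembling co-crystallization or soaking panels,
and at anyone triaging "what might this protein bind?" questions for
proteins with or without a solved structure.

## The method

The pipeline finds the query's homologs among the library chains by
optimal local alignment (Smith–Waterman, BLOSUM62, affine gaps 11/1, top
20 hits), partitions the query into predicted domains from the homolog
annotations (zero-overlap transfer in rank order; unassigned runs > 100
residues become unknown-type domains; linkers split at their midpoint),
searches each domain against a full-chain + per-domain sequence database,
and superposes every hit structure onto the best-scoring reference by
iterative Kabsch fitting on equivalenced main-chain atoms, trimming the
worst 10% of residue pairs per iteration until the RMSD falls below 12 Å.

Every ligand of every hit structure is then scored by its interactions
with its own protein, weighted by how conserved each contacted residue is
in the query through the alignment:

    achieved = Σ_hbonds  w(class) + Σ_contact residues  v(class)
    w = 3 / 2 / 1 / −1   (identical / similar / other / gap)
    v = 2 / 1 / 0 / −1

with hydrogen bonds as polar (N/O/S) heavy-atom pairs ≤ 3.35 Å, contacts
as heavy-atom pairs ≤ 3.9 Å counted once per residue (never for a residue
that already hydrogen-bonds the ligand). The *maximum* score is the
ceiling the same interactions would reach if every contacted residue were
identical: `3·#hbonds + 2·#contact residues`. Scores from separate domain
searches of one ligand are merged so each residue counts once at its best
conservation class.

All candidates — structure-derived ligands plus filtered source compounds
(IC50 ≤ 100 nM with a binding constant for ChEMBL-style records; ≥ 4
atoms and ≥ 50 Da for ChEBI-style; duplicates removed by graph identity)
— are clustered by maximum-common-subgraph Tanimoto similarity,
|MCS|/(|A|+|B|−|MCS|) over heavy atoms, with complete linkage at 0.4, so
every pair inside a cluster is at least 40% similar. Clusters rank by
their best achieved score; source compounds follow the scored ligands
within each cluster, ordered by associated-protein identity and then
cross-reference count.

## Worked example

The package ships a synthetic study-set generator with known ground
truth: a 120-residue query, homolog complexes at 90/60/30% identity
sharing a conserved binding site (three hydrogen bonds + two contacts,
score ceiling 13), and a six-compound source table.

```r
library(ligscout)
ss  <- makeStudySet(seed = 1)
res <- runPipeline(ss$query, ss$structures, ss$annotations, ss$compounds)
resultTable(res)[, c("cluster_rank", "ligand_id", "source",
                     "score_achieved", "score_max", "structure_id",
                     "assoc_identity_pct")]
#>   cluster_rank ligand_id source score_achieved score_max structure_id assoc_identity_pct
#> 1            1       LIG    pdb             13        13          h30               30.3
#> 2            1       LIG    pdb             13        13          h60               61.5
#> 3            1       LIG    pdb             13        13          h90               90.0
#> 4            1       LIG    pdb             13        13         self              100.0
#> 5            1 cmp_near1 chembl             NA        NA         <NA>               90.0
#> 6            1 cmp_near2  chebi             NA        NA         <NA>               90.0
#> 7            2   cmp_far   kegg             NA        NA         <NA>               61.5
```

Every planted complex achieves its score ceiling of 13 because the
binding-site residues are conserved in all homologs — down to 30% overall
identity — so the ligand ranks first with `achieved = maximum`; the
structure identical to the query reports 100% identity. The two source
compounds most similar to the planted ligand join its cluster (rank 1);
the unrelated benzene scaffold forms its own cluster (rank 2). Compounds
failing the activity or size filters (`cmp_weak`, IC50 500 nM;
`cmp_small`, 18 Da) and the cross-source duplicate never appear.
Comparing against the known cognates:

```r
evaluateAgainstCognates(res, ss$cognates)$per_cognate
#>   cognate_id best_similarity best_candidate cluster co_members
#> 1        LIG               1  h30:LIG:A:501      C2          5
#> 2     LIG-d1               1      cmp_near1      C2          5
```

A command-line front end is installed as `exec/ligscout`
(`ligscout run`, `ligscout evaluate`, `ligscout fixtures`).

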
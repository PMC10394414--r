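---
title: "Mining and comparing assembly-line PKS clusters: methods and design notes"
author: "pksminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparing assembly-line PKS clusters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksminer)
```

## The problem

Assembly-line (modular) polyketide synthases (PKSs) are giant multi-protein
enzymes in which each module — minimally a ketosynthase (KS), usually an
acyltransferase (AT), and an acyl carrier protein (ACP), often with
ketoreductase (KR), dehydratase (DH), enoylreductase (ER) or
methyltransferase (MT) tailoring domains — extends a growing polyketide
chain by one cycle. Because the KS domain is the most conserved part of
every module, a consensus KS protein makes an effective probe for finding
assembly lines in raw nucleotide data. `pksminer` implements the full
catalogue-construction workflow around that idea: KS scanning, locus
merging, cluster calling, architectural classification, two rounds of
redundancy elimination, pairwise similarity analysis (networks, dendrogram,
rediscovery and novelty statistics), and detection of GRINS — genetic
repeats of intense nucleotide skews — plus a ground-truthed synthetic data
generator that makes every stage testable without touching an external
database.

## Pipeline model

1. **KS scanning** (`scan_ks`). All six reading frames of a record are
   translated and locally aligned against the consensus KS (BLOSUM62,
   affine gaps, open 11 / extend 1 — the conventional protein-search
   parameters). Within each frame the best local alignment is recorded,
   masked, and the frame re-scanned, so multiple KS copies per frame are
   recovered. Hits need a raw score of at least `min_score` (default 200)
   over at least `min_len_aa` aligned residues (default 150). A full-length
   KS match scores in the thousands while the best chance alignment on
   random sequence stays below roughly 60, so the default is conservative
   in both directions. Minus-strand hits are mapped back to plus-strand
   intervals; all internal coordinates are 0-based half-open.

2. **Discretization** (`discretize_hits`). Hits whose inter-interval gap is
   at most `min_separation` (default 3000 bp) merge transitively into one
   discrete KS locus; distinct loci are therefore separated by more than
   3 kbp. The gap is measured end-to-start, not midpoint-to-midpoint; a gap
   of exactly 3000 bp merges. This both collapses repeated hits against one
   KS and keeps single-KS loci (fatty-acid synthases, iterative PKSs) from
   inflating cluster calls.

3. **Cluster calling** (`call_candidate_clusters`). KS loci are chained
   while consecutive gaps are at most `max_gap` (default 20 kbp, boundary
   inclusive); chains with at least `min_ks` loci (default 3) become
   candidate clusters. Chaining, rather than requiring all pairs to be
   within 20 kbp, is deliberate: an all-pairs rule would cap cluster span
   at 20 kbp, while real assembly lines routinely exceed that.

4. **Classification** (`classify_cluster`). Modules are delimited KS-to-KS
   over the annotations in protein order. A module owning an AT is cis-AT,
   otherwise trans-AT; any C/A/PCP domain marks NRPS (hybrid) character;
   clusters with no AT and no ACP anywhere are unclassifiable as PKS
   modules and fall to "other hybrid". This yields the seven-way scheme:
   {cis, trans, mixed} × {PKS, PKS-NRPS hybrid}, plus "other hybrid".

5. **Exact deduplication** (`dedup_identical`). Within a species, clusters
   equal by nucleotide containment (either strand) *or* by domain
   architecture signature collapse to one representative (longest span,
   then earliest deposit, then smallest id). Architecture equality ignores
   coordinates on purpose: duplicate unassembled contigs shift coordinates
   but not domain order. Unknown species never collapse.

6. **Similarity scoring** (`pairwise_similarity`). The directed score
   S(a→b) sums, over the proteins of *a*, the identity fraction of each
   protein's best local alignment against any protein of *b* multiplied by
   the residues that alignment covers, normalised by *a*'s total residue
   count; the reported score is the mean of the two directions, in
   percent. Local alignment is essential — domains and whole modules
   repeat, so global alignment over-penalises architectural rearrangement.
   Each query residue counts at most once (one best alignment per protein,
   no HSP tiling); this is the simplest contract consistent with
   local-alignment scoring, and the mean-of-directions normalisation is a
   documented package decision. Identical clusters score exactly 100;
   random unrelated protein sets score in single digits; homologs at 5%
   amino-acid divergence score ≈95.

7. **Redundancy pruning** (`remove_redundant`). A greedy sweep in priority
   order (earliest deposit, longest protein complement, then id) retains a
   cluster iff it scores at most the redundancy threshold (default 90%)
   against everything already retained. The sweep is deliberately not
   transitive: in a chain A~B, B~C with A and C dissimilar, B is removed
   and both A and C stay. The retained set's pairwise maximum is ≤90 and
   every removed cluster maps to a retained partner above 90 (the cover
   property, asserted in the test suite).

8. **Networks and dendrogram** (`build_network`, `build_dendrogram`).
   Edges require similarity *strictly* greater than the network threshold
   (default 50%); singleton nodes are the deorphanization candidates. The
   dendrogram is UPGMA (average linkage) on the distance 100 − similarity,
   serialised as Newick; UPGMA is chosen because the catalogue artefact is
   distance-based and ultrametric trees display uniformly.

9. **GRINS detection** (`detect_grins`). A GRINS is called where a
   sustained skewed region and an internal repeat coincide. Skew profiles
   use 150 bp windows at 30 bp steps; candidate regions are maximal runs
   of windows where |GC skew| and |TA skew| both reach 0.25 with constant
   signs, spanning ≥700 bp (operationalising "approximately 1 kbp").
   Internal repeats are found with exact 16-mer seeds off the
   self-diagonal, chained per diagonal, greedily extended, and scored by
   per-site identity (≥90% over ≥700 bp, direct repeats). A skewed region
   with ≥50% reciprocal overlap with one repeat copy is reported as a
   GRINS, carrying its partner span and repeat identity.

10. **Catalogue statistics** (`discovery_timeseries`, `doubling_time`,
    `type_distribution`, `orphan_fraction`, `cluster_histogram`,
    `phylum_distribution`, `rediscovery_rate`, `nearest_characterized`,
    `novelty_fraction`). Doubling time is ln 2 divided by the slope of an
    ordinary least-squares fit of log cumulative counts on year, over the
    years with positive counts (fitting on cumulative rather than
    incremental counts is the package's choice; the series is much less
    noisy). Year-only deposit dates resolve to July 1 so they land
    mid-year. The rediscovery series orders clusters by date (ties by id)
    and counts a cluster as rediscovered iff it exceeds the redundancy
    threshold against any earlier cluster. Novelty is the percentage of
    orphans whose best characterized neighbour scores strictly below 50%;
    a score of exactly 50 is not novel.

## The synthetic-data generator

`generate_cluster` emits records that reproduce the statistical structure
the pipeline exploits, with a truth manifest (KS spans, domain
annotations, protein placements, GRINS plants, expected type label) that
scores every stage without re-deriving ground truth:

* **Module grammar.** Per-module domain blocks (KS, optional AT, optional
  KR/DH, ACP, terminal TE; C–A–PCP modules in hybrids) are emitted in
  order, packed into proteins (default two modules per protein) separated
  by intergenic spacers, with background flanks. Domain blocks are
  back-translated through a fixed one-codon-per-residue table chosen for
  near-neutral GC and TA skews, so synthetic coding sequence cannot mimic
  GRINS-grade compositional bias.
* **KS blocks** are copies of a frozen synthetic consensus-like KS
  diverged at 18% per residue. Two consequences drove that number: the
  scanner must still find every block trivially (it does — ~80% identity
  over 430 residues), and two KS blocks of one cluster must stay safely
  below the 90% DNA-identity repeat threshold (pairwise ≈80% at the DNA
  level), so inter-module KS similarity cannot create false GRINS.
* **Module geometry.** Each module's post-KS content is padded to at least
  1100 aa, placing consecutive KS loci more than 3 kbp apart — the
  geometry of real cis-AT modules (1500–2000 aa) and the regime the 3 kbp
  discretization rule presumes. Without the pad, minimal KS-AT-ACP toy
  modules would merge into a single locus and no cluster could reach the
  three-KS minimum.
* **GRINS plants** duplicate a composition-biased segment (default 1 kbp,
  both skews ≈ +0.6) into two intergenic spacers, the second copy lightly
  mutated (1%). The default composition is deliberately *intense*: the
  per-window threshold is 0.25 and a 150 bp window fluctuates by roughly
  ±0.1 around the regional mean, so a plant whose mean skew sits near the
  threshold is fragmented by window noise and is not a usable ground-truth
  positive. At a mean of 0.6 the per-window failure probability is ~3×10⁻⁴
  and recovery is essentially deterministic.
* **Homologs** (`mutate_homolog`) apply substitutions per residue at the
  protein level (rebuilding DNA by back-translation) and per site to
  non-coding segments, with optional protein-level indels remapped onto
  the domain coordinates. Divergence is therefore specified in amino-acid
  terms, matching how homolog calibrations are quoted (5% divergence →
  ≈95% similarity; 50% divergence → ≈50%). Indels are confined to
  proteins and substitutions to both strata; reading frames are never
  broken.
* **Catalogues** (`generate_catalog`) draw families with type and phylum
  frequencies loosely matching a real catalogue census, assign family
  members distinct species (so exact dedup leaves them to the similarity
  stage), optionally add byte-identical duplicates under fresh accessions
  (which exact dedup must remove), and date everything by inverse-CDF
  sampling from an exponential discovery process (default rate ln 2 / 2.5
  per year over 1994–2022).

What the generator does **not** emulate: real codon usage, phylogenetic
correlation between families, sequencing error, fragmented assemblies,
or annotation noise in domain tables. Passing tests therefore demonstrate
the pipeline's correctness on clean, well-specified signal and its
calibration under the stated noise models — not robustness to the full
messiness of public databases.

## Numerical and degenerate-input choices

* Windows with zero G+C (or T+A) content return skew 0 and carry a
  degenerate flag; they never extend a skewed run.
* Similarity is clamped to [0, 100]; the matrix validator enforces
  symmetry within 1e-9 and an exact 100 diagonal.
* Greedy pruning and dedup break all ties deterministically
  (date → length → lexicographic id), so repeated runs are byte-stable.
* Undated clusters sort last in pruning priority; they are an error in
  the rediscovery series (listed by id) and a warning (and exclusion) in
  the discovery series.
* `doubling_time` refuses flat or shrinking series and needs at least
  three years of positive counts.
* Empty inputs short-circuit: empty FASTA → empty list; no hits → no
  domains → no candidates; an empty catalogue writes a header-only table.

## Problem sizes in the tests

The test suite and acceptance checks run entirely on synthetic data:
oracle-equivalence checks use 500 seeded random instances per operation
(≤50 intervals, ≤25-node graphs, ≤2.6 kbp repeat instances); GRINS
recovery uses 100 planted and 100 control clusters; similarity
calibrations use 3–4-module clusters and catalogues of 8–11 clusters;
growth-rate recovery uses 50 replicates of 2000 dated clusters. These
sizes were chosen to exercise every code path with comfortable statistical
margins while keeping a full run in the minutes range on one core.

## Known limitations

* The pairwise similarity score is this package's own formalisation of a
  coverage-weighted local-alignment score; published scores from other
  pipelines (whose exact parameters are not public) will differ in detail,
  so absolute values should be compared only within one scorer.
* The KS scanner is alignment-based, not profile-based; a profile HMM
  would be more sensitive to deeply diverged KS families.
* Internal-repeat detection looks for direct repeats only and computes
  identity over same-length spans (no indel tolerance within a repeat);
  inverted repeats and indel-riddled repeats are out of scope.
* E-value statistics are not reproduced; hit filtering is by raw score.
* GenBank CDS extraction is not built in: proteins and their genomic
  placements are explicit inputs (or come from the generator).
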
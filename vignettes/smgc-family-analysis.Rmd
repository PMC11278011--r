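---
title: "Predicting and comparing secondary-metabolite gene clusters with smgctools"
author: "smgctools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and comparing secondary-metabolite gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smgctools)
```

## The problem

Filamentous fungi such as *Aspergillus* species encode their secondary
metabolism in compact genomic neighbourhoods: a *backbone* enzyme (a
polyketide synthase, nonribosomal peptide synthetase, hybrid of the two,
prenyltransferase, or terpene cyclase) surrounded by *tailoring* enzymes
(P450s, methyltransferases, oxidoreductases, ...) that decorate the core
product. Comparative questions — how many clusters does a genome carry, how
many are shared between species, which are variations of one known cluster —
require four computational steps that this package implements as one
pipeline:

1. **Prediction** of secondary-metabolite gene clusters (SMGCs) from gene
   coordinates and PFAM domain content (a SMURF-style method);
2. **Similarity scoring** of cluster pairs from protein percent identities;
3. **Family detection** by random-walk community detection on the weighted
   cluster network;
4. **Genetic dereplication** of families against characterized MIBiG
   records, plus best-bidirectional-hit (BBH) ortholog groups for a
   concatenated species phylogeny.

A synthetic pangenome generator with planted cluster families provides
exact ground truth, so every stage is testable without any genome download.

## Cluster prediction

A gene is called a **backbone** from its multi-domain PFAM composition.
Seven classes are recognized, evaluated in a fixed order so that compound
compositions resolve deterministically — HYBRID first (PKS-defining plus
NRPS-defining domains in any order), then PKS (ketosynthase + acyl
transferase), NRPS (condensation + adenylation + carrier), PKS-like (at
least two PKS-specific domains plus another domain), NRPS-like
(adenylation + condensation + a terminal thioesterase or reductase),
DMATS prenyltransferase, and terpene cyclase. The PFAM accessions behind
each role ship as an editable TSV (`backbone_domain_roles.tsv`); the
default accessions follow the SMURF lineage of fungal cluster predictors.
Because common NRPS-like enzymes (e.g. aspulvinone E synthetase) lack a
condensation domain, the condensation requirement of the NRPS-like rule
can be dropped via `predictor_config(nrps_like_requires_condensation =
FALSE)`; the stricter reading is the default.

Each backbone seeds a cluster that grows gene by gene in both directions.
Extension stops when an intergenic gap exceeds `max_intergenic_bp`
(default 3000 bp; the gap between consecutive genes is
`start(next) − end(prev) − 1` on 1-based inclusive coordinates) or when
more than `max_non_sm_genes` (default 6) consecutive genes lack an
SM-specific PFAM. SM-specific domains — the backbone domains plus common
tailoring activities, again an editable data file — may therefore sit
*inside* a cluster in runs of up to six, but never at its borders: after
extension the borders are trimmed back to the nearest gene with SM
evidence. Extensions from different seeds that touch merge into a single
cluster, so a hybrid neighbourhood with two backbones is one cluster, not
two. Strand is recorded but ignored; the prediction rules are
strand-agnostic.

## Similarity scoring

Cluster proteins are compared all-vs-all with an exact affine-gap
Smith–Waterman aligner (BLOSUM62, gap open 11, extend 1 — a gap of length
*k* costs 11 + *k*). Percent identity is identical columns over aligned
columns, and significance is the Karlin–Altschul estimate
*E = K·m·n·e^(−λS)* with the published gapped BLOSUM62 parameters
(λ = 0.267, K = 0.041). The default e-value cutoff is 1e−10 for cluster
comparison and 1e−5 for ortholog inference. The aligner is implemented in
C++ and is validated in the test suite against an independent local
alignment implementation; sequences are compared exactly, with no seeding
heuristics.

The score of a cluster pair combines the two enzyme roles:

score = sum(pident, tailoring) / nmax(tailoring) × 0.3 +
        sum(pident, backbone) / nmax(backbone) × 0.7

where *nmax* is the larger of the two clusters' enzyme counts for that
role. Two choices deserve explanation:

* **"Sum of hits" is a one-to-one matching.** A raw sum over the
  many-to-many hit table can exceed 100 when paralogs are present. The
  default `pairing_policy = "optimal_one_to_one"` reduces the hits of each
  role to a maximum-weight one-to-one matching (computed exactly by
  dynamic programming over subsets), which bounds the score at 100 and
  makes a cluster score exactly 100 against itself. The literal unbounded
  reading remains available as `"best_hit_per_query"`.
* **Zero tailoring genes.** When both clusters lack tailoring enzymes the
  tailoring term is 0/0; the backbone weight is then renormalized to 1 so
  that identity still scores 100. When only one side lacks them the
  tailoring term is 0 with nmax taken from the other cluster — absence of
  evidence scores as dissimilarity, not as a missing term.

Every pair with a positive score becomes a weighted edge of the cluster
network (the edge threshold is configurable; the community step, not the
threshold, is the intended filter for weak edges).

## Family detection

Families are communities under the walktrap algorithm (short random walks
on the weighted graph driving agglomerative merging), with walk length 4 —
the method's common default; the published description names the method
family but no parameters. Detection runs per connected component, and
isolated clusters become singleton families. Any community with more
members than the number of species in the analysis is re-clustered by one
further walktrap round on its induced subgraph; this refinement can only
split, never merge, so the result is always a partition. A community still
oversized after the second round is accepted with a warning. Family
labels are assigned by each family's smallest member id, making the
output deterministic and order-independent.

From the family table the package derives the summary statistics of a
comparative analysis: family counts, singleton families (confined to one
genome), per-species unique-family counts, and the directional
shared-cluster matrix whose (A, B) entry is the percentage of A's clusters
whose family also contains a cluster of B. Sharing is defined by family
co-membership, not by a direct score threshold — the alternative reading —
because it keeps the matrix consistent with the family partition.

## Genetic dereplication

MIBiG-style GenBank records are read with a minimal flat-file reader
(accession, definition, organism, CDS `/translation` qualifiers; no
conceptual translation), filtered to *Aspergillus* and *Penicillium*
organisms by default. A record labels a family when any record protein
hits any cluster protein at **strictly more than 95% identity** with at
least 50% query coverage; the coverage floor is this package's addition,
because identity over a short local alignment is not evidence of cluster
identity, and it is exposed in `derep_config()`. The label propagates to
every cluster of the family (family-closed labelling), and labels from
multiple records concatenate sorted by accession. A stricter mode
requiring two distinct record proteins is available but off by default.

## Ortholog groups and phylogeny preparation

For each ordered species pair, a protein's best hits (all hits tied at
the maximum raw score) define BBH edges when reciprocal; ortholog groups
are connected components over all proteins. A species contributing two
tied members to a group is dropped from that group (configurable to
dropping the whole group). *Monocore* groups — exactly one member in every
species — are ranked by mean pairwise identity; the most conserved *n*
(200 in a full-scale analysis) are concatenated per species in sorted
group order and exported as FASTA for external MAFFT → Gblocks → RAxML
runs, whose settings are documented as comments in a generated run
script. How the original analysis chose among monocore groups is not
stated anywhere; conservation ranking with deterministic ties is this
package's documented choice.

## The synthetic pangenome generator

`generate_pangenome()` emulates the inputs of a comparative fungal
study: multiple genomes, each with several scaffolds of background genes
(housekeeping PFAMs only, independent random proteins) and planted
cluster families (one backbone with the full class composition plus 2–4
tailoring genes carrying SM-specific PFAMs). Defaults describe six
genomes, twelve families, 85% within-family protein identity — a
desk-scale rendition of a section-level comparison. Two guarantees make
the truth table exact:

* intra-cluster gaps are drawn within the 3 kb rule (200–1500 bp) while
  all other gaps exceed it (3500–8000 bp), so planted extents are
  unambiguous and any prediction error is attributable to the predictor;
* cross-genome homologs are mutated from a family ancestor with
  *disjoint* substitution sets per species, so every homolog pair differs
  at exactly 2·m positions and pairwise identity equals the configured
  target up to rounding (this "star" design is why `target_identity` is a
  pairwise quantity). Substitutions are uniform over the 19 alternative
  residues and no indels are introduced, keeping identity exactly
  controllable; users wanting matrix-biased substitutions can swap
  `mutate_protein()`.

What the simulator does **not** emulate: nucleotide sequence, introns,
realistic PFAM e-value distributions, gene losses within clusters,
paralogous cluster copies within a genome, or borderline gap sizes.
Passing tests on simulated data therefore demonstrate correctness of the
implemented rules, not robustness to the annotation noise of real
genomes.

## Numerical and degenerate-input choices

* Identical protein ids count as pident 100 in scoring lookups (the hit
  table excludes self-hits); this keeps self-similarity exactly 100.
* Assignment problems larger than 20 enzymes per role are rejected rather
  than approximated; real clusters are far below this.
* A gap of exactly 3000 bp is inside a cluster (the rule is a maximum
  allowed size, so the comparison is strict only beyond it).
* Empty inputs return empty, typed results (zero-row tables, 0×7 census)
  rather than errors, except where the operation is undefined (scoring a
  cluster with no backbone, concatenating zero groups).
* All randomness is confined to the simulator and derived from a single
  integer seed; analysis stages are deterministic, with ties broken by
  sorted identifiers throughout.

## Problem sizes used in the validation suite

The test and acceptance runs use pangenomes of 2–6 species with 4–12
planted families and 8–30 background genes per scaffold, proteins of
120–250 residues, and 200 random pairs for the aligner oracle — sizes
chosen so the full validation completes in about a minute on one core
while still exercising every rule at its boundary (gaps of exactly 3000
and 3500 bp, runs of exactly 6 and 7 SM-free genes, identities of exactly
94 and 96 percent).

## Known limitations

* The shipped SM-specific PFAM list is a curated starting set, not the
  outcome of an enrichment analysis over experimentally characterized
  clusters; analyses of real genomes should review and extend it.
* The internal aligner is exact but quadratic; for full proteome
  all-vs-all at the scale of 18 fungal genomes an external BLAST+ run is
  the practical route, and its tabular output can be ingested in place of
  the internal hit table.
* Dereplication labels depend on the local MIBiG snapshot; results are
  reproducible only against a pinned snapshot directory.
* Walktrap on very sparse networks can place weakly connected clusters in
  unexpected communities; the second-round refinement bounds family size
  but does not guarantee species-level purity.
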
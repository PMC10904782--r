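---
title: "Curating virus-encoded methane-metabolism AMGs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating virus-encoded methane-metabolism AMGs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamp)
```

## The inference chain

Viruses of bacteria and archaea sometimes carry host-derived metabolic
genes — auxiliary metabolic genes (AMGs) — that can reprogram host
metabolism during infection. When the host metabolism in question is
methane production or oxidation, such genes connect viral ecology directly
to greenhouse-gas cycling. Deciding that a metagenome-assembled contig (a)
is viral, (b) carries a *bona fide* AMG rather than mis-binned host
sequence, (c) maps onto methane-metabolism (MM) pathway modules, and (d)
can be attributed to a host lineage, is a chain of inferences, each with
its own error modes. `vamp` implements that chain as testable, reusable
stages with explicit parameters:

1. **Ensemble virus calling.** Per-contig scores from three virus
   predictors are combined by a four-criterion union rule:
   (i) VirSorter category 1, 2, 4 or 5; (ii) DeepVirFinder score ≥ 0.9
   with p < 0.05; (iii) MARVEL probability ≥ 90%; (iv) DeepVirFinder
   ≥ 0.7 with p < 0.05 *and* MARVEL ≥ 70%. Comparisons are literal
   (p = 0.05 exactly fails) and a missing tool output simply fails its
   criterion — the predictors were run on heterogeneous datasets and
   absence of a score is not an error. Contigs are eligible when ≥ 5 kb,
   or circular and 1.5–5.0 kb. A k-mer containment screen
   (k = 21, τ = 0.5 by default) flags contigs matching known laboratory
   phage genomes; it is a presence screen, not an aligner.

2. **vOTU clustering.** Local-alignment fragments (BLAST outfmt-6 style)
   are merged per contig pair: fragments are sorted by query start,
   overlapping bases are trimmed from later-sorted fragments so each base
   counts once, and ANI is the length-weighted mean identity of the
   trimmed fragments. Aligned fraction (AF) is computed on each contig
   independently. An edge joins contigs at ANI ≥ 95% and AF ≥ 0.80 *on
   the shorter contig* (the larger of the two AFs) — the
   shorter-sequence convention used by community vOTU standards, made
   explicit here because "80% of their lengths" is ambiguous on its own.
   Clustering is greedy-centroid: contigs are processed longest first and
   join the first (longest) centroid they share an edge with, so the
   longest member is always the representative seed. Single-linkage is
   available behind `method = "single"` for sensitivity analysis; it can
   only merge greedy clusters, never split them.

3. **Abundance ecology.** Mean coverage depths are normalized to
   *coverage per gigabase*: `depth × 1e9 / library_bases`, which removes
   library-size differences across samples. Community differences use
   Bray–Curtis dissimilarity, classical-scaling PCoA, and a one-way
   distance-based PERMANOVA with pseudo-F computed directly from the
   distance matrix and significance from label permutations
   (999 by default).

4. **AMG curation.** Candidate AMGs on viral contigs are accepted only if
   they survive five independent checks: flanked by phage or hallmark
   genes within a 5-gene window on each side; no transposon-category gene
   in that window; a KEGG KO present; a PFAM accession present and
   consistent with the KO; and location inside the kept (non-host)
   interval after boundary trimming. Every violated check contributes its
   own rejection reason, so a rejected call explains itself.

5. **Pathway exclusivity.** Accepted AMGs are classified against a
   KO → pathway-module map: `exclusive_mm` when every module the KO
   belongs to is a methane-metabolism module, `shared_mm` when MM and
   non-MM modules mix, `non_mm` otherwise. A habitat-association matrix
   (distinct KO × habitat, counting carrying contigs) summarizes habitat
   breadth.

6. **Host linkage.** Four evidence types per virus × MAG pair: CRISPR
   spacer match (≤ 1 substitution, spacers ≥ 25 nt, either strand), exact
   full-length tRNA match (≥ 60 nt), k-mer containment of the virus in
   the MAG, and L1 distance between canonical tetranucleotide profiles.
   Evidence is combined with weights (3, 2, 2, 1) and a reporting
   threshold of 3, so a CRISPR hit alone suffices but composition alone
   never does. Lineage-specific virus/host abundance ratios divide the
   summed abundance of vOTUs linked to a lineage by the summed abundance
   of the lineage's MAGs; a lineage with zero host abundance yields an
   explicitly undefined ratio, never an infinity.

7. **Selection screening.** Gene-level pN/pS from per-site variant
   tables, with NG86-style fractional expected-site counting: each of the
   nine single-nucleotide changes per codon is classified by translation,
   each codon position contributes `syn/3` synonymous and `(3−syn)/3`
   nonsynonymous sites, and changes to stop codons count nonsynonymous.
   `pN/pS = (N_obs/N_sites) / (S_obs/S_sites)`; a gene with only
   synonymous polymorphism has pN/pS = 0, the signature of strong
   purifying selection.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `min_ani`, `min_af` | 95, 0.80 | percent, fraction | species-level vOTU convention |
| screen `k`, `tau` | 21, 0.5 | nt, fraction | contaminant containment screen |
| AMG `window` | 5 | genes | operationalizes "surrounded by phage genes" |
| trim `min_run`, `host_frac` | 3, 0.7 | genes, fraction | host-region run length / purity |
| host weights | 3, 2, 2, 1 | — | CRISPR > tRNA ≈ similarity > composition |
| host `threshold` | 3 | — | one strong or two weak evidence lines |
| `s_min`, `d_max` | 0.5, 0.1 | fraction, L1 | similarity / composition firing points |
| CRISPR `max_mismatch`, `min_len` | 1, 25 | nt | conventional spacer stringency |
| `n_permutations` | 999 | — | PERMANOVA precision floor 1/1000 |

All of these are exposed through `pipeline_params()` or the individual
stage functions; none are hard-coded.

## The synthetic-community generator

`generate_community()` produces every input the chain consumes — contig
FASTA, gene annotations, predictor scores, alignment fragments, depth
tables, MAG records with spacers and tRNAs, variant tables — with planted
truth for each stage. Its default configuration emulates a two-site,
three-depth sediment coring design (50, 100, 225 cm) with paired bulk
metagenomes and viromes (12 samples), library sizes drawn log-uniformly
over 3–15 Gbases so normalization faces unequal libraries, and a small
fraction of vOTUs shared between sites. Key constructions:

* **Virus calls.** Planted viral contigs receive scores passing one of
  the four criteria in rotation; decoys fail all four by margin.
* **Cluster families.** Children are per-site substituted copies of a
  parent (no indels), so true ANI is analytic and the emitted full-length
  fragments carry the exactly measured identity. Family divergence is
  capped at 4% to keep true ANI above the clustering threshold.
* **AMG contexts.** Each planted candidate sits in a gene plan that
  either satisfies all curation rules (`flanked`) or violates exactly one
  (`terminal`, `transposon`, `inconsistent`, `host_region`, `no_ko`), so
  rejected calls carry a single reason and toggling that one condition
  flips the call.
* **Host evidence.** Each virus carries a verbatim CRISPR spacer of its
  true host MAG (every second one also a tRNA); these insertions are
  protected from family mutation so the evidence stays intact.
* **Variants.** Synonymous/nonsynonymous SNP budgets are realized by
  enumerating all single-nucleotide changes of the planted gene,
  classifying them by translation, and sampling the requested counts at
  distinct positions.

What the generator does **not** emulate: read-level data (FASTQ, quality,
coverage noise), assembly artifacts (chimerism beyond the planted host
runs, indels, repeats), genuine phylogenetic signal in sequence
composition (backbones are i.i.d. uniform), database incompleteness, and
correlated predictor errors. Passing tests on these fixtures therefore
demonstrates that the *inference rules* are implemented exactly as
specified — not that the upstream predictors are accurate on real data.

## Numerical and design choices

* **Boundary-trim rule.** The host-like terminal run is the maximal run
  of ≥ `min_run` genes with no hallmark gene and cellular fraction
  ≥ `host_frac`, *ending on a cellular gene*. Without the last clause a
  4-cellular + 1-phage run (fraction 0.8) would trim a phage gene; the
  trim stops at the innermost cellular gene instead. Interior genes are
  never trimmed.
* **Overlap trimming** in fragment merging assigns contested bases to the
  earlier-sorted fragment — deterministic count-once semantics.
* **Permutation p-values** include the observed statistic in numerator
  and denominator, `p = (1 + #[F* ≥ F]) / (1 + n_perm)`, the standard
  unbiased permutation estimate; an exhaustive mode enumerates all label
  orderings for small n and is checked against independent enumeration.
  Permutations are drawn under an explicit seed and the caller's RNG
  state is restored afterwards.
* **Percentages** (occupancy partitions) are reported rounded half-up to
  one decimal; half-up is applied uniformly rather than mixing
  conventions.
* **Degenerate inputs.** A sample pair with zero total abundance has its
  Bray–Curtis distance defined as 0 with a warning; samples with no
  observed features are excluded from ordination and PERMANOVA; a lineage
  with zero host abundance yields an undefined (flagged) ratio; codons
  with ambiguous bases contribute nonsynonymous sites with a warning; a
  gene with no synonymous observations has status `zero_syn_undefined`
  rather than an infinite ratio.
* **Tie-breaks.** Cluster processing order is length-descending then
  lexicographic contig id; host-prediction ties break by composition
  distance then MAG id. Both are total orders, so reruns are
  byte-identical.
* **Missing KO vs inconsistent annotation** are distinct rejection
  reasons (`no_ko` vs `annotation_inconsistent`): the former means the
  gene cannot be placed in any pathway, the latter that its two
  annotation sources disagree. A missing PFAM counts as inconsistent — a
  conservative stance that favors false negatives over false AMGs.

## Problem sizes

The shipped tests and the acceptance script run communities of 25–40
contigs with 6 MAGs and 12 samples, 200-instance clustering-oracle
sweeps, exhaustive PERMANOVA enumeration up to n = 8 with a 200-replicate
null calibration at 999 permutations, 100-gene codon-enumeration checks,
and a 999-codon neutral pN/pS simulation with 10⁴ mutations. These sizes
exercise every rule and boundary while keeping a full run in the order of
a minute; all generator counts scale up through `community_config()`.

## Known limitations

* The host-linkage aggregate is a transparent weighted-evidence score,
  not a trained probabilistic model; agreement with published host
  predictors is not asserted.
* The bundled KO → module and KO → PFAM maps are a minimal curated
  snapshot sufficient for the methane-metabolism classification logic and
  the test fixtures; production analyses should supply full KEGG/PFAM
  derived tables via `load_pathway_map(path, ko_pfam_path)`.
* pN/pS treats SNPs independently against the reference codon background
  (no haplotype phasing) and is a within-population statistic; per-lineage
  dN/dS from codon models is out of scope (an external column can be
  carried through for reporting).
* Alignments themselves are inputs: the package merges and thresholds
  fragments but does not compute them.
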
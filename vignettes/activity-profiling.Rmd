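---
title: "Profiling anaerobic Foraminifera activity from sediment metatranscriptomes"
author: "ForamActivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling anaerobic Foraminifera activity from sediment metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ForamActivity)
```

## The problem

Benthic Foraminifera are shelled protists that remain active — sometimes
thrive — in anoxic marine sediments. Metatranscriptomics can read out their
activity directly: assemble total RNA reads into contigs, call open reading
frames (ORFs), assign each ORF a taxon by protein homology, and compare the
share of transcription attributable to Foraminifera across sediment depths
or incubation timepoints.

The statistical obstacle is the library chemistry. Single-primer isothermal
amplification (SPIA), used by low-input RNA-seq kits, multiplies individual
transcripts by essentially random factors, so depth-based measures such as
RPKM vary by orders of magnitude between technical replicates of the same
extract. What *is* stable between technical replicates is which distinct
ORFs were expressed at all. ForamActivity therefore builds its activity
statistic on presence/absence:

$$f_g = \frac{\#\{\text{unique ORFs assigned to group } g\}}
             {\#\{\text{unique ORFs assigned to any group}\}}$$

per sample, with every distinct ORF counted once regardless of its read
depth. Fold changes between conditions are ratios of these fractions
(averaged over replicates, with the per-replicate range reported), group
structure is tested with ANOSIM on Bray-Curtis distances, and samples are
clustered with UPGMA.

## Pipeline stages and their parameters

1. **ORF calling** (`findOrfs`). Six-frame scan; an ORF runs from the first
   start codon after the previous in-frame stop to the next stop, or to the
   contig edge (flagged partial). Eukaryotic mode admits ATG starts;
   prokaryotic mode also GTG/TTG (translated as their encoded residue).
   Defaults: minimum contig 300 nt (the conventional assembly floor for
   these libraries), minimum ORF 100 aa (the conventional default of
   eukaryotic ORF callers; configurable). The coding-likelihood stages of
   production callers are deliberately not reproduced: the activity
   statistic needs coordinates and translations, not coding-potential
   scores, and externally produced ORF tables are accepted.
2. **Annotation** (`annotateOrfs`, `applyThresholds`, `assignBestHit`). A
   hit counts iff bit score ≥ 50, percent identity ≥ 30 and alignment
   length ≥ 50 residues — all inclusive, reading "minimum x of 50" as ≥ 50.
   "Amino-acid similarity" is implemented as percent identity (the `pident`
   column of tabular alignment output); the best hit is the highest bit
   score, ties broken by lower e-value then lexicographic subject id, so
   assignment is deterministic and order-independent. Precomputed 12-column
   tabular hits can be supplied; otherwise a built-in seed-and-extend
   search (shared k-mer shortlist, then exact Smith-Waterman with BLOSUM62,
   gap 11/1) scores candidates, with bit scores from the gapped
   Karlin-Altschul constants λ = 0.267, K = 0.041 (configurable; production
   aligners use their own internal convention, which they do not expose).
   Taxonomic resolution deliberately stops at (group, genus): short-read
   protein homology cannot separate congeneric species.
3. **Contaminant filtering** (`filterContaminants`). ORFs whose best-hit
   genus is on a laboratory blocklist are removed; the removed fraction is
   reported and a warning fires at ≥ 10%, the QC ceiling expected of clean
   libraries.
4. **Profiling** (`buildProfile`, `groupFraction`, `kogComposition`,
   `foldChange`). Presence/absence as above. "Unique ORF" is keyed by ORF
   id within one sample's assembly; cross-sample clustering of ORFs is out
   of scope. Protist-group fractions can be computed within the eukaryote
   denominator via `within=`. KOG class compositions are fractions within a
   group; an optional description-keyword rule aggregates
   mitochondria-related classes. An RPKM implementation ships only as the
   contrast oracle for robustness tests, not as a supported output.
5. **Community statistics** (`distanceMatrix`, `anosimTest`, `upgmaTree`).
   Bray-Curtis on fractional vectors (default) or Jaccard on presence
   sets. The distance metric behind the published style of analysis is
   never stated by the upstream tools; Bray-Curtis on compositional
   vectors is the field's default and is declared here. ANOSIM uses
   Clarke's R on midranks with p = (1 + #{R\* ≥ R}) / (1 + n~perm~);
   when the number of distinct label arrangements is at most `nPermutations`
   the test enumerates all of them and p is exact (for the 9-sample 2/4/3
   incubation design: 1260 arrangements, so the smallest attainable p is
   1/1260 ≈ 0.0008 — consistent with a reported p of 0.001 at those group
   sizes). R is reported as Clarke's R and never squared. UPGMA places each
   merge at half the average inter-cluster distance with a lexicographic
   tie-break, yielding a deterministic ultrametric tree.
6. **18S barcode extension** (`detectSeedOtus`, `trimSeed`, `greedyExtend`,
   `restrictToBarcode`, `coverageStats`). Seed OTUs are detected by
   nucleotide similarity (e-value ≤ 1e-10) against full-length references,
   restricted to the ~1000-nt 3' barcoding window, and trimmed 10 nt on
   both ends. Up to 20 iterations of greedy extension recruit reads
   overlapping the consensus by ≥ 30 nt at ≥ 95% identity (the same
   identity used for contig read mapping), rescue mates of end-anchored
   reads under relaxed criteria, extend each end by the column-wise
   majority of the overhangs, and correct interior columns when coverage
   ≥ 3. Majority ties emit IUPAC ambiguity codes rather than arbitrary
   picks — the automated analogue of conservative manual base calling.
   Because read placement is substitution-only, a read can only extend an
   end it is anchored flush against, which guards against repeat-induced
   chimeras.

## What the synthetic generator emulates — and what it does not

`communitySpec()` describes a community of taxa (a Foraminifera-like target
group, other eukaryote groups, prokaryotes, and optionally a planted
contaminant genus), per-sample expression fractions (which fraction of each
taxon's genes is transcribed), and a sequencing model. Key choices:

- **Amplification bias** is modelled as an i.i.d. log-normal(0, σ²)
  multiplicative depth factor per transcript, σ = 2 by default: a
  heavy-tailed multiplicative model is the simplest mechanism that produces
  orders-of-magnitude depth variability between technical replicates while
  leaving the expressed-ORF set untouched. Nothing published quantifies
  SPIA bias; σ is configurable.
- **Contigs** are emitted one per transcribed gene, error-free — assembly
  is out of scope, so chimeras and fragmentation are not simulated.
- **Genes** are built codon-wise (ATG + sense codons + stop) so each
  carries exactly one full-length planted ORF whose translation is in the
  reference database under an `id|group|genus|kog` header; KOG classes are
  uniform over the 25 class letters since downstream profiling is
  label-agnostic.
- **Reads** are 2 × 150 nt pairs, insert 350 ± 50 nt (the kit used for
  such libraries does not pin these; they are configurable defaults, not
  assertions), constant Phred 30 qualities, substitution errors only — no
  indels, PCR chimeras or strand-specific protocol.
- **Technical replicates** share the transcribed-gene set by construction
  (composition depends only on spec and sample, never the replicate seed);
  only amplification and error draws differ. For robustness measurements an
  ORF counts as *detected* in a replicate iff it drew at least one read
  pair, so the unique-ORF fraction has genuine (small) sampling noise to
  compare against per-ORF depth noise.

Passing tests on these data therefore demonstrate correctness of the
*computation* under the stated statistical structure; they cannot
demonstrate robustness to assembly artefacts, chimeric ORFs, database
incompleteness, or genuinely novel lineages with no homologs — the main
ways real sediment metatranscriptomes are harder.

The preset `incubationCommunitySpec(fold = 25)` programs a two-condition
experiment in which the target group's unique-ORF *fraction* rises 25-fold.
Because raising the target's expression also enlarges the denominator, the
preset solves for the expressed-gene counts that give the requested
fraction ratio exactly (4 vs 132 expressed target genes against 400
always-expressed other genes), rather than naively scaling expression.

## Numerical and degenerate-input choices

- Thresholds are inclusive everywhere; assignment ties are broken
  deterministically (bit score, e-value, subject id).
- A zero `totalAssigned` makes fractions an explicit error, never a silent
  zero; an all-zero feature-vector pair gets Bray-Curtis distance 0 (to
  itself) / 1 (to others) with a flag on the distance object.
- Local alignments with no positive-scoring cell report raw score 0 and no
  alignment rather than a degenerate 1-residue match.
- ANOSIM uses midranks for tied distances; permutation p-values use the
  add-one convention; exhaustive enumeration is chosen automatically
  whenever it is no more work than sampling.
- Greedy extension is deterministic for fixed input ordering: IUPAC codes
  at tied majority columns, convergence when an iteration adds no bases,
  hard cap at 20 iterations.
- All simulation entry points take a seed and restore the caller's RNG
  state; identical (spec, seed) reproduce byte-identical outputs.

## Problem sizes used by the test suite

The suite runs entirely on generated data: oracle equivalence on 200 random
contigs (300–3000 nt) and 30 random protein pairs; the end-to-end
fold-change recovery on 4 samples of ~700 genes each; extension recovery on
20 seeded 1500-nt references at 50× plus one at 125× with 1% error; ANOSIM
calibration on 500 null data sets of 10 samples with 199 permutations each.
These sizes were chosen so the full suite exercises every claim at desk
scale; all of them, and the generator defaults, are ordinary function
arguments if larger runs are wanted.

## Known limitations

- The ORF caller reports the longest ORF per stop-bounded region and does
  not score coding potential; heavily fragmented transcripts yield partial
  ORFs that are flagged but not specially handled.
- The built-in homology search is a desk-scale tool; for real databases
  (many GB) use a production aligner and feed the tabular output in via
  `readBlastTab()`.
- Greedy extension assumes substitution-dominated error; indel-rich reads
  would break its gapless placement model.
- Whether a reported "R² = 0.75" from ANOSIM denotes Clarke's R or its
  square cannot be decided from published text alone; this package reports
  Clarke's R and never squares it.
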
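# ForamActivity

Quantifying the transcriptional activity of benthic Foraminifera (and other
microbial eukaryote groups) in marine-sediment metatranscriptomes.

## The problem

Foraminifera are shelled protists that stay active — and can thrive — in
anoxic marine sediments. Their activity can be read out from total-RNA
metatranscriptomes: assemble reads into contigs, call open reading frames
(ORFs), assign each ORF a taxon by protein homology, and compare the share
of transcription attributable to Foraminifera across sediment depths or
incubation timepoints.

Low-input RNA-seq chemistry gets in the way: single-primer isothermal
amplification (SPIA) multiplies individual transcripts by essentially random
factors, so depth-based normalizations (RPKM and kin) vary by orders of
magnitude between technical replicates. What stays stable is *which* ORFs
were expressed at all. ForamActivity therefore normalizes by unique-ORF
presence/absence:

```
f_g = (# unique ORFs assigned to group g) / (# unique ORFs assigned to any group)
```

with every distinct ORF counted once regardless of read depth. On top of
this statistic the package provides:

- six-frame ORF prediction (eukaryotic ATG / prokaryotic ATG+GTG+TTG modes),
- thresholded best-hit annotation (bit score ≥ 50, identity ≥ 30%,
  alignment ≥ 50 residues; group + genus + KOG class), with a built-in
  desk-scale Smith-Waterman search or externally produced tabular hits,
- contaminant-genus filtering against a laboratory blocklist with a 10% QC
  warning,
- fold changes of group activity between conditions,
- Bray-Curtis / Jaccard distances, ANOSIM (Clarke's R, exact enumeration
  when feasible) and UPGMA clustering,
- greedy iterative extension of 18S rRNA barcode seeds from reads, with
  per-base coverage reporting,
- a synthetic-community generator with full ground truth (including
  SPIA-style log-normal amplification bias) that makes every stage testable
  without external data.

## Worked example

A one-command synthetic demonstration: an incubation-style experiment with
two oxic `t0` samples and two anoxic samples, programmed so the target
group's unique-ORF fraction rises 25-fold:

```r
library(ForamActivity)
m <- runPipeline(list(outdir = "demo_run", seed = 7))
str(m$stages)
#> $ synthesize: samples: 4, contigs: 1912
#> $ orfs      : contigs_in: 1912, orfs_out: 2027
#> $ annotate  : orfs_in: 2027, assigned: 1912
#> $ filter    : kept: 1987, removed: 40, contamination_fraction: 0.0209
#> $ profile   : samples: 4, fold_change: 25.1
#> $ stats     : anosim_R: 1, anosim_p: 0.333
```

Reading the numbers: all 1912 planted genes were called and assigned
(spurious short ORFs in other frames stay unassigned and drop out of the
denominator); 2.1% of assigned ORFs hit the planted `Pseudomonas`
contaminant and were removed — below the 10% QC ceiling; the programmed
25-fold activity increase is recovered as 25.1 through the whole pipeline;
ANOSIM separates the two conditions perfectly (R = 1), and with only 4
samples the exact enumerated p cannot go below 2/6 ≈ 0.33 — which is why
real designs use more replicates (a 2/4/3 design has 1260 arrangements and
a p floor of 1/1260 ≈ 0.0008).

Piece by piece, the same machinery looks like:

```r
spec  <- incubationCommunitySpec(fold = 25, seed = 7)
refs  <- generateReferenceSet(spec)           # protein DB + 18S references
sim   <- simulateSample(spec, "anoxic_1")     # contigs, paired reads, truth
orfs  <- findOrfs(sim$contigs)                # six-frame ORF calling
asn   <- annotateOrfs(orfProteins(orfs), refs$proteins)
kept  <- filterContaminants(asn, "Pseudomonas")$kept
prof  <- buildProfile(kept, "anoxic_1", "1", "anoxic")
groupFraction(prof, "Foraminifera")
#> [1] 0.2481203    # programmed: 132 / (132 + 400) = 0.248
```

And the 18S barcode branch:

```r
ref   <- as.character(refs$ssuRefs[[1]])
reads <- simulate18SReads(ref, coverage = 125, readLength = 150,
                          errorRate = 0.01, seed = 8)
st    <- greedyExtend(trimSeed(substr(ref, 701, 800), 10), reads)
bc    <- restrictToBarcode(st, ref, 1000)
c(identity = 1 - bc$nDiff / nchar(bc$sequence),
  coverage = coverageStats(st)$mean)
#> identity coverage
#>    1.000  124.9
```

## Layout

- `R/` — implementation (S4 classes in `AllClasses.R`, one file per stage)
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent oracles in `helper-oracles.R`
- `vignettes/activity-profiling.Rmd` — the methods vignette: model,
  parameters, generator assumptions, numerical choices, limitations
- `inst/scripts/foramactivity.R` — thin CLI wrapper over `runPipeline()`
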
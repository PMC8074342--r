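# nanoiso

Isoform discovery, quantification and differential transcript usage (DTU)
analysis for long-read RNA-seq.

Nanopore cDNA reads are long enough to span whole transcripts, but their
high error rate scatters splice sites by a few bases and library
preparation truncates many molecules, so naive per-read isoform calls are
dominated by artefacts. `nanoiso` implements a reference-guided
identification-and-quantification algorithm for genome-aligned long reads,
the SQANTI-style structural audit of its output, and a transcript-level
DTU test with stage-wise false-discovery-rate control — together with a
spike-in-style simulator that provides ground truth for every stage, so
the whole pipeline is testable without any external data. It is aimed at
transcriptomics researchers analysing bulk (or demultiplexed single-cell)
long-read RNA-seq with a two-group design.

## The method

**Isoform identification.** Reads are grouped by their splice-junction
chain — the ordered intron list `(d_1,a_1),...,(d_k,a_k)` obtained from
`N` gaps in the CIGAR. Each donor/acceptor is corrected to the nearest
annotated site of the same kind when it lies strictly within 5 bp
(configurable); groups whose chains agree within 5 bp per site and whose
transcript starts/ends agree within 100 bp are merged; a group whose chain
is a one-side-anchored contiguous sub-chain of a longer group is collapsed
into it as a likely truncated fragment; and groups with at least 10
supporting reads survive. A surviving chain that matches a reference
transcript (chain plus both ends within 100 bp) is reported as that
transcript; anything else becomes a novel isoform named
`<gene>_<start>_<end>_<k>` after its host gene.

**Quantification.** Every read is assigned to the compatible catalog
transcript (its corrected chain a contiguous sub-chain of the
transcript's) with the highest fraction of transcript covered, provided
strictly more than 80% of the read's bases align within the transcript's
exons; ties go to the transcript with fewer junctions. Reads covering at
least 95% of their transcript are counted as full-length.

**DTU testing.** After expression filtering (gene count ≥ 10 in every
sample; transcript count ≥ 10 in ≥ k samples), each transcript's
log2-CPM fold-change between groups is contrasted against the
precision-weighted mean fold-change of the gene's other isoforms:

    relFC_t = logFC_t − Σ_{j≠t} w̃_j logFC_j / Σ_{j≠t} w̃_j,
    T_t     = relFC_t / se_t,

with variances squeezed towards a mean–variance trend by an
empirical-Bayes moments estimator and a Welch–Satterthwaite t reference.
Gene-level p-values are Simes combinations of the gene's transcript
p-values; the stage-wise procedure screens genes by BH-adjusted Simes
p-value, then confirms transcripts within screened genes by
Holm-within-gene adjustment scaled by (tested genes / screened genes).

## Worked example

Simulate the default spike-in-like experiment — 76 genes, 160 transcripts,
two mixes with 44 differentially expressed genes and proportion swaps in
28 genes — with realistic truncation and splice-site jitter, then run the
full pipeline:

```r
library(nanoiso)

des    <- sim_design()
ann    <- make_annotation(des, seed = 1)
truth  <- make_mix_design(ann, des, seed = 1)
design <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
sim    <- simulate_reads(ann, truth, noise_model(), library_size = 20000,
                         sample_mixes = design, seed = 1)

catalog <- discover(sim$reads, ann, discovery_config())
catalog
#> nanoiso catalog: 167 isoforms ( 7 novel ), 79892 supporting reads

q   <- quantify(sim$reads, catalog, quant_config())
rec <- classify_catalog(catalog, ann)
category_summary(rec, q$counts)
#>    category n_isoforms n_reads
#> 1:      FSM        160   79814
#> 2:    genic          7     177

full_length_fraction(q$assignments)$fraction
#> [1] 0.402

cfg <- dtu_config(min_tx_samples = 2)
res <- stagewise(dtu_test(filter_expression(q$counts, cfg), design, cfg), cfg)
```

All 160 annotated isoforms are recovered as full splice matches; the 7
novel entries are short single-exon clusters of heavily truncated reads
(177 of ~80k reads), classified `genic`. About 40% of reads are
full-length under the default truncation model. Evaluating the DTU calls
against the simulator's truth (novel artefacts labelled non-DTU):

```r
#>         level adjustment  TP FP FN    FDR TPR
#> 1:       gene         BH  28  1  0 0.0345   1
#> 2:       gene  stagewise  28  1  0 0.0345   1
#> 3: transcript         BH  56  2  0 0.0345   1
#> 4: transcript  stagewise  56  1  0 0.0175   1
```

All 28 DTU genes and all 56 swapped transcripts are found; stage-wise
confirmation trims the false discoveries.

A thin command-line wrapper over the same functions is installed at
`inst/exec/nanoiso` (subcommands `simulate`, `discover`, `quantify`,
`classify`, `dtu`, `report`), driven by the same JSON configuration file
that holds every threshold above.

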
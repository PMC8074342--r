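---
title: "nanoiso: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanoiso: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoiso)
```

This vignette documents the statistical models and algorithmic decisions
behind `nanoiso`: what each stage assumes, which parameters matter and why
their defaults are what they are, what the simulator does and does not
emulate, and where the design was genuinely open.

## Coordinates and data model

All genomic intervals are 0-based half-open; GTF (1-based inclusive) and
SAM (1-based positions) are converted at the I/O boundary and nowhere
else. A transcript is an ordered list of non-overlapping exons; its
identity for matching purposes is its *junction chain*, the ordered list
of intron (donor-end, acceptor-start) pairs. Single-exon transcripts have
an empty chain and are handled by interval logic instead. Strand is
required: discovery and classification compare chains per
(chromosome, strand), which reflects stranded spliced alignment of cDNA
reads; unstranded annotation records are rejected rather than guessed.

## Isoform discovery

The discovery stage is a deterministic pipeline
`group → correct → merge → collapse → finalize`, run independently per
(chromosome, strand). Reads are first grouped by *exact* chain equality;
tolerance handling is deferred entirely to the correction and merge steps.
This split keeps the grouping order-independent: the alternative —
greedy clustering with a similarity radius — makes the result depend on
input order, which we consider a defect in a tool whose outputs feed
statistical tests.

Parameters (all in the `discovery` section of the JSON configuration):

* `junction_tol` (bp, default 5): a splice site is snapped to the nearest
  annotated site of the same kind when its distance is *strictly* less
  than this. Nanopore splice-site scatter is typically 1–4 bp; platforms
  with lower error rates warrant 1 bp. Snapping is per-site and
  independent for donor and acceptor; ties between two equally near
  annotated sites go to the smaller coordinate, a deterministic
  convention. A snap that would invert a junction (donor ≥ acceptor)
  abandons correction for that group with a warning.
* `end_tol` (bp, default 100): transcript start/end tolerance, applied to
  each end independently (our reading of an ambiguous joint-versus-per-end
  question; per-end is the weaker and therefore safer merge condition
  given that truncation collapsing handles larger 5' deficits anyway).
* `min_support` (reads, default 10): the high-confidence threshold. The
  boundary is sharp and tested at 9 versus 10 supporting reads.
* `trunc_collapse` (`"either"` or `"3prime"`): truncated fragments are
  collapsed into a longer form when their chain is a contiguous sub-chain
  anchored at one end (shared end within `end_tol`, all missing junctions
  on the other side). Whether only 3'-incomplete chains should collapse
  is genuinely open: cDNA truncation is predominantly 5'-biased, but
  3'-incomplete fragments occur too, so the symmetric `"either"` is the
  default and the stricter `"3prime"` is a switch.

Merging processes groups in descending support (ties broken
lexicographically on the chain key) and absorbs a group into the first
kept group whose chain has equal length, per-junction distances strictly
below `junction_tol` at both sites, and median read start/end within
`end_tol`; the kept (larger) group's chain wins. Collapsing proceeds from
the shortest chain upward with transitive pooling, and a fragment
matching several full-length candidates goes to the one with the highest
support. Both orderings exist to make the output invariant under
permutation of the input reads, which the test suite asserts.

Representative transcript ends are the mode of member read starts/ends
(ties resolved outward). The mode, unlike the median, is robust to a
pooled population of truncated reads whose ends are spread uniformly.

Novel isoforms are named `<gene>_<start+1>_<end>_<k>` with the host gene
chosen by maximal same-strand exonic overlap and `k` a per-gene counter;
isoforms without any host gene get a `novelgene_<chrom>_<n>` gene id.

## Read-to-transcript assignment

The original tool re-aligns reads to the transcript sequences; `nanoiso`
instead projects compatibility through the genome alignment: a read is
compatible with a transcript when its corrected junction chain is a
contiguous sub-chain of the transcript's chain and its span lies inside
the transcript's span extended by `end_tol`. This avoids a second aligner
and sequence data entirely, is deterministic, and at the error scales the
junction correction absorbs, agrees with re-alignment on everything but
pathological cases (e.g. a read whose true alignment is to an exon copy
elsewhere). Among compatible transcripts with strictly more than
`min_read_aligned_frac` (default 0.80) of the read aligned within the
transcript's exons, the read goes to the highest transcript coverage,
ties to fewer junctions then smaller id — a convention chosen for
determinism since coverage ties are almost always a short transcript
contained in a longer one, where the more parsimonious model is
preferred. Bases consumed by deletions sit inside alignment blocks but
are not read bases, so they are subtracted from the exon overlap before
dividing by read length.

A read covering at least `full_length_cov` (default 0.95, inclusive) of
its assigned transcript's exonic bases is *full-length*; the strict 0.80
and inclusive 0.95 boundaries are both asserted in unit tests.

## Structural classification

Catalog isoforms are audited against the reference annotation in a fixed
decision order (full splice match; incomplete splice match; novel in
catalog; novel not in catalog; antisense; fusion; genic; intergenic); the
order exists to make the eight categories mutually exclusive and
exhaustive, which the category-summary accounting relies on. FSM/ISM are
junction-defined and ignore transcript ends. "Novel in catalog" requires
every donor and every acceptor to be annotated (new combinations of known
sites); a single unannotated site makes the isoform "novel not in
catalog". The boundary between fusion and genic/intergenic for partially
overlapping genes is not standardised; here *fusion* means exonic overlap
with two or more same-strand genes. Mono-exonic isoforms collapse to
`genic`/`antisense`/`intergenic`. The whole classifier is verified
against an independent brute-force enumerator (explicit sub-chain and
site-set enumeration) on hundreds of randomized annotations.

## The DTU test

For a gene with k ≥ 2 retained transcripts, with log2-CPM fold-changes
`logFC_t` between two groups (n₁, n₂ ≥ 2 samples):

* pooled within-group variances `s²_t` (df = n₁+n₂−2) are squeezed
  towards a mean–variance trend by a moments estimator of a scaled
  inverse-chi-square prior, giving posterior variances with
  `df_total = df + df_prior`;
* the relative fold-change contrasts `logFC_t` against the
  precision-weighted mean of the gene's *other* transcripts, with the
  averaging weights taken from the *prior/trended* variances;
* the statistic `relFC_t / se_t` is referred to a t distribution with
  Welch–Satterthwaite effective degrees of freedom;
* gene p-values are Simes combinations; BH is applied across transcripts
  and across genes separately; the stage-wise procedure screens genes at
  BH(Simes) ≤ α and confirms transcripts by Holm-within-gene scaled by
  G/R (tested/screened genes), capped at 1.

Three choices deserve justification because simpler alternatives fail in
measurable ways:

1. **Degrees of freedom.** The naive choice df = n₁+n₂−2 ignores that the
   squared standard error sums two independent variance estimates; for a
   two-isoform gene with equal variances the exact null is t with
   2(n₁+n₂−2) df. Using the naive df makes the test conservative by a
   factor ~2 in type-I error at α = 0.05 with 3v3 samples. The
   Welch–Satterthwaite combination fixes this and reduces to the exact
   answer in the symmetric case.
2. **Variance moderation.** With duplicate samples the raw variances have
   2 df, and precision weights built from them are so noisy that a gene's
   true usage changes leak into the relative fold-changes of its
   *unchanged* isoforms — inflating transcript-level FDR several-fold in
   our power simulations. Squeezing the variances (and, crucially, using
   the deterministic trended precisions for the rest-of-gene average)
   removes the leak while leaving per-transcript standard errors honest.
   `moderate = FALSE` restores the raw closed-form test with a 1e-8
   variance floor.
3. **Non-robust trend fit.** The log-variance statistic
   `e = log s² − ψ(d/2) + log(d/2)` has left-skewed log-chi-square noise;
   a robustified lowess (the default iterated fit) systematically trims
   the left tail and inflates the fitted variance by ~8%, which alone
   biases the type-I error visibly. The trend therefore uses a single
   non-robust lowess pass (`iter = 0`).

The gene-level F-test variant is not implemented; Simes aggregation is
the screening statistic throughout. Library sizes are plain column sums
of the filtered matrix (no TMM), since between-sample normalisation
belongs to the gene-level expression analysis that is out of scope here.

Expression filters follow the spike-in analysis conventions: genes need a
summed count of at least `min_gene_count` (10) in *every* sample;
transcripts need `min_tx_count` (10) in at least `min_tx_samples` samples
(3 for replicated tissue designs, 2 for duplicate spike-in designs).
Genes left with one transcript stay in the matrix but are untestable.

## The simulator

The generator emulates a synthetic spliced spike-in experiment: 76
non-overlapping genes on one artificial chromosome carrying 160
transcripts (per-gene composition 1×28, 2×26, 3×12, 4×6, 5×4), two mixes
with 21 up- and 23 down-regulated genes (4-fold) and 28 genes whose two
designated isoforms swap proportions 0.7/0.3 ↔ 0.3/0.7 (56 DTU
transcripts; gene totals preserved for pure-DTU genes). Gene abundances
are log-normal (σ = 0.7) with within-gene proportions floored at 0.05 so
every expressed isoform keeps a workable expected count.

Isoforms are built by skipping distinct subsets of internal exons of a
shared scaffold (exons U[80, 300] bp, introns U[200, 2000] bp), always
keeping the scaffold's terminal exons. This construction guarantees that
within a gene all chains are distinct and none is a contiguous sub-chain
of a sibling — so a noise-free dataset is *exactly* identifiable and the
recovery tests can demand equality rather than similarity. The price is
that alternative transcription start/end sites and alternative donors or
acceptors a few bases apart are not represented; the jitter-robustness
tests probe the latter regime independently through the noise model.

The noise model:

* **Truncation** is a per-kilobase breakage process:
  P(truncated | length L) = 1 − (1 − `p_trunc`)^(L/1000), i.e. `p_trunc`
  (default 0.5) is the truncation probability of a 1 kb transcript —
  about the median transcript length in typical cDNA libraries. The
  length scaling makes reads of longer transcripts less often
  full-length, the qualitative pattern real datasets show; a flat
  per-read probability (`length_scaled = FALSE`) cannot produce any
  length trend. Truncated reads lose a U(0.05, 0.6) fraction, from the 5'
  end with weight 0.7 (cDNA truncation is 5'-biased), the 3' end with
  0.3.
* **Splice-site jitter**: each site independently moves by ±U{1..3} bp
  with probability 0.1.
* **End jitter**: rounded Normal(0, `end_sd` = 30 bp), clipped at 3
  standard deviations and inside the gene locus. The 3σ clip is a model
  statement — a bounded end-placement error — which keeps the default
  end noise strictly below the 100 bp end tolerance so that the
  jitter-robustness property (catalog identical to the noise-free one)
  is a theorem of the tolerances rather than a high-probability event.

Reads are emitted directly as coordinate-sorted SAM alignments (CIGARs
over M/N only) rather than sequences: alignment itself is out of scope,
and emitting what the pipeline consumes keeps the round trip exactly
invertible. Base-call errors inside exons, quality scores, barcodes,
chimeric reads and intron retention are *not* modelled; passing tests
therefore demonstrate algorithmic correctness under the stated noise
model, not robustness to every artefact of real nanopore data.

Sequencing of a fixed RNA pool is emulated at the count level by Poisson
noise around expected counts (technical replicates of the same mix have
no biological variance component); the count-level simulators back the
statistical calibration studies, where read-level simulation would add
nothing but runtime.

## Problem sizes and numerical conventions

The acceptance-style checks run, per the package's own choices: the
noise-free and jitter recovery runs at 4 samples × 200,000 reads;
truncation metrology at 10,000 reads on a 76-gene single-isoform design
(isolating the truncation model from assignment ambiguity between
overlapping isoforms, with `end_sd = 0` so the model-implied full-length
fraction is exact); the null calibration at 20 replicates of 1000 genes
(3v3); power at 20 replicates of the default mix design (2v2, every
transcript ≥ 100 expected counts; FDR being an expectation, it is
estimated as the mean false-discovery proportion across replicates); and
the classifier audit on 500 randomized cases. Degenerate inputs are
handled conservatively: empty GTFs parse to empty annotations, empty
read sets to empty catalogs and zero count columns; a truncation draw
that would leave an empty read is replaced by the full-length read; BH
and Simes cap at 1; zero screened genes yields zero DTU calls rather
than a division by zero.

## Known limitations

* Discovery never invents splice sites outside read evidence, so a
  transcript expressed exclusively below `min_support` is invisible.
* Compatibility by genome-projection can mis-assign reads whose best
  transcriptome alignment disagrees with their genome alignment
  (paralogous exons); a re-alignment hook would slot in at the
  candidate-generation step.
* The DTU test assumes two groups; factorial designs would need the
  linear-model generalisation.
* Simes screening is exact for two-isoform genes but mildly conservative
  under the negative dependence induced by leave-one-out contrasts in
  genes with many isoforms.
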
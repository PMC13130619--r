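---
title: "Triage of out-of-frame kinase fusions: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of out-of-frame kinase fusions: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfrescue)
```

## The problem

Clinical fusion-calling pipelines routinely discard chimeric transcripts
whose junction is out of frame: a frameshifted 3' partner usually hits a
stop codon within a handful of codons, so no functional kinase is expected
and the event is filtered before a molecular tumor board ever sees it.
That filter has a blind spot. If an ATG downstream of the junction happens
to sit on the 3' partner's *native* codon grid, the ribosome can
re-initiate there and translate the wild-type downstream protein — kinase
domain included. An out-of-frame fusion can therefore still produce an
active, drug-targetable kinase. `orfrescue` implements the tertiary
analysis needed to catch such events: chimeric transcript reconstruction,
reading-frame classification, downstream-ATG rescue scanning, an
exon-level 5'/3' expression-imbalance test, and a five-criterion triage
workflow, plus a fully seeded synthetic data generator so every step is
testable offline.

## Coordinate and sequence model

All internal coordinates are 0-based half-open; GTF and caller tables are
converted from 1-based inclusive at the boundary, which keeps junction
arithmetic free of off-by-one cases. A transcript model stores exons in
transcript (5'→3') rank order, so rank 1 is the leftmost exon on `+` genes
and the rightmost on `-` genes; spliced sequences are per-exon
reverse-complemented accordingly. The CDS span is held in transcript
coordinates and — in references written by this package — *includes* the
stop codon, so "translation reaches the annotated CDS end" and "the first
stop is the annotated stop" coincide. (Ensembl GTFs exclude the stop from
CDS rows; that shifts `cds_end` by 3 nt and does not affect junction
phase.) When a caller names a transcript it is used; otherwise the
longest-CDS transcript of the gene is selected, since the three supported
callers annotate transcripts inconsistently.

## Frame classification

Let $u$ be the offset of the 5' partner's start codon (ATG1), $j$ the
junction offset (first 3'-partner base), and $\phi \in \{0,1,2\}$ the
position of the first retained 3' base within its native codon
($\phi = 0$: codon start). Translating from ATG1, the junction is in frame
when

$$(j - u) \bmod 3 \;=\; \phi$$

*and* translation reaches the 3' CDS end without a premature stop. The
second clause matters: with $\phi \neq 0$ the junction codon is chimeric
(part 5', part 3') and can itself be a stop even when the grids align, so
phase equality alone is not sufficient. For out-of-frame junctions the
package reports `stop_distance_codons`, the number of complete codons at
or past the junction up to and including the first stop (0 if the stop
spans the junction). No threshold is applied to this number — "a stop
immediately downstream" is an observation, not a cutoff — because any
threshold would be an invention; downstream logic only uses the
in/out-of-frame status.

Breakpoints at annotated exon boundaries retain the full exon on the
retained side; intronic coordinates within `snap_tol` (default 10 nt) of a
boundary are snapped, which absorbs the small cross-caller jitter, and
anything farther inside an intron is an error rather than a guess.

## Rescue scanning

Every ATG at or past the junction is enumerated in transcript order. An
ATG at offset $o$ maps to 3'-transcript position $t$; it is
*frame-restoring* when $t$ lies on the native codon grid
($t \equiv \text{cds\_start} \pmod 3$) **and** within the coding region
proper — a grid-aligned ATG in the 3' UTR restores nothing. For a
frame-restoring start the wild-type residue is
$(t - \text{cds\_start})/3 + 1$, and translation from it reproduces the
wild-type protein suffix exactly (this is asserted sequence-level in the
tests). A start is *domain-covering* when its residue precedes the
annotated kinase-domain start and its ORF runs past the domain end; a
`partial_domain` flag relaxes this to junctions inside the domain, off by
default because full-domain retention is the conservative reading of
"kinase domain preserved". Successive frame-restoring downstream starts
are labeled ATG2, ATG3, …; non-restoring ATGs are reported but unlabeled,
since they produce unrelated short peptides. No Kozak-context scoring is
applied: initiation-site usage is ultimately an experimental question, and
scoring would silently demote candidates.

The source of kinase-domain coordinates is deliberately a user input (a
four-column TSV): there is no canonical machine-readable domain table that
ships with annotation, and hard-coding one would hide a load-bearing
assumption.

## The 5'/3' imbalance test

A functional fusion transcribes the retained exons of each partner from
the fusion promoter while lost exons are expressed only from the
wild-type allele, producing a step in per-exon read counts at the
breakpoint. The procedure: order exon counts by transcript rank; split at
the breakpoint-containing exon, which joins the *retained* side (group 1
for the 5' partner, group 2 for the 3' partner — the assignment consistent
with counting the first retained kinase exon among the elevated block);
drop zero-count exons (unmeasured exons are also dropped but reported
separately, because zero and missing are different statements); compare
groups with a Wilcoxon rank-sum test; call the gene significant at
p < 0.05; and call the fusion imbalanced only when **both** partners are
significant.

Exon counts are small integer vectors with heavy ties, which is exactly
where the large-sample normal approximation is least trustworthy, so the
package computes the *exact* permutation distribution of the mid-rank sum
conditional on the observed tie pattern, by dynamic programming over
subset sums (equivalent to enumerating all $\binom{n_1+n_2}{n_1}$
labelings). The two-sided p-value is the probability of a rank sum at
least as far from its permutation mean as observed. `auto` mode uses the
exact test up to $n_1+n_2 = 20$ and the tie-corrected,
continuity-corrected normal approximation beyond; the two agree within
0.006 at $n_1=n_2=15$ in simulation. The alternative defaults to
two-sided because the source procedure states none; a
`direction_required` flag additionally demands the biologically expected
direction (retained side higher) before declaring significance.

Two guardrails are worth spelling out:

* **Minimum informative group.** A group reduced to one nonzero exon
  cannot reach p < 0.05; reporting it as "not significant" would conflate
  absence of evidence with balance. Groups smaller than `min_nonzero`
  (default 2) make the gene *indeterminate*, which propagates to an
  indeterminate fusion verdict with a reason string.
* **Discreteness floor.** The exact two-sided p-value for a 2-vs-5 split
  is at least $2/\binom{7}{2} = 0.095$. A 5' partner contributing only two
  retained exons out of seven — precisely the geometry of the motivating
  clinical case — can therefore *never* pass at α = 0.05 under this test;
  only a one-sided or approximate test can get it there. The package keeps
  the stated α and test, reports exact p-values, and leaves the choice of
  sidedness to the user; the synthetic panel gives its 5' genes a 5-of-12
  breakpoint so the dual-gene rule is attainable. No multiple-testing
  correction is applied across fusions (none is specified); reports carry
  the fusion count so users can apply their own.

## Triage

Five criteria are evaluated per harmonized fusion: C1 the 3' partner is on
the druggable-kinase list (an editable input; a conservative default list
ships with the package); C2 in-strand orientation (caller-reported
fragment strands must equal the annotated gene strands); C3 out-of-frame
junction *by recomputation* — caller labels are recorded for audit but
never trusted, since callers frequently mislabel frames; C4 kinase domain
preserved; C5 dual-gene imbalance. A fusion passing all five and carrying
at least one frame-restoring, domain-covering rescue start is a
`candidate_functional_out_of_frame`. A fusion recomputed as in frame that
passes C1/C2/C4/C5 is an `in_frame_imbalanced_candidate`, and is flagged
`reclassified` when a caller had labeled it out of frame. Any
indeterminate criterion routes the fusion to a `needs_input` stratum —
mirroring a manual-review step — rather than silently filtering it.
Classification is a pure conjunction: breaking any single criterion can
only demote, never promote (tested by flipping criteria one at a time).

Cross-caller harmonization groups calls by ordered gene pair and merges
breakpoints within a 10 nt window (single-linkage components, so the
result is independent of input order); the window is configurable because
the tolerance behind "consistently identified by all tools" is not
quantified anywhere.

## What the synthetic generator emulates — and what it does not

`make_toy_reference()` builds two multi-exon protein-coding genes whose
exon partitions are solved so that an exon-boundary fusion of the
configured breakpoint exons has exactly the requested junction frame
shift. Coding sequences are random sense codons *excluding ATG*, so the
planted rescue ATGs are provably the only codon-aligned starts; a
premature stop is planted a chosen number of codons past the junction in
the ATG1 frame, and the construction verifies no earlier stop exists on
that frame (the planted off-grid TAA can complete a codon-aligned ATG
immediately downstream — a corner found by the randomized recovery tests —
which the generator clears). Exon counts are negative-binomial with a
configurable dispersion (default 0.1, a typical RNA-seq overdispersion)
and a step fold-change (default 10×) on retained exons; the noise family
is a modeling choice, as the source data show only raw counts. The default
geometry echoes the motivating case: a 7-exon 5' partner fused at exon 2
to a 29-exon, 1620-residue kinase at exon 18, rescue starts at residues
973 and 997 (24 residues apart), domain 1116–1392, 50× baseline coverage.

The generator does *not* simulate reads (no FASTQ/BAM, no alignment or
sequencing error), expression of the unfused wild-type allele, isoform
mixtures, or GC/length biases. A green test therefore establishes that the
*analysis logic* is correct on data with the assumed structure — it says
nothing about caller accuracy or count-extraction artifacts upstream of
this package. The index-case worked example in the acceptance suite runs
on this synthetic stand-in (the real supplementary cDNA and reference
transcript are not redistributable offline); it validates that the code
recovers the published junction/rescue geometry from sequence alone, not
that it reproduces the original alignment.

## Numerical and degenerate-input choices

Exact-test tie handling uses mid-ranks conditional on the observed tie
pattern; support is held in half-rank units so all arithmetic is integer.
Subset counts are accumulated in doubles (exact up to $2^{53}$, far above
$\binom{30}{15}$). All-zero count vectors yield empty groups and an
indeterminate result. Reverse-complementation round-trips are identity by
construction; duplicate contig names, conflicting strands within a
transcript, overlapping exons, and domain rows with inverted residue
ranges are rejected loudly. Every stochastic path flows from one seed, and
identical inputs produce byte-identical TSV reports (fixed column order,
no timestamps).

## Known limitations

Single-breakpoint events only (no reciprocal-pair merging, by design — the
criteria concern the 3' partner specifically); no read-level evidence
re-examination; no Kozak or ribosome-profiling support for start-site
usage; kinase-domain coordinates must be supplied; GFF3 is out of scope.
The imbalance test compares exons within one gene in one sample — it is
not a cross-sample normalization or differential-expression method.
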
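---
title: "Genotyping structural variants from k-mer counts: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping structural variants from k-mer counts: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svkmer)
```

## The idea

A structural variant changes the copy number of a well-defined set of k-mers
in the carrier's genome. A deletion destroys the k-mers inside the deleted
interval and those spanning its two reference breakpoints, while creating
k-mers that span the novel junction between the surviving flanks. An
insertion creates the k-mers of the inserted sequence and of its two
junctions, and destroys the reference k-mers spanning the insertion point. An
inversion creates and destroys junction k-mers at both of its breakpoints.
Because the count of a locus-unique k-mer in whole-genome sequencing reads is
proportional to its copy number, counting a handful of such k-mers per SV —
directly in the raw reads — is sufficient to genotype it. No read mapping is
involved at genotyping time, which also makes the calls independent of the
reference version the sample may have been aligned to.

## Likelihood model

Let μ and σ² be the sample-wide mean and variance of the count of a k-mer
present at one locus on both haplotypes (copy number 2). We model the count
of a copy-2 k-mer as N(μ, σ²); a copy-1 k-mer, being one of the two
haplotype-level summands, as N(μ/2, σ²/2); and a copy-0 k-mer (absent from
the genome) as mean 0 with a small fixed variance ε. Every panel k-mer
carries a table mapping each genotype to its expected diploid copy number:
0/1/2 under 0/0, 0/1, 1/1 for alt-derived k-mers, and the mirror 2/1/0 for
reference-derived k-mers. The genotype of an SV with counted k-mers k₁…kₙ is
the argmax over g of Σᵢ log p(cᵢ | N(μ_g,i, σ²_g,i)) — a product likelihood
under an independence approximation that ignores the overlap between
adjacent k-mers. The approximation costs little in practice because the
decision is driven by where the counts sit relative to 0, μ/2 and μ, not by
their joint covariance.

Numerical choices:

* Likelihoods are computed and summed in log space only.
* ε = max(1, (μ/10)²). The variance of the absent model must be positive and
  small; making it scale mildly with depth stops isolated error-derived hits
  at high coverage from being over-penalized, while the floor of 1 keeps the
  density proper at low depth.
* Counts are capped at 2μ before evaluation. A k-mer sitting on an
  unrecognized repeat can show a count far above μ; without the cap its
  quadratic log-density would dominate the sum in the wrong direction.
* Ties break toward fewer alternate alleles (0/0 < 0/1 < 1/1), the
  conservative choice.
* An SV with zero surviving k-mers is reported as missing (`./.`), never
  guessed.

μ and σ² are estimated per sample from control k-mers: reference k-mers
verified to occur at exactly one locus and to lie outside every SV footprint
(on real genomes, conserved exonic k-mers play this role; the extractor
samples them uniformly, 10 000 by default). The top and bottom 2.5% of
control counts are trimmed before taking mean and variance, guarding against
collapsed repeats and dropped loci; the variance is floored at 1 and the mean
at 0.1. The estimate needs ≥ 100 controls to be warning-free. The expected
value of μ on clean data is coverage × (L−k+1)/L for read length L, since
only windows fully containing the k-mer count.

## Counting

k-mers are packed into 64-bit integers at 2 bits per base, scanned with a
rolling update, and matched canonically (the smaller of a k-mer and its
reverse complement by integer value), because reads come from unknown
strands. The packed default k = 32 fills one machine word; any k ≤ 32 is
supported and small k values are used throughout the unit tests.

Counting is guarded by *neighbor verification*. At extraction time each panel
k-mer stores the two windows at ±1 base in the haplotype it came from. At
counting time an occurrence is accepted only if an adjacent window of the
read, left or right, matches a stored neighbor. The rule is a disjunction
over the adjacent windows that are checkable: a window outside the read or
containing an ambiguous base is not checkable, and an occurrence with no
checkable adjacent window (a read exactly k long) is accepted — rejecting it
would bias counts at read ends. Control k-mers store their reference
neighbors, so they are counted under exactly the same regime as SV k-mers
and the depth estimate is not shifted relative to them. Two further
decisions, both unobservable on non-repetitive panels: a k-mer occurring
twice in one read contributes two occurrences, and windows containing
ambiguous bases invalidate only themselves.

## Extraction

Candidates per SV: all windows of the spliced alternate haplotype straddling
a novel junction (`junction_alt`); all reference windows straddling a
breakpoint (`junction_ref`); for deletions, windows fully inside the deleted
interval (`inner_ref`); for insertions, windows fully inside the inserted
sequence (`inner_alt`). An SV shorter than k simply has no inner k-mers.
Inversions contribute candidates at both junctions; inversion records here
carry exact breakpoints, the natural generalization given that the other
event types define junctions the same way.

Filters, in order; each only removes candidates, never rewrites one:

1. **Reference occurrence.** Candidates are counted over the whole reference
   (canonically). Alt-derived k-mers must have no occurrence outside the
   footprint windows of the input SVs (interval ± (k−1) bases);
   reference-derived k-mers must occur exactly once, at their own locus.
   This implements the locus-uniqueness requirement and is idempotent.
2. **Cross-SV deduplication.** A canonical code claimed by two SVs is
   removed from both; the model attributes each count to exactly one SV.
3. **Per-SV cap.** At most 64 k-mers per SV are kept, junction k-mers
   first: they exist for every event type and length, whereas inner k-mer
   counts scale with event size and add little beyond ~64.
4. **Training concordance.** The survivors are counted on each training
   sample (a sample with known genotypes); each candidate alone is used to
   genotype its SV, and candidates that mispredict in any sample with known
   truth are removed (strict AND across samples — with few training samples
   the selective pressure should be maximal). SVs whose genotype is unknown
   everywhere pass unchanged.

When a mapped training BAM is available, candidates can additionally be
harvested from soft-clipped reads whose clip point lies within 100 bp of a
breakpoint (every read k-mer overlapping a clipped base, neighbors taken from
the read). This path tolerates approximate breakpoints, since the junction
sequence is learned from the reads rather than spliced from coordinates. The
read-derived and reference-derived candidate sets are unioned before
filtering; the filters treat both identically.

The fraction of SVs retaining ≥ 1 k-mer (the extraction rate) is the panel's
coverage of the catalog and is recorded in the panel's `extraction`
attribute.

## The simulator

The bundled simulator replicates the evaluation protocol at desk scale: a
uniform random reference; non-overlapping DELs/INSs (optionally INVs) of
50–500 bp separated by ≥ 2k bases, genotyped 0/1 / 1/1 for training genomes
and 0/0 / 0/1 / 1/1 for test genomes; a diploid genome built by applying each
SV to 2, 1 or 0 haplotypes; and wgsim-like paired-end reads: uniform
fragment placement on both haplotypes, fragment length N(400, 50²), mate 2
reverse-complemented, substitution errors at 0.1% per base by default, and
`round(coverage × diploid_length / (4 × read_length))` pairs. Indel
sequencing errors are not modeled: k-mer counting is length-sensitive, so an
indel error behaves like a substitution (it breaks the windows covering it)
and would only depress counts marginally. Quality scores are constant and
never used. All randomness descends from one top-level seed; equal seeds
give byte-identical FASTQ output.

What the simulator deliberately does not emulate: real repeat structure
(satellites, segmental duplications), GC-coverage bias, and chimeric or
low-quality reads. A uniform random reference makes almost every candidate
k-mer unique, so passing tests bound the method's behavior on
non-repetitive loci; they say nothing about SVs embedded in tandem repeats,
where reference filtering removes most candidates on real genomes.

## Scale of the bundled evaluation

The package's acceptance checks run the full protocol on a 5 Mb reference
with 300 SVs — training extraction at 30× and 10×, then genotyping of an
independently re-genotyped 30× sample — which exercises every pipeline stage
in a few minutes on one core; unit tests use smaller instances (16 bp toy
references up to 300 kb simulations) chosen so each property is legible by
hand. The extraction rate and calling accuracy at this scale sit at or very
near 100%, consistent with what uniform-random references can show (see
above); the interesting failure modes of real genomes live in the repeat
structure that the simulator intentionally omits.

## Known limitations

* Duplications, translocations, multi-allelic and nested events are out of
  scope; overlapping input SVs are handled only by dropping shared k-mers.
* Genotypes are called per SV and per sample; there is no joint calling,
  imputation, or sharing of k-mers between SVs.
* The normal model is a continuous approximation to a discrete count; it is
  intended for μ ≥ 10 (roughly ≥ 15× coverage at k = 32, L = 100). Below
  that, the 0/1-vs-1/1 boundary blurs first.
* Precision and recall are presence-level (a 0/1 call on a 1/1 truth is a
  true positive); TGR/FGR are exact-genotype. Both conventions are stated on
  `evaluate_calls()`.
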
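---
title: "Methods: small RNA analysis of miRNA-mediated insect defense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA analysis of miRNA-mediated insect defense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdefense)
```

mirdefense implements the complete analysis chain of a two-genotype,
two-timepoint plant small RNA sequencing experiment: the kind of study that
contrasts a highly resistant and a highly susceptible soybean genotype
(sample codes HRK and HSK) before and after leaf-feeding insect stress
(0 h and 48 h), with two biological replicates per condition — eight
libraries in all. This vignette explains each model and procedure, the
tunable parameters and their defaults, and the design decisions taken where
the underlying methods are conventionally under-specified.

## Raw read filtering

`filter_reads()` screens raw reads with seven removal rules applied in a
fixed order; a read is attributed to the *first* rule it violates, so clean
reads plus per-rule removals always sum to the input total (this exact
conservation is asserted on every run). Three of the seven rules are
conventionally named but rarely defined; our committed definitions are:

* **Low sequencing quality** (rule 1): more than 20% of raw-read bases below
  Phred 13 (`min_base_phred`, `max_low_qual_frac`). This matches common
  small RNA QC practice and makes the rule seedably testable.
* **5' adapter contamination** (rule 3): the 3'-trimmed insert contains the
  first 12 nt of the 5' adapter as an exact substring
  (`adapter5_probe_len`).
* **polyA** (rule 6): insert at least 70% A, or an A-homopolymer of 10 nt or
  more (`polya_frac`, `polya_run`).

The N-proportion rule (rule 2, more than 10% N) is evaluated on the trimmed
insert — the quantity of interest is the informative fragment — falling back
to the whole read when no 3' adapter is found. 3' adapter location uses an
exact search on a 10 nt adapter prefix, with a single-mismatch scan and an
exact 3'-end overlap (minimum 6 nt) as fallbacks; matching is deterministic
(leftmost, exact before mismatched). There is no upper length cut: only
inserts below 18 nt are removed, and the length histogram reports whatever
lengths survive.

## Annotation priority and library accounting

Unique clean sequences are mapped to the genome by exact dictionary search
on both strands (a single-mismatch mode exists for small inputs). Each
unique sequence then receives exactly one annotation: the first class in the
priority order miRNA > piRNA > snoRNA > Rfam-derived classes (rRNA, tRNA,
sncRNA) > precursor whose reference set contains the sequence as an exact
substring. The piRNA slot is retained so that the priority order is
implemented verbatim even though plant piRNA reference sets are empty in
practice. Exact substring indexing was chosen over a heuristic aligner
because it is deterministic and directly checkable against a brute-force
first-match oracle; the tests do exactly that comparison.

Mapped-but-unannotated sequences are classified by gene-model overlap (exon
wins over intron at a shared boundary; anything else is intergenic),
mirroring the rows of a standard sequencing report: total, clean, mapped,
intergenic/exon/intron, the annotation classes, and unmapped. The rRNA
fraction of clean reads serves as a per-library quality gate: a library
passes while the fraction is strictly below 60% (`rrna_qc_gate()`).

## Quantification and conservation

Known matures are counted by exact sequence identity with a 3' trailing
tolerance of up to 2 nt (a read and a mature match when one is a prefix of
the other from the shared 5' end); internal mismatches never count.
Expression is standardized as tags per million, `TPM = C * 1e6 / N`. `N` is
the library's clean read count — the convention under which the per-class
percentages of the standard report are reproduced — and is configurable;
when `N` is the column sum of the counted rows, TPM sums to exactly one
million per library, which the tests assert.

miRNA families are graded by the number of plant species carrying the
family: more than 10 species is highly conserved, 5–9 moderately, 2–4
lowly, exactly 1 non-conserved. The published grading bands leave an
occurrence of exactly 10 unspecified; we assign it to the adjacent
moderately-conserved band and emit a one-time message, so grading is a
total function for occurrence ≥ 1.

## Novel miRNA calling

Unannotated mapped loci closer than 10 nt (`merge_dist`) are clustered; each
cluster's most abundant read seeds a candidate window of the cluster span
±150 nt (`flank`), clipped at contig ends. The window is folded and the
stem enclosing the seed mature is extracted: among the base pairs enclosing
the mature (tried innermost-first, so that flank sequence incidentally
pairing around the hairpin cannot exhaust the span budget), the first
enclosed subsequence satisfying every criterion is the precursor.

**Energy model.** Folding minimizes energy over all nested (pseudoknot-free)
structures under a deliberately simple per-pair model: GC −3, AU −2, GU −1
kcal/mol, hairpin loops of at least 3 nt, no stacking terms. The model
makes an exhaustive dynamic-programming oracle feasible, and the test suite
verifies the compiled fold against that oracle on every sequence up to
40 nt. A `folder` hook on `fold_mfe()` accepts an external thermodynamic
folder for realism; all thresholds below are defined on whatever model is
plugged in.

**Criteria.** A candidate is accepted when all of the following hold, and an
independent validator routine re-derives each criterion from the stored
sequence, structure and mature placement:

* precursor length 69–910 nt and mature length 19–30 nt;
* a single *dominant* stem-loop: exactly one hairpin loop whose closing
  helix carries a contiguous stack of at least 4 pairs
  (`min_stem_depth`) — shallow one-to-three-pair hairpins are tie-breaking
  artifacts of equal-energy structures near the terminal loop, not
  structure;
* the mature entirely on one arm (never straddling the loop), with at least
  16 of its bases paired to the star region (`min_mature_paired`), and a
  2 nt 3' overhang consistent with dicer processing that stays inside the
  precursor;
* |MFE|/length > 0.2 kcal/mol/nt, and |MFEI| > 0.85, where
  AMFE = MFE/length×100 and MFEI = AMFE / GC%. The per-nucleotide energy
  criterion is read as "more negative than −0.2 kcal/mol/nt", its universal
  usage, and both index thresholds are applied to magnitudes — MFE is
  negative, so thresholding the signed index would reject everything.

Acceptance is monotone in the MFEI threshold (raising it never adds
candidates), and dinucleotide-shuffled decoys must be accepted at under 5%;
both properties are exercised in the tests. The fraction of accepted
matures whose first base is U is reported alongside the calls, as 5'-U is
the expected signature of plant mature miRNAs.

## Differential expression

The test is the classic two-library MA-plot binomial model. Replicate counts
are summed per condition before testing, because the model has no replicate
term; per-replicate information still enters through the genotype-specific
flag (below). With condition counts `C1`, `C2` and library totals `N1`,
`N2`, the statistics are `M = log2 C1 − log2 C2` and
`A = (log2 C1 + log2 C2)/2`. Under the null hypothesis of one common
sampling proportion `p = (C1+C2)/(N1+N2)`, `M` is approximately normal with
mean `log2(N1/N2)` and delta-method variance
`(1−p)/ln(2)^2 × (1/(N1 p) + 1/(N2 p))`; the two-sided p-value comes from
that normal. The committed variance form is validated two ways: an exact
conditional test (`C1 ~ Binomial(k, N1/(N1+N2))` given `k = C1+C2`,
two-sided by summing outcomes no more probable than the observed one, ties
included) is proven super-uniform by exhaustive enumeration for every
`k ≤ 50`, and the normal test's type-I error at the 5% level is measured
within [0.035, 0.065] under a seeded binomial null of 100,000 replicates.

Multiple testing uses Benjamini–Hochberg (chosen over other q-value
estimators for determinism); a miRNA is called when `q ≤ 0.001` and its
|log2 fold change| ≥ 1, where the fold change is computed on mean TPM with
a floor of 0.01 TPM so that "almost no expression" cases stay finite. Zero
counts enter `M` with a half-count floor for the same reason. A
genotype/condition-specificity flag marks miRNAs with zero counts in every
replicate of one condition and at least 10 summed counts in the other.

Called miRNAs are partitioned into the design's three types:
genotype-constitutive (DE between genotypes before feeding, subclassified by
joint direction at 48 h), induced-in-both (DE in both within-genotype
feeding comparisons, subclassified by direction concordance), and
induced-genotype-specific (DE in exactly one induced comparison, split by
genotype). The partition is verified against a brute-force set-algebra
oracle.

## Target prediction and conjoint analysis

Plant miRNA target sites are scored with the classic penalty scheme:
mismatch 1, G:U wobble 0.5, gap 2, all doubled at miRNA positions 2–13 from
the 5' end (a bulged site base takes the weight of the position it
interrupts). Alignments allow at most one gap and minimize total penalty by
dynamic programming; the tests compare the scorer against brute-force
enumeration of all admissible alignments. Two modes run per miRNA ×
transcript and their union is taken, deduplicated by site interval: a
lenient mode accepting weighted penalty ≤ 4.0, and a strict mode requiring
un-doubled raw penalty ≤ 8 with a minimum contiguous complementary stretch
of 17. These cutoffs are our interpretation of the customary
target-prediction tool settings (a score cutoff of 4; a minimal
complementary length of 17, penalty 8, one gap) — the tools themselves
document flags, not formulas — and every threshold is exposed in
`target_modes()`. Transcripts are scanned full-length on the plus strand
with 1-based inclusive coordinates.

Because plant miRNAs act predominantly by transcript cleavage, regulation is
assumed negative: within each comparison, `conjoint_negative_pairs()` emits
(miRNA, transcript) pairs where the transcript is a predicted target, both
sides are called DE with |log2FC| ≥ 1, and the directions are opposite.
Every emitted pair is re-validated against these invariants in the tests,
and the summary reports distinct miRNA/target counts, per-comparison
counts, per-miRNA target counts, and transcripts shared by several miRNAs.

## Enrichment and qRT-PCR

Term enrichment is the upper-tail hypergeometric test per GO/KEGG term, with
BH adjustment within each namespace (standard practice; a global adjustment
is a one-line change for the caller). Significance is gated on the raw
p ≤ 0.05 by default, with the q-gated column emitted alongside, since
either convention is found in practice. The universe defaults to all genes
in the annotation map and is exposed as an argument.

Stem-loop qRT-PCR quantification uses 2^−ΔΔCt with `mir1520d` as the
default reference gene: ΔCt is the mean target-minus-reference Ct within a
sample (replicates paired by index), ΔΔCt the treated-minus-control
difference, and the p-value a two-sided two-sample t-test on per-replicate
ΔCt values at α = 0.05. RQ is invariant to adding a constant to all Ct
values of a sample, and `concordance_check()` compares the sign of
log2(RQ) with the sequencing fold change, reporting the agreement fraction.

## The synthetic experiment

`sim_config()` defines the study conditions the generator emulates; its
defaults are fixed and are the conditions under which every recovery
guarantee is stated:

* eight libraries (HRK/HSK × 0/48 h × 2 replicates) of roughly
  150,000–220,000 reads — typical published depths for such designs scaled
  down 100-fold to desk scale;
* a ~90.6% clean-read rate from seven planted contamination classes (3%
  low-quality, 3% missing 3' adapter, 1% adapter dimers, 0.8% each 5'
  contamination and sub-18-nt inserts, 0.4% each high-N and polyA);
* insert lengths 18–32 nt with peaks at 20, 21 and 24 nt; rRNA at ~2% of
  clean reads; known miRNAs at ~4.5%; a genomic background making up the
  rest, with ~10% unmappable reads;
* 60 catalogued miRNAs in a lognormal abundance spectrum, 25% planted DE
  with |log2FC| in [1, 3] (the recovery tests use [2, 3]), two miRNAs
  expressed only in the resistant genotype, and 8 planted novel hairpins
  whose matures start with U;
* per planted DE miRNA, two target transcripts carrying perfect
  complementary sites with opposite-direction mRNA fold changes, plus 30
  decoy transcripts.

Three generator design choices deserve explanation. First, planted fold
changes are realized by *shrinking the lower condition* and are restricted
to miRNAs below the 85th abundance percentile: since proportions
renormalize, any planted change shifts every null miRNA's apparent fold
change by the total-abundance ratio, and reductions on sub-dominant miRNAs
keep that compositional drift below ~0.1 log2 units — small enough that
null miRNAs stay well inside the call threshold. Second, planted hairpins
are palindromic stems with a 4-pair GC clamp next to an all-A terminal
loop; under the per-pair energy model this makes the planted structure the
*unique* optimum, so recovery failures indicate algorithmic faults rather
than tie-breaking ambiguity in the traceback. Third, replicate counts are
pure multinomial draws from the condition proportions — the DE model
assumes binomial sampling — with an optional Dirichlet-multinomial
`overdispersion` knob for robustness experiments only.

What the generator does *not* emulate: per-base sequencing errors,
polymorphism, isomiR ladders (beyond the ±1 nt 3' trailing variants of
known matures), biological replicate overdispersion by default, and
realistic hairpin thermodynamics. Passing tests therefore demonstrate
correctness of the implemented procedures and their statistical calibration
under the stated model, not robustness to every artifact of real
sequencing data.

All randomness flows from the single configuration seed through per-stage
derived seeds; rerunning any stage with the same configuration reproduces
identical bytes, which the pipeline tests assert on the written TSVs.

## Problem sizes and runtime

The unit tests run the generator at 2,000–10,000 reads per library; the
end-to-end and recovery checks use the full default configuration (~1.4
million reads, about two minutes on one CPU), 100,000-replicate null
calibration for the test size, exhaustive enumeration up to `k = 50` for
the exact test, sequences up to 40 nt for the fold oracle, and 200
dinucleotide-shuffled decoys for the hairpin criteria. `run_pipeline()` on
the default configuration completes the whole chain — QC through qPCR —
well inside ten minutes on a single CPU.

## Known limitations

* The exact-substring annotation and mapping model ignores mismatches by
  default (a 1-mismatch mode exists but scales only to small inputs);
  isomiRs beyond the 3' trailing tolerance are not assigned to matures.
* The per-pair energy model is a caricature of RNA thermodynamics; MFEI
  values are comparable within the model but not to literature values
  computed with nearest-neighbour parameters. Use the `folder` hook when
  thermodynamic realism matters.
* The DE model inherits the limitations of two-library binomial testing:
  with replicates summed, biological overdispersion inflates significance;
  the q ≤ 0.001 threshold compensates only informally.
* Target prediction scans transcript sequence only; it knows nothing of
  target-site accessibility or degradome evidence.
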
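---
title: "Inferring restriction–modification systems from bacterial methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring restriction-modification systems from bacterial methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylRM)
```

## The inference problem

SMRT sequencing detects methylated bases from polymerase kinetics and
summarizes them per recognition motif: `nGenome` occurrences of the motif in
the assembly, `nDetected` of them methylated, and their ratio as a
modification fraction. Separately, the genome annotation names candidate
restriction–modification (RM) genes. `methylRM` connects the two: it
classifies annotated genes into RM roles, reconstructs the operons they form,
assigns observed motifs to the enzymes that plausibly produce them, and
dissects the specificity determinants of type I systems.

Two biological facts shape the design. First, type I recognition motifs are
bipartite — two specific 3–4 bp half-sites separated by a nonspecific spacer
of 5–8 `N`s — and each half is read by one target recognition domain (TRD) of
the HsdS specificity subunit, so motif structure and protein architecture
mirror each other. Second, RM genes travel in operons whose gene order is
diagnostic: a chromosomal three-gene `hsdMSR` arrangement is the classical
form, while a four-gene `hsdRSMS` arrangement carries two specificity
subunits (a short, fully conserved one of 191 aa and a long one of ~390–400
aa with two TRDs) flanking the methyltransferase, with the 3′ end of `hsdM`
overlapping the 5′ end of `hsdS_long` by 8 bp — a translational-coupling
signature the pipeline checks explicitly.

## Gene classification and operons

`classify_rm_gene()` applies ordered keyword rules to annotation text
(first match wins): specificity/`subunit S` → hsdS; `subunit M` or type I
modification → hsdM; `subunit R` → hsdR; DUF3578/McrB and McrC tags → the
two-gene methylation-dependent (type IV) pair; helicase-like genes are split
by length — a fused methyltransferase–endonuclease (type IIG) gene runs well
above the 4000 nt floor, while a type III `res` gene is shorter and sits next
to a site-specific methyltransferase (`adjacent_mtase`); family-tagged or
plain restriction endonucleases, adenine/cytosine methyltransferases and
restriction-associated ATPases fill out the type II/III roles. Falling
through leaves `unknown`; every rule fired is recorded as evidence.

Completeness floors (`rm_rules()`): hsdR ≥ 1800 nt, hsdM ≥ 1200 nt,
hsdS ≥ 450 nt, fused IIG ≥ 4000 nt. They sit below the smallest complete
instance of each role we curated (2787/1464/576 nt) and above every
truncated one (423/198 nt), so "truncated" is a length verdict, not a parsed
annotation flag. All floors are configurable.

`reconstruct_operons()` builds maximal same-strand runs of RM-role genes
with intergenic gaps ≤ `max_gap` (default 200 nt — operons of interest are
contiguous, and a separately promoted `hsdR` does not break contiguity),
normalizes gene order to transcription orientation, and matches role
sequences: `R,S,M,S → hsdRSMS`, `M,S,R → hsdMSR`, `R,S,M → hsdRSM`,
mod+res → type III, mcrB+mcrC → type IV, methyltransferase+endonuclease →
type II pair; other runs are `single`/`partial`. Topology labels are
invariant under reverse-complementing a replicon (a tested property). A
strain has a complete type I system iff one operon carries non-truncated
hsdR, hsdM and at least one non-truncated hsdS.

Regulatory heuristics: the Shine-Dalgarno finder reports the best `AGGAGG`
match with ≤ 1 mismatch whose 3′ end lies 4–16 nt upstream of the start
codon; the σ70 finder reports the best `TTGACA` (≤ 2 mismatches) + 16–19 nt
spacer + `TATAAT` (≤ 1 mismatch) pair, scored by total mismatches with ties
resolved toward the gene start (with a warning). These are consensus-matching
heuristics, not promoter predictors; they support reading planted or strongly
canonical signals, nothing more.

## Motif algebra

Motifs are IUPAC strings with an optional annotated methylated position.
Since each IUPAC code denotes a unique base set, reverse complementation and
palindromy are exact string operations. The methylated-base annotation is
never mapped across strands: the opposite strand's methylated base is an
independent biological site and is stored per strand.

`bipartite_decompose()` splits a motif around its single longest internal
run of `N` (leftmost on ties, with a warning), requiring run length ≥ 3 —
long enough to exclude compact type II motifs — and fully specific
half-sites. `predict_half_site_motif()` implements the half-site deletion
rule `h + N^s + revcomp(h)`, palindromic by construction, which models the
symmetrized specificity of type I systems that lose one TRD.

`scan_motif()` reports plus-strand hits of the pattern and minus-strand hits
of its reverse complement, both at leftmost plus-strand coordinates.
Palindromic motifs are reported once per duplex site with strand `+`;
asymmetric motifs are **not** deduplicated, because SMRT reports tally the
two strands of an asymmetric motif pair as separate motif entries. An
unknown subject base (`N`) is matched only by a pattern `N`; other degenerate
pattern codes require a determined base. Circular replicons wrap
`min(len(pattern) − 1, len(seq))` bases across the origin. The scanner is
Biostrings-backed and is validated against an exhaustive sliding-window
oracle in the test suite.

`modification_fraction()` rounds half-up (`0.125 → 0.13`) because printed
motif reports use fixed two-decimal display; base R's banker's rounding
would not reproduce printed tables.

## Family classification and trees

Percent identity is computed from a Needleman–Wunsch global alignment
(BLOSUM62, gap open 10, gap extend 1, end gaps penalized) as
`100 × matches / alignment length` **including gap columns** — stated
explicitly because "percent identity" is ambiguous across tools; this choice
is conservative and symmetric. Because optimal-score alignments are not
unique and tie-breaking could differ between argument orders, the two
sequences are put into a canonical order before aligning, making the
statistic exactly symmetric. Aligner parameters are conventional defaults;
identity values against references reproduce published-scale figures only
approximately (the package's family thresholds are deliberately coarse).

`classify_family()` takes the argmax over one reference per family and
applies the consensus thresholds: `member` at ≥ 70% identity, `novel` when
every family scores < 30%, `borderline` between — the zone where new
families are debated. Verdicts are monotone in identity (tested).

`nj_tree()` is a standard Saitou–Nei neighbor-joining implementation with
deterministic lowest-index tie-breaking in the Q-matrix. Negative branch
lengths arising on non-additive matrices are clamped to zero with the
deficit shifted to the sister branch, preserving cherry length. On additive
matrices the generating tree is recovered exactly (tested against path
distances and against `ape::nj` topologies on random trees). Distances for
tree building are `1 − identity/100`.

## HsdS architecture

Conservation is the modal-residue frequency per column among non-gap
characters (columns with > 50% gaps score 0), smoothed by a centered moving
average of width 9 columns; an entropy-based score is available via
`method = "entropy"`. Modal frequency was chosen over entropy as the default
because it matches the visual idiom of conservation plots and is directly
interpretable as agreement.

`segment_trds()` calls maximal runs below threshold 0.5 of length ≥ 50
columns TRDs (TRDs are ~150 aa domains; 50 avoids noise calls), caps them at
two (keeping the two longest with a warning), and labels the remaining runs
positionally (N-CR/cCR/C-CR around two TRDs; one CR when none — the
fully conserved short-subunit case). Segmentation is deterministic and
shifts exactly with prepended conserved columns.

Repeat detection: `find_tandem_tetrapeptide_repeats()` reports every 4-mer
repeated in direct succession (the classical central-region signature);
`find_short_repeats()` finds k-mers (k = 4–8) repeated with inter-copy gaps
≤ 5 residues, preferring maximal units — a unit is suppressed when it is a
substring of a reported longer unit covering the same occurrences. A
consequence worth knowing: if both copies of a planted 5-mer happen to share
a flanking residue, the maximal reported unit is the 6-mer containing it;
downstream checks therefore test containment, not string equality. Both
finders are validated against brute-force enumeration oracles.

## Motif assignment

Genes are pooled across strains and clustered into families by single
linkage at 90% identity (`stats::hclust` + `cutree`), because orthologous
systems — not locus tags — are what recur across strains.
`concordance_match()` scores each family by the fraction of strains where
family presence equals motif presence. The default `min_score = 1` demands
perfect concordance for an assignment, reflecting that such assignments are
trusted only when a single candidate co-occurs exactly; ties are reported
`ambiguous`, never resolved arbitrarily, and an all-absent motif vector
triggers a warning since absent families trivially score 1.

## The synthetic-data generator

`generate_strain()` plants operons with curated role sequences and gene
lengths (hsdRSMS: 2787/576/1557/1170 nt with an 8 bp hsdM–hsdS_long
overlap; hsdMSR: 1515/1215/3123 nt; type III: 2001/2700 nt; type IV:
2028/1323 nt overlapping by 4 bp; IIG: 4737 nt) into i.i.d. background
sequence with GC 0.33 (staphylococcal-like), with AGGAGG before every ORF
and σ70 boxes before the operon (and before hsdS_short in hsdRSMS).
`simulate_motif_report()` models detection as per-site Bernoulli
(`n_detected ~ Binomial(n_genome, fraction)`) with Poisson coverage and a
deterministic increasing coverage→score link — sufficient to exercise report
parsing and the fraction statistic without modeling polymerase kinetics.
`generate_hsds_cohort()` mutates conserved-region consensus at a low rate
(default 2%/residue) and samples TRD blocks independently per sequence; the
planted central repeat pair is re-written after mutation, treating it as a
conserved feature. `generate_cohort_with_motif_linkage()` mirrors gene-family
presence in motif presence with optional corruption positions.

What the generator does **not** emulate: real codon usage and amino-acid
composition, homology between paralogs, indels in alignments (cohort rows
are gap-free and pre-aligned), read-level kinetics, and assembly artifacts.
Passing the recovery tests therefore demonstrates the pipeline's arithmetic
and logic, not robustness to messy annotations or alignments.

## Problem sizes and numerical choices

The test suite runs the randomized oracle comparisons at 1000 instances per
operation, neighbor-joining recovery on 200 random trees of up to 12 taxa,
and end-to-end recovery on 100 seeded replicates (12 kb replicons, 11-row
cohorts, 4-strain linkage cohorts) with a ≥ 95% recovery requirement for the
stochastic stages; the acceptance script uses 50 trees and 30 replicates.
These sizes were chosen to make sampling error negligible relative to the
pass thresholds while keeping a full run in the low minutes on one CPU.

Degenerate inputs are handled by policy, not error, where a policy is
defensible: an entirely variable conservation profile yields a single
alignment-spanning TRD with a warning; compound (`join`) CDS locations are
collapsed to their outer span with a warning (RM genes are single-exon);
strandless genes are excluded from operon runs with a warning. Hard errors
are reserved for contract violations: `n_detected > n_genome`, `nGenome = 0`
fractions, frame errors, NaN distances, duplicate tree labels, strandless
base-modification calls.

## Limitations

Classification is keyword-and-length based by design — no HMM/profile
domain detection — so it is only as good as the annotation vocabulary it was
curated from. Family classification depends on user-supplied reference
proteins and conventional aligner parameters; identities near the 30%/70%
thresholds should be treated as borderline by construction. The pipeline
consumes SMRT motif summaries; it does not perform base calling, motif
discovery, or enrichment statistics beyond the fraction report.
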
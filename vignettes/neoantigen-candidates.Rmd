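---
title: "From somatic variants to prioritized neoantigen candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic variants to prioritized neoantigen candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neopept)
```

## The problem and the model

A somatic mutation in a coding region can create peptides absent from the
normal proteome. If such a peptide binds one of the patient's HLA
molecules, it may be presented to T cells — a neoantigen. `neopept` turns a
somatic call set into a ranked table of candidate peptides by composing
four ingredients: sequence construction, wild-type exclusion, binding
capability, and tumor-genomics context (expression, allele-specific
expression, subclonality).

The unit of analysis is a fixed-length peptide window. For every event the
package edits the affected transcript's spliced cDNA in transcript
coordinates, re-translates, and compares the mutant translation with the
wild type:

- **Missense SNVs.** The altered residues are the positions where the two
  equal-length proteins differ; every window of length $\ell$ covering at
  least one of them is emitted, paired with the positionally matched
  wild-type window. The mismatch count $M$ is the Hamming distance of the
  pair.
- **Frameshift indels** (and stop-loss events). The mutant translation runs
  from the start codon through the first downstream stop; if no stop is
  reached before the transcript end, the candidate carries a no-stop flag.
  Novel residues extend from the first position that differs from the wild
  type to the end; windows covering them have no wild-type counterpart.
- **In-frame indels.** The altered block is bounded by the common prefix
  and suffix of the two proteins; for a clean deletion (empty block) the
  windows must straddle the deletion junction. Wild-type windows are taken
  from the unedited protein at the prefix-anchored offset.
- **Fusions (BND records).** Each breakend ALT string is canonicalized into
  "segment 1 reads 5' into the junction, segment 2 continues 3' of it",
  which resolves all four bracket classes including reverse-complement
  joins. A transcript qualifies as donor when the retained genomic side is
  its 5' side and the breakpoint lies at or after its start codon; the
  fused cDNA is donor prefix + inserted sequence + acceptor portion, and is
  translated from the donor start codon. Windows occurring as substrings of
  either parent protein are removed, which leaves exactly the
  junction-spanning windows for in-frame joins and the whole novel tail for
  out-of-frame joins.
- **Raw RNA sequences.** Translated from the first ATG (optionally all
  three frames); windows found in any reference protein of the stated gene
  are removed. An unknown gene reference keeps everything and warns —
  silently over-filtering would be worse than under-filtering here.

After construction, a global filter removes every candidate whose mutant
peptide occurs as a substring of *any* loaded wild-type protein, not only
the source gene's. This is the stronger of the two defensible readings of
wild-type exclusion; it guarantees the invariant that every reported
peptide is genuinely tumor-specific with respect to the loaded annotation,
and it also enforces that each mutant/wild-type pair differs in at least
one residue.

### Co-occurrence patterns

Optionally (all three switches default to off), the package enumerates edit
patterns when somatic events co-occur on one transcript: every on/off
combination of the somatic edits (the all-off pattern is the wild type and
is excluded), capped at `max_cooccurring` events — beyond the cap only
single-variant and all-variant patterns are kept, with a warning. Germline
SNPs, when integration is enabled, are applied to **both** the mutant and
the wild-type sequence of every pattern: the patient's wild type carries
the SNP too, so treating it as somatic would manufacture spurious
mismatches. Each pattern receives a deterministic identifier (a 32-bit FNV
hash of the sorted variant keys) so re-runs are comparable.

## Binding capability

The package never re-implements the neural binding predictors. It consumes
their output: whitespace-table parsers for netMHCpan 4.0 and netMHCIIpan
3.2 and a CSV parser for MHCflurry, each extracting affinity (nM) and
percentile rank. `predict_binding()` enforces completeness — exactly one
result per (peptide, allele) pair, mutant and wild type — and aborts naming
the first missing pair, because a silent dropout would corrupt every score
downstream. Class II alleles are refused class I-length peptides and class
I-only backends.

For offline work and testing there is a deterministic surrogate: IC50 is
$\exp(u \ln 50000)$ nM with $u \in (0,1)$ derived from a 32-bit hash of
(peptide, allele, seed), so results are identical across runs and
platforms and span the plausible 1–50000 nM range; the percentile rank is
a fixed strictly increasing map of IC50 into $(0, 100]$. The surrogate
carries no biology — it exists so the pipeline's plumbing, determinism and
scoring can be exercised end to end without licensed binaries.

## Expression, allele-specific expression, subclonality

Total expression `E` is an exact-match gene lookup (duplicate rows are
summed with a warning). Allele-specific expression is `VAF × E` from DNA,
or `alt/(ref+alt) × E` from an RNA allele-count table. The units of `E`
are whatever the user's table is in; note that the expression factor
below saturates near `E ≈ 3`, so heavily scaled units (raw counts) should
be normalized first.

Subclonality: a variant observed in $a$ of $N$ reads, at tumor purity
$\alpha$ and total somatic copy number $q$ (from an ASCAT-style segment
table), has expected variant allele fraction
$f(c) = \alpha c \,/\, (2(1-\alpha) + \alpha q)$ when carried by a fraction
$c$ of tumor cells at multiplicity one. On an even grid over $(0, 1]$
(step 0.01) the posterior under a uniform prior is proportional to the
binomial likelihood $\mathrm{Binom}(a \mid N, f(c))$; with $N = 0$ it is
the prior itself. The reported `C` is the posterior median, defined as the
smallest grid value with cumulative probability at least 0.5 — a
deterministic tie-break. Mutation multiplicity is fixed at one (the model
has no multiplicity term); $f(c) \le 1$ holds for all valid inputs
($q \ge 1$), so the defensive clamp in the code never fires on valid data.

## Priority scores

$$P_I = \bigl[L_I(I_m)\, f(A, E)\bigr]\,\bigl[1 - 2^{-M} L_I(I_w)\bigr]\, C,
\qquad
P_R = \bigl[L_R(R_m)\, f(A, E)\bigr]\,\bigl[1 - 2^{-M} L_R(R_w)\bigr]\, C$$

with $f(A,E) = \tanh(g(A)E)$, $g(A) = \tanh(5A)$,
$L_I(x) = 1/(1+e^{0.015(x-500)})$, $L_R(x) = 1/(1+e^{5(x-2)})$, and
$C(x) = 1/(1+e^{-30(x-0.8)})$ at the median CCF $x$.

Two notational choices deserve a flag, since the source formulas admit
more than one reading:

- The wild-type bracket is implemented as $1 - 2^{-M} L(\cdot_w)$ — the
  only grouping that stays in $[0,1]$ and reduces sensibly: a strongly
  binding wild type with few mismatches halves the score at most; many
  mismatches or a non-binding wild type push the factor to 1.
- The clonality factor is implemented as the *logistic*
  $1/(1+e^{-30(x-0.8)})$. The additive form with a minus sign would be
  negative or divergent for $x < 0.8$; the logistic matches the form of
  $L_I$ and $L_R$, is increasing in clonality, and crosses 0.5 at a median
  CCF of 0.8.

Missing optionals substitute neutral values — wild-type term 1 when no
wild-type peptide exists ($M \to \infty$), $E = 1$ when expression is
missing, $C = 1$ without a posterior — and every substitution is flagged
per row in the report's `substitutions` column. The VAF $A$ is mandatory;
without it the score is reported missing rather than silently neutralized,
because $f(A, E)$ has no sensible default at unknown allele frequency. A
rank-based score in the style of earlier prioritizers,
$L_R(R_m)\,E\,A\,(1 - 2^{-M}L_R(R_w))$, is included for comparison and
labelled as an interpretation — its exact original form is not published
alongside the composite scores above.

Rows are emitted per peptide length and per pattern without cross-length
deduplication (each is a distinct predictor query), sorted by the selected
score descending with deterministic key tie-breaks, and missing optionals
are rendered as `.`.

## The synthetic fixture generator

`make_fixture()` builds a deterministic toy genome: each transcript is a
start codon, random non-stop codons, and a terminal stop, with optional
short UTRs, 1–3 exons and random strand, placed on one contig with random
spacers; the truth record stores each protein as derived from the codons
drawn, independently of the splice/translate code path. It emulates the
*structural* features that matter to this package — strand, splicing, UTR
offsets, frame — at CDS lengths of tens of codons. It does not emulate
real gene architecture (long introns, alternative isoforms, paralogy,
biased codon usage) or real binding (the surrogate is hash noise), so
passing tests demonstrate correctness of construction, coordinate
arithmetic and filtering logic, not predictive performance on real tumors.
`random_coding_variants()` draws SNVs and 1–3 bp indels confined to single
exons and to the CDS; splice-spanning events are a deliberate blind spot of
the generator because the pipeline classifies them as non-coding by policy
(splice-site handling is genuinely ambiguous without an isoform model, so
they are logged and skipped rather than guessed at).

## Numerical and policy choices

- Coordinates are 0-based half-open internally; VCF and report coordinates
  are 1-based, converted only at I/O boundaries.
- Indels are left-normalized against the reference before CDS mapping, so
  equivalent VCF encodings of one event map to one edit.
- VAF comes from `FORMAT/AD` when present; records without counts get
  depth 0 and a missing VAF (never silently guessed).
- Translation uses the standard code only; codons containing `N` become
  `X`, and windows containing `X` are suppressed rather than scored.
- Transcripts with an empty CDS interval are loaded but excluded from
  peptide generation, with a log message.
- Windows shorter than the requested length (tiny proteins) are dropped by
  default (`keep_short = TRUE` retains them); binding predictors expect
  fixed lengths.
- Default peptide lengths are 8–11 for HLA class I and 15 for class II —
  the community-standard windows of the external predictors.
- The CCF grid step defaults to 0.01; the posterior median's tie-break is
  "smallest grid value reaching CDF 0.5".

## Problem sizes used in the checks

The automated checks run the construction-vs-oracle comparison on 200
random SNVs and 100 random indels (k = 3 windows on ~8 toy transcripts),
1000 random posterior evaluations, 200 posterior-recovery replicates at
read depth 1000, and toy pipelines of a handful of variants — sizes at
which every path, including the brute-force oracles, completes in seconds
to a couple of minutes on one core.

One caveat worth stating precisely: at depth $N = 1000$, purity 0.8 and
$q = 2$, the binomial sampling noise of $a/N$ maps to a standard deviation
of about 0.034 on the CCF scale, so the probability that the posterior
median lands within $\pm 0.05$ of the true CCF is 0.897 (computed exactly
by enumerating the median over all $a$) — no estimator at this depth can
place 95% of replicates in that band. The recovery test therefore checks
the empirical hit rate against that exactly enumerated rate.

## Known limitations

- No proteasomal-cleavage or TAP-transport modelling; prioritization stops
  at binding capability plus the genomic context factors.
- Co-occurrence is positional, not read-backed phasing: two somatic SNVs in
  one window are combined even if they might lie on different haplotypes.
- Selenoproteins and non-standard genetic codes are unsupported.
- The fusion path requires the donor breakpoint to be exonic and at or
  after the CDS start; intronic breakpoints (common in real fusions, where
  splicing determines the junction exon) are flagged unproductive rather
  than modelled.
- BAM-based allele counting is out of scope for the core path: RNA allele
  counts are consumed as a table, keeping the package free of alignment
  dependencies.
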
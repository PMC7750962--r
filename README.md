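# neopept

Candidate neoantigen peptides from somatic variants, in R.

Tumor-specific mutant peptides (neoantigens) arise when somatic mutations
alter protein sequence; those that bind the patient's HLA molecules can be
presented to T cells and are prime targets for cancer immunotherapy.
`neopept` is a pipeline for constructing and prioritizing such candidates
from standard genomics inputs. It is aimed at cancer-genomics analysts who
have somatic calls (VCF), a transcript annotation (refFlat/GenePred) and an
HLA typing result, and want a ranked, filterable candidate table without
leaving R.

## What it does

- **Peptide construction.** Builds mutant peptide windows for every
  supported event class by editing the transcript's cDNA and re-translating:
  - missense SNVs: every k-mer covering the altered residue, paired with the
    positionally matched wild-type k-mer;
  - in-frame and out-of-frame (frameshift) indels: frameshifts are translated
    from the start codon through the first downstream stop (or transcript
    end, flagged), and every window containing a novel residue is emitted;
  - structural variants in VCF break-end (BND) notation: fusion transcripts
    are assembled from the donor 5' portion and the acceptor portion dictated
    by the bracket orientation, translated, and windows occurring in either
    parent protein are removed;
  - raw mutant RNA sequences (e.g. an externally assembled fusion), filtered
    against the reference proteins of the stated gene;
  - optional co-occurrence patterns: multiple SNVs on one peptide, SNVs
    inside a frameshift's novel region, and germline SNPs applied to both
    the mutant and the wild-type sequence.
- **Wild-type exclusion.** No emitted peptide ever matches a substring of
  any loaded wild-type protein.
- **Binding capability.** Parsers for netMHCpan 4.0, netMHCIIpan 3.2 and
  MHCflurry output attach IC50 (nM) and %rank per peptide–allele pair; a
  deterministic surrogate predictor makes the whole pipeline runnable and
  testable offline.
- **Quantification.** Total gene expression `E`, allele-specific expression
  (`VAF × E`, or RNA-count based), and tumor subclonality as a grid
  posterior over the cancer-cell fraction (CCF).
- **Prioritization.** Composite priority scores on either scale:

  `P_I = L_I(I_m) · f(A, E) · (1 − 2^(−M) L_I(I_w)) · C`

  `P_R = L_R(R_m) · f(A, E) · (1 − 2^(−M) L_R(R_w)) · C`

  with `f(A, E) = tanh(g(A)·E)`, `g(A) = tanh(5A)`,
  `L_I(x) = 1/(1 + exp(0.015(x − 500)))`, `L_R(x) = 1/(1 + exp(5(x − 2)))`
  and clonality factor `C(x) = 1/(1 + exp(−30(x − 0.8)))` evaluated at the
  posterior median CCF. `I_m/I_w` are mutant/wild-type IC50, `R_m/R_w` the
  %ranks, `A` the variant allele frequency, `M` the mutant–wild-type
  mismatch count. A rank-based comparison score in the style of earlier
  prioritizers is reported alongside.

The CCF posterior treats a variant seen in `a` of `N` reads at purity
`α` and total somatic copy number `q` as binomial with success rate
`f(c) = αc / (2(1 − α) + αq)` under a uniform prior on `c ∈ (0, 1]`.

## Worked example

The built-in toy fixture has two single-exon genes (`TOYG1`, protein
`MDEKL`; `TOYG2`, protein `MDE`) and a somatic VCF with a missense SNV, a
synonymous SNV and a 1-bp frameshift deletion:

```r
library(neopept)
fx <- toy_fixture()
paths <- write_fixture(fx, "ex")
write_toy_vcf("ex/somatic.vcf")
writeLines("HLA-A*02:01", "ex/hla.txt")
writeLines(c("TOYG1\t4.0", "TOYG2\t1.5"), "ex/expr.tsv")
writeLines("chrT\t1\t100\t1\t1", "ex/cn.tsv")

res <- neo_run("ex/genome.fa", "ex/transcripts.refflat", "ex/hla.txt",
               vcf_file = "ex/somatic.vcf", expression_file = "ex/expr.tsv",
               copy_number_file = "ex/cn.tsv", purity = 0.8,
               lengths = 3, predictor_seed = 0, out_dir = "exout")
res$report[, c("mut_peptide", "wt_peptide", "ic50_mut", "ccf_median",
               "score_priority_ic50")]
```

```
  mut_peptide wt_peptide  ic50_mut ccf_median score_priority_ic50
1         MDN       <NA>     4.228       0.64           6.970e-03
2         DNE       <NA>     9.197       0.64           6.970e-03
3         MNE        MDE 15799.061       0.83          1.537e-100
4         NEK        DEK 33713.686       0.83          1.524e-217
```

Reading the output: the synonymous SNV yields nothing; the missense SNV
yields the two 3-mers covering the changed residue (`MNE`, `NEK`) paired
with their wild-type windows; the frameshift yields the two novel-region
windows (`MDN`, `DNE`) with no wild-type counterpart. Here the surrogate
predictor happens to assign strong binding (low IC50) to the frameshift
peptides, so they rank on top; the missense windows bind poorly and their
scores collapse through the logistic transform. The CCF medians (0.64
subclonal-ish, 0.83 near-clonal) come from each variant's read counts and
the provided copy-number/purity, and scale the scores through the
clonality factor. `neo_run()` also writes `peptides_mut.fasta`,
`peptides_wt.fasta` and `report.tsv` (the full fixed-schema table whose
missing optionals are `.`).

A thin CLI with `run`, `fixtures` and `filter` subcommands is installed at
`inst/cli/neopept`.

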
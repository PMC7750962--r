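Package: neopept
Title: Neoantigen Candidate Peptides from Somatic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs tumor-specific mutant peptides from somatic SNVs,
    insertions/deletions, structural-variant breakends (gene fusions) and raw
    mutant RNA sequences, using a genome FASTA and refFlat/GenePred transcript
    models. Attaches MHC binding capability (parsers for netMHCpan, netMHCIIpan
    and MHCflurry output plus a deterministic offline surrogate predictor),
    total and allele-specific RNA expression, and a grid posterior over the
    cancer-cell fraction computed from read counts, tumor purity and somatic
    copy number. Candidates are filtered against the wild-type proteome and
    ranked with logistic/tanh composite priority scores on either IC50 or
    percentile rank.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
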
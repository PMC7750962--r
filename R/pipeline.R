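# End-to-end pipeline: files in, FASTA + report out.

#' Run the neoantigen candidate pipeline
#'
#' Loads the genome and transcript models, reads somatic variants (VCF or
#' pre-annotated table), optional breakend SVs, optional mutant RNA
#' sequences; builds mutant/wild-type peptide windows per event class;
#' filters candidates matching the wild-type proteome; attaches binding
#' capability, expression, allele-specific expression and the CCF posterior
#' median; and writes the mutant/wild-type FASTA pair plus the integrated
#' report TSV.
#'
#' @param genome_file Genome FASTA.
#' @param transcripts_file refFlat/GenePred TSV.
#' @param hla_file HLA allele list.
#' @param vcf_file Somatic SNV/indel VCF, or NULL.
#' @param sv_vcf_file BND-format SV VCF, or NULL.
#' @param rna_sequences Named character vector of mutant RNA sequences
#'   (names are gene symbols or accessions), or NULL.
#' @param annotated_file Pre-annotated variant table, or NULL (alternative
#'   to `vcf_file`).
#' @param annotated_dialect `"annovar"` or `"vep_minimal"`.
#' @param expression_file Gene-expression TSV, or NULL.
#' @param allele_count_file RNA allele-count TSV, or NULL.
#' @param copy_number_file ASCAT-style segment TSV, or NULL.
#' @param purity Tumor purity in (0, 1]; required with `copy_number_file`.
#' @param snp_vcf_file Germline SNP VCF, or NULL (used only when
#'   `policy$enable_snp_integration`).
#' @param lengths Peptide lengths; defaults to 8-11 (HLA class I). Use 15
#'   for class II.
#' @param predictor Binding backend passed to [predict_binding()].
#' @param predictor_seed Seed for the surrogate backend.
#' @param score_mode `"ic50"` or `"rank"`.
#' @param policy A [combination_policy()].
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with `candidates`, `report`, `paths` and a
#'   `log` of substitution/skip counts.
#' @export
neo_run <- function(genome_file, transcripts_file, hla_file,
                    vcf_file = NULL, sv_vcf_file = NULL,
                    rna_sequences = NULL,
                    annotated_file = NULL, annotated_dialect = "annovar",
                    expression_file = NULL, allele_count_file = NULL,
                    copy_number_file = NULL, purity = NULL,
                    snp_vcf_file = NULL,
                    lengths = 8:11, predictor = "surrogate",
                    predictor_seed = 0L, score_mode = "ic50",
                    policy = combination_policy(), out_dir = ".") {
  genome <- load_genome(genome_file)
  txs <- read_refflat(transcripts_file)
  alleles <- parse_hla_list(hla_file)
  log <- list(n_noncoding = 0L, n_synonymous = 0L, n_wildtype_removed = 0L)

  avs <- list()
  if (!is.null(vcf_file)) {
    variants <- read_vcf(vcf_file, "small_variant")
    for (i in seq_len(nrow(variants)))
      avs <- c(avs, annotate_variant(variants[i, ], txs, genome))
  }
  if (!is.null(annotated_file))
    avs <- c(avs, read_annotated_table(annotated_file, annotated_dialect,
                                       txs, genome))
  snps <- list()
  if (!is.null(snp_vcf_file) && policy$enable_snp_integration) {
    snp_records <- read_vcf(snp_vcf_file, "snp")
    for (i in seq_len(nrow(snp_records)))
      snps <- c(snps, annotate_variant(snp_records[i, ], txs, genome))
  }

  cands <- empty_candidates()
  use_patterns <- policy$enable_multi_snv || policy$enable_frameshift_snv ||
    policy$enable_snp_integration
  if (use_patterns) {
    by_tx <- split(c(avs, snps),
                   vapply(c(avs, snps), `[[`, "", "transcript_id"))
    for (ev in by_tx) {
      coding <- Filter(function(e)
        e$effect %in% c("missense", "inframe_indel", "frameshift",
                        "stop_gain", "stop_loss") ||
          identical(e$variant$origin, "germline_snp"), ev)
      som_n <- sum(vapply(coding, function(e)
        !identical(e$variant$origin, "germline_snp"), TRUE))
      if (som_n == 0L) next
      ord <- order(vapply(coding, function(e) e$cds_pos %||% NA_integer_,
                          1L))
      coding <- coding[ord]
      for (pat in enumerate_patterns(coding, policy)) {
        tx <- coding[[pat$somatic[1L]]]$tx
        cands <- rbind(cands, build_pattern_peptides(tx, genome, coding,
                                                     pat, lengths))
      }
    }
  } else {
    for (av in avs) {
      if (av$effect %in% c("missense", "stop_gain", "stop_loss")) {
        cands <- rbind(cands, build_snv_peptides(av, genome, lengths))
      } else if (av$effect %in% c("inframe_indel", "frameshift")) {
        cands <- rbind(cands, build_indel_peptides(av, genome, lengths))
      } else if (av$effect == "synonymous") {
        log$n_synonymous <- log$n_synonymous + 1L
      } else {
        log$n_noncoding <- log$n_noncoding + 1L
      }
    }
  }
  if (!is.null(sv_vcf_file)) {
    bnds <- read_vcf(sv_vcf_file, "sv")
    for (fc in pair_breakends(bnds))
      cands <- rbind(cands, build_fusion_peptides(fc, txs, genome, lengths))
  }
  if (!is.null(rna_sequences)) {
    for (i in seq_along(rna_sequences))
      cands <- rbind(cands, build_rna_peptides(rna_sequences[[i]],
                                               names(rna_sequences)[i],
                                               txs, genome, lengths))
  }

  proteome <- wildtype_proteome(txs, genome)
  cands <- filter_wildtype_matches(cands, proteome)
  log$n_wildtype_removed <- attr(cands, "n_removed")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mut_fasta = file.path(out_dir, "peptides_mut.fasta"),
                wt_fasta = file.path(out_dir, "peptides_wt.fasta"),
                report = file.path(out_dir, "report.tsv"),
                config = file.path(out_dir, "run_config.json"))
  write_peptide_fasta(cands, paths$mut_fasta, paths$wt_fasta)

  bindings <- predict_binding(cands, alleles, predictor,
                              seed = predictor_seed)
  expression <- if (!is.null(expression_file))
    read_expression_table(expression_file) else NULL
  allele_counts <- if (!is.null(allele_count_file))
    read_allele_counts(allele_count_file) else NULL
  copy_number <- if (!is.null(copy_number_file))
    read_copy_number(copy_number_file) else NULL
  report <- build_report(cands, bindings, alleles, score_mode,
                         expression = expression,
                         allele_counts = allele_counts,
                         copy_number = copy_number, purity = purity)
  write_report(report, paths$report)
  writeLines(config_json(list(lengths = lengths, predictor = predictor,
                              predictor_seed = predictor_seed,
                              score_mode = score_mode,
                              purity = purity)), paths$config)
  invisible(list(candidates = cands, report = report, paths = paths,
                 log = log))
}

# Tiny flat JSON echo of the run configuration (reproducibility record).
config_json <- function(x) {
  enc <- vapply(names(x), function(k) {
    v <- x[[k]]
    val <- if (is.null(v)) "null"
           else if (is.character(v)) paste0('"', v, '"')
           else if (length(v) > 1L) paste0("[", paste(v, collapse = ","), "]")
           else as.character(v)
    paste0('"', k, '": ', val)
  }, character(1L))
  paste0("{", paste(enc, collapse = ", "), "}")
}
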
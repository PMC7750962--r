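# Score factor functions, priority/previous scores, report assembly,
# filters, determinism.

test_that("logistic factors hit their midpoints and saturate", {
  expect_equal(logistic_ic50(500), 0.5, tolerance = 1e-12)
  expect_equal(logistic_ic50(0), 1 / (1 + exp(-7.5)), tolerance = 1e-12)
  expect_lt(logistic_ic50(1e6), 1e-12)
  expect_equal(logistic_rank(2), 0.5, tolerance = 1e-12)
  expect_equal(logistic_rank(0), 1 / (1 + exp(-10)), tolerance = 1e-12)
  expect_lt(logistic_rank(100), 1e-12)
  expect_equal(clonality_factor(0.8), 0.5, tolerance = 1e-12)
  expect_equal(clonality_factor(1.0), 1 / (1 + exp(-6)), tolerance = 1e-12)
  expect_lt(clonality_factor(0.01), 1e-9)
})

test_that("tanh factors vanish at zero and saturate with expression", {
  expect_equal(allele_factor(0), 0)
  expect_equal(allele_factor(1), tanh(5), tolerance = 1e-12)
  expect_equal(expression_factor(0.5, 0), 0)
  expect_equal(expression_factor(0, 10), 0)
  expect_equal(expression_factor(1, 1), tanh(tanh(5)), tolerance = 1e-12)
  expect_gt(expression_factor(1, 1000), 1 - 1e-9)
})

test_that("all factors are bounded in [0,1] and monotone over dense grids", {
  # strictly decreasing where not saturated to double-precision limits,
  # non-increasing and bounded everywhere
  ic <- seq(0, 50000, length.out = 2000)
  expect_true(all(diff(logistic_ic50(ic)) <= 0))
  expect_true(all(diff(logistic_ic50(seq(0, 3000, by = 10))) < 0))
  expect_true(all(logistic_ic50(ic) >= 0 & logistic_ic50(ic) <= 1))
  rk <- seq(0, 100, length.out = 2000)
  expect_true(all(diff(logistic_rank(rk)) <= 0))
  expect_true(all(diff(logistic_rank(seq(0, 10, by = 0.05))) < 0))
  expect_true(all(logistic_rank(rk) >= 0 & logistic_rank(rk) <= 1))
  A <- seq(0, 1, length.out = 500)
  expect_true(all(diff(allele_factor(A)) > 0))
  expect_true(all(allele_factor(A) >= 0 & allele_factor(A) <= 1))
  E <- seq(0, 20, length.out = 500)
  expect_true(all(diff(expression_factor(0.5, E)) >= 0))
  expect_true(all(diff(expression_factor(0.5, seq(0, 3, by = 0.01))) > 0))
  expect_true(all(diff(expression_factor(A, 2)) > 0))
  expect_true(all(expression_factor(A, 2) >= 0 & expression_factor(A, 2) <= 1))
  x <- seq(0.01, 1, length.out = 500)
  expect_true(all(diff(clonality_factor(x)) > 0))
  expect_true(all(clonality_factor(x) >= 0 & clonality_factor(x) <= 1))
})

test_that("priority_score composes the verified factors with neutral substitutions", {
  # I_m = 500, no wild type, A = 1, E = 1, median CCF = 0.8
  got <- priority_score(list(I_m = 500, R_m = 1, A = 1, E = 1,
                             C_median = 0.8), "ic50")
  expect_equal(got$score, 0.5 * tanh(tanh(5)) * 1 * 0.5, tolerance = 1e-12)
  expect_true("wt_term=1" %in% got$substitutions)

  # missing E and CCF substitute neutral values, flagged
  g2 <- priority_score(list(I_m = 500, A = 1), "ic50")
  expect_setequal(g2$substitutions, c("E=1", "wt_term=1", "C=1"))
  expect_equal(g2$score, 0.5 * tanh(tanh(5)), tolerance = 1e-12)

  # enormous mutant IC50 drives the score to zero
  expect_lt(priority_score(list(I_m = 1e6, A = 1, E = 5, M = 1,
                                C_median = 1), "ic50")$score, 1e-12)
  # weak wild-type binder (I_w large) pushes the wild-type term to 1
  strong_wt <- priority_score(list(I_m = 100, I_w = 10, M = 1, A = 1,
                                   E = 1), "ic50")
  weak_wt <- priority_score(list(I_m = 100, I_w = 1e7, M = 1, A = 1,
                                 E = 1), "ic50")
  no_wt <- priority_score(list(I_m = 100, A = 1, E = 1), "ic50")
  expect_equal(weak_wt$score, no_wt$score, tolerance = 1e-9)
  expect_lt(strong_wt$score, weak_wt$score)

  # missing VAF: score is missing-flagged
  miss <- priority_score(list(I_m = 100, E = 1), "ic50")
  expect_true(is.na(miss$score))
  expect_equal(miss$substitutions, "A_missing")
})

test_that("priority_score is monotone in each input", {
  base <- list(I_m = 400, R_m = 1.5, I_w = 800, R_w = 4, M = 2, A = 0.5,
               E = 2, C_median = 0.7)
  s <- function(ins, mode = "ic50") priority_score(ins, mode)$score
  upd <- function(k, v) { b <- base; b[[k]] <- v; b }
  # decreasing in mutant affinity (both modes)
  expect_true(all(diff(vapply(seq(10, 5000, length.out = 50),
                              function(x) s(upd("I_m", x)), 0)) < 0))
  expect_true(all(diff(vapply(seq(0.1, 50, length.out = 50),
                              function(x) s(upd("R_m", x), "rank"), 0)) < 0))
  # non-decreasing in A, E, M and median CCF
  for (k in c("A", "E", "M", "C_median")) {
    hi <- switch(k, A = 1, E = 10, M = 8, C_median = 1)
    lo <- switch(k, A = 0.05, E = 0.1, M = 1, C_median = 0.05)
    vals <- vapply(seq(lo, hi, length.out = 40),
                   function(x) s(upd(k, x)), 0)
    expect_true(all(diff(vals) >= -1e-15))
  }
})

test_that("previous_score matches independent hand evaluation", {
  expect_equal(previous_score(list(R_m = 1, A = 0, E = 5, M = 1))$score, 0)
  # no wild type: reduces to L_R(R_m) * E * A
  got <- previous_score(list(R_m = 1, A = 0.4, E = 5))
  expect_equal(got$score, (1 / (1 + exp(5 * (1 - 2)))) * 5 * 0.4,
               tolerance = 1e-12)
  full <- previous_score(list(R_m = 1, R_w = 3, M = 2, A = 0.4, E = 5))
  lr <- function(x) 1 / (1 + exp(5 * (x - 2)))
  expect_equal(full$score, lr(1) * 5 * 0.4 * (1 - 2^-2 * lr(3)),
               tolerance = 1e-12)
})

toy_report <- function(score_mode = "ic50", alleles = NULL, ...) {
  fx <- toy_fixture()
  avs <- list(
    annotate_variant(list(contig = "chrT", pos = 4L, ref = "G", alt = "A",
                          depth_N = 20L, alt_reads_a = 8L, vaf = 0.4,
                          origin = "somatic"), fx$transcripts,
                     fx$genome)[[1L]],
    annotate_variant(list(contig = "chrT", pos = 36L, ref = "TG", alt = "T",
                          depth_N = 40L, alt_reads_a = 10L, vaf = 0.25,
                          origin = "somatic"), fx$transcripts,
                     fx$genome)[[1L]])
  cands <- rbind(build_snv_peptides(avs[[1L]], fx$genome, 3L),
                 build_indel_peptides(avs[[2L]], fx$genome, 3L))
  cands <- filter_wildtype_matches(
    cands, neopept:::wildtype_proteome(fx$transcripts, fx$genome))
  alleles <- alleles %||% rbind(normalize_hla("A0201"),
                                normalize_hla("B1501"))
  bindings <- predict_binding(cands, alleles, "surrogate", seed = 5L)
  build_report(cands, bindings, alleles, score_mode, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("build_report emits one row per candidate-allele pair, sorted", {
  rep <- toy_report()
  expect_equal(nrow(rep), 8L)          # 4 candidates x 2 alleles
  expect_identical(names(rep), neopept:::REPORT_COLUMNS)
  expect_true(all(diff(rep$score_priority_ic50) <= 1e-15))
  # wild-type columns filled only for paired candidates
  expect_equal(sum(!is.na(rep$wt_peptide)), 4L)
  expect_true(all(is.na(rep$ic50_wt) == is.na(rep$wt_peptide)))
  # missing expression and CCF flagged as substitutions
  expect_true(all(grepl("E=1", rep$substitutions)))
  expect_true(all(grepl("C=1", rep$substitutions)))

  # a missing binding pair is a hard error
  fxa <- rbind(normalize_hla("A0201"))
  cands <- data.frame(mut_peptide = "MNE", wt_peptide = "MDE",
                      gene_symbol = "TOYG1", transcript_id = "NM_TOY1",
                      event_class = "snv", mutation_protein_pos = 2L,
                      window_start = 1L, length = 3L, pattern_id = "x",
                      source_variants = "k", no_stop_flag = FALSE,
                      aa_change = "D2N", contig = "chrT", pos = 4L,
                      ref = "G", alt = "A", depth_N = 20L, alt_reads_a = 8L,
                      vaf = 0.4, exon_start = 0L, exon_end = 18L,
                      stringsAsFactors = FALSE)
  bindings <- surrogate_predict("MNE", "HLA-A*02:01", 0L)
  expect_error(build_report(cands, bindings, fxa), "missing binding result")
})

test_that("report attaches expression, ASE and CCF when inputs are given", {
  expr <- tempfile(fileext = ".tsv")
  writeLines(c("TOYG1\t4.0", "TOYG2\t1.5"), expr)
  counts <- tempfile(fileext = ".tsv")
  writeLines("chrT\t4\t6\t2", counts)
  cn <- tempfile(fileext = ".tsv")
  writeLines("chrT\t1\t100\t1\t1", cn)
  rep <- toy_report(expression = read_expression_table(expr),
                    allele_counts = read_allele_counts(counts),
                    copy_number = read_copy_number(cn), purity = 0.8)
  snv_rows <- rep[rep$gene_symbol == "TOYG1", ]
  expect_equal(unique(snv_rows$expression_total), 4.0)
  expect_equal(unique(snv_rows$expression_allele_specific), 0.4 * 4.0)
  expect_equal(unique(snv_rows$rna_vaf), 0.25)
  expect_equal(unique(snv_rows$expression_allele_specific_rna), 0.25 * 4.0)
  # CCF median matches a direct posterior evaluation (a=8, N=20, q=2)
  expect_equal(unique(snv_rows$ccf_median),
               ccf_posterior(8, 20, 0.8, 2)$median_c)
  expect_false(any(grepl("E=1", snv_rows$substitutions)))
})

test_that("apply_filters is conjunctive and drops missing-value rows", {
  rows <- data.frame(ic50_mut = c(100, 499, 501), rank_mut = c(0.1, 3, 9),
                     expression_total = c(5, NA, 2),
                     ccf_median = c(0.9, 0.2, NA),
                     score_priority_ic50 = c(0.5, 0.1, 0.01))
  expect_equal(nrow(apply_filters(rows, max_ic50 = 500)), 2L)
  expect_equal(nrow(apply_filters(rows)), 3L)                # identity
  f <- apply_filters(rows, min_ccf = 0.1)
  expect_equal(nrow(f), 2L)              # NA CCF row dropped
  expect_equal(attr(f, "n_dropped_missing"), 1L)
  # brute-force scan oracle for the combined filter
  combined <- apply_filters(rows, max_ic50 = 500, min_expression = 1,
                            min_ccf = 0.5)
  manual <- rows[!is.na(rows$expression_total) & !is.na(rows$ccf_median) &
                 rows$ic50_mut <= 500 & rows$expression_total >= 1 &
                 rows$ccf_median >= 0.5, ]
  expect_equal(nrow(combined), nrow(manual))
})

test_that("two identical pipeline runs produce byte-identical outputs", {
  fxp1 <- toy_files()
  out1 <- file.path(fxp1[["dir"]], "run1")
  out2 <- file.path(fxp1[["dir"]], "run2")
  r1 <- neo_run(fxp1[["genome"]], fxp1[["transcripts"]], fxp1[["hla"]],
                vcf_file = fxp1[["vcf"]], lengths = 3L, predictor_seed = 9L,
                out_dir = out1)
  r2 <- neo_run(fxp1[["genome"]], fxp1[["transcripts"]], fxp1[["hla"]],
                vcf_file = fxp1[["vcf"]], lengths = 3L, predictor_seed = 9L,
                out_dir = out2)
  for (f in c("peptides_mut.fasta", "peptides_wt.fasta", "report.tsv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  expect_identical(r1$report, r2$report)
})
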
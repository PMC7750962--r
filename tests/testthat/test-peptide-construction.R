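# Peptide window construction for SNVs, indels, fusions, RNA sequences;
# combination patterns; wild-type filtering; FASTA output.

toy_av <- function(fx, pos, ref, alt, depth = 20L, alt_reads = 8L) {
  avs <- annotate_variant(
    list(contig = "chrT", pos = pos, ref = ref, alt = alt, depth_N = depth,
         alt_reads_a = alt_reads, vaf = alt_reads / depth,
         origin = "somatic"),
    fx$transcripts, fx$genome)
  avs[[1L]]
}

test_that("missense SNV windows enumerate k-mers over the altered residue", {
  fx <- toy_fixture()                      # NM_TOY1 protein MDEKL
  av <- toy_av(fx, 4L, "G", "A")           # codon 2 GAT -> AAT
  cands <- build_snv_peptides(av, fx$genome, 3L)
  expect_equal(cands$mut_peptide, c("MNE", "NEK"))
  expect_equal(cands$wt_peptide, c("MDE", "DEK"))
  expect_equal(cands$mutation_protein_pos, c(2L, 2L))
  expect_equal(cands$aa_change, rep("D2N", 2L))

  # protein shorter than the window: dropped unless short emission enabled
  expect_equal(nrow(build_snv_peptides(av, fx$genome, 9L)), 0L)
  short <- build_snv_peptides(av, fx$genome, 9L, keep_short = TRUE)
  expect_equal(short$mut_peptide, "MNEKL")

  # mutation at residue 1: only windows starting at residue 1
  av1 <- toy_av(fx, 1L, "A", "C")          # ATG -> CTG (M1L)
  c1 <- build_snv_peptides(av1, fx$genome, 3L)
  expect_true(all(c1$window_start == 1L))
})

test_that("frameshift deletion emits novel-region windows without wild type", {
  fx <- toy_fixture()                      # NM_TOY2: cDNA ATGGATGAATGAATAATAG
  av <- toy_av(fx, 36L, "TG", "T")         # deletes the 7th coding base
  cands <- build_indel_peptides(av, fx$genome, 3L)
  expect_setequal(cands$mut_peptide, c("MDN", "DNE"))
  expect_true(all(is.na(cands$wt_peptide)))
  expect_equal(cands$event_class, rep("frameshift", 2L))
  expect_false(any(cands$no_stop_flag))
  # independent oracle: translate the edited cDNA directly
  expect_identical(oracle_translate("ATGGATAATGAATAATAG")$protein, "MDNE")
})

test_that("a frameshift hitting an immediate stop yields no candidates", {
  # deleting the 4th coding base of ATGTGATTT... gives ATG TGA ... -> stop
  p <- write_tmp_fasta(list(chrT = "ATGTTGATTTACCCGGG"))
  g <- load_genome(p)
  tx <- transcript_model("t1", "G1", "chrT", "+", cbind(0L, 17L), 0L, 9L)
  txs <- suppressMessages(transcript_set(list(tx)))
  av <- annotate_variant(list(contig = "chrT", pos = 3L, ref = "GT",
                              alt = "G", depth_N = 10L, alt_reads_a = 5L,
                              vaf = 0.5, origin = "somatic"), txs, g)[[1L]]
  expect_equal(av$effect, "frameshift")
  expect_equal(nrow(build_indel_peptides(av, g, 3L)), 0L)
})

test_that("in-frame deletion windows overlap the junction with homologous wild type", {
  # MDEKL minus residue 3 (GAA): in-frame deletion
  fx <- toy_fixture()
  av <- toy_av(fx, 6L, "TGAA", "T")        # deletes cds 7-9
  expect_equal(av$effect, "inframe_indel")
  cands <- build_indel_peptides(av, fx$genome, 3L)
  # mutant protein MDKL; windows cover the D|K junction
  expect_true(all(grepl("DK", cands$mut_peptide)))
  expect_true(all(!is.na(cands$wt_peptide)))
  expect_true(all(nchar(cands$mut_peptide) == nchar(cands$wt_peptide)))
  # full-translation diff oracle
  contig <- unclass(fx$genome)[["chrT"]]
  expect_setequal(cands$mut_peptide,
                  oracle_expected_windows(contig, fx$transcripts$NM_TOY1,
                                          6L, "TGAA", "T", 3L))
})

test_that("window enumeration equals the full-translation oracle on random events", {
  fx <- make_fixture(n_transcripts = 5L, cds_len_range = c(30L, 60L),
                     seed = 31L)
  vars <- random_coding_variants(fx, n_snv = 40L, n_indel = 20L, seed = 32L)
  contig <- unclass(fx$genome)[["chrS"]]
  n_checked <- 0L
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    tx <- fx$transcripts[[v$transcript_id]]
    variant <- list(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
                    depth_N = 10L, alt_reads_a = 5L, vaf = 0.5,
                    origin = "somatic")
    got <- package_windows(fx, c(variant, transcript_id = v$transcript_id),
                           3L)
    if (got$effect %in% c("noncoding")) next
    exp_k <- oracle_expected_windows(contig, tx, v$pos, v$ref, v$alt, 3L)
    expect_setequal(got$kmers, exp_k)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 40L)
})

test_that("synonymous variants yield zero candidates end to end", {
  fx <- toy_fixture()
  av <- toy_av(fx, 9L, "A", "G")
  expect_equal(av$effect, "synonymous")
  # the pipeline never routes synonymous events to a builder; assert the
  # oracle agrees there is nothing to emit
  contig <- unclass(fx$genome)[["chrT"]]
  expect_length(oracle_expected_windows(contig, fx$transcripts$NM_TOY1,
                                        9L, "A", "G", 3L), 0L)
})

test_that("in-frame fusions keep only junction-spanning windows", {
  fx <- fusion_fixture()
  vcf <- write_tmp_lines(fusion_vcf_lines(pos = 9L, mate_pos = 14L),
                         ext = ".vcf")
  fc <- pair_breakends(read_vcf(vcf, "sv"))[[1L]]
  cands <- build_fusion_peptides(fc, fx$transcripts, fx$genome, 3L)
  # fused protein MDEFW; MDE is in the donor (MDEKL) so only DEF/EFW remain
  expect_setequal(cands$mut_peptide, c("DEF", "EFW"))
  expect_true(all(is.na(cands$wt_peptide)))
  expect_equal(unique(cands$event_class), "fusion")
  # substring scan of both parent proteins
  for (pep in cands$mut_peptide) {
    expect_false(grepl(pep, "MDEKL", fixed = TRUE))
    expect_false(grepl(pep, "MPRFW", fixed = TRUE))
  }
})

test_that("out-of-frame fusions emit novel residues until the stop", {
  fx <- fusion_fixture()
  vcf <- write_tmp_lines(fusion_vcf_lines(pos = 9L, mate_pos = 11L),
                         ext = ".vcf")
  fc <- pair_breakends(read_vcf(vcf, "sv"))[[1L]]
  cands <- build_fusion_peptides(fc, fx$transcripts, fx$genome, 3L)
  expect_gt(nrow(cands), 0L)
  # full-translation oracle on the joined sequence
  joined <- paste0("ATGGATGAA", substr("GGGGATGCCTCGTTTCTGGTGAACGTAC", 11L,
                                       22L))   # acceptor exon ends at 22
  mut_p <- oracle_translate(joined)$protein
  expect_true(all(vapply(cands$mut_peptide, grepl, TRUE, x = mut_p,
                         fixed = TRUE)))
  for (pep in cands$mut_peptide) {
    expect_false(grepl(pep, "MDEKL", fixed = TRUE))
    expect_false(grepl(pep, "MPRFW", fixed = TRUE))
  }
})

test_that("a fusion whose acceptor contributes an immediate stop yields nothing", {
  fx <- fusion_fixture()
  vcf <- write_tmp_lines(fusion_vcf_lines(pos = 9L, mate_pos = 20L),
                         ext = ".vcf")
  fc <- pair_breakends(read_vcf(vcf, "sv"))[[1L]]
  expect_message(cands <- build_fusion_peptides(fc, fx$transcripts,
                                                fx$genome, 3L),
                 "unproductive|no translatable")
  expect_equal(nrow(cands), 0L)
})

test_that("RNA sequences filter against the reference proteins of their gene", {
  fx <- toy_fixture()
  wt_seq <- "ATGGATGAAAAGCTTTGA"           # identical to NM_TOY1
  expect_equal(nrow(build_rna_peptides(wt_seq, "TOYG1", fx$transcripts,
                                       fx$genome, 3L)), 0L)
  # one codon changed: only windows covering the changed residue survive
  mut_seq <- "ATGGATCAAAAGCTTTGA"           # E3Q
  cands <- build_rna_peptides(mut_seq, "TOYG1", fx$transcripts, fx$genome, 3L)
  expect_setequal(cands$mut_peptide, c("MDQ", "DQK", "QKL"))
  # unknown gene reference: kept with a warning
  expect_warning(all_k <- build_rna_peptides(mut_seq, "NOSUCH",
                                             fx$transcripts, fx$genome, 3L),
                 "not in transcript set")
  expect_equal(nrow(all_k), 3L)            # MDQ.. windows of MDQKL
  # no ATG under the default frame policy
  expect_warning(none <- build_rna_peptides("CCCCCCCCCCCC", "TOYG1",
                                            fx$transcripts, fx$genome, 3L),
                 "no ATG")
  expect_equal(nrow(none), 0L)
})

test_that("pattern enumeration covers multi-SNV subsets and respects the cap", {
  fx <- toy_fixture()
  e1 <- toy_av(fx, 4L, "G", "A")
  e2 <- toy_av(fx, 7L, "G", "C")           # GAA -> CAA (E3Q)
  pol <- combination_policy(enable_multi_snv = TRUE, max_cooccurring = 3L)
  pats <- enumerate_patterns(list(e1, e2), pol)
  expect_length(pats, 3L)                  # each alone + both; all-off excluded
  expect_equal(sort(vapply(pats, function(p) length(p$somatic), 1L)),
               c(1L, 1L, 2L))
  # stable ids: re-enumeration gives identical pattern ids
  pats2 <- enumerate_patterns(list(e1, e2), pol)
  expect_identical(vapply(pats, `[[`, "", "pattern_id"),
                   vapply(pats2, `[[`, "", "pattern_id"))
  # over the cap: singletons + all-variants, with warning
  e3 <- toy_av(fx, 10L, "A", "C")
  pol1 <- combination_policy(enable_multi_snv = TRUE, max_cooccurring = 2L)
  expect_warning(pats3 <- enumerate_patterns(list(e1, e2, e3), pol1),
                 "exceeds cap")
  expect_length(pats3, 4L)
})

test_that("germline SNPs appear in both mutant and wild-type peptides", {
  fx <- toy_fixture()
  som <- toy_av(fx, 4L, "G", "A")          # D2N somatic
  snp <- annotate_variant(
    list(contig = "chrT", pos = 7L, ref = "G", alt = "C", depth_N = 30L,
         alt_reads_a = 15L, vaf = 0.5, origin = "germline_snp"),
    fx$transcripts, fx$genome)[[1L]]       # E3Q germline
  pol <- combination_policy(enable_snp_integration = TRUE)
  pats <- enumerate_patterns(list(som, snp), pol)
  expect_length(pats, 1L)
  cands <- build_pattern_peptides(fx$transcripts$NM_TOY1, fx$genome,
                                  list(som, snp), pats[[1L]], 3L)
  # wild type is the SNP-adjusted protein MDQKL; mutant is MNQKL
  expect_setequal(cands$mut_peptide, c("MNQ", "NQK"))
  expect_setequal(cands$wt_peptide, c("MDQ", "DQK"))
})

test_that("an SNV inside a frameshift's novel region edits the shifted translation", {
  fx <- toy_fixture()
  fs <- toy_av(fx, 36L, "TG", "T")          # frameshift deletion (cds 7)
  snv <- toy_av(fx, 41L, "G", "C")          # cds 11, downstream of the shift
  pol <- combination_policy(enable_frameshift_snv = TRUE,
                            max_cooccurring = 2L)
  pats <- enumerate_patterns(list(fs, snv), pol)
  both <- Filter(function(p) length(p$somatic) == 2L, pats)[[1L]]
  cands <- build_pattern_peptides(fx$transcripts$NM_TOY2, fx$genome,
                                  list(fs, snv), both, 3L)
  # oracle: apply both edits to the cDNA and translate
  expect_identical(oracle_translate("ATGGATAATCAATAATAG")$protein, "MDNQ")
  expect_setequal(cands$mut_peptide, c("MDN", "DNQ"))
  expect_true(all(is.na(cands$wt_peptide)))
})

test_that("wild-type filtering leaves exactly the informative toy candidates", {
  fx <- toy_fixture()
  missense <- build_snv_peptides(toy_av(fx, 4L, "G", "A"), fx$genome, 3L)
  frameshift <- build_indel_peptides(toy_av(fx, 36L, "TG", "T"),
                                     fx$genome, 3L)
  all_c <- rbind(missense, frameshift)
  proteome <- neopept:::wildtype_proteome(fx$transcripts, fx$genome)
  kept <- filter_wildtype_matches(all_c, proteome)
  expect_equal(nrow(kept), 4L)
  expect_setequal(kept$mut_peptide, c("MNE", "NEK", "MDN", "DNE"))
  # a candidate equal to a wild-type window elsewhere is removed
  planted <- all_c
  planted$mut_peptide[1L] <- "DEK"         # substring of MDEKL
  expect_equal(attr(filter_wildtype_matches(planted, proteome),
                    "n_removed"), 1L)
})

test_that("emitted pairs differ and mutant peptides avoid the proteome", {
  fx <- make_fixture(n_transcripts = 5L, seed = 77L)
  vars <- random_coding_variants(fx, n_snv = 30L, n_indel = 15L, seed = 78L)
  proteome <- neopept:::wildtype_proteome(fx$transcripts, fx$genome)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    got <- package_windows(fx, list(contig = v$contig, pos = v$pos,
                                    ref = v$ref, alt = v$alt, depth_N = 10L,
                                    alt_reads_a = 5L, vaf = 0.5,
                                    origin = "somatic",
                                    transcript_id = v$transcript_id), 3L)
    if (!length(got$kmers)) next
    cands <- data.frame(mut_peptide = got$kmers,
                        stringsAsFactors = FALSE)
    kept <- filter_wildtype_matches(cands, proteome)
    # surviving mutants are absent from every wild-type protein
    for (pep in kept$mut_peptide)
      expect_false(any(vapply(proteome, grepl, TRUE, pattern = pep,
                              fixed = TRUE)))
  }
})

test_that("peptide FASTA output is deterministic and headers round-trip", {
  fx <- toy_fixture()
  cands <- rbind(build_snv_peptides(toy_av(fx, 4L, "G", "A"), fx$genome, 3L),
                 build_indel_peptides(toy_av(fx, 36L, "TG", "T"),
                                      fx$genome, 3L))
  f1m <- tempfile(fileext = ".fa"); f1w <- tempfile(fileext = ".fa")
  f2m <- tempfile(fileext = ".fa"); f2w <- tempfile(fileext = ".fa")
  write_peptide_fasta(cands, f1m, f1w)
  write_peptide_fasta(cands[sample(nrow(cands)), ], f2m, f2w)
  expect_identical(readLines(f1m), readLines(f2m))
  expect_identical(readLines(f1w), readLines(f2w))
  # wild-type file holds only candidates with a wild-type counterpart
  expect_equal(sum(grepl("^>", readLines(f1w))), 2L)
  # headers parse back to candidate keys
  hdr <- sub("^>", "", grep("^>", readLines(f1m), value = TRUE))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  expect_true(all(lengths(parts) == 6L))
  expect_setequal(unique(vapply(parts, `[`, "", 2L)),
                  c("NM_TOY1", "NM_TOY2"))
})
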
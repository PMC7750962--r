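# Synthetic fixtures: deterministic toy genomes, transcript models and VCFs
# used by the test-suite and runnable end-to-end at toy scale.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codon <- function(exclude_stop = TRUE) {
  repeat {
    cod <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
    if (!exclude_stop || !(cod %in% STOP_CODONS)) return(cod)
  }
}

#' Generate a deterministic toy genome with valid transcripts
#'
#' Builds a synthetic contig carrying `n_transcripts` well-formed coding
#' transcripts (start codon, no internal stop, in-frame terminal stop),
#' optionally multi-exon and on the minus strand, separated by random spacer
#' sequence. A truth record holds each transcript's protein, derived at
#' generation time directly from the codons drawn (independently of the
#' splice/translate code path).
#'
#' @param n_transcripts Number of transcripts to generate.
#' @param cds_len_range Integer range (multiples of 3 are drawn from it) for
#'   the CDS length, start and stop codons included.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param multi_exon Allow 2-3 exons per transcript.
#' @param minus_strand Allow minus-strand transcripts.
#' @param utr Add short untranslated regions around the CDS.
#' @return List with `genome` (`genome_seq`), `transcripts`
#'   (`transcript_set`) and `truth` (data.frame of transcript_id, gene_symbol,
#'   protein).
#' @export
make_fixture <- function(n_transcripts = 3L, cds_len_range = c(30L, 60L),
                         seed = 1L, multi_exon = TRUE, minus_strand = TRUE,
                         utr = TRUE) {
  stopifnot(n_transcripts >= 1L, length(cds_len_range) == 2L)
  choices <- seq.int(cds_len_range[1L], cds_len_range[2L])
  choices <- choices[choices %% 3L == 0L & choices >= 9L]
  if (!length(choices)) stop("cds_len_range admits no feasible CDS length")
  set.seed(seed)
  contig <- "chrS"
  genome_parts <- character(0L)
  cursor <- 0L
  txs <- list()
  truth <- list()
  for (i in seq_len(n_transcripts)) {
    n_cod <- sample(choices, 1L) %/% 3L
    codons <- c("ATG",
                vapply(seq_len(n_cod - 2L), function(j) random_codon(),
                       character(1L)),
                sample(STOP_CODONS, 1L))
    cds <- paste(codons, collapse = "")
    protein <- paste(Biostrings::GENETIC_CODE[codons[-length(codons)]],
                     collapse = "")
    u5 <- if (utr) sample(0:6, 1L) else 0L
    u3 <- if (utr) sample(0:6, 1L) else 0L
    tx_seq <- paste0(paste(sample(BASES, u5, replace = TRUE), collapse = ""),
                     cds,
                     paste(sample(BASES, u3, replace = TRUE), collapse = ""))
    strand <- if (minus_strand && stats::runif(1) < 0.5) "-" else "+"
    # genomic plus-strand sequence of the transcript body
    body <- if (strand == "-") revcomp(tx_seq) else tx_seq
    n_exons <- if (multi_exon) sample(1:3, 1L) else 1L
    n_exons <- min(n_exons, nchar(body) %/% 6L)
    # split the body into exons with random introns between them
    cuts <- if (n_exons > 1L)
      sort(sample(seq_len(nchar(body) - 1L), n_exons - 1L)) else integer(0L)
    seg_bounds <- cbind(c(0L, cuts), c(cuts, nchar(body)))
    spacer_len <- sample(8:20, 1L)
    spacer <- paste(sample(BASES, spacer_len, replace = TRUE), collapse = "")
    genome_parts <- c(genome_parts, spacer)
    cursor <- cursor + spacer_len
    exon_starts <- integer(n_exons); exon_ends <- integer(n_exons)
    pieces <- character(0L)
    for (e in seq_len(n_exons)) {
      if (e > 1L) {
        intron_len <- sample(4:12, 1L)
        # splice-agnostic toy introns (no GT..AG requirement)
        pieces <- c(pieces,
                    paste(sample(BASES, intron_len, replace = TRUE),
                          collapse = ""))
        cursor <- cursor + intron_len
      }
      exon_starts[e] <- cursor
      seg <- substr(body, seg_bounds[e, 1L] + 1L, seg_bounds[e, 2L])
      pieces <- c(pieces, seg)
      cursor <- cursor + nchar(seg)
      exon_ends[e] <- cursor
    }
    genome_parts <- c(genome_parts, pieces)
    # CDS bounds in genomic space: skip the UTRs in transcript orientation
    tx_start <- exon_starts[1L]; tx_end <- exon_ends[n_exons]
    if (strand == "+") {
      cds_start_g <- nth_exonic_pos(exon_starts, exon_ends, u5 + 1L)
      cds_end_g <- nth_exonic_pos(exon_starts, exon_ends, u5 + nchar(cds)) + 1L
    } else {
      total <- nchar(body)
      cds_end_g <- nth_exonic_pos(exon_starts, exon_ends, total - u5) + 1L
      cds_start_g <- nth_exonic_pos(exon_starts, exon_ends,
                                    total - u5 - nchar(cds) + 1L)
    }
    id <- sprintf("NM_%04d", i)
    txs[[i]] <- transcript_model(id, sprintf("GENE%d", i), contig, strand,
                                 cbind(exon_starts, exon_ends),
                                 cds_start_g, cds_end_g)
    truth[[i]] <- data.frame(transcript_id = id,
                             gene_symbol = sprintf("GENE%d", i),
                             protein = protein, stringsAsFactors = FALSE)
  }
  tail_spacer <- paste(sample(BASES, 10L, replace = TRUE), collapse = "")
  genome <- structure(stats::setNames(paste(c(genome_parts, tail_spacer),
                                            collapse = ""), contig),
                      class = "genome_seq")
  list(genome = genome,
       transcripts = suppressMessages(transcript_set(txs)),
       truth = do.call(rbind, truth))
}

# Genomic 0-based position of the n-th exonic base (1-based n, plus order).
nth_exonic_pos <- function(starts, ends, n) {
  lens <- ends - starts
  cum <- cumsum(lens)
  ex <- which(n <= cum)[1L]
  prior <- if (ex > 1L) cum[ex - 1L] else 0L
  as.integer(starts[ex] + (n - prior) - 1L)
}

#' Write fixture files to disk
#'
#' Serializes a [make_fixture()] result (or the [toy_fixture()]) as a genome
#' FASTA, a refFlat transcript table and a truth TSV.
#'
#' @param fx Fixture list from [make_fixture()] or [toy_fixture()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(unclass(fx$genome))
  Biostrings::writeXStringSet(ss, fa, width = 70L)
  rf <- file.path(dir, "transcripts.refflat")
  rows <- vapply(unclass(fx$transcripts), function(tx) {
    paste(tx$gene_symbol, tx$transcript_id, tx$contig, tx$strand,
          tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L],
          tx$cds_start, tx$cds_end, nrow(tx$exons),
          paste0(paste(tx$exons[, 1L], collapse = ","), ","),
          paste0(paste(tx$exons[, 2L], collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(rows, rf)
  tr <- file.path(dir, "truth.tsv")
  utils::write.table(fx$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genome = fa, transcripts = rf, truth = tr))
}

#' The standard hand-built toy fixture
#'
#' Two plus-strand single-exon transcripts on one contig:
#' `NM_TOY1` with CDS `ATGGATGAAAAGCTTTGA` (protein `MDEKL`) and `NM_TOY2`
#' with CDS `ATGGATGAATGAATAATAG` span (protein `MDE`, stop at codon 4, with
#' downstream in-transcript sequence so frameshifts can run on). The
#' companion VCF ([write_toy_vcf()]) carries one synonymous SNV, one missense
#' SNV and one 1-bp frameshift deletion.
#'
#' @return Same structure as [make_fixture()].
#' @export
toy_fixture <- function() {
  s1 <- "ATGGATGAAAAGCTTTGA"            # MDEKL*
  spacer <- "CCCCCCCCCCCC"              # 12 nt
  s2 <- "ATGGATGAATGAATAATAG"           # MDE* (+ runway for frameshift)
  contig_seq <- paste0(s1, spacer, s2, "CCCC")
  genome <- structure(stats::setNames(contig_seq, "chrT"),
                      class = "genome_seq")
  tx1 <- transcript_model("NM_TOY1", "TOYG1", "chrT", "+",
                          cbind(0L, 18L), 0L, 18L)
  tx2 <- transcript_model("NM_TOY2", "TOYG2", "chrT", "+",
                          cbind(30L, 49L), 30L, 42L)  # CDS = ATGGATGAATGA
  truth <- data.frame(transcript_id = c("NM_TOY1", "NM_TOY2"),
                      gene_symbol = c("TOYG1", "TOYG2"),
                      protein = c("MDEKL", "MDE"), stringsAsFactors = FALSE)
  list(genome = genome,
       transcripts = suppressMessages(transcript_set(list(tx1, tx2))),
       truth = truth)
}

#' Write the toy somatic VCF
#'
#' Three somatic records on the [toy_fixture()] contig: a missense SNV
#' (chrT:4 G>A, codon 2 GAT>AAT, D2N), a synonymous SNV (chrT:9 A>G,
#' GAA>GAG) and a frameshift deletion (chrT:36 TG>T, removing the 7th coding
#' base of `NM_TOY2`).
#'
#' @param path Output VCF path.
#' @return Invisibly, `path`.
#' @export
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chrT\t4\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t0/1:12,8:20",
    "chrT\t9\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:15,5:20",
    "chrT\t36\t.\tTG\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:30,10:40")
  writeLines(lines, path)
  invisible(path)
}

#' Draw random coding variants on a fixture
#'
#' Samples SNVs and short indels that fall inside exons (away from exon
#' boundaries for indels) of coding fixture transcripts, in VCF-style
#' (anchored) `ref`/`alt` encoding. Used by the oracle-equivalence tests.
#'
#' @param fx Fixture from [make_fixture()].
#' @param n_snv,n_indel Counts to draw.
#' @param seed Integer seed.
#' @return data.frame with contig, pos (1-based), ref, alt, transcript_id.
#' @export
random_coding_variants <- function(fx, n_snv = 50L, n_indel = 20L, seed = 1L) {
  set.seed(seed)
  txs <- Filter(is_coding, unclass(fx$transcripts))
  contig <- function(tx) unclass(fx$genome)[[tx$contig]]
  out <- list()
  draw_cds_gpos <- function(tx, margin) {
    # random CDS position whose +/- margin neighbourhood stays in one exon
    # and inside the CDS (edits must not spill into the UTRs)
    for (attempt in 1:50) {
      cp <- sample(seq_len(cds_len(tx)), 1L)
      g <- cds_to_genomic(tx, cp)
      ex <- which(tx$exons[, 1L] <= g - 1L & g - 1L < tx$exons[, 2L])
      in_exon <- g - 1L - margin >= tx$exons[ex, 1L] &&
        g - 1L + margin < tx$exons[ex, 2L]
      if (!in_exon) next
      flank <- seq.int(g - margin, g + margin)
      flank <- flank[flank >= 1L]
      if (all(!is.na(vapply(flank, function(p) genomic_to_cds(tx, p),
                            integer(1L))))) return(g)
    }
    NA_integer_
  }
  for (i in seq_len(n_snv)) {
    tx <- txs[[sample(length(txs), 1L)]]
    g <- draw_cds_gpos(tx, 0L)
    if (is.na(g)) next
    ref <- substr(contig(tx), g, g)
    alt <- sample(setdiff(BASES, ref), 1L)
    out[[length(out) + 1L]] <- data.frame(
      contig = tx$contig, pos = g, ref = ref, alt = alt,
      transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_indel)) {
    tx <- txs[[sample(length(txs), 1L)]]
    k <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {                       # deletion of k bases
      g <- draw_cds_gpos(tx, k + 1L)
      if (is.na(g)) next
      ref <- substr(contig(tx), g, g + k)
      alt <- substr(contig(tx), g, g)
    } else {                                           # insertion of k bases
      g <- draw_cds_gpos(tx, 1L)
      if (is.na(g)) next
      ref <- substr(contig(tx), g, g)
      alt <- paste0(ref, paste(sample(BASES, k, replace = TRUE),
                               collapse = ""))
    }
    out[[length(out) + 1L]] <- data.frame(
      contig = tx$contig, pos = g, ref = ref, alt = alt,
      transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
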
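# Genome + transcript model: FASTA loading, refFlat/GenePred parsing,
# spliced cDNA/CDS extraction, translation and coordinate conversion.
#
# Conventions: all internal coordinates are 0-based half-open; VCF and report
# coordinates are 1-based and converted only at the I/O boundary.

#' Load a genome FASTA into memory
#'
#' Reads every record with [Biostrings::readDNAStringSet()], uppercases the
#' sequences and enforces the `{A,C,G,T,N}` alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of contig sequences, class `genome_seq`.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  # read raw letters (readDNAStringSet silently drops non-IUPAC codes,
  # which would defeat the alphabet contract below)
  ss <- Biostrings::readBStringSet(path)
  contigs <- toupper(as.character(ss))
  names(contigs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig name in ", path, ": ",
         names(contigs)[duplicated(names(contigs))][1L])
  }
  if (any(nchar(contigs) == 0L)) {
    stop("empty sequence for contig: ", names(contigs)[nchar(contigs) == 0L][1L])
  }
  for (nm in names(contigs)) {
    bad <- regexpr("[^ACGTN]", contigs[[nm]])
    if (bad > 0L) {
      stop("illegal character '", substr(contigs[[nm]], bad, bad),
           "' in contig ", nm, " at offset ", bad)
    }
  }
  structure(contigs, class = "genome_seq")
}

#' Construct a transcript model
#'
#' A strand-aware exon/CDS structure from which spliced cDNA and protein
#' sequences are derived. Exons must be sorted, non-overlapping, 0-based
#' half-open; the CDS interval must lie within the exon union.
#'
#' @param transcript_id Accession (NM_ID role).
#' @param gene_symbol Gene symbol.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of 0-based half-open `[start, end)` intervals.
#' @param cds_start,cds_end 0-based half-open genomic CDS bounds. Equal bounds
#'   mark a non-coding transcript (loaded but excluded from peptide work).
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_symbol, contig, strand,
                             exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon in ", transcript_id)
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons not sorted by start in ", transcript_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in ", transcript_id)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end < cds_start) stop("cds_end < cds_start in ", transcript_id)
  tx <- structure(list(transcript_id = transcript_id,
                       gene_symbol = gene_symbol,
                       contig = contig, strand = strand, exons = exons,
                       cds_start = cds_start, cds_end = cds_end),
                  class = "transcript_model")
  if (is_coding(tx)) {
    inside <- exonic_len_in(tx, cds_start, cds_end)
    span <- cds_end - cds_start
    covered_s <- any(exons[, 1L] <= cds_start & cds_start < exons[, 2L])
    covered_e <- any(exons[, 1L] < cds_end & cds_end <= exons[, 2L])
    if (!covered_s || !covered_e)
      stop("CDS bounds outside exon union in ", transcript_id)
    if (inside == 0L) stop("CDS has zero exonic length in ", transcript_id)
  }
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), CDS [%d,%d)>\n",
              x$transcript_id, x$gene_symbol, x$contig, x$strand,
              nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

is_coding <- function(tx) tx$cds_end > tx$cds_start

# Number of exonic bases within genomic interval [from, to).
exonic_len_in <- function(tx, from, to) {
  sum(pmax(0L, pmin(tx$exons[, 2L], to) - pmax(tx$exons[, 1L], from)))
}

spliced_len <- function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L])

# Spliced bases 5' of the CDS in transcript orientation.
utr5_len <- function(tx) {
  if (tx$strand == "+") exonic_len_in(tx, -1L, tx$cds_start)
  else exonic_len_in(tx, tx$cds_end, .Machine$integer.max)
}

cds_len <- function(tx) exonic_len_in(tx, tx$cds_start, tx$cds_end)

#' Spliced cDNA sequence of a transcript
#'
#' Concatenates exon sequences in transcription order; reverse-complemented
#' for minus-strand transcripts.
#'
#' @param tx A `transcript_model`.
#' @param genome A `genome_seq`.
#' @return Nucleotide string (5'->3' in transcript orientation).
#' @export
spliced_cdna <- function(tx, genome) {
  seqs <- contig_of(tx, genome)
  if (any(tx$exons[, 2L] > nchar(seqs)))
    stop("exon outside contig bounds for ", tx$transcript_id)
  parts <- substring(seqs, tx$exons[, 1L] + 1L, tx$exons[, 2L])
  cdna <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(cdna) else cdna
}

contig_of <- function(tx, genome) {
  if (!tx$contig %in% names(genome))
    stop("contig ", tx$contig, " not in genome")
  genome[[tx$contig]]
}

#' Coding sequence of a transcript
#'
#' The spliced cDNA restricted to the CDS, in translation orientation.
#' A CDS length not divisible by 3 is flagged with a warning (malformed
#' annotation) but still returned.
#'
#' @inheritParams spliced_cdna
#' @return Nucleotide string starting at the annotated start codon.
#' @export
cds_sequence <- function(tx, genome) {
  if (!is_coding(tx)) stop("transcript ", tx$transcript_id, " has no CDS")
  cdna <- spliced_cdna(tx, genome)
  u5 <- utr5_len(tx)
  cl <- cds_len(tx)
  if (cl %% 3L != 0L)
    warning("CDS length of ", tx$transcript_id, " not a multiple of 3")
  substr(cdna, u5 + 1L, u5 + cl)
}

#' Translate a nucleotide string
#'
#' Standard genetic code; translation stops at the first stop codon. Codons
#' containing `N` (or any non-ACGT base) translate to `X`. Trailing 1-2 nt
#' are ignored.
#'
#' @param nt Nucleotide string, length >= 3.
#' @return List with `protein` (amino-acid string, no stop character) and
#'   `no_stop` (TRUE when no stop codon was reached).
#' @export
translate_nt <- function(nt) {
  stopifnot(nchar(nt) >= 3L)
  n_codon <- nchar(nt) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(nt, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(protein = paste(aa[seq_len(stop_at[1L] - 1L)], collapse = ""),
         no_stop = FALSE)
  } else {
    list(protein = paste(aa, collapse = ""), no_stop = TRUE)
  }
}

# Plus-orientation spliced offset (0-based) of a genomic position, or NA.
spliced_offset_plus <- function(tx, g0) {
  hit <- which(tx$exons[, 1L] <= g0 & g0 < tx$exons[, 2L])
  if (!length(hit)) return(NA_integer_)
  prior <- if (hit > 1L) sum(tx$exons[seq_len(hit - 1L), 2L] -
                             tx$exons[seq_len(hit - 1L), 1L]) else 0L
  as.integer(prior + (g0 - tx$exons[hit, 1L]))
}

#' Map a genomic position to a transcript (cDNA) coordinate
#'
#' @param tx A `transcript_model`.
#' @param gpos 1-based genomic position.
#' @return 1-based position in the spliced transcript, or `NA` for intronic
#'   or out-of-transcript positions.
#' @export
genomic_to_cdna <- function(tx, gpos) {
  p <- spliced_offset_plus(tx, as.integer(gpos) - 1L)
  if (is.na(p)) return(NA_integer_)
  if (tx$strand == "+") p + 1L else spliced_len(tx) - p
}

#' Map a genomic position to a CDS coordinate
#'
#' @inheritParams genomic_to_cdna
#' @return 1-based CDS coordinate (1 = first base of the start codon), or
#'   `NA` when the position is intronic, UTR, or outside the transcript.
#' @export
genomic_to_cds <- function(tx, gpos) {
  if (!is_coding(tx)) return(NA_integer_)
  cp <- genomic_to_cdna(tx, gpos)
  if (is.na(cp)) return(NA_integer_)
  u5 <- utr5_len(tx)
  if (cp <= u5 || cp > u5 + cds_len(tx)) return(NA_integer_)
  cp - u5
}

#' Map a CDS coordinate back to its genomic position
#'
#' Inverse of [genomic_to_cds()].
#'
#' @param tx A `transcript_model`.
#' @param cds_pos 1-based CDS coordinate.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(tx, cds_pos) {
  cp <- utr5_len(tx) + as.integer(cds_pos)          # cDNA coordinate
  p <- if (tx$strand == "+") cp - 1L else spliced_len(tx) - cp  # plus offset
  lens <- tx$exons[, 2L] - tx$exons[, 1L]
  cum <- cumsum(lens)
  ex <- which(p < cum)[1L]
  prior <- if (ex > 1L) cum[ex - 1L] else 0L
  as.integer(tx$exons[ex, 1L] + (p - prior) + 1L)
}

#' Read transcript models from a refFlat/GenePred table
#'
#' Expects the 11 refFlat columns (geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) with 0-based
#' half-open coordinates and comma-separated exon bounds.
#'
#' @param path Path to a tab-separated refFlat file (no header).
#' @return A `transcript_set`.
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stop("transcript table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 11L) stop("refFlat table needs 11 columns, got ", ncol(df))
  txs <- lapply(seq_len(nrow(df)), function(i) {
    starts <- as.integer(strsplit(df[i, 10L], ",")[[1L]])
    ends <- as.integer(strsplit(df[i, 11L], ",")[[1L]])
    if (length(starts) != df[i, 9L] || length(ends) != df[i, 9L])
      stop("exonCount mismatch in row ", i)
    transcript_model(transcript_id = df[i, 2L], gene_symbol = df[i, 1L],
                     contig = df[i, 3L], strand = df[i, 4L],
                     exons = cbind(starts, ends),
                     cds_start = df[i, 7L], cds_end = df[i, 8L])
  })
  transcript_set(txs)
}

#' Bundle transcripts into an indexed set
#'
#' @param txs List of `transcript_model` objects.
#' @return Object of class `transcript_set` (list keyed by transcript id).
#' @export
transcript_set <- function(txs) {
  ids <- vapply(txs, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript_id: ",
                               ids[duplicated(ids)][1L])
  names(txs) <- ids
  ncod <- vapply(txs, Negate(is_coding), logical(1L))
  if (any(ncod))
    message("loaded ", sum(ncod), " non-coding transcript(s); ",
            "excluded from peptide generation")
  structure(txs, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set of %d transcript(s)>\n", length(x)))
  invisible(x)
}

#' Transcripts whose exons cover a genomic position
#'
#' @param txs A `transcript_set`.
#' @param contig Contig name.
#' @param gpos 1-based genomic position.
#' @return List of `transcript_model` objects (possibly empty).
#' @export
transcripts_at <- function(txs, contig, gpos) {
  g0 <- as.integer(gpos) - 1L
  Filter(function(tx) {
    tx$contig == contig && !is.na(spliced_offset_plus(tx, g0))
  }, unclass(txs))
}

# Wild-type protein of every coding transcript in the set.
wildtype_proteome <- function(txs, genome) {
  coding <- Filter(is_coding, unclass(txs))
  vapply(coding, function(tx) translate_nt(cds_sequence(tx, genome))$protein,
         character(1L))
}
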
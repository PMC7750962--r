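# Independent oracle for variant effects and peptide windows.
#
# Works at the genome level: applies the edit to the contig string, shifts
# exon/CDS boundaries, re-splices with its own string code, translates with
# Biostrings::translate, and enumerates expected k-mer windows by brute
# force. Shares no code path with the package's cDNA-coordinate editing.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

oracle_translate <- function(nt) {
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  if (nchar(nt) < 3L) return(list(protein = "", no_stop = TRUE))
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")))
  stop_i <- regexpr("*", aa, fixed = TRUE)
  if (stop_i > 0L) list(protein = substr(aa, 1L, stop_i - 1L),
                        no_stop = FALSE)
  else list(protein = aa, no_stop = TRUE)
}

oracle_splice <- function(contig, exons, strand) {
  s <- paste(substring(contig, exons[, 1L] + 1L, exons[, 2L]), collapse = "")
  if (strand == "-") oracle_revcomp(s) else s
}

# Apply a VCF-style (anchored) edit at the genome level; returns the edited
# contig plus shifted exon and CDS boundaries for one transcript.
oracle_apply_genomic <- function(contig, tx, pos, ref, alt) {
  g0 <- pos - 1L                       # 0-based start of ref
  g1 <- g0 + nchar(ref)                # 0-based end (exclusive)
  delta <- nchar(alt) - nchar(ref)
  new_contig <- paste0(substr(contig, 1L, pos - 1L), alt,
                       substr(contig, pos + nchar(ref), nchar(contig)))
  shift <- function(b) ifelse(b >= g1, b + delta, b)
  list(contig = new_contig,
       exons = cbind(shift(tx$exons[, 1L]), shift(tx$exons[, 2L])),
       cds_start = shift(tx$cds_start), cds_end = shift(tx$cds_end))
}

# Wild-type and mutant proteins of tx under one genomic edit; the mutant
# translation runs from the start codon through the transcript end.
oracle_proteins <- function(contig, tx, pos, ref, alt) {
  wt_cdna <- oracle_splice(contig, tx$exons, tx$strand)
  u5_wt <- oracle_utr5(contig, tx, tx$exons, tx$cds_start, tx$cds_end)
  wt <- oracle_translate(substr(wt_cdna, u5_wt + 1L, nchar(wt_cdna)))
  ed <- oracle_apply_genomic(contig, tx, pos, ref, alt)
  mut_cdna <- oracle_splice(ed$contig, ed$exons, tx$strand)
  u5_mut <- oracle_utr5(ed$contig, tx, ed$exons, ed$cds_start, ed$cds_end)
  mut <- oracle_translate(substr(mut_cdna, u5_mut + 1L, nchar(mut_cdna)))
  list(wt = wt, mut = mut)
}

oracle_utr5 <- function(contig, tx, exons, cds_start, cds_end) {
  if (tx$strand == "+")
    sum(pmax(0L, pmin(exons[, 2L], cds_start) - exons[, 1L]))
  else
    sum(pmax(0L, exons[, 2L] - pmax(exons[, 1L], cds_end)))
}

oracle_effect <- function(contig, tx, pos, ref, alt) {
  d <- nchar(alt) - nchar(ref)
  pr <- oracle_proteins(contig, tx, pos, ref, alt)
  wt <- pr$wt$protein; mut <- pr$mut$protein
  if (d %% 3L != 0L) return("frameshift")
  if (d != 0L) return("inframe_indel")
  if (identical(wt, mut)) return("synonymous")
  if (nchar(mut) < nchar(wt)) return("stop_gain")
  if (nchar(mut) > nchar(wt)) return("stop_loss")
  "missense"
}

oracle_kmers <- function(prot, positions, len) {
  lm <- nchar(prot)
  if (lm < len) return(character(0L))
  out <- character(0L)
  for (start in seq_len(lm - len + 1L)) {
    if (any(positions >= start & positions <= start + len - 1L)) {
      k <- substr(prot, start, start + len - 1L)
      if (!grepl("X", k, fixed = TRUE)) out <- c(out, k)
    }
  }
  out
}

# Expected mutant k-mer set for one edit (brute-force enumeration from the
# full edited translation).
oracle_expected_windows <- function(contig, tx, pos, ref, alt, len) {
  pr <- oracle_proteins(contig, tx, pos, ref, alt)
  wt <- pr$wt$protein; mut <- pr$mut$protein
  eff <- oracle_effect(contig, tx, pos, ref, alt)
  if (eff %in% c("synonymous", "noncoding")) return(character(0L))
  if (eff %in% c("frameshift", "stop_loss")) {
    n <- min(nchar(wt), nchar(mut))
    p <- 0L
    while (p < n && substr(wt, p + 1L, p + 1L) == substr(mut, p + 1L, p + 1L))
      p <- p + 1L
    if (p >= nchar(mut)) return(character(0L))
    return(oracle_kmers(mut, seq.int(p + 1L, nchar(mut)), len))
  }
  if (eff %in% c("missense", "stop_gain")) {
    n <- min(nchar(wt), nchar(mut))
    wv <- strsplit(substr(wt, 1L, n), "")[[1L]]
    mv <- strsplit(substr(mut, 1L, n), "")[[1L]]
    diffs <- which(wv != mv)
    if (!length(diffs)) return(character(0L))
    return(oracle_kmers(mut, diffs, len))
  }
  # in-frame indel: altered block bounded by common prefix/suffix, or the
  # deletion junction when the block is empty
  lm <- nchar(mut); lw <- nchar(wt)
  n <- min(lm, lw)
  p <- 0L
  while (p < n && substr(wt, p + 1L, p + 1L) == substr(mut, p + 1L, p + 1L))
    p <- p + 1L
  s <- 0L
  while (s < n - p &&
         substr(wt, lw - s, lw - s) == substr(mut, lm - s, lm - s))
    s <- s + 1L
  positions <- if (lm - s >= p + 1L) seq.int(p + 1L, lm - s)
               else sort(unique(pmax(1L, pmin(lm, c(p, p + 1L)))))
  oracle_kmers(mut, positions, len)
}

# Package-side window set for the same edit, via annotate + builders.
package_windows <- function(fx, variant, len) {
  avs <- annotate_variant(variant, fx$transcripts, fx$genome)
  avs <- Filter(function(a) a$transcript_id == variant$transcript_id, avs)
  if (!length(avs)) return(list(effect = "noncoding", kmers = character(0L)))
  av <- avs[[1L]]
  cands <- if (av$effect %in% c("missense", "stop_gain", "stop_loss"))
    build_snv_peptides(av, fx$genome, len)
  else if (av$effect %in% c("inframe_indel", "frameshift"))
    build_indel_peptides(av, fx$genome, len)
  else empty_candidates()
  list(effect = av$effect, kmers = cands$mut_peptide)
}
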
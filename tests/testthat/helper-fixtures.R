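# Shared fixture builders for the suite.

write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("genome", fileext = ".fa", tmpdir = dir)
  lines <- unlist(lapply(names(records), function(n) c(paste0(">", n),
                                                       records[[n]])))
  writeLines(lines, path)
  path
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Toy fixture files (genome FASTA, refFlat, somatic VCF, HLA list) in a
# fresh directory; returns the path set.
toy_files <- function(dir = tempfile("toy")) {
  fx <- toy_fixture()
  paths <- write_fixture(fx, dir)
  vcf <- file.path(dir, "somatic.vcf")
  write_toy_vcf(vcf)
  hla <- file.path(dir, "hla.txt")
  writeLines("HLA-A*02:01", hla)
  c(paths, vcf = vcf, hla = hla, dir = dir)
}

# A two-gene fusion fixture: both genes plus-strand, single-exon, on
# separate contigs, with an in-frame junction.
#   donor GENE_D on chrD: CDS ATG GAT GAA AAG CTT TGA (MDEKL)
#   acceptor GENE_A on chrA: CDS ATG CCT CGT TTC TGG TGA (MPRFW)
fusion_fixture <- function() {
  d_seq <- "ATGGATGAAAAGCTTTGA"
  a_seq <- "ATGCCTCGTTTCTGGTGA"
  genome <- structure(c(chrD = paste0(d_seq, "ACGTACGTAC"),
                        chrA = paste0("GGGG", a_seq, "ACGTAC")),
                      class = "genome_seq")
  txd <- transcript_model("NM_D", "GENE_D", "chrD", "+", cbind(0L, 18L),
                          0L, 18L)
  txa <- transcript_model("NM_A", "GENE_A", "chrA", "+", cbind(4L, 22L),
                          4L, 22L)
  list(genome = genome,
       transcripts = suppressMessages(transcript_set(list(txd, txa))))
}

# BND VCF lines for a reciprocal junction: donor chrD kept through pos
# (1-based) joined to acceptor chrA from mate_pos on.
fusion_vcf_lines <- function(pos = 9L, mate_pos = 11L) {
  c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    sprintf("chrD\t%d\tbnd_u\tA\tA[chrA:%d[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_v\tGT\t0/1",
            pos, mate_pos),
    sprintf("chrA\t%d\tbnd_v\tC\t]chrD:%d]C\t.\tPASS\tSVTYPE=BND;MATEID=bnd_u\tGT\t0/1",
            mate_pos, pos))
}
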
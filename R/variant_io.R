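# Variant input: VCF (small variants, breakend SVs, germline SNPs),
# pre-annotated tables, in-package coding-effect annotation.

#' Read a VCF file
#'
#' Small-variant and SNP modes return one row per (record, alt allele) with
#' read support pulled from `FORMAT/AD` and `FORMAT/DP` (first sample) when
#' present; records lacking counts get `depth_N = 0` and a missing VAF. SV
#' mode parses breakend (BND) ALT strings into orientation + mate; malformed
#' bracket notation skips the record with a per-line message.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @param mode `"small_variant"`, `"sv"` or `"snp"`.
#' @return data.frame of variant records (`contig, pos, ref, alt, depth_N,
#'   alt_reads_a, vaf, origin`) or of breakend records (`contig, pos, id,
#'   mate_contig, mate_pos, orientation, inserted_seq, mate_id`).
#' @export
read_vcf <- function(path, mode = c("small_variant", "sv", "snp")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_frame(mode))
  if (mode == "sv") return(parse_bnd_records(fix))

  has_gt <- nrow(v@gt) > 0L && ncol(v@gt) >= 2L
  ad <- if (has_gt) vcfR::extract.gt(v, element = "AD")[, 1L] else
    rep(NA_character_, nrow(fix))
  dp <- if (has_gt) suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP")[, 1L])) else
    rep(NA_integer_, nrow(fix))

  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    ad_i <- if (!is.na(ad[i]))
      suppressWarnings(as.integer(strsplit(ad[i], ",")[[1L]])) else NULL
    for (k in seq_along(alts)) {
      a_reads <- if (!is.null(ad_i) && length(ad_i) >= k + 1L)
        ad_i[k + 1L] else NA_integer_
      depth <- if (!is.na(dp[i])) dp[i]
               else if (!is.null(ad_i)) sum(ad_i, na.rm = TRUE)
               else NA_integer_
      out[[length(out) + 1L]] <- data.frame(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        depth_N = ifelse(is.na(depth), 0L, depth),
        alt_reads_a = ifelse(is.na(a_reads), 0L, a_reads),
        vaf = if (!is.na(depth) && depth > 0L && !is.na(a_reads))
          a_reads / depth else NA_real_,
        origin = if (mode == "snp") "germline_snp" else "somatic",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

empty_variant_frame <- function(mode) {
  if (mode == "sv")
    data.frame(contig = character(), pos = integer(), id = character(),
               mate_contig = character(), mate_pos = integer(),
               orientation = character(), inserted_seq = character(),
               mate_id = character(), stringsAsFactors = FALSE)
  else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), depth_N = integer(),
               alt_reads_a = integer(), vaf = numeric(), origin = character(),
               stringsAsFactors = FALSE)
}

# The four BND join classes, keyed by (t before/after bracket, bracket type):
#   "t["  t[p[   left side of here joined to plus strand starting at mate
#   "t]"  t]p]   left side of here joined to revcomp of left-of-mate
#   "]t"  ]p]t   plus strand up to mate joined before right side of here
#   "[t"  [p[t   revcomp of right-of-mate joined before right side of here
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([A-Za-z]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([A-Za-z]*)$",
    alt, perl = TRUE))[[1L]]
  if (length(m) == 0L || m[3L] != m[6L]) return(NULL)
  t_first <- nchar(m[2L]) > 0L
  t_after <- nchar(m[7L]) > 0L
  if (t_first == t_after) return(NULL)      # exactly one side carries bases
  bracket <- m[3L]
  orientation <- if (t_first) paste0("t", bracket) else paste0(bracket, "t")
  t_seq <- toupper(if (t_first) m[2L] else m[7L])
  # the anchor (reference) base sits adjacent to the junction
  inserted <- if (t_first) substr(t_seq, 2L, nchar(t_seq))
              else substr(t_seq, 1L, nchar(t_seq) - 1L)
  list(orientation = orientation, mate_contig = m[4L],
       mate_pos = as.integer(m[5L]), inserted_seq = inserted)
}

parse_bnd_records <- function(fix) {
  out <- list()
  for (i in seq_len(nrow(fix))) {
    p <- parse_bnd_alt(fix$ALT[i])
    if (is.null(p)) {
      message("skipping malformed BND ALT at record ", i, ": ", fix$ALT[i])
      next
    }
    mate_id <- sub(".*MATEID=([^;]+).*", "\\1", fix$INFO[i])
    if (identical(mate_id, fix$INFO[i])) mate_id <- NA_character_
    out[[length(out) + 1L]] <- data.frame(
      contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      id = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".", paste0("bnd", i),
                  fix$ID[i]),
      mate_contig = p$mate_contig, mate_pos = p$mate_pos,
      orientation = p$orientation, inserted_seq = p$inserted_seq,
      mate_id = mate_id, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_variant_frame("sv"))
  do.call(rbind, out)
}

# Serialize a breakend row back to its ALT bracket string.
bnd_alt_string <- function(b, anchor_base = "N") {
  mate <- paste0(b$mate_contig, ":", b$mate_pos)
  switch(b$orientation,
    "t[" = paste0(anchor_base, b$inserted_seq, "[", mate, "["),
    "t]" = paste0(anchor_base, b$inserted_seq, "]", mate, "]"),
    "]t" = paste0("]", mate, "]", b$inserted_seq, anchor_base),
    "[t" = paste0("[", mate, "[", b$inserted_seq, anchor_base),
    stop("unknown orientation: ", b$orientation))
}

#' Write variant or breakend records to a minimal VCF
#'
#' Minimal VCF 4.2 serializer used for round-trip checks and debugging;
#' restores `DP`/`AD` for small variants and bracketed ALT + `MATEID` for
#' breakends.
#'
#' @param records data.frame from [read_vcf()].
#' @param path Output path.
#' @param genome Optional `genome_seq` used to recover breakend anchor bases.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  if ("orientation" %in% names(records)) {
    body <- vapply(seq_len(nrow(records)), function(i) {
      b <- records[i, ]
      anchor <- if (!is.null(genome) && b$contig %in% names(genome))
        substr(genome[[b$contig]], b$pos, b$pos) else "N"
      info <- if (!is.na(b$mate_id)) paste0("SVTYPE=BND;MATEID=", b$mate_id)
              else "SVTYPE=BND"
      paste(b$contig, b$pos, b$id, anchor, bnd_alt_string(b, anchor), ".",
            "PASS", info, "GT", "0/1", sep = "\t")
    }, character(1L))
  } else {
    body <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      ref_reads <- max(0L, r$depth_N - r$alt_reads_a)
      paste(r$contig, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
            "GT:AD:DP",
            sprintf("0/1:%d,%d:%d", ref_reads, r$alt_reads_a, r$depth_N),
            sep = "\t")
    }, character(1L))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Left-normalize an indel against the reference
#'
#' Shifts an anchored VCF indel to its smallest genomic position that
#' preserves the haplotype (VCF admits several encodings of one event).
#' SNVs and balanced substitutions are returned unchanged.
#'
#' @param contig_seq Reference contig sequence (character scalar).
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt VCF allele strings.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(contig_seq, pos, ref, alt) {
  pos <- as.integer(pos)
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn > 0L && an > 0L &&
        substr(ref, rn, rn) == substr(alt, an, an) &&
        (rn > 1L || an > 1L)) {
      if (rn == 1L || an == 1L) {
        if (pos <= 1L) break
        prev <- substr(contig_seq, pos - 1L, pos - 1L)
        ref <- paste0(prev, substr(ref, 1L, rn - 1L))
        alt <- paste0(prev, substr(alt, 1L, an - 1L))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1L, rn - 1L)
        alt <- substr(alt, 1L, an - 1L)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Reduce a (pos, ref, alt) pair to a minimal edit: trim the shared suffix,
# then the shared prefix. Returns pos/ref/alt of the differing core; for a
# pure insertion ref becomes "" (insertion between pos-1 and pos).
trim_alleles <- function(pos, ref, alt) {
  s <- common_suffix_len(ref, alt, max_len = min(nchar(ref), nchar(alt)))
  ref <- substr(ref, 1L, nchar(ref) - s)
  alt <- substr(alt, 1L, nchar(alt) - s)
  p <- common_prefix_len(ref, alt)
  list(pos = as.integer(pos + p),
       ref = substr(ref, p + 1L, nchar(ref)),
       alt = substr(alt, p + 1L, nchar(alt)))
}

# Build the cDNA-space edit for a trimmed genomic edit on one transcript.
# Returns list(cdna_pos, ref_len, alt) in transcript orientation, or NULL
# when the edit touches non-exonic sequence (splice-spanning).
cdna_edit <- function(tx, pos, ref, alt) {
  rl <- nchar(ref)
  if (rl == 0L) {                                   # insertion between pos-1, pos
    c_prev <- genomic_to_cdna(tx, pos - 1L)
    c_next <- genomic_to_cdna(tx, pos)
    if (is.na(c_prev) || is.na(c_next) || abs(c_next - c_prev) != 1L)
      return(NULL)
    if (tx$strand == "+")
      list(cdna_pos = c_prev + 1L, ref_len = 0L, alt = alt)
    else
      list(cdna_pos = c_next + 1L, ref_len = 0L, alt = revcomp(alt))
  } else {
    cpos <- vapply(seq.int(pos, pos + rl - 1L),
                   function(g) genomic_to_cdna(tx, g), integer(1L))
    if (anyNA(cpos)) return(NULL)
    lo <- min(cpos); hi <- max(cpos)
    if (hi - lo != rl - 1L) return(NULL)            # not contiguous in cDNA
    a <- if (tx$strand == "+") alt else revcomp(alt)
    list(cdna_pos = lo, ref_len = rl, alt = a)
  }
}

# Apply cDNA-space edits (list of cdna_pos/ref_len/alt), descending position.
apply_cdna_edits <- function(cdna, edits) {
  if (!length(edits)) return(cdna)
  ord <- order(vapply(edits, `[[`, 1, "cdna_pos"), decreasing = TRUE)
  for (e in edits[ord]) {
    left <- substr(cdna, 1L, e$cdna_pos - 1L)
    right <- substr(cdna, e$cdna_pos + e$ref_len, nchar(cdna))
    cdna <- paste0(left, e$alt, right)
  }
  cdna
}

#' Annotate a variant against overlapping transcripts
#'
#' Classifies the coding effect of one small variant by editing each
#' overlapping transcript's cDNA and comparing the wild-type and mutant
#' translations. Indels are left-normalized first. Variants spanning a
#' splice boundary are classified `noncoding` (and never yield peptides).
#'
#' @param v One-row data.frame (or list) with `contig, pos, ref, alt` (plus
#'   read-support fields, carried through).
#' @param txs A `transcript_set`.
#' @param genome A `genome_seq`.
#' @return List of annotated-variant records, one per overlapping coding
#'   transcript; each has `variant`, `transcript_id`, `cds_pos`, `effect`,
#'   `edit` (cDNA-space) and `tx`.
#' @export
annotate_variant <- function(v, txs, genome) {
  v <- as.list(v)
  if (identical(v$ref, v$alt)) stop("ref equals alt at ", v$contig, ":", v$pos)
  contig_seq <- genome[[v$contig]]
  if (is.null(contig_seq)) stop("contig ", v$contig, " not in genome")
  obs <- substr(contig_seq, v$pos, v$pos + nchar(v$ref) - 1L)
  if (obs != v$ref)
    stop("ref allele mismatch at ", v$contig, ":", v$pos,
         " (expected ", obs, ", got ", v$ref, ")")
  norm <- left_normalize(contig_seq, v$pos, v$ref, v$alt)
  tr <- trim_alleles(norm$pos, norm$ref, norm$alt)
  # positions the edit touches, for transcript lookup
  probe <- if (nchar(tr$ref) == 0L) c(tr$pos - 1L, tr$pos)
           else seq.int(tr$pos, tr$pos + nchar(tr$ref) - 1L)
  hits <- list()
  for (g in probe) {
    for (tx in transcripts_at(txs, v$contig, g)) {
      hits[[tx$transcript_id]] <- tx
    }
  }
  out <- list()
  for (tx in hits) {
    if (!is_coding(tx)) next
    ed <- cdna_edit(tx, tr$pos, tr$ref, tr$alt)
    eff <- classify_edit(tx, genome, ed)
    out[[length(out) + 1L]] <- list(
      variant = v, transcript_id = tx$transcript_id,
      cds_pos = if (is.null(ed)) NA_integer_
                else max(1L, ed$cdna_pos - utr5_len(tx)),
      effect = eff, edit = ed, tx = tx)
  }
  out
}

classify_edit <- function(tx, genome, ed) {
  if (is.null(ed)) return("noncoding")
  u5 <- utr5_len(tx); cl <- cds_len(tx)
  cds_lo <- u5 + 1L; cds_hi <- u5 + cl
  intersects <- if (ed$ref_len == 0L)
    ed$cdna_pos > cds_lo && ed$cdna_pos <= cds_hi
  else
    ed$cdna_pos <= cds_hi && (ed$cdna_pos + ed$ref_len - 1L) >= cds_lo
  if (!intersects) return("noncoding")
  d <- nchar(ed$alt) - ed$ref_len
  if (d %% 3L != 0L) return("frameshift")
  cdna <- spliced_cdna(tx, genome)
  wt <- translate_nt(substr(cdna, cds_lo, nchar(cdna)))
  mut_cdna <- apply_cdna_edits(cdna, list(ed))
  mut <- translate_nt(substr(mut_cdna, cds_lo, nchar(mut_cdna)))
  if (d != 0L) return("inframe_indel")
  if (mut$protein == wt$protein) return("synonymous")
  if (nchar(mut$protein) < nchar(wt$protein)) return("stop_gain")
  if (nchar(mut$protein) > nchar(wt$protein)) return("stop_loss")
  "missense"
}

#' Read a pre-annotated variant table
#'
#' Supports a minimal ANNOVAR-style dialect (tab-separated columns `Chr`,
#' `Start`, `Ref`, `Alt`, `AAChange` with entries of the form
#' `GENE:NM_x:exonN:c.4G>A:p.D2N`, comma-separated for multiple transcripts)
#' and a minimal VEP-style dialect (`Location`, `Allele`, `Gene`, `Feature`,
#' `Consequence`, `HGVSc`, `HGVSp`). Rows whose transcript is absent from
#' `txs` are dropped with a message.
#'
#' @param path Table path.
#' @param dialect `"annovar"` or `"vep_minimal"`.
#' @param txs A `transcript_set`.
#' @param genome A `genome_seq` (used to realize the cDNA edit).
#' @return List of annotated-variant records as from [annotate_variant()].
#' @export
read_annotated_table <- function(path, dialect = c("annovar", "vep_minimal"),
                                 txs, genome) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- if (dialect == "annovar") c("Chr", "Start", "Ref", "Alt", "AAChange")
          else c("Location", "Allele", "Feature", "Consequence", "HGVSc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s) for dialect ", dialect,
                         ": ", paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    if (dialect == "annovar") {
      entries <- strsplit(df$AAChange[i], ",", fixed = TRUE)[[1L]]
      for (ent in entries) {
        f <- strsplit(ent, ":", fixed = TRUE)[[1L]]
        if (length(f) < 4L) next
        nm <- f[2L]
        c_str <- f[grepl("^c\\.", f)][1L]
        p_str <- if (any(grepl("^p\\.", f))) f[grepl("^p\\.", f)][1L]
                 else NA_character_
        rec <- table_row_to_av(nm, c_str, p_str, df$Chr[i],
                               as.integer(df$Start[i]), df$Ref[i], df$Alt[i],
                               txs, genome)
        if (!is.null(rec)) out[[length(out) + 1L]] <- rec
      }
    } else {
      nm <- df$Feature[i]
      c_str <- sub("^[^:]*:", "", df$HGVSc[i])
      p_str <- if ("HGVSp" %in% names(df))
        sub("^[^:]*:", "", df$HGVSp[i]) else NA_character_
      loc <- strsplit(df$Location[i], ":", fixed = TRUE)[[1L]]
      rec <- table_row_to_av(nm, c_str, p_str, loc[1L],
                             as.integer(sub("-.*", "", loc[2L])),
                             NA_character_, df$Allele[i], txs, genome,
                             consequence = df$Consequence[i])
      if (!is.null(rec)) out[[length(out) + 1L]] <- rec
    }
  }
  out
}

# Parse a c.-notation coding change into a CDS-space edit.
# Handles c.<pos><ref>><alt>, c.<pos>del<seq>, c.<s>_<e>del[seq],
# c.<s>_<e>ins<seq>.
parse_hgvs_c <- function(c_str) {
  c_str <- sub("^c\\.", "", c_str)
  m <- regmatches(c_str, regexec("^([0-9]+)([ACGT])>([ACGT])$", c_str))[[1L]]
  if (length(m)) return(list(cds_pos = as.integer(m[2L]), ref = m[3L],
                             alt = m[4L], kind = "snv"))
  m <- regmatches(c_str,
                  regexec("^([0-9]+)(?:_([0-9]+))?del([ACGT]*)$", c_str))[[1L]]
  if (length(m)) {
    s <- as.integer(m[2L])
    e <- if (nchar(m[3L])) as.integer(m[3L]) else
      if (nchar(m[4L])) s + nchar(m[4L]) - 1L else s
    return(list(cds_pos = s, del_len = e - s + 1L, alt = "", kind = "del"))
  }
  m <- regmatches(c_str, regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", c_str))[[1L]]
  if (length(m)) return(list(cds_pos = as.integer(m[2L]) + 1L, del_len = 0L,
                             alt = m[4L], kind = "ins"))
  NULL
}

effect_from_p <- function(p_str, c_edit) {
  if (!is.na(p_str)) {
    p <- sub("^p\\.", "", p_str)
    if (grepl("fs", p)) return("frameshift")
    if (grepl("\\*$", p) || grepl("X$", p)) return("stop_gain")
    if (grepl("del|ins", p)) return("inframe_indel")
    m <- regmatches(p, regexec("^([A-Z])([0-9]+)([A-Z])$", p))[[1L]]
    if (length(m)) return(if (m[2L] == m[4L]) "synonymous" else "missense")
    if (grepl("=", p)) return("synonymous")
  }
  if (!is.null(c_edit) && c_edit$kind != "snv") {
    d <- nchar(c_edit$alt) - c_edit$del_len
    return(if (d %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  NA_character_
}

table_row_to_av <- function(nm, c_str, p_str, contig, pos, ref, alt,
                            txs, genome, consequence = NULL) {
  if (!nm %in% names(txs)) {
    message("dropping annotated row: transcript ", nm, " not loaded")
    return(NULL)
  }
  tx <- txs[[nm]]
  ce <- parse_hgvs_c(c_str)
  eff <- effect_from_p(p_str, ce)
  if (is.na(eff) && !is.null(consequence)) {
    eff <- if (grepl("synonymous", consequence)) "synonymous"
           else if (grepl("missense", consequence)) "missense"
           else if (grepl("frameshift", consequence)) "frameshift"
           else if (grepl("inframe", consequence)) "inframe_indel"
           else if (grepl("stop_gained", consequence)) "stop_gain"
           else if (grepl("stop_lost", consequence)) "stop_loss"
           else "noncoding"
  }
  if (is.na(eff)) eff <- "noncoding"
  ed <- NULL
  if (!is.null(ce)) {
    u5 <- utr5_len(tx)
    ed <- if (ce$kind == "snv")
      list(cdna_pos = u5 + ce$cds_pos, ref_len = 1L, alt = ce$alt)
    else
      list(cdna_pos = u5 + ce$cds_pos, ref_len = ce$del_len, alt = ce$alt)
  }
  list(variant = list(contig = contig, pos = pos, ref = ref, alt = alt,
                      depth_N = 0L, alt_reads_a = 0L, vaf = NA_real_,
                      origin = "somatic"),
       transcript_id = nm,
       cds_pos = if (!is.null(ce)) ce$cds_pos else NA_integer_,
       effect = eff, edit = ed, tx = tx)
}

#' Pair breakend records into fusion candidates
#'
#' Reciprocal mates (matched by `MATEID` when present, else by coordinates)
#' merge into one candidate; unpaired breakends are kept as single-sided
#' candidates with a warning.
#'
#' @param records Breakend data.frame from `read_vcf(mode = "sv")`.
#' @return List of fusion candidates; each has `seg1`, `seg2` (contig, pos,
#'   side, read), `inserted_seq` and `ids`. `seg1` feeds 5' into the
#'   junction, `seg2` continues 3' of it.
#' @export
pair_breakends <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(list())
  used <- logical(n)
  cands <- list()
  mate_of <- function(i) {
    for (j in seq_len(n)) {
      if (j == i || used[j]) next
      id_match <- !is.na(records$mate_id[i]) &&
        identical(records$mate_id[i], records$id[j])
      coord_match <- records$mate_contig[i] == records$contig[j] &&
        records$mate_pos[i] == records$pos[j] &&
        records$mate_contig[j] == records$contig[i] &&
        records$mate_pos[j] == records$pos[i]
      if (id_match || coord_match) return(j)
    }
    NA_integer_
  }
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- mate_of(i)
    ids <- records$id[i]
    if (!is.na(j)) {
      used[j] <- TRUE
      ids <- c(ids, records$id[j])
    } else {
      warning("unpaired breakend ", records$id[i], "; kept single-sided")
    }
    cands[[length(cands) + 1L]] <- canonical_junction(records[i, ], ids,
                                                      single = is.na(j))
  }
  cands
}

# Canonical (seg1 -> junction -> seg2) form of one breakend record.
canonical_junction <- function(b, ids, single = FALSE) {
  seg_here <- list(contig = b$contig, pos = b$pos)
  seg_mate <- list(contig = b$mate_contig, pos = b$mate_pos)
  segs <- switch(b$orientation,
    "t[" = list(seg1 = c(seg_here, side = "left", read = "+"),
                seg2 = c(seg_mate, side = "right", read = "+")),
    "t]" = list(seg1 = c(seg_here, side = "left", read = "+"),
                seg2 = c(seg_mate, side = "left", read = "-")),
    "]t" = list(seg1 = c(seg_mate, side = "left", read = "+"),
                seg2 = c(seg_here, side = "right", read = "+")),
    "[t" = list(seg1 = c(seg_mate, side = "right", read = "-"),
                seg2 = c(seg_here, side = "right", read = "+")))
  structure(list(seg1 = segs$seg1, seg2 = segs$seg2,
                 inserted_seq = b$inserted_seq, ids = ids,
                 single_sided = single),
            class = "fusion_candidate")
}

#' @export
print.fusion_candidate <- function(x, ...) {
  cat(sprintf("<fusion %s:%d (%s,%s) -> %s:%d (%s,%s)%s>\n",
              x$seg1$contig, x$seg1$pos, x$seg1$side, x$seg1$read,
              x$seg2$contig, x$seg2$pos, x$seg2$side, x$seg2$read,
              if (nchar(x$inserted_seq)) paste0(" +", x$inserted_seq) else ""))
  invisible(x)
}
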
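# Mutant/wild-type peptide window construction for SNVs, indels, fusions and
# raw RNA sequences; combination patterns; wild-type-match filtering.

candidate_columns <- c("gene_symbol", "transcript_id", "event_class",
                       "mut_peptide", "wt_peptide", "mutation_protein_pos",
                       "window_start", "length", "pattern_id",
                       "source_variants", "no_stop_flag", "aa_change",
                       "contig", "pos", "ref", "alt", "depth_N",
                       "alt_reads_a", "vaf", "exon_start", "exon_end")

empty_candidates <- function() {
  df <- data.frame(gene_symbol = character(), transcript_id = character(),
                   event_class = character(), mut_peptide = character(),
                   wt_peptide = character(), mutation_protein_pos = integer(),
                   window_start = integer(), length = integer(),
                   pattern_id = character(), source_variants = character(),
                   no_stop_flag = logical(), aa_change = character(),
                   contig = character(), pos = integer(), ref = character(),
                   alt = character(), depth_N = integer(),
                   alt_reads_a = integer(), vaf = numeric(),
                   exon_start = integer(), exon_end = integer(),
                   stringsAsFactors = FALSE)
  df
}

variant_key <- function(v) {
  paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
}

#' Deterministic pattern identifier
#'
#' Hash of the sorted source-variant keys (reproducibility over prettiness).
#'
#' @param keys Character vector of variant keys.
#' @return 8-hex-digit identifier.
#' @export
pattern_id <- function(keys) {
  h <- fnv1a32(paste(sort(keys), collapse = ";"))
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Enumerate fixed-length windows of mut_prot that contain at least one
# altered residue, pairing each with the positionally matched wild-type
# window when wt_prot is given. Windows containing 'X' are dropped.
enum_windows <- function(mut_prot, wt_prot, altered, lengths,
                         keep_short = FALSE) {
  lm <- nchar(mut_prot)
  rows <- list()
  for (len in sort(unique(as.integer(lengths)))) {
    eff_len <- len
    if (lm < len) {
      if (!keep_short || lm < 1L) next
      eff_len <- lm
    }
    for (start in seq_len(lm - eff_len + 1L)) {
      win <- seq.int(start, start + eff_len - 1L)
      if (!any(altered %in% win)) next
      mp <- substr(mut_prot, start, start + eff_len - 1L)
      if (grepl("X", mp, fixed = TRUE)) next
      wp <- if (is.null(wt_prot)) NA_character_
            else substr(wt_prot, start, start + eff_len - 1L)
      if (!is.na(wp) && nchar(wp) < eff_len) wp <- NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        window_start = start, length = eff_len, mut_peptide = mp,
        wt_peptide = wp, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Shared assembly of a candidate data.frame from enumerated windows.
finish_candidates <- function(win, tx, event_class, mutation_pos, av,
                              no_stop, pat = NULL, keys = NULL,
                              aa_change = NA_character_) {
  if (is.null(win)) return(empty_candidates())
  rownames(win) <- NULL
  v <- if (!is.null(av)) av$variant else NULL
  keys <- keys %||% (if (!is.null(v)) variant_key(v) else "na")
  data.frame(
    gene_symbol = tx$gene_symbol, transcript_id = tx$transcript_id,
    event_class = event_class, mut_peptide = win$mut_peptide,
    wt_peptide = win$wt_peptide, mutation_protein_pos = mutation_pos,
    window_start = win$window_start, length = win$length,
    pattern_id = pat %||% pattern_id(keys),
    source_variants = paste(keys, collapse = ";"),
    no_stop_flag = no_stop,
    aa_change = aa_change,
    contig = tx$contig,
    pos = if (!is.null(v)) as.integer(v$pos) else NA_integer_,
    ref = if (!is.null(v)) v$ref else NA_character_,
    alt = if (!is.null(v)) v$alt else NA_character_,
    depth_N = if (!is.null(v)) as.integer(v$depth_N %||% 0L) else NA_integer_,
    alt_reads_a = if (!is.null(v)) as.integer(v$alt_reads_a %||% 0L)
                  else NA_integer_,
    vaf = if (!is.null(v)) as.numeric(v$vaf %||% NA_real_) else NA_real_,
    exon_start = unname(tx$exons[1L, 1L]),
    exon_end = unname(tx$exons[nrow(tx$exons), 2L]),
    stringsAsFactors = FALSE)
}

# Wild-type protein of av's transcript and the mutant protein after applying
# the given cDNA edits (translated from the start codon through the first
# stop, running into the 3'UTR when the frame is lost).
mutant_translation <- function(tx, genome, edits) {
  cdna <- spliced_cdna(tx, genome)
  u5 <- utr5_len(tx)
  wt <- translate_nt(substr(cdna, u5 + 1L, nchar(cdna)))
  mut_cdna <- apply_cdna_edits(cdna, edits)
  mut <- translate_nt(substr(mut_cdna, u5 + 1L, nchar(mut_cdna)))
  list(wt = wt, mut = mut)
}

#' Build peptide windows for a missense (or stop-affecting) SNV
#'
#' Emits, for each requested length, every window of the mutant protein that
#' covers an altered residue, paired with the positionally matched wild-type
#' window.
#'
#' @param av Annotated-variant record (effect `missense`, `stop_gain` or
#'   `stop_loss`).
#' @param genome A `genome_seq`.
#' @param lengths Integer peptide lengths.
#' @param keep_short Keep windows from proteins shorter than the requested
#'   length (dropped by default; predictors want fixed lengths).
#' @return Candidate data.frame (possibly empty).
#' @export
build_snv_peptides <- function(av, genome, lengths, keep_short = FALSE) {
  stopifnot(av$effect %in% c("missense", "stop_gain", "stop_loss"))
  tr <- mutant_translation(av$tx, genome, list(av$edit))
  wt_p <- tr$wt$protein; mut_p <- tr$mut$protein
  if (av$effect == "stop_loss") {
    # novel tail: treat like a frameshift novel region (no wild-type pair)
    p <- common_prefix_len(wt_p, mut_p)
    if (p >= nchar(mut_p)) return(empty_candidates())
    altered <- seq.int(p + 1L, nchar(mut_p))
    win <- enum_windows(mut_p, NULL, altered, lengths, keep_short)
    return(finish_candidates(win, av$tx, "snv", min(altered), av,
                             tr$mut$no_stop,
                             aa_change = aa_change_label(wt_p, mut_p, altered)))
  }
  n <- min(nchar(wt_p), nchar(mut_p))
  wv <- strsplit(substr(wt_p, 1L, n), "")[[1L]]
  mv <- strsplit(substr(mut_p, 1L, n), "")[[1L]]
  altered <- which(wv != mv)
  if (!length(altered)) return(empty_candidates())
  pair_wt <- if (av$effect == "missense") wt_p else NULL
  win <- enum_windows(mut_p, pair_wt, altered, lengths, keep_short)
  finish_candidates(win, av$tx, "snv", altered[1L], av, tr$mut$no_stop,
                    aa_change = aa_change_label(wt_p, mut_p, altered))
}

aa_change_label <- function(wt_p, mut_p, altered) {
  if (!length(altered)) return(NA_character_)
  i <- altered[1L]
  w <- if (i <= nchar(wt_p)) substr(wt_p, i, i) else "-"
  m <- if (i <= nchar(mut_p)) substr(mut_p, i, i) else "-"
  paste0(w, i, m)
}

#' Build peptide windows for an indel
#'
#' Frameshifts translate the edited cDNA from the start codon through the
#' first stop (or the transcript end, setting the no-stop flag) and emit
#' every window containing a novel residue, with no wild-type counterpart.
#' In-frame indels behave like a multi-residue substitution: windows overlap
#' the altered block (or the deletion junction) and the wild-type window is
#' taken from the unedited protein at the homologous (prefix-anchored)
#' offset.
#'
#' @inheritParams build_snv_peptides
#' @param av Annotated-variant record (effect `inframe_indel` or
#'   `frameshift`).
#' @export
build_indel_peptides <- function(av, genome, lengths, keep_short = FALSE) {
  stopifnot(av$effect %in% c("inframe_indel", "frameshift"))
  tr <- mutant_translation(av$tx, genome, list(av$edit))
  wt_p <- tr$wt$protein; mut_p <- tr$mut$protein
  lm <- nchar(mut_p); lw <- nchar(wt_p)
  if (av$effect == "frameshift") {
    p <- common_prefix_len(wt_p, mut_p)
    if (p >= lm) return(empty_candidates())   # immediate stop at the shift
    altered <- seq.int(p + 1L, lm)
    win <- enum_windows(mut_p, NULL, altered, lengths, keep_short)
    return(finish_candidates(win, av$tx, "frameshift", p + 1L, av,
                             tr$mut$no_stop,
                             aa_change = paste0(aa_change_label(wt_p, mut_p,
                                                                altered), "fs")))
  }
  p <- common_prefix_len(wt_p, mut_p)
  s <- common_suffix_len(wt_p, mut_p, max_len = min(lm, lw) - p)
  altered <- if (lm - s >= p + 1L) seq.int(p + 1L, lm - s)
             else sort(unique(pmax(1L, pmin(lm, c(p, p + 1L)))))  # deletion junction
  win <- enum_windows(mut_p, wt_p, altered, lengths, keep_short)
  finish_candidates(win, av$tx, "inframe_indel", altered[1L], av,
                    tr$mut$no_stop,
                    aa_change = aa_change_label(wt_p, mut_p, altered))
}

# Spliced acceptor-side sequence of seg2, read away from the junction.
acceptor_sequence <- function(tx, seg, genome) {
  ex <- tx$exons
  if (seg$side == "right") {
    keep <- ex[, 2L] > seg$pos - 1L
    ex <- ex[keep, , drop = FALSE]
    if (!nrow(ex)) return("")
    ex[1L, 1L] <- max(ex[1L, 1L], seg$pos - 1L)
  } else {
    keep <- ex[, 1L] < seg$pos
    ex <- ex[keep, , drop = FALSE]
    if (!nrow(ex)) return("")
    ex[nrow(ex), 2L] <- min(ex[nrow(ex), 2L], seg$pos)
  }
  contig <- genome[[tx$contig]]
  s <- paste(substring(contig, ex[, 1L] + 1L, ex[, 2L]), collapse = "")
  if (seg$read == "-") revcomp(s) else s
}

#' Build peptide windows for a fusion candidate
#'
#' Joins the donor transcript's 5' portion (through the breakpoint), any
#' inserted sequence, and the acceptor portion dictated by the breakend
#' orientation; translates from the donor start codon through the first stop;
#' then removes every window occurring as a substring of either parent
#' wild-type protein. Unproductive candidates (non-exonic ends, breakpoint
#' upstream of the donor CDS) yield an empty result with a message.
#'
#' @param fc A `fusion_candidate` from [pair_breakends()].
#' @param txs A `transcript_set`.
#' @param genome A `genome_seq`.
#' @param lengths Integer peptide lengths.
#' @return Candidate data.frame (possibly empty).
#' @export
build_fusion_peptides <- function(fc, txs, genome, lengths) {
  if (isTRUE(fc$single_sided)) {
    message("single-sided breakend ", paste(fc$ids, collapse = ","),
            ": no fusion peptides")
    return(empty_candidates())
  }
  donors <- Filter(function(tx) {
    is_coding(tx) &&
      ((fc$seg1$read == "+" && tx$strand == "+" && fc$seg1$side == "left") ||
       (fc$seg1$read == "-" && tx$strand == "-" && fc$seg1$side == "right"))
  }, transcripts_at(txs, fc$seg1$contig, fc$seg1$pos))
  acceptors <- Filter(is_coding, transcripts_at(txs, fc$seg2$contig,
                                                fc$seg2$pos))
  if (!length(donors) || !length(acceptors)) {
    message("unproductive fusion ", paste(fc$ids, collapse = ","),
            ": breakends not exonic on compatible transcripts")
    return(empty_candidates())
  }
  out <- list()
  for (donor in donors) {
    c1 <- genomic_to_cdna(donor, fc$seg1$pos)
    u5 <- utr5_len(donor)
    if (is.na(c1) || c1 <= u5) next       # breakpoint upstream of CDS start
    donor_cdna <- spliced_cdna(donor, genome)
    prefix <- substr(donor_cdna, 1L, c1)
    donor_prot <- translate_nt(cds_sequence(donor, genome))$protein
    for (acc in acceptors) {
      acc_seq <- acceptor_sequence(acc, fc$seg2, genome)
      if (!nchar(acc_seq)) next
      fused <- paste0(prefix, fc$inserted_seq, acc_seq)
      tr <- translate_nt(substr(fused, u5 + 1L, nchar(fused)))
      mut_p <- tr$protein
      junction_res <- (c1 - u5 - 1L) %/% 3L + 1L
      if (!nchar(mut_p) || junction_res > nchar(mut_p)) next
      acc_prot <- translate_nt(cds_sequence(acc, genome))$protein
      win <- enum_windows(mut_p, NULL, seq_len(nchar(mut_p)), lengths)
      if (is.null(win)) next
      keep <- !vapply(win$mut_peptide, is_substring_of_any,
                      logical(1L), haystacks = c(donor_prot, acc_prot))
      win <- win[keep, , drop = FALSE]
      if (!nrow(win)) next
      keys <- paste0("fusion:", paste(fc$ids, collapse = "+"))
      cand <- finish_candidates(win, donor, "fusion", junction_res, NULL,
                                tr$no_stop, keys = keys,
                                aa_change = paste0("fus(",
                                                   donor$gene_symbol, "-",
                                                   acc$gene_symbol, ")"))
      cand$gene_symbol <- paste0(donor$gene_symbol, "-", acc$gene_symbol)
      cand$pos <- fc$seg1$pos
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) {
    message("unproductive fusion ", paste(fc$ids, collapse = ","),
            ": no translatable junction")
    return(empty_candidates())
  }
  do.call(rbind, out)
}

#' Build peptide windows from a raw mutant RNA sequence
#'
#' Translates the sequence (default: frame 1 from the first ATG; optionally
#' all three frames), emits every window, and removes windows occurring in
#' any reference protein of the associated gene. An unknown gene reference
#' keeps all windows and warns.
#'
#' @param seq Nucleotide string (mutant RNA/cDNA; `U` is accepted).
#' @param gene_ref Gene symbol or transcript accession used to collect
#'   reference proteins for filtering.
#' @param txs A `transcript_set`.
#' @param genome A `genome_seq`.
#' @param lengths Integer peptide lengths.
#' @param frame_policy `"first_atg"` (default) or `"all_frames"`.
#' @return Candidate data.frame (possibly empty).
#' @export
build_rna_peptides <- function(seq, gene_ref, txs, genome, lengths,
                               frame_policy = c("first_atg", "all_frames")) {
  frame_policy <- match.arg(frame_policy)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (nchar(seq) < 3L * min(lengths))
    stop("RNA sequence shorter than 3*min(lengths)")
  ref_txs <- Filter(function(tx) {
    is_coding(tx) &&
      (tx$gene_symbol == gene_ref || tx$transcript_id == gene_ref)
  }, unclass(txs))
  ref_prots <- vapply(ref_txs, function(tx)
    translate_nt(cds_sequence(tx, genome))$protein, character(1L))
  if (!length(ref_prots))
    warning("gene reference ", gene_ref,
            " not in transcript set; wild-type filtering skipped")
  starts <- if (frame_policy == "first_atg") {
    a <- regexpr("ATG", seq, fixed = TRUE)
    if (a < 0L) {
      warning("no ATG in RNA sequence; no peptides generated")
      return(empty_candidates())
    }
    as.integer(a)
  } else 1:3
  rows <- list()
  for (st in starts) {
    if (nchar(seq) - st + 1L < 3L) next
    tr <- translate_nt(substr(seq, st, nchar(seq)))
    if (!nchar(tr$protein)) next
    win <- enum_windows(tr$protein, NULL, seq_len(nchar(tr$protein)), lengths)
    if (is.null(win)) next
    if (length(ref_prots)) {
      keep <- !vapply(win$mut_peptide, is_substring_of_any, logical(1L),
                      haystacks = ref_prots)
      win <- win[keep, , drop = FALSE]
    }
    if (!nrow(win)) next
    tx_stub <- if (length(ref_txs)) ref_txs[[1L]] else
      list(gene_symbol = gene_ref, transcript_id = gene_ref,
           contig = NA_character_, exons = matrix(c(NA_integer_, NA_integer_),
                                                  ncol = 2L))
    cand <- finish_candidates(win, tx_stub, "rna", 1L, NULL, tr$no_stop,
                              keys = paste0("rna:", gene_ref, ":frame", st),
                              aa_change = "rna")
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) return(empty_candidates())
  do.call(rbind, rows)
}

#' Combination policy for co-occurring events
#'
#' Controls the optional generation of all edit patterns when multiple SNVs
#' share a peptide window, SNVs fall in a frameshift's novel region, or
#' germline SNPs overlap the mutant peptide. All three options default to
#' off.
#'
#' @param enable_multi_snv,enable_frameshift_snv,enable_snp_integration
#'   Logical switches for the three co-occurrence cases.
#' @param max_cooccurring Cap on jointly enumerated somatic events.
#' @return A `combination_policy` list.
#' @export
combination_policy <- function(enable_multi_snv = FALSE,
                               enable_frameshift_snv = FALSE,
                               enable_snp_integration = FALSE,
                               max_cooccurring = 3L) {
  stopifnot(max_cooccurring >= 1L)
  structure(list(enable_multi_snv = enable_multi_snv,
                 enable_frameshift_snv = enable_frameshift_snv,
                 enable_snp_integration = enable_snp_integration,
                 max_cooccurring = as.integer(max_cooccurring)),
            class = "combination_policy")
}

#' Enumerate edit patterns for co-located events on one transcript
#'
#' Somatic events are enumerated in all on/off combinations (the all-off
#' pattern is wild type and excluded); germline SNPs, when integration is
#' enabled, are applied to both the mutant and the wild-type sequence of
#' every pattern. Above the co-occurrence cap only single-variant patterns
#' plus the all-variants pattern are kept, with a warning.
#'
#' @param events List of annotated-variant records on one transcript, sorted
#'   by CDS position; germline SNPs are recognized by
#'   `variant$origin == "germline_snp"`.
#' @param policy A [combination_policy()].
#' @return List of patterns; each has `somatic` (indices into `events`),
#'   `snps` (indices), and `pattern_id`.
#' @export
enumerate_patterns <- function(events, policy = combination_policy()) {
  origin <- vapply(events, function(e) e$variant$origin %||% "somatic", "")
  som <- which(origin != "germline_snp")
  snp <- which(origin == "germline_snp")
  if (!policy$enable_snp_integration) snp <- integer(0L)
  combine <- policy$enable_multi_snv || policy$enable_frameshift_snv
  subsets <- if (!combine || length(som) <= 1L) {
    lapply(som, identity)
  } else if (length(som) > policy$max_cooccurring) {
    warning("co-occurring somatic count ", length(som), " exceeds cap ",
            policy$max_cooccurring,
            "; truncating to single-variant + all-variants patterns")
    c(lapply(som, identity), list(som))
  } else {
    unlist(lapply(seq_along(som), function(k)
      utils::combn(som, k, simplify = FALSE)), recursive = FALSE)
  }
  lapply(subsets, function(idx) {
    keys <- vapply(events[sort(c(idx, snp))],
                   function(e) variant_key(e$variant), "")
    list(somatic = sort(idx), snps = snp, pattern_id = pattern_id(keys))
  })
}

#' Build peptides for one enumerated edit pattern
#'
#' Applies the pattern's somatic edits plus any SNP edits to the mutant
#' sequence, and the SNP edits alone to the wild-type sequence, then runs the
#' window machinery: frameshift-like patterns (net length change not a
#' multiple of 3) emit unpaired windows over the novel region; in-frame
#' patterns pair windows with the SNP-adjusted wild type.
#'
#' @param tx A `transcript_model`.
#' @param genome A `genome_seq`.
#' @param events List of annotated-variant records (as in
#'   [enumerate_patterns()]).
#' @param pattern One pattern from [enumerate_patterns()].
#' @param lengths Integer peptide lengths.
#' @param keep_short See [build_snv_peptides()].
#' @return Candidate data.frame.
#' @export
build_pattern_peptides <- function(tx, genome, events, pattern, lengths,
                                   keep_short = FALSE) {
  som_edits <- lapply(events[pattern$somatic], `[[`, "edit")
  snp_edits <- lapply(events[pattern$snps], `[[`, "edit")
  if (any(vapply(c(som_edits, snp_edits), is.null, TRUE)))
    return(empty_candidates())
  cdna <- spliced_cdna(tx, genome)
  u5 <- utr5_len(tx)
  wt_cdna <- apply_cdna_edits(cdna, snp_edits)
  mut_cdna <- apply_cdna_edits(cdna, c(som_edits, snp_edits))
  wt <- translate_nt(substr(wt_cdna, u5 + 1L, nchar(wt_cdna)))
  mut <- translate_nt(substr(mut_cdna, u5 + 1L, nchar(mut_cdna)))
  wt_p <- wt$protein; mut_p <- mut$protein
  net <- sum(vapply(som_edits, function(e) nchar(e$alt) - e$ref_len, 1))
  av0 <- events[[pattern$somatic[1L]]]
  keys <- vapply(events[sort(c(pattern$somatic, pattern$snps))],
                 function(e) variant_key(e$variant), "")
  if (net %% 3L != 0L) {
    p <- common_prefix_len(wt_p, mut_p)
    if (p >= nchar(mut_p)) return(empty_candidates())
    altered <- seq.int(p + 1L, nchar(mut_p))
    win <- enum_windows(mut_p, NULL, altered, lengths, keep_short)
    return(finish_candidates(win, tx, "frameshift", p + 1L, av0, mut$no_stop,
                             pat = pattern$pattern_id, keys = keys,
                             aa_change = paste0(aa_change_label(wt_p, mut_p,
                                                                altered), "fs")))
  }
  n <- min(nchar(wt_p), nchar(mut_p))
  wv <- strsplit(substr(wt_p, 1L, n), "")[[1L]]
  mv <- strsplit(substr(mut_p, 1L, n), "")[[1L]]
  altered <- which(wv != mv)
  if (nchar(mut_p) > n) altered <- c(altered, seq.int(n + 1L, nchar(mut_p)))
  if (!length(altered)) return(empty_candidates())
  win <- enum_windows(mut_p, wt_p, altered, lengths, keep_short)
  finish_candidates(win, tx, "snv", altered[1L], av0, mut$no_stop,
                    pat = pattern$pattern_id, keys = keys,
                    aa_change = aa_change_label(wt_p, mut_p, altered))
}

#' Remove candidates matching the wild-type proteome
#'
#' Drops every candidate whose mutant peptide occurs as a substring of any
#' loaded wild-type protein. The number removed is recorded in the
#' `n_removed` attribute.
#'
#' @param cands Candidate data.frame.
#' @param wt_proteome Character vector of wild-type proteins (all loaded
#'   coding transcripts).
#' @return Filtered candidate data.frame.
#' @export
filter_wildtype_matches <- function(cands, wt_proteome) {
  if (!nrow(cands)) return(structure(cands, n_removed = 0L))
  keep <- !vapply(cands$mut_peptide, is_substring_of_any, logical(1L),
                  haystacks = wt_proteome)
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_removed = sum(!keep))
}

#' Write mutant and wild-type peptide FASTA files
#'
#' Record order is deterministic (transcript, mutation position, pattern,
#' length, window); headers encode
#' `gene|transcript|event|pattern|window_start|length`. The wild-type file
#' contains only candidates with a wild-type counterpart, under identical
#' headers.
#'
#' @param cands Candidate data.frame.
#' @param path_mut,path_wt Output FASTA paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_peptide_fasta <- function(cands, path_mut, path_wt) {
  ord <- order(cands$transcript_id, cands$mutation_protein_pos,
               cands$pattern_id, cands$length, cands$window_start)
  cands <- cands[ord, , drop = FALSE]
  hdr <- sprintf("%s|%s|%s|%s|%d|%d", cands$gene_symbol, cands$transcript_id,
                 cands$event_class, cands$pattern_id, cands$window_start,
                 cands$length)
  mut <- Biostrings::AAStringSet(cands$mut_peptide)
  names(mut) <- hdr
  Biostrings::writeXStringSet(mut, path_mut)
  has_wt <- !is.na(cands$wt_peptide)
  wt <- Biostrings::AAStringSet(cands$wt_peptide[has_wt])
  names(wt) <- hdr[has_wt]
  Biostrings::writeXStringSet(wt, path_wt)
  invisible(list(mut = path_mut, wt = path_wt))
}
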
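# Report assembly: one row per (candidate, allele), fixed column order,
# missing optionals rendered as a sentinel, threshold filters.

REPORT_COLUMNS <- c("hla", "gene_symbol", "wt_peptide", "mut_peptide",
                    "ic50_mut", "rank_mut", "ic50_wt", "rank_wt",
                    "chromosome", "nm_id", "aa_change", "ref", "alt",
                    "exon_start", "exon_end", "mutation_position",
                    "depth", "vaf", "expression_total",
                    "expression_allele_specific", "rna_vaf",
                    "expression_allele_specific_rna", "ccf_median",
                    "score_priority_ic50", "score_priority_rank",
                    "score_previous", "event_class", "pattern_id",
                    "substitutions")

#' Assemble the integrated report
#'
#' One row per (candidate, allele). Binding results must cover every mutant
#' and wild-type pair (a missing pair is a hard error). Optional
#' quantification inputs attach total expression, allele-specific
#' expression and the CCF posterior median; missing values stay `NA` and
#' their neutral-substitution flags are recorded per row. Rows are sorted by
#' the selected priority score, descending, with deterministic key
#' tie-breaks.
#'
#' @param cands Candidate data.frame (after wild-type filtering).
#' @param bindings Binding data.frame from [predict_binding()].
#' @param alleles data.frame from [parse_hla_list()].
#' @param score_mode `"ic50"` or `"rank"` (selects the sort score).
#' @param expression Named expression vector, or NULL.
#' @param allele_counts RNA allele-count data.frame, or NULL.
#' @param copy_number Copy-number segment data.frame, or NULL.
#' @param purity Tumor purity in (0, 1]; required with `copy_number`.
#' @param grid_step CCF posterior grid step.
#' @return data.frame with the fixed report schema (`REPORT_COLUMNS`).
#' @export
build_report <- function(cands, bindings, alleles,
                         score_mode = c("ic50", "rank"),
                         expression = NULL, allele_counts = NULL,
                         copy_number = NULL, purity = NULL,
                         grid_step = 0.01) {
  score_mode <- match.arg(score_mode)
  if (!nrow(cands)) return(empty_report())
  bkey <- paste(bindings$peptide, bindings$allele)
  lookup <- function(peptide, allele) {
    i <- match(paste(peptide, allele), bkey)
    if (is.na(i)) stop("missing binding result for pair (", peptide, ", ",
                       allele, ")")
    bindings[i, ]
  }
  rows <- list()
  for (ci in seq_len(nrow(cands))) {
    cand <- cands[ci, ]
    E <- attach_expression(cand$gene_symbol, expression)
    ase_dna <- allele_specific_expression_dna(cand$vaf, E)
    rna_vaf <- NA_real_; ase_rna <- NA_real_
    if (!is.null(allele_counts) && !is.na(cand$pos)) {
      hit <- which(allele_counts$contig == cand$contig &
                   allele_counts$pos == cand$pos)
      if (length(hit)) {
        ar <- allele_specific_expression_rna(
          allele_counts$ref_count[hit[1L]],
          allele_counts$alt_count[hit[1L]], E)
        rna_vaf <- ar$rna_vaf; ase_rna <- ar$ase
      }
    }
    ccf_med <- NA_real_
    if (!is.null(copy_number) && !is.na(cand$pos) &&
        !is.na(cand$depth_N) && cand$depth_N > 0L) {
      q <- copy_number_at(copy_number, cand$contig, cand$pos)
      if (!is.na(q) && q >= 1L) {
        stopifnot(!is.null(purity))
        ccf_med <- ccf_posterior(cand$alt_reads_a, cand$depth_N,
                                 purity, q, grid_step)$median_c
      }
    }
    M <- if (!is.na(cand$wt_peptide))
      hamming(cand$mut_peptide, cand$wt_peptide) else NA_integer_
    for (ai in seq_len(nrow(alleles))) {
      al <- alleles$name[ai]
      bm <- lookup(cand$mut_peptide, al)
      bw <- if (!is.na(cand$wt_peptide)) lookup(cand$wt_peptide, al) else NULL
      ins <- list(I_m = bm$ic50_nm, R_m = bm$rank_pct,
                  I_w = if (!is.null(bw)) bw$ic50_nm else NA_real_,
                  R_w = if (!is.null(bw)) bw$rank_pct else NA_real_,
                  M = M, A = cand$vaf, E = E, C_median = ccf_med)
      p_i <- priority_score(ins, "ic50")
      p_r <- priority_score(ins, "rank")
      p_prev <- previous_score(ins)
      rows[[length(rows) + 1L]] <- data.frame(
        hla = al, gene_symbol = cand$gene_symbol,
        wt_peptide = cand$wt_peptide, mut_peptide = cand$mut_peptide,
        ic50_mut = bm$ic50_nm, rank_mut = bm$rank_pct,
        ic50_wt = if (!is.null(bw)) bw$ic50_nm else NA_real_,
        rank_wt = if (!is.null(bw)) bw$rank_pct else NA_real_,
        chromosome = cand$contig, nm_id = cand$transcript_id,
        aa_change = cand$aa_change, ref = cand$ref, alt = cand$alt,
        exon_start = cand$exon_start, exon_end = cand$exon_end,
        mutation_position = cand$pos, depth = cand$depth_N, vaf = cand$vaf,
        expression_total = E, expression_allele_specific = ase_dna,
        rna_vaf = rna_vaf, expression_allele_specific_rna = ase_rna,
        ccf_median = ccf_med,
        score_priority_ic50 = p_i$score, score_priority_rank = p_r$score,
        score_previous = p_prev$score,
        event_class = cand$event_class, pattern_id = cand$pattern_id,
        substitutions = paste(unique(c(p_i$substitutions,
                                       p_r$substitutions)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  score_col <- if (score_mode == "ic50") "score_priority_ic50"
               else "score_priority_rank"
  ord <- order(-xtfrm(rep[[score_col]]), rep$nm_id, rep$mut_peptide,
               rep$hla, method = "radix")
  rep <- rep[ord, REPORT_COLUMNS, drop = FALSE]
  rownames(rep) <- NULL
  rep
}

empty_report <- function() {
  df <- as.data.frame(stats::setNames(
    replicate(length(REPORT_COLUMNS), character(0L), simplify = FALSE),
    REPORT_COLUMNS), stringsAsFactors = FALSE)
  df
}

#' Apply conjunctive report filters
#'
#' Rows failing any provided threshold are removed; rows with a missing
#' value in a filtered field are removed too and counted in the
#' `n_dropped_missing` attribute.
#'
#' @param rows Report data.frame.
#' @param max_ic50 Keep rows with mutant IC50 <= this (nM).
#' @param max_rank Keep rows with mutant %rank <= this.
#' @param min_expression Keep rows with total expression >= this.
#' @param min_ccf Keep rows with median CCF >= this.
#' @param min_score Keep rows with the ic50-mode priority score >= this.
#' @return Filtered data.frame with attributes `n_removed` and
#'   `n_dropped_missing`.
#' @export
apply_filters <- function(rows, max_ic50 = NULL, max_rank = NULL,
                          min_expression = NULL, min_ccf = NULL,
                          min_score = NULL) {
  keep <- rep(TRUE, nrow(rows))
  dropped_missing <- 0L
  check <- function(values, pass) {
    miss <- is.na(values)
    dropped_missing <<- dropped_missing + sum(miss & keep)
    keep <<- keep & !miss & pass
  }
  if (!is.null(max_ic50)) check(rows$ic50_mut, rows$ic50_mut <= max_ic50)
  if (!is.null(max_rank)) check(rows$rank_mut, rows$rank_mut <= max_rank)
  if (!is.null(min_expression))
    check(rows$expression_total, rows$expression_total >= min_expression)
  if (!is.null(min_ccf)) check(rows$ccf_median, rows$ccf_median >= min_ccf)
  if (!is.null(min_score))
    check(rows$score_priority_ic50, rows$score_priority_ic50 >= min_score)
  keep[is.na(keep)] <- FALSE
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_removed = sum(!keep),
            n_dropped_missing = dropped_missing)
}

#' Write the report TSV
#'
#' Fixed column order; `NA` rendered as the `.` sentinel; numeric columns
#' printed with full precision so identical runs give byte-identical files.
#'
#' @param rows Report data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path) {
  out <- rows
  for (cn in names(out)) {
    v <- out[[cn]]
    s <- if (is.numeric(v)) vapply(v, format, character(1L), digits = 15,
                                   trim = TRUE) else as.character(v)
    s[is.na(v)] <- MISSING_TOKEN
    out[[cn]] <- s
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
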
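# Binding capability: HLA allele handling, a deterministic surrogate
# predictor, and parsers for netMHCpan/netMHCIIpan/MHCflurry output.

CLASS_II_GENES <- c("DRB1", "DRB3", "DRB4", "DRB5", "DQA1", "DQB1",
                    "DPA1", "DPB1")

#' Parse and normalize a list of HLA alleles
#'
#' Accepts one allele per line or comma-separated tokens, in loose notation
#' (`HLA-A*02:01`, `A0201`, `DRB1*04:05`, ...). Duplicates collapse after
#' normalization.
#'
#' @param path Text file of alleles.
#' @return data.frame with `name` (normalized, e.g. `HLA-A*02:01`) and
#'   `mhc_class` (`"I"` or `"II"`).
#' @export
parse_hla_list <- function(path) {
  toks <- unlist(strsplit(readLines(path), "[,\\s]+"))
  toks <- toks[nzchar(toks)]
  parsed <- lapply(toks, normalize_hla)
  out <- unique(do.call(rbind, parsed))
  rownames(out) <- NULL
  out
}

#' Normalize one HLA allele name
#'
#' @param tok Allele string in any common loose notation.
#' @return One-row data.frame with `name` and `mhc_class`.
#' @export
normalize_hla <- function(tok) {
  t0 <- toupper(gsub("[*: ]", "", sub("^HLA-?", "", toupper(tok))))
  m <- regmatches(t0, regexec("^([ABC]|DRB[1345]|DQA1|DQB1|DPA1|DPB1)([0-9]{4})$",
                              t0))[[1L]]
  if (length(m) == 0L)
    stop("unparseable HLA allele: '", tok, "'")
  gene <- m[2L]; digits <- m[3L]
  name <- sprintf("HLA-%s*%s:%s", gene, substr(digits, 1L, 2L),
                  substr(digits, 3L, 4L))
  data.frame(name = name,
             mhc_class = if (gene %in% CLASS_II_GENES) "II" else "I",
             stringsAsFactors = FALSE)
}

#' Deterministic surrogate binding predictor
#'
#' An offline stand-in predictor with the contract shape of the external
#' tools: IC50 is `exp(u * ln 50000)` nM for a hash-derived uniform
#' `u in (0,1)` over `(peptide, allele, seed)`, so results lie in
#' `[1, 50000]` nM and are identical across calls and platforms; the
#' percentile rank is a fixed strictly increasing map of IC50 into
#' `(0, 100]`.
#'
#' @param peptide Amino-acid string.
#' @param allele Normalized allele name.
#' @param seed Integer seed mixed into the hash.
#' @return One-row data.frame: `peptide, allele, ic50_nm, rank_pct, backend`.
#' @export
surrogate_predict <- function(peptide, allele, seed = 0L) {
  h <- fnv1a32(paste(peptide, allele, seed, sep = "|"))
  u <- (h + 0.5) / 4294967296
  ic50 <- exp(u * log(50000))
  rank <- 100 * sqrt(ic50 / 50000)
  data.frame(peptide = peptide, allele = allele, ic50_nm = ic50,
             rank_pct = rank, backend = "surrogate",
             stringsAsFactors = FALSE)
}

#' Predict binding for all candidate-allele pairs
#'
#' Produces exactly one result per (mutant peptide, allele) pair and one per
#' (wild-type peptide, allele) pair where a wild type exists. With a parser
#' backend, `parsed` supplies externally computed results and any missing
#' pair is a hard error (silent dropouts would corrupt scoring). Class II
#' alleles are refused class I-length peptides.
#'
#' @param cands Candidate data.frame.
#' @param alleles data.frame from [parse_hla_list()].
#' @param predictor `"surrogate"` or one of the parser backends
#'   (`"netmhcpan_parser"`, `"netmhciipan_parser"`, `"mhcflurry_parser"`).
#' @param seed Seed for the surrogate.
#' @param parsed Binding data.frame from a parser, required for parser
#'   backends.
#' @return data.frame of binding results covering all required pairs.
#' @export
predict_binding <- function(cands, alleles, predictor = "surrogate",
                            seed = 0L, parsed = NULL) {
  stopifnot(predictor %in% c("surrogate", "netmhcpan_parser",
                             "netmhciipan_parser", "mhcflurry_parser"))
  peptides <- unique(c(cands$mut_peptide,
                       cands$wt_peptide[!is.na(cands$wt_peptide)]))
  if (predictor == "netmhcpan_parser" && any(alleles$mhc_class == "II"))
    stop("class II allele routed to a class I backend (netMHCpan)")
  if (predictor == "netmhciipan_parser" && any(alleles$mhc_class == "I"))
    stop("class I allele routed to a class II backend (netMHCIIpan)")
  for (i in seq_len(nrow(alleles))) {
    if (alleles$mhc_class[i] == "II" && any(nchar(peptides) < 12L))
      stop("class II allele ", alleles$name[i],
           " given class I-length peptides (shortest: ",
           min(nchar(peptides)), ")")
  }
  need <- expand.grid(peptide = peptides, allele = alleles$name,
                      stringsAsFactors = FALSE)
  if (predictor == "surrogate") {
    res <- do.call(rbind, lapply(seq_len(nrow(need)), function(i)
      surrogate_predict(need$peptide[i], need$allele[i], seed)))
  } else {
    if (is.null(parsed)) stop("parser backend needs 'parsed' results")
    key_have <- paste(parsed$peptide, parsed$allele)
    key_need <- paste(need$peptide, need$allele)
    missing <- !key_need %in% key_have
    if (any(missing)) {
      i <- which(missing)[1L]
      stop("backend result missing for pair (", need$peptide[i], ", ",
           need$allele[i], ")")
    }
    res <- parsed[match(key_need, key_have), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Parse netMHCpan 4.0-style tabular output
#'
#' Locates the whitespace-separated header row (containing `Peptide` and a
#' rank column) and reads data rows until the closing dashes, extracting the
#' affinity (nM) and percentile-rank columns.
#'
#' @param path Output file of the external tool.
#' @return Binding data.frame (`peptide, allele, ic50_nm, rank_pct,
#'   backend`).
#' @export
parse_netmhcpan_output <- function(path) {
  parse_nmp_table(path, backend = "netmhcpan",
                  aff_names = c("Aff(nM)", "Affinity(nM)"),
                  rank_names = c("%Rank_BA", "%Rank", "Rank"))
}

#' Parse netMHCIIpan 3.2-style tabular output
#'
#' @inheritParams parse_netmhcpan_output
#' @return Binding data.frame.
#' @export
parse_netmhciipan_output <- function(path) {
  parse_nmp_table(path, backend = "netmhciipan",
                  aff_names = c("Affinity(nM)", "Aff(nM)"),
                  rank_names = c("%Rank", "Rank"))
}

parse_nmp_table <- function(path, backend, aff_names, rank_names) {
  lines <- readLines(path)
  hdr_i <- which(grepl("\\bPeptide\\b", lines))[1L]
  if (is.na(hdr_i)) stop(backend, " output: no header row with 'Peptide'")
  hdr <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1L]]
  pep_col <- match("Peptide", hdr)
  allele_col <- which(hdr %in% c("HLA", "MHC", "Allele"))[1L]
  aff_col <- which(hdr %in% aff_names)[1L]
  rank_col <- which(hdr %in% rank_names)[1L]
  if (is.na(pep_col)) stop(backend, " output: missing Peptide column")
  if (is.na(allele_col)) stop(backend, " output: missing allele column")
  if (is.na(aff_col)) stop(backend, " output: missing affinity (nM) column")
  if (is.na(rank_col)) stop(backend, " output: missing %rank column")
  out <- list()
  for (i in seq.int(hdr_i + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^-+$", ln)) {
      if (length(out)) break else next
    }
    f <- strsplit(ln, "\\s+")[[1L]]
    if (length(f) < max(pep_col, allele_col, aff_col, rank_col))
      stop(backend, " output: truncated line ", i)
    out[[length(out) + 1L]] <- data.frame(
      peptide = f[pep_col], allele = f[allele_col],
      ic50_nm = as.numeric(f[aff_col]), rank_pct = as.numeric(f[rank_col]),
      backend = backend, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop(backend, " output: no data rows")
  res <- do.call(rbind, out)
  res$allele <- vapply(res$allele, function(a) normalize_hla(a)$name, "")
  res
}

#' Parse an MHCflurry-style CSV
#'
#' Expects `allele`, `peptide`, an affinity column
#' (`mhcflurry_affinity`/`mhcflurry_prediction`/`affinity`) and a percentile
#' column (`mhcflurry_affinity_percentile`/`affinity_percentile`/
#' `percentile`).
#'
#' @param path CSV path.
#' @return Binding data.frame.
#' @export
parse_mhcflurry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  aff <- intersect(c("mhcflurry_affinity", "mhcflurry_prediction", "affinity"),
                   names(df))[1L]
  pct <- intersect(c("mhcflurry_affinity_percentile", "affinity_percentile",
                     "percentile"), names(df))[1L]
  if (!all(c("allele", "peptide") %in% names(df)) || is.na(aff) || is.na(pct))
    stop("mhcflurry CSV: missing column (need allele, peptide, ",
         "an affinity and a percentile column)")
  data.frame(peptide = df$peptide,
             allele = vapply(df$allele, function(a) normalize_hla(a)$name, ""),
             ic50_nm = as.numeric(df[[aff]]),
             rank_pct = as.numeric(df[[pct]]),
             backend = "mhcflurry", stringsAsFactors = FALSE)
}
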
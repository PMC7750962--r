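# Expression, allele-specific expression, and the cancer-cell-fraction
# posterior computed from read counts, tumor purity and somatic copy number.

#' Read a gene-expression table
#'
#' Two-column TSV (gene, value), header optional. Duplicate gene rows are
#' summed with a warning.
#'
#' @param path TSV path.
#' @return Named numeric vector of expression levels.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]                       # header row
  vals <- as.numeric(df[[2L]])
  if (any(vals < 0, na.rm = TRUE)) stop("negative expression value in ", path)
  if (anyDuplicated(df[[1L]])) {
    warning("duplicate gene rows in expression table; summing")
    vals <- tapply(vals, df[[1L]], sum)
    return(vals[unique(df[[1L]])])
  }
  stats::setNames(vals, df[[1L]])
}

#' Look up a gene's expression level
#'
#' Exact-match lookup; an absent gene returns `NA` (rendered as the missing
#' sentinel in the report).
#'
#' @param gene_symbol Gene symbol.
#' @param table Named numeric vector from [read_expression_table()].
#' @return Expression level `E`, or `NA` when absent.
#' @export
attach_expression <- function(gene_symbol, table) {
  if (is.null(table) || !gene_symbol %in% names(table)) return(NA_real_)
  unname(table[[gene_symbol]])
}

#' Allele-specific expression from the DNA VAF
#'
#' The variant allele's share of the gene's total expression, `VAF * E`.
#'
#' @param vaf DNA variant allele frequency in `[0, 1]`.
#' @param E Total expression level of the gene (>= 0).
#' @return `vaf * E`, or `NA` when either input is missing.
#' @export
allele_specific_expression_dna <- function(vaf, E) {
  if (is.na(vaf) || is.na(E)) return(NA_real_)
  stopifnot(vaf >= 0, vaf <= 1, E >= 0)
  vaf * E
}

#' Allele-specific expression from RNA allele counts
#'
#' @param ref_count,alt_count RNA read counts at the variant locus.
#' @param E Total expression level of the gene.
#' @return List with `rna_vaf = alt/(ref+alt)` and `ase = rna_vaf * E`;
#'   both `NA` at zero coverage.
#' @export
allele_specific_expression_rna <- function(ref_count, alt_count, E) {
  stopifnot(ref_count >= 0, alt_count >= 0)
  cov <- ref_count + alt_count
  if (cov == 0L) return(list(rna_vaf = NA_real_, ase = NA_real_))
  rna_vaf <- alt_count / cov
  list(rna_vaf = rna_vaf, ase = if (is.na(E)) NA_real_ else rna_vaf * E)
}

#' Read an RNA allele-count table
#'
#' TSV with columns contig, pos, ref_count, alt_count (header optional).
#'
#' @param path TSV path.
#' @return data.frame with those four columns.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.integer(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]
  stats::setNames(data.frame(df[[1L]], as.integer(df[[2L]]),
                             as.integer(df[[3L]]), as.integer(df[[4L]]),
                             stringsAsFactors = FALSE),
                  c("contig", "pos", "ref_count", "alt_count"))
}

#' Read an ASCAT-style copy-number segment table
#'
#' TSV with columns contig, start, end, nA, nB (1-based inclusive segment
#' bounds; header optional). `q = nA + nB` is the total somatic copy number
#' used by the CCF posterior.
#'
#' @param path TSV path.
#' @return data.frame with contig, start, end, copy_A, copy_B.
#' @export
read_copy_number <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.integer(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]
  out <- stats::setNames(data.frame(df[[1L]], as.integer(df[[2L]]),
                                    as.integer(df[[3L]]),
                                    as.integer(df[[4L]]),
                                    as.integer(df[[5L]]),
                                    stringsAsFactors = FALSE),
                         c("contig", "start", "end", "copy_A", "copy_B"))
  if (any(out$copy_A < 0L | out$copy_B < 0L)) stop("negative copy number")
  out
}

# Total copy number of the segment overlapping a position, or NA.
copy_number_at <- function(cn, contig, pos) {
  hit <- which(cn$contig == contig & cn$start <= pos & pos <= cn$end)
  if (!length(hit)) return(NA_integer_)
  cn$copy_A[hit[1L]] + cn$copy_B[hit[1L]]
}

#' Grid posterior over the cancer-cell fraction
#'
#' With a variant seen in `a` of `N` reads at a locus of total somatic copy
#' number `q` in a sample of purity `alpha`, the expected variant allele
#' fraction of a single-copy mutation carried by a fraction `c` of tumor
#' cells is `f(c) = alpha*c / (2*(1-alpha) + alpha*q)`. Under a uniform
#' prior on `c`, the posterior on an even grid over `(0, 1]` is proportional
#' to the binomial likelihood `dbinom(a, N, f(c))`. With `N = 0` the
#' posterior is the prior. The median is the smallest grid value whose
#' cumulative probability reaches 0.5.
#'
#' @param a Variant-supporting read count.
#' @param N Total read depth (`0 <= a <= N`).
#' @param alpha Tumor purity in `(0, 1]`.
#' @param q Total somatic copy number (>= 1).
#' @param grid_step Grid spacing (default 0.01).
#' @return Object of class `ccf_posterior`: list with `grid`, `probs`
#'   (summing to 1) and `median_c`.
#' @export
ccf_posterior <- function(a, N, alpha, q, grid_step = 0.01) {
  if (a < 0 || a > N) stop("need 0 <= a <= N")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (q < 1) stop("q must be >= 1")
  grid <- seq(grid_step, 1, by = grid_step)
  if (N == 0) {
    probs <- rep(1 / length(grid), length(grid))
  } else {
    f <- alpha * grid / (2 * (1 - alpha) + alpha * q)
    f <- pmin(pmax(f, 0), 1)      # no-op for valid input; kept as a guard
    w <- stats::dbinom(a, N, f)
    if (sum(w) == 0) w <- rep(1, length(grid))   # numerically degenerate
    probs <- w / sum(w)
  }
  median_c <- grid[which(cumsum(probs) >= 0.5)[1L]]
  structure(list(grid = grid, probs = probs, median_c = median_c),
            class = "ccf_posterior")
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat(sprintf("<ccf_posterior on %d-point grid, median C = %.3f>\n",
              length(x$grid), x$median_c))
  invisible(x)
}

#' Equal-tailed credible interval of a CCF posterior
#'
#' @param x A `ccf_posterior`.
#' @param level Coverage (default 0.95).
#' @return Numeric vector `c(lower, upper)` on the grid.
#' @export
ccf_credible_interval <- function(x, level = 0.95) {
  cdf <- cumsum(x$probs)
  lo <- x$grid[which(cdf >= (1 - level) / 2)[1L]]
  hi <- x$grid[which(cdf >= 1 - (1 - level) / 2)[1L]]
  c(lower = lo, upper = hi)
}
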
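# Priority scores: logistic transforms of binding capability, tanh
# expression/VAF factor, logistic clonality factor, and their composition.

#' Logistic transform of IC50 (nM)
#'
#' `L_I(x) = 1 / (1 + exp(0.015 (x - 500)))`: strictly decreasing, 0.5 at
#' the conventional 500 nM binding threshold.
#'
#' @param x IC50 in nM (>= 0).
#' @return Value in (0, 1).
#' @export
logistic_ic50 <- function(x) 1 / (1 + exp(0.015 * (x - 500)))

#' Logistic transform of percentile rank
#'
#' `L_R(x) = 1 / (1 + exp(5 (x - 2)))`: strictly decreasing, 0.5 at the
#' conventional 2% rank threshold.
#'
#' @param x Percentile rank (>= 0).
#' @return Value in (0, 1).
#' @export
logistic_rank <- function(x) 1 / (1 + exp(5 * (x - 2)))

#' Variant-allele-frequency factor
#'
#' `g(A) = tanh(5 A)`: 0 at A = 0, saturating towards 1 for clonal,
#' high-VAF variants.
#'
#' @param A VAF in `[0, 1]`.
#' @return Value in `[0, tanh(5)]`.
#' @export
allele_factor <- function(A) tanh(5 * A)

#' Combined expression/VAF factor
#'
#' `f(A, E) = tanh(g(A) E)`: zero when the variant allele is absent or the
#' gene silent, saturating to 1 with expression.
#'
#' @param A VAF in `[0, 1]`.
#' @param E Expression level (>= 0).
#' @return Value in `[0, 1)`.
#' @export
expression_factor <- function(A, E) tanh(allele_factor(A) * E)

#' Clonality factor from the median cancer-cell fraction
#'
#' `C(x) = 1 / (1 + exp(-30 (x - 0.8)))`: increasing in clonality, 0.5 at a
#' median CCF of 0.8, so subclonal mutations are strongly down-weighted.
#'
#' @param x Median CCF in `(0, 1]`.
#' @return Value in (0, 1).
#' @export
clonality_factor <- function(x) 1 / (1 + exp(-30 * (x - 0.8)))

#' Composite priority score of a candidate peptide
#'
#' `P = L(mut) * f(A, E) * (1 - 2^{-M} L(wt)) * C(median CCF)` with `L`
#' either the IC50 or the rank transform. Missing optionals substitute
#' neutral values — wild-type term 1 when no wild-type peptide exists
#' (mismatch count treated as infinite), `E = 1` when expression is missing,
#' clonality term 1 when no CCF posterior is available — and every
#' substitution is flagged. The VAF `A` is mandatory; without it the score
#' is `NA`.
#'
#' @param inputs List with `I_m`, `R_m` (mutant IC50/rank), optional `I_w`,
#'   `R_w`, `M` (mismatch count >= 1), `A` (VAF), optional `E`, optional
#'   `C_median`.
#' @param mode `"ic50"` or `"rank"`.
#' @return List with `score` and `substitutions` (character vector of
#'   neutral substitutions applied).
#' @export
priority_score <- function(inputs, mode = c("ic50", "rank")) {
  mode <- match.arg(mode)
  L <- if (mode == "ic50") logistic_ic50 else logistic_rank
  xm <- if (mode == "ic50") inputs$I_m else inputs$R_m
  xw <- if (mode == "ic50") inputs$I_w else inputs$R_w
  if (is.null(xm) || is.na(xm)) stop("mutant affinity missing")
  subs <- character(0L)
  A <- inputs$A
  if (is.null(A) || is.na(A))
    return(list(score = NA_real_, substitutions = "A_missing"))
  E <- inputs$E
  if (is.null(E) || is.na(E)) { E <- 1; subs <- c(subs, "E=1") }
  wt_term <- if (is.null(xw) || is.na(xw)) {
    subs <- c(subs, "wt_term=1")
    1
  } else {
    M <- inputs$M
    if (is.null(M) || is.na(M)) stop("M required when wild type present")
    1 - 2^(-M) * L(xw)
  }
  C_term <- if (is.null(inputs$C_median) || is.na(inputs$C_median)) {
    subs <- c(subs, "C=1")
    1
  } else clonality_factor(inputs$C_median)
  list(score = L(xm) * expression_factor(A, E) * wt_term * C_term,
       substitutions = subs)
}

#' Comparison score in the style of earlier rank-based prioritizers
#'
#' `L_R(R_m) * E * A * (1 - 2^{-M} L_R(R_w))`, reducing to
#' `L_R(R_m) * E * A` without a wild-type peptide. Included in the report
#' for comparison; labelled as an interpretation of the earlier tools'
#' score.
#'
#' @inheritParams priority_score
#' @return List with `score` and `substitutions`.
#' @export
previous_score <- function(inputs) {
  if (is.null(inputs$R_m) || is.na(inputs$R_m)) stop("mutant rank missing")
  subs <- character(0L)
  A <- inputs$A
  if (is.null(A) || is.na(A))
    return(list(score = NA_real_, substitutions = "A_missing"))
  E <- inputs$E
  if (is.null(E) || is.na(E)) { E <- 1; subs <- c(subs, "E=1") }
  wt_term <- if (is.null(inputs$R_w) || is.na(inputs$R_w)) {
    subs <- c(subs, "wt_term=1")
    1
  } else 1 - 2^(-inputs$M) * logistic_rank(inputs$R_w)
  list(score = logistic_rank(inputs$R_m) * E * A * wt_term,
       substitutions = subs)
}
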
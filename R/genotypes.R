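#' Genotype counts for one phenotype group
#'
#' The atomic data unit of the package: counts of the three genotypes at one
#' biallelic SNP for one group of subjects. The orientation is fixed by
#' convention: the first count is the common (non-risk) homozygote GG, the
#' second the heterozygote GT, and the third the risk-allele homozygote TT,
#' so that odds ratios computed downstream are always relative to the major
#' allele G.
#'
#' @param n_gg Count of major-allele homozygotes (GG).
#' @param n_gt Count of heterozygotes (GT).
#' @param n_tt Count of risk-allele homozygotes (TT).
#' @return An object of class `genotype_counts`: an integer vector of length
#'   three with names `gg`, `gt`, `tt`.
#' @examples
#' g <- genotype_counts(79, 94, 30)
#' allele_counts(g)
#' carrier_counts(g)
#' @export
genotype_counts <- function(n_gg, n_gt, n_tt) {
  x <- c(gg = n_gg, gt = n_gt, tt = n_tt)
  if (length(x) != 3L || anyNA(x)) {
    stop("genotype counts must be three non-missing numbers", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("genotype counts must be non-negative, got (",
         paste(x, collapse = ", "), ")", call. = FALSE)
  }
  if (any(x != round(x))) {
    stop("genotype counts must be whole numbers", call. = FALSE)
  }
  structure(as.integer(round(x)), names = c("gg", "gt", "tt"),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  n <- sum(x)
  cat(sprintf("Genotype counts: GG=%d GT=%d TT=%d  (n=%d", x[1], x[2], x[3], n))
  if (n > 0) {
    al <- allele_counts(x)
    cat(sprintf(", risk allele frequency %.3f", al["t"] / (2 * n)))
  }
  cat(")\n")
  invisible(x)
}

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(genotype_counts(x[1], x[2], x[3]))
  }
  stop("cannot interpret object as genotype counts", call. = FALSE)
}

#' Allele counts from genotype counts
#'
#' Collapses a genotype-count triple to counts of the two alleles: each GG
#' subject carries two G alleles, each GT one of each, each TT two T alleles.
#'
#' @param g A [genotype_counts] object (or a length-3 numeric vector in
#'   GG, GT, TT order).
#' @return Named integer vector `c(g = ..., t = ...)` with the non-risk (G)
#'   and risk (T) allele counts; the two always sum to twice the number of
#'   subjects.
#' @examples
#' allele_counts(genotype_counts(26, 81, 74))  # 133 G, 229 T
#' @export
allele_counts <- function(g) {
  g <- as_genotype_counts(g)
  c(g = 2L * g[["gg"]] + g[["gt"]], t = g[["gt"]] + 2L * g[["tt"]])
}

#' Carrier counts from genotype counts
#'
#' Dichotomises the group into carriers of at least one copy of the risk
#' allele (GT + TT) and non-carriers (GG).
#'
#' @inheritParams allele_counts
#' @return Named integer vector `c(carriers = ..., non_carriers = ...)`
#'   summing to the number of subjects.
#' @examples
#' carrier_counts(genotype_counts(79, 94, 30))  # 124 carriers, 79 non-carriers
#' @export
carrier_counts <- function(g) {
  g <- as_genotype_counts(g)
  c(carriers = g[["gt"]] + g[["tt"]], non_carriers = g[["gg"]])
}

#' Risk-allele frequency of a group
#'
#' @inheritParams allele_counts
#' @return Proportion of T alleles among all alleles of the group.
#' @export
risk_allele_frequency <- function(g) {
  al <- allele_counts(g)
  unname(al["t"] / sum(al))
}
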
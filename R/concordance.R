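#' Cross-tabulate DGE classes against expression-pattern groups
#'
#' Counts annotated transcripts per (DGE class, expression-pattern group).
#' The default grouping folds the oral-plus-endoderm variant into the
#' oral type (\code{O_endo -> O}) and keeps the mixed delayed/aboral type
#' (\code{D_A}) distinct from \code{D}, matching how the expression
#' profiles are tallied in the screen this package reproduces.
#'
#' @param records Data.frame with columns \code{dge_class} (1..4) and
#'   \code{pattern} (one of O, O_endo, IE, A, D, D_A).
#' @param pattern_grouping Named character vector mapping raw patterns to
#'   groups.
#' @return List with \code{counts} (class x group table) and
#'   \code{class_totals}.
#' @export
class_pattern_table <- function(records,
                                pattern_grouping = c(O = "O",
                                                     O_endo = "O",
                                                     IE = "IE", A = "A",
                                                     D = "D", D_A = "D_A")) {
  stopifnot(nrow(records) > 0)
  unknown <- setdiff(unique(records$pattern), names(pattern_grouping))
  if (length(unknown)) {
    stop("unknown pattern label(s): ", paste(unknown, collapse = ", "))
  }
  group <- pattern_grouping[records$pattern]
  counts <- table(class = factor(records$dge_class, levels = 1:4),
                  pattern = factor(group,
                                   levels = unique(unname(pattern_grouping))))
  list(counts = counts, class_totals = rowSums(counts))
}

#' Sample Pearson correlation
#'
#' Thin, argument-checked wrapper around the sample Pearson correlation,
#' used for cross-condition z-score concordance. Constant input is an
#' error (the coefficient is undefined), not an NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "pearson")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table (rows = groups,
#' columns = property): the first cell follows a hypergeometric
#' distribution given the margins, and the two-sided p-value sums the
#' probabilities of all tables no more probable than the observed one
#' (with the conventional 1e-7 relative slack for floating-point ties).
#' The odds ratio is the plain cross-product ratio ad/(bc); it is
#' \code{Inf} when bc = 0 and \code{NaN} when both products vanish.
#'
#' @param t 2x2 non-negative integer matrix \code{rbind(c(a, b), c(c, d))}
#'   with positive row and column margins.
#' @return List with \code{odds_ratio} and \code{p} (two-sided).
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  stopifnot(all(dim(t) == c(2, 2)))
  if (any(t < 0) || any(t != round(t))) {
    stop("cells must be non-negative integers")
  }
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  if (any(c(a + b, c + d, a + c, b + d) == 0)) {
    stop("all margins must be positive")
  }
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p)
}

#' Taxon-restriction enrichment between two class groups
#'
#' Compares the proportion of taxon-restricted transcripts between two
#' disjoint sets of DGE classes, restricted to transcripts with complete
#' predicted ORFs, and tests the 2x2 split (restricted vs not, group A vs
#' group B) with [fisher_exact_2x2()].
#'
#' @param records Data.frame with columns \code{dge_class},
#'   \code{restricted} (logical), \code{orf_complete} (logical).
#' @param group_a,group_b Disjoint, non-empty sets of classes (e.g.
#'   \code{1:3} vs \code{4}).
#' @return List with \code{proportion_a}, \code{proportion_b},
#'   \code{table} (the 2x2 counts), and \code{fisher} (or NULL with a
#'   message when no transcript is restricted, where the odds ratio is
#'   undefined).
#' @export
taxon_enrichment <- function(records, group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            length(intersect(group_a, group_b)) == 0)
  records <- records[records$orf_complete, , drop = FALSE]
  in_a <- records$dge_class %in% group_a
  in_b <- records$dge_class %in% group_b
  if (!any(in_a) || !any(in_b)) {
    stop("a class group is empty after the complete-ORF filter")
  }
  ra <- sum(records$restricted[in_a]); na <- sum(in_a)
  rb <- sum(records$restricted[in_b]); nb <- sum(in_b)
  tab <- rbind(group_a = c(restricted = ra, other = na - ra),
               group_b = c(restricted = rb, other = nb - rb))
  fisher <- if (ra + rb == 0) {
    message("no restricted transcripts in either group; ",
            "odds ratio undefined")
    NULL
  } else {
    fisher_exact_2x2(tab)
  }
  list(proportion_a = ra / na, proportion_b = rb / nb,
       table = tab, fisher = fisher)
}

#' qPCR expression level from a cycle threshold
#'
#' N = 2^-Ct: one fewer amplification cycle to threshold means twice the
#' template.
#'
#' @param Ct Finite numeric vector of cycle thresholds.
#' @return Expression level vector.
#' @export
qpcr_expression <- function(Ct) {
  if (any(!is.finite(Ct))) stop("Ct must be finite")
  2^(-Ct)
}

#' Reference-normalized fold change, from qPCR cycles or read counts
#'
#' Computes (gene / reference)_experimental / (gene / reference)_control on
#' a common scale for the two assays:
#' \itemize{
#'   \item \code{qpcr}: inputs are Ct values; the result is the
#'     delta-delta-Ct fold change 2^-(ddCt);
#'   \item \code{counts}: inputs are mapped-read counts; the same ratio is
#'     formed from reference-normalized counts.
#' }
#'
#' @param gene,reference Length-2 numeric vectors \code{c(control,
#'   experimental)} of Ct values or counts for the gene of interest and
#'   the reference gene.
#' @param type \code{"qpcr"} or \code{"counts"}.
#' @return Scalar fold change (experimental relative to control).
#' @export
normalized_fold_change <- function(gene, reference,
                                   type = c("qpcr", "counts")) {
  type <- match.arg(type)
  stopifnot(length(gene) == 2, length(reference) == 2)
  if (type == "qpcr") {
    n_gene <- qpcr_expression(gene)
    n_ref <- qpcr_expression(reference)
  } else {
    if (any(reference == 0)) stop("zero reference count")
    n_gene <- gene
    n_ref <- reference
  }
  (n_gene[2] / n_ref[2]) / (n_gene[1] / n_ref[1])
}
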
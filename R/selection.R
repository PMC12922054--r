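#' ADSV selection threshold of one direction's game
#'
#' The magnitude cutoff for candidate genes. The default statistic pools
#' the per-gene Shapley values of both conditions (2n values for n genes)
#' and returns their mean plus sample standard deviation (divisor
#' 2n - 1). The `"adsv"` statistic instead applies mean + sample SD to
#' the n ADSV values themselves.
#'
#' @param phiC,phiE Per-gene Shapley values of the control and
#'   experimental games (named numeric vectors or `shapley_result`s).
#' @param stat `"pooled_shapley"` (default) or `"adsv"`.
#' @return A single number.
#' @examples
#' toy <- toy_dataset()
#' blocks <- split_by_group(binarize(toy$expression, toy$labels, "over"),
#'                          toy$labels)
#' round(adsv_threshold(shapley_values(blocks$control),
#'                      shapley_values(blocks$experimental)), 3)
#' @export
adsv_threshold <- function(phiC, phiE, stat = c("pooled_shapley", "adsv")) {
  stat <- match.arg(stat)
  if (inherits(phiC, "shapley_result")) phiC <- phiC$phi
  if (inherits(phiE, "shapley_result")) phiE <- phiE$phi
  if (length(phiC) != length(phiE) || !identical(names(phiC), names(phiE)))
    stop_input("phiC and phiE must cover the same genes in the same order")
  if (length(phiC) < 2L)
    stop_input("threshold needs at least 2 genes (SD undefined)")
  x <- if (stat == "pooled_shapley") c(phiC, phiE) else abs(phiC - phiE)
  mean(x) + stats::sd(x)
}

#' Candidate genes passing both selection criteria
#'
#' A gene is a candidate when its CASh p-value is at most `alpha` *and*
#' its ADSV is at least the direction's threshold. Gene order follows the
#' input matrix.
#'
#' @param comparison A `game_comparison` from [cash_test()], or a list of
#'   them (one per direction), in which case the per-direction candidate
#'   sets are unioned, preserving first-appearance order.
#' @param alpha Significance level; defaults to the level stored in the
#'   comparison.
#' @return Character vector of gene identifiers.
#' @export
select_candidates <- function(comparison, alpha = NULL) {
  if (inherits(comparison, "game_comparison")) comparison <- list(comparison)
  out <- character(0)
  for (cmp in comparison) {
    stopifnot(inherits(cmp, "game_comparison"))
    a <- if (is.null(alpha)) attr(cmp, "alpha") else alpha
    p <- if (!is.null(cmp$adjusted_p)) cmp$adjusted_p else cmp$CASh_p
    hit <- cmp$gene_id[p <= a & cmp$ADSV >= attr(cmp, "threshold")]
    out <- union(out, hit)
  }
  out
}
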
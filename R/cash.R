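#' Absolute difference in Shapley values between conditions
#'
#' The method's effect-size statistic: a gene whose cooperative relevance
#' changes between conditions has a large `|phiC - phiE|`, even when mean
#' expression differences are unremarkable.
#'
#' @param phiC,phiE Per-gene Shapley values of the control and
#'   experimental games — named numeric vectors over the same genes in
#'   the same order, or `shapley_result` objects.
#' @return Named nonnegative numeric vector.
#' @export
adsv <- function(phiC, phiE) {
  if (inherits(phiC, "shapley_result")) phiC <- phiC$phi
  if (inherits(phiE, "shapley_result")) phiE <- phiE$phi
  if (length(phiC) != length(phiE) || !identical(names(phiC), names(phiE)))
    stop_input("phiC and phiE must cover the same genes in the same order")
  abs(phiC - phiE)
}

#' Configuration of the CASh resampling procedure
#'
#' @param n_resamples Number of resampling iterations B (default 1000).
#' @param resampling_mode `"permute_labels"` (default): uniformly random
#'   relabelings preserving the original group sizes; or
#'   `"bootstrap_labels"`: each sample independently relabelled control
#'   with probability `n_control / n`, rejecting degenerate draws.
#' @param recompute_binarization When `TRUE` (default) the control
#'   statistics and Boolean matrix are recomputed from raw expression
#'   under each pseudo-labelling — the Boolean encoding is a function of
#'   the control group, so a relabelling changes it. `FALSE` keeps the
#'   observed Boolean matrix fixed and only re-partitions its columns.
#' @param alpha Significance level for candidate selection (default 0.05).
#' @param seed Optional integer seed driving the whole resampling loop.
#' @param add_one_correction When `TRUE`, use `(1 + count) / (B + 1)` so
#'   p-values are never exactly zero. Off by default.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across genes within a direction.
#' @return A list of class `cash_config`.
#' @export
cash_config <- function(n_resamples = 1000,
                        resampling_mode = c("permute_labels",
                                            "bootstrap_labels"),
                        recompute_binarization = TRUE,
                        alpha = 0.05,
                        seed = NULL,
                        add_one_correction = FALSE,
                        adjust = c("none", "BH")) {
  resampling_mode <- match.arg(resampling_mode)
  adjust <- match.arg(adjust)
  if (!is.numeric(n_resamples) || n_resamples < 1)
    stop_input("n_resamples must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop_input("alpha must lie in (0, 1]")
  structure(
    list(n_resamples = as.integer(n_resamples),
         resampling_mode = resampling_mode,
         recompute_binarization = isTRUE(recompute_binarization),
         alpha = alpha, seed = seed,
         add_one_correction = isTRUE(add_one_correction),
         adjust = adjust),
    class = "cash_config"
  )
}

#' Randomly relabel samples as control/experimental
#'
#' Draws one pseudo-labelling from the current RNG stream.
#'
#' @param labels Group labels (named character vector).
#' @param mode `"permute_labels"`: permute the observed labels across
#'   samples, preserving group sizes; `"bootstrap_labels"`: independent
#'   relabelling with the observed control proportion, rejecting draws
#'   with fewer than 2 controls or 1 experimental (error after 1000
#'   rejections).
#' @return A named character vector over the same samples.
#' @export
resample_labels <- function(labels, mode = c("permute_labels",
                                             "bootstrap_labels")) {
  mode <- match.arg(mode)
  ids <- names(labels)
  if (mode == "permute_labels")
    return(stats::setNames(sample(unname(labels)), ids))
  p_ctrl <- mean(labels == "control")
  for (try in seq_len(1000L)) {
    draw <- ifelse(stats::runif(length(labels)) < p_ctrl,
                   "control", "experimental")
    if (sum(draw == "control") >= 2L && sum(draw == "experimental") >= 1L)
      return(stats::setNames(draw, ids))
  }
  stop_input("bootstrap relabelling rejected 1000 consecutive degenerate draws")
}

# Fast phi for the resampling loop: per-gene mean marginal contribution.
.phi <- function(B) {
  sizes <- colSums(B)
  marg <- sweep(B, 2L, pmax(sizes, 1), "/")
  marg[, sizes == 0] <- 0
  rowMeans(marg)
}

# Observed + resampled ADSV machinery shared by cash_test().
.adsv_under_labels <- function(X, labels, direction, B_fixed = NULL) {
  ctrl <- labels == "control"
  if (is.null(B_fixed)) {
    Xc <- X[, ctrl, drop = FALSE]
    mu <- rowMeans(Xc)
    s <- row_sds(Xc)
    thr <- if (direction == "over") mu + s else mu - s
    bits <- if (direction == "over") X >= thr else X <= thr
    Bm <- bits + 0
  } else {
    Bm <- B_fixed
  }
  abs(.phi(Bm[, ctrl, drop = FALSE]) - .phi(Bm[, !ctrl, drop = FALSE]))
}

#' CASh: resampling significance for differential cooperative relevance
#'
#' Computes the observed per-gene Shapley values of one direction's game
#' in each condition, their absolute difference (ADSV), the selection
#' threshold, and resampling p-values: samples are randomly relabelled B
#' times, the pipeline is re-run under each pseudo-labelling, and
#' `p_i = (1/B) * #{b : ADSV*_i >= ADSV_i}` with the inclusive indicator
#' (so a gene with zero observed ADSV always has p = 1).
#'
#' @param X Numeric genes-by-samples expression matrix.
#' @param labels Group labels covering every column of `X`.
#' @param direction `"over"` or `"under"`.
#' @param config A [cash_config()].
#' @param threshold_stat Passed to [adsv_threshold()].
#' @return A data frame of class `game_comparison` with columns
#'   `gene_id`, `meanShC`, `meanShE`, `ADSV`, `CASh_p`, `adjusted_p`
#'   (only when `config$adjust != "none"`) and `selected`, plus
#'   attributes `direction`, `threshold`, `alpha` and `config`.
#' @examples
#' toy <- toy_dataset()
#' cmp <- cash_test(toy$expression, toy$labels, "under",
#'                  cash_config(n_resamples = 200, seed = 1))
#' cmp
#' @export
cash_test <- function(X, labels, direction = c("over", "under"),
                      config = cash_config(),
                      threshold_stat = c("pooled_shapley", "adsv")) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "cash_config"))
  labels <- match_labels(X, labels)

  Bmat <- suppressWarnings(binarize(X, labels, direction))
  blocks <- split_by_group(Bmat, labels)
  phiC <- shapley_values(blocks$control)$phi
  phiE <- shapley_values(blocks$experimental)$phi
  a_obs <- adsv(phiC, phiE)
  thr <- adsv_threshold(phiC, phiE, stat = threshold_stat)

  Bfix <- if (config$recompute_binarization) NULL else Bmat
  count <- with_seed(config$seed, {
    cnt <- numeric(nrow(X))
    for (b in seq_len(config$n_resamples)) {
      lab_b <- resample_labels(labels, config$resampling_mode)
      a_b <- .adsv_under_labels(X, lab_b, direction, Bfix)
      cnt <- cnt + (a_b >= a_obs - 1e-12)
    }
    cnt
  })
  p <- if (config$add_one_correction) {
    (1 + count) / (config$n_resamples + 1)
  } else {
    count / config$n_resamples
  }
  names(p) <- rownames(X)

  out <- data.frame(gene_id = rownames(X), meanShC = unname(phiC),
                    meanShE = unname(phiE), ADSV = unname(a_obs),
                    CASh_p = unname(p), stringsAsFactors = FALSE)
  p_sel <- p
  if (config$adjust == "BH") {
    out$adjusted_p <- stats::p.adjust(out$CASh_p, method = "BH")
    p_sel <- stats::setNames(out$adjusted_p, out$gene_id)
  }
  out$selected <- p_sel <= config$alpha & a_obs >= thr
  rownames(out) <- NULL
  structure(out,
            class = c("game_comparison", "data.frame"),
            direction = direction, threshold = thr,
            alpha = config$alpha, config = config)
}

#' @export
print.game_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("%s-expression game: ADSV threshold %.3f, alpha %.3g, B = %d (%s%s)\n",
              attr(x, "direction"), attr(x, "threshold"), attr(x, "alpha"),
              attr(x, "config")$n_resamples,
              attr(x, "config")$resampling_mode,
              if (attr(x, "config")$recompute_binarization)
                ", recomputed binarization" else ", fixed matrix"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
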
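#' Specification of a synthetic two-condition expression dataset
#'
#' The generator emulates what the one-SD Boolean encoding is built to
#' detect: per-gene Gaussian baseline expression, with a planted subset
#' of signal genes shifted *jointly* in the same randomly chosen subset
#' of experimental samples. The coordinated shift is the designed-in
#' coalition — it creates cooperative signal rather than merely marginal
#' signal.
#'
#' @param n_genes Number of genes.
#' @param n_control,n_experimental Group sizes (`n_control >= 2`).
#' @param baseline_mean_range Interval from which per-gene baseline means
#'   are drawn uniformly (default `c(3, 7)`, log-intensity-like units).
#' @param baseline_sd_range Positive interval for per-gene baseline SDs
#'   (default `c(0.05, 0.35)`).
#' @param signal_genes Integer indices of planted signal genes (default
#'   none: a null dataset).
#' @param effect_size Shift applied to signal genes, in units of each
#'   gene's baseline SD (default 3).
#' @param affected_fraction Fraction of experimental samples shifted,
#'   jointly for all signal genes (default 0.6; at least one sample).
#' @param direction `"up"` or `"down"`.
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, n_control, n_experimental,
                           baseline_mean_range = c(3, 7),
                           baseline_sd_range = c(0.05, 0.35),
                           signal_genes = integer(0),
                           effect_size = 3,
                           affected_fraction = 0.6,
                           direction = c("up", "down"),
                           seed = NULL) {
  direction <- match.arg(direction)
  if (n_genes < 1) stop_input("n_genes must be positive")
  if (n_control < 2) stop_input("n_control must be at least 2")
  if (n_experimental < 1) stop_input("n_experimental must be positive")
  if (length(signal_genes) &&
      (any(signal_genes < 1) || any(signal_genes > n_genes)))
    stop_input("signal_genes must index genes in 1..n_genes")
  if (effect_size < 0) stop_input("effect_size must be nonnegative")
  if (affected_fraction <= 0 || affected_fraction > 1)
    stop_input("affected_fraction must lie in (0, 1]")
  if (any(baseline_sd_range <= 0))
    stop_input("baseline_sd_range must be positive")
  structure(
    list(n_genes = as.integer(n_genes),
         n_control = as.integer(n_control),
         n_experimental = as.integer(n_experimental),
         baseline_mean_range = baseline_mean_range,
         baseline_sd_range = baseline_sd_range,
         signal_genes = as.integer(signal_genes),
         effect_size = effect_size,
         affected_fraction = affected_fraction,
         direction = direction, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset from a specification
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression` (genes x samples matrix, controls
#'   `C1..`, experimentals `E1..`), `labels` (named character vector) and
#'   `signal_genes` (character vector of planted gene identifiers).
#'   Reproducible from `spec$seed`.
#' @examples
#' d <- generate_dataset(synthetic_spec(9, 5, 5, signal_genes = c(7, 8),
#'                                      direction = "down", seed = 1))
#' d$signal_genes
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    ns <- spec$n_control + spec$n_experimental
    gene_ids <- paste0("gene", seq_len(n))
    sample_ids <- c(paste0("C", seq_len(spec$n_control)),
                    paste0("E", seq_len(spec$n_experimental)))
    mu_g <- stats::runif(n, spec$baseline_mean_range[1],
                         spec$baseline_mean_range[2])
    sd_g <- stats::runif(n, spec$baseline_sd_range[1],
                         spec$baseline_sd_range[2])
    # rnorm recycles the per-gene parameters down each column.
    X <- matrix(stats::rnorm(n * ns, mean = mu_g, sd = sd_g), nrow = n,
                dimnames = list(gene_ids, sample_ids))
    if (length(spec$signal_genes) && spec$effect_size > 0) {
      n_aff <- max(1L, ceiling(spec$affected_fraction * spec$n_experimental))
      affected <- spec$n_control +
        sample.int(spec$n_experimental, n_aff)
      sgn <- if (spec$direction == "up") 1 else -1
      shift <- sgn * spec$effect_size * sd_g[spec$signal_genes]
      X[spec$signal_genes, affected] <-
        X[spec$signal_genes, affected] + shift
    }
    labels <- stats::setNames(rep(c("control", "experimental"),
                                  c(spec$n_control, spec$n_experimental)),
                              sample_ids)
    list(expression = X, labels = labels,
         signal_genes = gene_ids[spec$signal_genes])
  })
}

#' Bundled toy dataset: nine genes, five controls, five cases
#'
#' A small normalized expression matrix with known behaviour at every
#' stage of the workflow, shipped as plain text under `extdata`. Used
#' throughout the documentation, examples and tests.
#'
#' @return A list with `expression` (9 x 10 matrix) and `labels`.
#' @examples
#' toy <- toy_dataset()
#' toy$expression["gene1", "C1"]
#' @export
toy_dataset <- function() {
  ex <- system.file("extdata", "toy_expression.tsv", package = "cashgame")
  gl <- system.file("extdata", "toy_groups.tsv", package = "cashgame")
  list(expression = read_expression_matrix(ex),
       labels = read_group_labels(gl))
}
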
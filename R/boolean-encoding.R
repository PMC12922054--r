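#' Per-gene mean and standard deviation over the control samples
#'
#' The control statistics define the over-/under-expression thresholds:
#' a gene is flagged in a sample when its value lies at least one control
#' SD above (or below) its control mean. The SD is the sample standard
#' deviation (divisor n - 1).
#'
#' @param X Numeric genes-by-samples matrix with dimnames.
#' @param labels Group labels covering every column of `X` (see
#'   [group_labels()]).
#' @return A list of class `control_summary` with per-gene named numeric
#'   vectors `mean` and `sd`, and `n_control`.
#' @examples
#' toy <- toy_dataset()
#' cs <- control_summary(toy$expression, toy$labels)
#' round(cs$mean[1], 4)
#' @export
control_summary <- function(X, labels) {
  labels <- match_labels(X, labels)
  ctrl <- X[, labels == "control", drop = FALSE]
  structure(
    list(mean = rowMeans(ctrl), sd = row_sds(ctrl), n_control = ncol(ctrl)),
    class = "control_summary"
  )
}

#' Boolean-encode over- or under-expression relative to controls
#'
#' Produces the direction's indicator matrix: a cell is 1 when the
#' expression value is `>= mean + sd` of the gene's control values
#' (`direction = "over"`) or `<= mean - sd` (`direction = "under"`),
#' boundary included. All samples are encoded, controls too: the
#' control-restricted game and the selection threshold need them.
#'
#' @inheritParams control_summary
#' @param direction `"over"` or `"under"`.
#' @return An integer 0/1 matrix with the same dimnames as `X` and a
#'   `direction` attribute.
#' @details Genes whose control SD is zero get a degenerate threshold
#'   equal to the control mean; the formulas are applied literally and a
#'   warning lists the affected genes (a cell can then be 1 in both
#'   directions when the value equals the mean exactly).
#' @examples
#' toy <- toy_dataset()
#' B <- binarize(toy$expression, toy$labels, "over")
#' B["gene1", ]
#' @export
binarize <- function(X, labels, direction = c("over", "under")) {
  direction <- match.arg(direction)
  cs <- control_summary(X, labels)
  zero <- names(cs$sd)[cs$sd == 0]
  if (length(zero))
    warning(sprintf("zero control SD for gene(s) %s: threshold collapses to the control mean",
                    paste(zero, collapse = ", ")))
  thr <- if (direction == "over") cs$mean + cs$sd else cs$mean - cs$sd
  # thr is per-gene; comparison recycles it down each column of X.
  bits <- if (direction == "over") X >= thr else X <= thr
  B <- array(as.integer(bits), dim = dim(X), dimnames = dimnames(X))
  attr(B, "direction") <- direction
  B
}

#' Split a Boolean matrix into its control and experimental blocks
#'
#' @param B A Boolean matrix from [binarize()] (any 0/1 matrix with sample
#'   column names works).
#' @param labels Group labels covering every column of `B`.
#' @return A list with elements `control` and `experimental`, each a
#'   column-subset of `B` preserving within-group column order and the
#'   `direction` attribute.
#' @export
split_by_group <- function(B, labels) {
  missing <- setdiff(colnames(B), names(labels))
  if (length(missing))
    stop_input("no group label for sample(s): %s",
               paste(missing, collapse = ", "))
  labels <- normalize_label(labels[colnames(B)])
  out <- lapply(c(control = "control", experimental = "experimental"),
                function(g) {
                  blk <- B[, labels == g, drop = FALSE]
                  attr(blk, "direction") <- attr(B, "direction")
                  blk
                })
  out
}
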
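#' Per-sample winning coalitions of a Boolean block
#'
#' Each sample's coalition is the set of genes flagged 1 in that sample's
#' column. Empty coalitions are allowed and kept (they still count in the
#' Shapley divisor).
#'
#' @param B_group A 0/1 genes-by-samples matrix (typically one block from
#'   [split_by_group()]).
#' @return A named list, one character vector of gene identifiers per
#'   sample, in column order.
#' @export
supports <- function(B_group) {
  if (is.null(dim(B_group)) || ncol(B_group) == 0L)
    stop_input("Boolean block has no sample columns")
  genes <- rownames(B_group)
  stats::setNames(
    lapply(seq_len(ncol(B_group)), function(j) genes[B_group[, j] == 1]),
    colnames(B_group)
  )
}

#' Marginal contribution of a gene to one coalition
#'
#' Each observed coalition carries unit utility shared equally among its
#' members: a member of a size-k coalition contributes 1/k, a non-member 0.
#'
#' @param gene A gene identifier.
#' @param coalition Character vector of gene identifiers (may be empty).
#' @return A single number in `[0, 1]`.
#' @examples
#' marginal_contribution("g1", c("g1", "g2", "g3"))
#' @export
marginal_contribution <- function(gene, coalition) {
  if (length(coalition) && gene %in% coalition) 1 / length(coalition) else 0
}

#' Shapley values of the game induced by one Boolean block
#'
#' For a condition's block, every sample's coalition distributes unit
#' utility equally among its members; a gene's Shapley value is its mean
#' marginal contribution over *all* samples of the condition — samples
#' with empty coalitions contribute zero but stay in the divisor.
#'
#' @param B_group A 0/1 genes-by-samples matrix.
#' @return An object of class `shapley_result`: list with `marginals`
#'   (genes x samples matrix of per-sample contributions), `phi` (named
#'   per-gene means), `n_samples` and `n_nonempty`. Efficiency holds by
#'   construction: `sum(phi) == n_nonempty / n_samples`.
#' @examples
#' toy <- toy_dataset()
#' blocks <- split_by_group(binarize(toy$expression, toy$labels, "over"),
#'                          toy$labels)
#' round(shapley_values(blocks$experimental)$phi, 3)
#' @export
shapley_values <- function(B_group) {
  if (is.null(dim(B_group)) || ncol(B_group) == 0L)
    stop_input("Boolean block has no sample columns")
  sizes <- colSums(B_group)
  marg <- sweep(B_group, 2L, pmax(sizes, 1), "/")
  marg[, sizes == 0] <- 0
  attr(marg, "direction") <- NULL
  structure(
    list(marginals = marg, phi = rowMeans(marg),
         n_samples = ncol(B_group), n_nonempty = sum(sizes > 0),
         direction = attr(B_group, "direction")),
    class = "shapley_result"
  )
}

#' @export
print.shapley_result <- function(x, digits = 3, ...) {
  cat(sprintf("Microarray-game Shapley values (%d genes, %d samples, %d nonempty coalitions)\n",
              nrow(x$marginals), x$n_samples, x$n_nonempty))
  print(round(cbind(x$marginals, meanSh = x$phi), digits))
  invisible(x)
}

#' Aggregate coalitional game of a Boolean block
#'
#' Builds the explicit characteristic function: each sample contributes a
#' unanimity game on its (nonempty) coalition, and the aggregate worth of
#' a gene set `T` is the fraction of samples whose coalition is nonempty
#' and contained in `T`. Its classical Shapley value equals the closed
#' form computed by [shapley_values()].
#'
#' @inheritParams shapley_values
#' @return An object of class `microarray_game` with elements `players`,
#'   `support_masks` (per-sample bitmasks) and `n_samples`.
#' @seealso [game_value()], [brute_force_shapley()]
#' @export
microarray_game <- function(B_group) {
  if (is.null(dim(B_group)) || ncol(B_group) == 0L)
    stop_input("Boolean block has no sample columns")
  n <- nrow(B_group)
  if (n > 30L)
    stop_input("explicit game supports at most 30 players (got %d)", n)
  masks <- vapply(seq_len(ncol(B_group)), function(j) {
    idx <- which(B_group[, j] == 1)
    if (!length(idx)) 0L else sum(bitwShiftL(1L, idx - 1L))
  }, integer(1))
  structure(
    list(players = rownames(B_group), support_masks = masks,
         n_samples = ncol(B_group)),
    class = "microarray_game"
  )
}

#' Worth of a gene set in the aggregate game
#'
#' @param game A `microarray_game`.
#' @param coalition Character vector of player (gene) identifiers.
#' @return `v(T)`: the number of nonempty per-sample coalitions contained
#'   in `T`, divided by the number of samples.
#' @export
game_value <- function(game, coalition) {
  stopifnot(inherits(game, "microarray_game"))
  unknown <- setdiff(coalition, game$players)
  if (length(unknown))
    stop_input("unknown player(s): %s", paste(unknown, collapse = ", "))
  idx <- match(unique(coalition), game$players)
  mask <- if (!length(idx)) 0L else sum(bitwShiftL(1L, idx - 1L))
  s <- game$support_masks
  sum(s != 0L & bitwAnd(s, mask) == s) / game$n_samples
}

#' Classical Shapley value by exhaustive subset enumeration
#'
#' Validation oracle: evaluates the textbook subset-sum formula
#' `phi_i = sum_T |T|! (n-|T|-1)! / n! (v(T + i) - v(T))` over all
#' subsets of the player set, using the aggregate game's characteristic
#' function directly. Exponential in the number of players; capped at 20.
#' For routine use, [shapley_values()] computes the same values in
#' linear time via the unanimity decomposition.
#'
#' @param game A `microarray_game` (at most 20 players).
#' @return Named per-gene numeric vector of Shapley values.
#' @export
brute_force_shapley <- function(game) {
  stopifnot(inherits(game, "microarray_game"))
  n <- length(game$players)
  if (n > 20L)
    stop_input("brute-force enumeration capped at 20 players (got %d); use shapley_values()",
               n)
  masks <- 0:(2L^n - 1L)
  # v over all subsets: count nonempty supports contained in each mask.
  v <- numeric(length(masks))
  supp <- table(game$support_masks[game$support_masks != 0L])
  for (k in seq_along(supp)) {
    s <- as.integer(names(supp)[k])
    v <- v + as.numeric(supp[k]) * (bitwAnd(masks, s) == s)
  }
  v <- v / game$n_samples
  size <- integer(length(masks))
  for (b in 0:(n - 1L)) size <- size + (bitwAnd(masks, bitwShiftL(1L, b)) != 0L)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    Tm <- masks[bitwAnd(masks, bit) == 0L]
    t <- size[Tm + 1L]
    # |T|! (n-|T|-1)! / n!  ==  1 / (n * choose(n-1, |T|))
    w <- 1 / (n * choose(n - 1L, t))
    phi[i] <- sum(w * (v[Tm + bit + 1L] - v[Tm + 1L]))
  }
  stats::setNames(phi, game$players)
}
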
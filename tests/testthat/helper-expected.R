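# Frozen expected values for the bundled toy dataset (9 genes, 5 controls
# C1..C5, 5 experimental cases E1..E5). The Boolean matrices were derived
# by hand from the expression values (control mean +/- sample SD, boundary
# inclusive) and cross-checked against the package-independent arithmetic
# in these helpers; Shapley columns follow from them by direct counting.

toy_gene_ids <- paste0("gene", 1:9)
toy_sample_ids <- c(paste0("C", 1:5), paste0("E", 1:5))

toy_matrix <- function(bits) {
  matrix(bits, nrow = 9, byrow = TRUE,
         dimnames = list(toy_gene_ids, toy_sample_ids))
}

# Expected over-expression indicator (1 iff value >= control mean + SD).
expected_over <- toy_matrix(c(
  0,0,0,0,0, 0,1,0,0,1,
  0,0,0,0,0, 0,0,0,0,0,
  0,0,0,1,0, 0,0,0,0,0,
  0,0,0,1,0, 0,0,0,0,0,
  0,0,0,1,0, 0,0,0,0,1,
  0,0,0,0,1, 0,0,0,0,1,
  1,0,0,0,0, 0,0,0,0,0,
  0,0,0,1,0, 0,0,0,0,0,
  0,0,0,0,1, 0,0,0,0,0))

# Expected under-expression indicator (1 iff value <= control mean - SD).
expected_under <- toy_matrix(c(
  1,0,0,0,0, 1,0,0,1,0,
  0,0,0,0,1, 0,0,1,0,0,
  0,1,0,0,0, 0,1,0,1,0,
  1,0,0,0,0, 0,0,0,0,0,
  0,0,0,0,0, 1,0,0,1,0,
  0,0,0,0,0, 1,0,0,1,0,
  0,0,0,0,0, 0,0,1,1,1,
  0,0,0,0,0, 1,1,0,1,0,
  1,0,0,0,0, 0,0,0,0,0))

# Per-gene mean Shapley values (3 decimals) for the four game blocks.
expected_phi <- list(
  over_experimental  = c(0.267, 0, 0, 0, 0.067, 0.067, 0, 0, 0),
  under_experimental = c(0.083, 0.1, 0.133, 0, 0.083, 0.083, 0.333,
                         0.183, 0),
  over_control       = c(0, 0, 0.05, 0.05, 0.05, 0.1, 0.2, 0.05, 0.1),
  under_control      = c(0.067, 0.2, 0.2, 0.067, 0, 0, 0, 0, 0.067)
)
for (nm in names(expected_phi)) names(expected_phi[[nm]]) <- toy_gene_ids

# Per-sample Shapley columns, same layout as the blocks.
expected_marginals <- list()
expected_marginals$over_experimental <- matrix(c(
  0,1,0,0,1/3,
  0,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0,1/3,
  0,0,0,0,1/3,
  0,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0,0), nrow = 9, byrow = TRUE,
  dimnames = list(toy_gene_ids, paste0("E", 1:5)))
expected_marginals$under_experimental <- matrix(c(
  0.25,0,0,1/6,0,
  0,0,0.5,0,0,
  0,0.5,0,1/6,0,
  0,0,0,0,0,
  0.25,0,0,1/6,0,
  0.25,0,0,1/6,0,
  0,0,0.5,1/6,1,
  0.25,0.5,0,1/6,0,
  0,0,0,0,0), nrow = 9, byrow = TRUE,
  dimnames = list(toy_gene_ids, paste0("E", 1:5)))
expected_marginals$over_control <- matrix(c(
  0,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0.25,0,
  0,0,0,0.25,0,
  0,0,0,0.25,0,
  0,0,0,0,0.5,
  1,0,0,0,0,
  0,0,0,0.25,0,
  0,0,0,0,0.5), nrow = 9, byrow = TRUE,
  dimnames = list(toy_gene_ids, paste0("C", 1:5)))
expected_marginals$under_control <- matrix(c(
  1/3,0,0,0,0,
  0,0,0,0,1,
  0,1,0,0,0,
  1/3,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0,0,
  0,0,0,0,0,
  1/3,0,0,0,0), nrow = 9, byrow = TRUE,
  dimnames = list(toy_gene_ids, paste0("C", 1:5)))

# Expected ADSV columns (3 decimals) per direction.
expected_adsv <- list(
  over  = c(0.267, 0, 0.05, 0.05, 0.017, 0.033, 0.2, 0.05, 0.1),
  under = c(0.017, 0.1, 0.067, 0.067, 0.083, 0.083, 0.333, 0.183, 0.067)
)
for (nm in names(expected_adsv)) names(expected_adsv[[nm]]) <- toy_gene_ids

# ---- independent oracles -------------------------------------------------

# Shapley values of a Boolean block by direct per-sample counting,
# independent of the package's sweep-based implementation.
oracle_phi <- function(B) {
  phi <- numeric(nrow(B))
  for (j in seq_len(ncol(B))) {
    k <- sum(B[, j])
    if (k > 0) phi <- phi + B[, j] / k
  }
  stats::setNames(phi / ncol(B), rownames(B))
}

# Exact CASh p-values by enumerating every group-size-preserving
# relabelling (the permutation-null oracle; recomputes binarization).
oracle_exact_cash <- function(X, n_control, direction) {
  n <- ncol(X)
  adsv_for <- function(cc) {
    ee <- setdiff(seq_len(n), cc)
    Xc <- X[, cc, drop = FALSE]
    mu <- rowMeans(Xc)
    s <- apply(Xc, 1, sd)
    thr <- if (direction == "over") mu + s else mu - s
    Bm <- if (direction == "over") (X >= thr) + 0 else (X <= thr) + 0
    abs(oracle_phi(Bm[, cc, drop = FALSE]) -
          oracle_phi(Bm[, ee, drop = FALSE]))
  }
  obs <- adsv_for(seq_len(n_control))
  splits <- combn(n, n_control)
  cnt <- numeric(nrow(X))
  for (k in seq_len(ncol(splits)))
    cnt <- cnt + (adsv_for(splits[, k]) >= obs - 1e-12)
  list(p = cnt / ncol(splits), adsv = obs)
}

# Random 0/1 block with at least the given shape.
random_boolean_block <- function(n_genes, n_samples, p = 0.4) {
  matrix(rbinom(n_genes * n_samples, 1, p), nrow = n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

toy_path <- function(which) {
  system.file("extdata",
              c(expression = "toy_expression.tsv",
                groups = "toy_groups.tsv")[[which]],
              package = "cashgame")
}
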
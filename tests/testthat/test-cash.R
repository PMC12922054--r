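toy <- toy_dataset()

test_that("ADSV is the elementwise absolute Shapley difference", {
  for (d in c("over", "under")) {
    blocks <- split_by_group(binarize(toy$expression, toy$labels, d),
                             toy$labels)
    a <- adsv(shapley_values(blocks$control),
              shapley_values(blocks$experimental))
    expect_equal(round(a, 3), round(expected_adsv[[d]], 3))
  }
  expect_equal(unname(adsv(c(a = 0.1), c(a = 0.1))), 0)
  expect_error(adsv(c(a = 1), c(b = 1)), "same genes",
               class = "cashgame_input_error")
})

test_that("permuted relabelings preserve group sizes and are uniform", {
  lab <- toy$labels
  set.seed(5)
  for (rep in 1:20) {
    r <- resample_labels(lab, "permute_labels")
    expect_identical(names(r), names(lab))
    expect_identical(sum(r == "control"), 5L)
  }
  # 2 controls + 1 experimental: each of the 3 balanced assignments
  # should appear with frequency ~1/3
  small <- c(a = "control", b = "control", c = "experimental")
  set.seed(6)
  draws <- replicate(3000, names(which(
    resample_labels(small, "permute_labels") == "experimental")))
  freq <- table(factor(draws, levels = c("a", "b", "c"))) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.04))
})

test_that("bootstrap relabelings respect the degenerate-draw guard", {
  set.seed(8)
  for (rep in 1:50) {
    r <- resample_labels(toy$labels, "bootstrap_labels")
    expect_gte(sum(r == "control"), 2L)
    expect_gte(sum(r == "experimental"), 1L)
  }
})

test_that("resampling is reproducible from the seed", {
  cfg <- cash_config(n_resamples = 50, seed = 123)
  p1 <- cash_test(toy$expression, toy$labels, "under", cfg)$CASh_p
  p2 <- cash_test(toy$expression, toy$labels, "under", cfg)$CASh_p
  expect_identical(p1, p2)
  p3 <- cash_test(toy$expression, toy$labels, "under",
                  cash_config(n_resamples = 50, seed = 124))$CASh_p
  expect_false(identical(p1, p3))
})

test_that("zero observed ADSV forces p = 1 under the inclusive indicator", {
  for (seed in c(1, 999)) {
    cmp <- cash_test(toy$expression, toy$labels, "over",
                     cash_config(n_resamples = 25, seed = seed))
    expect_identical(cmp$CASh_p[cmp$gene_id == "gene2"], 1)
    expect_true(all(cmp$CASh_p[cmp$ADSV == 0] == 1))
    expect_true(all(cmp$CASh_p >= 0 & cmp$CASh_p <= 1))
  }
})

test_that("column-identical groups are exchangeable: all ADSV 0, all p 1", {
  half <- matrix(rnorm(4 * 3, 5), nrow = 4,
                 dimnames = list(paste0("g", 1:4), NULL))
  X <- cbind(half, half)
  colnames(X) <- c(paste0("C", 1:3), paste0("E", 1:3))
  lab <- setNames(rep(c("control", "experimental"), each = 3),
                  colnames(X))
  cmp <- cash_test(X, lab, "under", cash_config(n_resamples = 30, seed = 2))
  expect_true(all(cmp$ADSV == 0))
  expect_true(all(cmp$CASh_p == 1))
})

test_that("the add-one estimator bounds p away from zero", {
  cfg <- cash_config(n_resamples = 40, seed = 9, add_one_correction = TRUE)
  p <- cash_test(toy$expression, toy$labels, "under", cfg)$CASh_p
  expect_true(all(p >= 1 / 41 & p <= 1))
  expect_equal(round(p * 41) / 41, p)  # multiples of 1/(B+1)
})

test_that("Monte-Carlo p-values agree with exhaustive relabeling on a tiny design", {
  set.seed(21)
  X <- matrix(rnorm(5 * 6, 5, 0.5), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  lab <- setNames(rep(c("control", "experimental"), each = 3),
                  colnames(X))
  exact <- oracle_exact_cash(X, 3, "under")
  cmp <- cash_test(X, lab, "under",
                   cash_config(n_resamples = 4000, seed = 31))
  expect_equal(cmp$ADSV, unname(exact$adsv), tolerance = 1e-12)
  se <- sqrt(pmax(exact$p * (1 - exact$p), 0.25 / 20) / 4000)
  expect_true(all(abs(cmp$CASh_p - exact$p) <= 4 * se + 1e-9))
})

test_that("fixed-matrix mode only re-partitions the observed Boolean matrix", {
  # under fixed-matrix resampling the pooled multiset of bits is constant,
  # so a gene flagged in no sample at all keeps ADSV* = 0 in every draw
  cfg <- cash_config(n_resamples = 60, seed = 4,
                     recompute_binarization = FALSE)
  cmp <- cash_test(toy$expression, toy$labels, "over", cfg)
  B <- binarize(toy$expression, toy$labels, "over")
  never <- rowSums(B) == 0
  expect_true(all(cmp$CASh_p[never] == 1))
  expect_true(all(cmp$CASh_p >= 0 & cmp$CASh_p <= 1))
})

test_that("Benjamini-Hochberg adjustment matches p.adjust and drives selection", {
  cfg <- cash_config(n_resamples = 50, seed = 13, adjust = "BH")
  cmp <- cash_test(toy$expression, toy$labels, "under", cfg)
  expect_equal(cmp$adjusted_p, p.adjust(cmp$CASh_p, "BH"))
  expect_identical(cmp$selected,
                   cmp$adjusted_p <= 0.05 &
                     cmp$ADSV >= attr(cmp, "threshold"))
})

test_that("configuration arguments are validated", {
  expect_error(cash_config(n_resamples = 0), "positive",
               class = "cashgame_input_error")
  expect_error(cash_config(alpha = 0), "alpha",
               class = "cashgame_input_error")
  expect_error(cash_config(alpha = 1.2), "alpha",
               class = "cashgame_input_error")
})
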
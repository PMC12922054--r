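#' Run the full workflow: encode, split, Shapley, ADSV, CASh, select
#'
#' Orchestrates the whole analysis for one or both directions: Boolean
#' encoding against control statistics, group split, per-condition
#' Shapley values, ADSV, CASh resampling p-values, the mean-plus-SD
#' magnitude threshold, and the two-criterion candidate selection. When
#' both directions are analysed the candidate sets are unioned.
#'
#' @param expression A numeric genes-by-samples matrix, or a path to a
#'   delimited file for [read_expression_matrix()].
#' @param labels Group labels: a named character vector, `sample=label`
#'   tokens, or a path to a labels file.
#' @param direction `"both"` (default), `"over"` or `"under"`.
#' @param config A [cash_config()].
#' @param out_dir Optional output directory; when given, per-direction
#'   results tables (`results_over.tsv`, `results_under.tsv`), the
#'   candidate list (`candidates.txt`) and a run manifest
#'   (`manifest.json`) are written there.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `comparisons` (named list of
#'   `game_comparison` objects), `candidates` (character vector) and
#'   `manifest` (list). Deterministic given input, config and seed.
#' @examples
#' toy <- toy_dataset()
#' res <- run_pipeline(toy$expression, toy$labels,
#'                     config = cash_config(n_resamples = 200, seed = 1),
#'                     quiet = TRUE)
#' res$candidates
#' @export
run_pipeline <- function(expression, labels,
                         direction = c("both", "over", "under"),
                         config = cash_config(), out_dir = NULL,
                         quiet = FALSE) {
  direction <- match.arg(direction)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  if (is.character(expression) && length(expression) == 1L) {
    say("reading expression matrix from %s", expression)
    expression <- read_expression_matrix(expression)
  }
  if (is.character(labels) && (is.null(names(labels)) ||
                               any(names(labels) == ""))) {
    labels <- read_group_labels(labels)
  }
  labels <- match_labels(expression, labels)
  say("matrix: %d genes x %d samples (%d control, %d experimental)",
      nrow(expression), ncol(expression), sum(labels == "control"),
      sum(labels == "experimental"))

  dirs <- if (direction == "both") c("over", "under") else direction
  comparisons <- list()
  for (d in dirs) {
    cmp <- cash_test(expression, labels, d, config)
    n_coal <- sum(colSums(suppressWarnings(
      binarize(expression, labels, d))) > 0)
    say("%s game: %d nonempty coalitions, threshold %.3f, B = %d, seed = %s",
        d, n_coal, attr(cmp, "threshold"), config$n_resamples,
        if (is.null(config$seed)) "none" else config$seed)
    comparisons[[d]] <- cmp
  }
  candidates <- select_candidates(comparisons)
  say("candidates: %s",
      if (length(candidates)) paste(candidates, collapse = ", ") else "(none)")

  manifest <- list(
    package = "cashgame",
    version = as.character(utils::packageVersion("cashgame")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_genes = nrow(expression), n_samples = ncol(expression),
    n_control = sum(labels == "control"),
    n_experimental = sum(labels == "experimental"),
    direction = direction,
    config = config[c("n_resamples", "resampling_mode",
                      "recompute_binarization", "alpha", "seed",
                      "add_one_correction", "adjust")],
    candidates = candidates
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in names(comparisons))
      write_results_table(comparisons[[d]],
                          file.path(out_dir, sprintf("results_%s.tsv", d)))
    writeLines(candidates, file.path(out_dir, "candidates.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    say("results written to %s", out_dir)
  }
  invisible(list(comparisons = comparisons, candidates = candidates,
                 manifest = manifest))
}
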
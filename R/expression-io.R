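#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects gene identifiers in the first column and sample identifiers in
#' the header row; every remaining cell must parse as a finite real.
#' Row and column order are preserved exactly as found in the file, since
#' all downstream tables are aligned to the input ordering.
#'
#' @param path Path to a CSV or TSV file.
#' @param delimiter `"auto"` (default) sniffs the first line for a tab and
#'   falls back to a comma; otherwise a single delimiter character.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @details Missing or non-numeric cells are rejected with their positions:
#'   the Boolean encoding has no missing-data rule, and silent imputation
#'   would change coalitions invisibly.
#' @examples
#' path <- system.file("extdata", "toy_expression.tsv", package = "cashgame")
#' X <- read_expression_matrix(path)
#' dim(X)
#' @export
read_expression_matrix <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stop_input("expression file not found: %s", path)
  sep <- sniff_delimiter(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_input("empty expression matrix in %s", path)
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop_input("duplicate gene identifier(s): %s",
               paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop_input("duplicate sample identifier(s): %s",
               paste(dup_s, collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    pos <- apply(bad[seq_len(min(5L, nrow(bad))), , drop = FALSE], 1L,
                 function(ij) sprintf("(%s, %s)", gene_ids[ij[1L]],
                                      sample_ids[ij[2L]]))
    stop_input("%d missing or non-numeric cell(s), e.g. at %s",
               nrow(bad), paste(pos, collapse = ", "))
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

sniff_delimiter <- function(path, delimiter) {
  if (!identical(delimiter, "auto")) return(delimiter)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]; the gene-identifier column is
#' labelled `gene_id`.
#'
#' @param X Numeric genes-by-samples matrix with dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(X, path) {
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.label_aliases <- list(
  control = c("control", "ctrl", "c"),
  experimental = c("experimental", "case", "exp", "e")
)

normalize_label <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA_character_, length(lx))
  out[lx %in% .label_aliases$control] <- "control"
  out[lx %in% .label_aliases$experimental] <- "experimental"
  if (anyNA(out))
    stop_input("unknown group label(s): %s; expected control/c or experimental/case/e",
               paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Construct group labels from a named vector or `sample=label` tokens
#'
#' Labels are normalised to the two-value vocabulary `control` /
#' `experimental` (accepted aliases, case-insensitive: `c`, `ctrl`;
#' `case`, `exp`, `e`).
#'
#' @param x Either a character vector named by sample identifier, or an
#'   unnamed character vector of `sample=label` tokens.
#' @return A named character vector of `"control"` / `"experimental"`.
#' @examples
#' group_labels(c(S1 = "control", S2 = "case", S3 = "C"))
#' group_labels(c("S1=control", "S2=experimental"))
#' @export
group_labels <- function(x) {
  if (is.null(names(x)) || any(names(x) == "")) {
    if (!all(grepl("=", x, fixed = TRUE)))
      stop_input("labels must be named by sample or given as sample=label tokens")
    parts <- strsplit(x, "=", fixed = TRUE)
    ids <- vapply(parts, `[[`, "", 1L)
    lab <- vapply(parts, function(p) paste(p[-1L], collapse = "="), "")
  } else {
    ids <- names(x)
    lab <- unname(x)
  }
  lab <- normalize_label(lab)
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      if (length(unique(lab[ids == id])) > 1L)
        stop_input("sample %s labelled with conflicting groups", id)
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; lab <- lab[keep]
  }
  stats::setNames(lab, ids)
}

#' Read group labels from a two-column file or from tokens
#'
#' @param path_or_tokens Either a path to a two-column delimited file
#'   (sample identifier, label; an optional header line is detected and
#'   skipped), or a character vector of `sample=label` tokens.
#' @return A named character vector as returned by [group_labels()].
#' @export
read_group_labels <- function(path_or_tokens) {
  x <- path_or_tokens
  if (length(x) > 1L || any(grepl("=", x, fixed = TRUE)))
    return(group_labels(x))
  if (!file.exists(x)) stop_input("labels file not found: %s", x)
  sep <- sniff_delimiter(x, "auto")
  df <- utils::read.table(x, header = FALSE, sep = sep,
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("labels file must have two columns: %s", x)
  # Drop a header line whose second field is not a recognised label.
  probe <- tryCatch(normalize_label(df[1L, 2L]), error = function(e) NULL)
  if (is.null(probe)) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop_input("no label rows in %s", x)
  group_labels(stats::setNames(df[[2L]], df[[1L]]))
}

# Check labels against a matrix's samples and return them in column order.
# Requires >= 2 controls (the control SD is undefined otherwise) and
# >= 1 experimental sample.
match_labels <- function(X, labels) {
  missing <- setdiff(colnames(X), names(labels))
  if (length(missing))
    stop_input("no group label for sample(s): %s",
               paste(missing, collapse = ", "))
  labels <- labels[colnames(X)]
  if (sum(labels == "control") < 2L)
    stop_input("need at least 2 control samples (control SD undefined)")
  if (sum(labels == "experimental") < 1L)
    stop_input("need at least 1 experimental sample")
  labels
}

#' Write a per-direction results table as tab-delimited text
#'
#' Columns: `gene_id`, `meanShC`, `meanShE`, `ADSV`, `CASh_p`,
#' `adjusted_p` (when multiple-testing adjustment was requested) and
#' `selected`. Values are written at full precision so a rewrite/reread
#' cycle is value-identical.
#'
#' @param comparison A `game_comparison` object from [cash_test()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "game_comparison"))
  utils::write.table(as.data.frame(comparison), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
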
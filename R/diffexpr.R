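# Sex imputation from a marker gene and two-group differential expression.
#
# The output is a per-gene weight vector: the log2 fold change (male minus
# female) for genes passing a Benjamini-Hochberg FDR threshold, and exactly
# zero otherwise. Positive weights are male-biased by convention so that
# downstream task scores are signed male-vs-female.

#' Impute sample sex from a male-marker gene
#'
#' Samples whose marker value lies strictly above the upper
#' `1 - quantile` empirical quantile are called male; strictly below the
#' lower `quantile` quantile, female; all others unassigned. With the
#' default 0.16 the cutoffs sit roughly one standard deviation either side
#' of the mean for a unimodal marker.
#'
#' @param matrix Gene x sample numeric matrix (log2 scale).
#' @param marker_gene Row name of the marker gene.
#' @param quantile Tail mass per side, in (0, 0.5); default 0.16.
#' @return Named character vector over samples with values `"male"`,
#'   `"female"`, `"unassigned"`.
#' @export
impute_sex <- function(matrix, marker_gene, quantile = 0.16) {
  assert_scalar_num(quantile, "quantile", 1e-9, 0.5 - 1e-9)
  if (!marker_gene %in% rownames(matrix))
    abort_("marker gene '%s' not in matrix", marker_gene,
           class = "tidegem_config_error")
  v <- matrix[marker_gene, ]
  if (max(v) - min(v) < 1e-12)
    abort_("marker gene values are constant; quantiles are degenerate",
           class = "tidegem_degenerate_error")
  out <- stats::setNames(rep("unassigned", length(v)), colnames(matrix))
  if (length(v) < ceiling(1 / quantile)) {
    warning("too few samples for quantile-based sex imputation; ",
            "all samples unassigned")
    return(out)
  }
  qlo <- stats::quantile(v, quantile, names = FALSE)
  qhi <- stats::quantile(v, 1 - quantile, names = FALSE)
  out[v > qhi] <- "male"
  out[v < qlo] <- "female"
  out
}

# Vectorized Welch two-sample test on the rows of a matrix; equivalent per
# gene to stats::t.test(x, y) (checked in the test suite). Degenerate rows
# where both groups have zero variance get p = 1 when the means agree and
# p = 0 otherwise.
welch_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(diff = m1 - m2, t = tstat, df = df, p = p)
}

#' Two-group differential expression (male vs female)
#'
#' Per gene: log2 fold change = mean(male) - mean(female) of the log2
#' values, a two-sided Welch two-sample test, Benjamini-Hochberg FDR, and a
#' weight equal to the log2 fold change where FDR < `fdr_threshold` and 0
#' otherwise.
#'
#' @param matrix Gene x sample numeric matrix on the log2 scale.
#' @param labels Named character vector (sample -> `"male"`/`"female"`;
#'   other values are ignored). At least 3 samples per sex are required.
#' @param fdr_threshold FDR cutoff below which a gene keeps its fold change
#'   as weight; default 0.1.
#' @return A `de_weights` data.frame with columns `gene`, `log2fc`, `p`,
#'   `fdr`, `weight` and attribute `fdr_threshold`.
#' @export
differential_expression <- function(matrix, labels, fdr_threshold = 0.1) {
  assert_scalar_num(fdr_threshold, "fdr_threshold", 0, 1)
  labels <- labels[names(labels) %in% colnames(matrix)]
  males <- names(labels)[labels == "male"]
  females <- names(labels)[labels == "female"]
  if (length(males) < 3 || length(females) < 3)
    abort_("need at least 3 labeled samples per sex (got %d male, %d female)",
           length(males), length(females), class = "tidegem_config_error")
  w <- welch_rows(matrix, match(males, colnames(matrix)),
                  match(females, colnames(matrix)))
  fdr <- stats::p.adjust(w$p, method = "BH")
  res <- data.frame(gene = rownames(matrix), log2fc = unname(w$diff),
                    p = unname(w$p), fdr = unname(fdr),
                    weight = ifelse(fdr < fdr_threshold, unname(w$diff), 0),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, fdr_threshold = fdr_threshold,
            class = c("de_weights", "data.frame"))
}

#' Restrict differential-expression weights to a model's genes
#'
#' @param weights A `de_weights` object.
#' @param model A `metabolic_model`.
#' @return The weights restricted to genes present in the model; errors if
#'   the intersection is empty.
#' @export
restrict_to_model <- function(weights, model) {
  stopifnot(inherits(weights, "de_weights"),
            inherits(model, "metabolic_model"))
  keep <- weights$gene %in% model_genes(model)
  if (!any(keep))
    abort_("no gene in the weight table occurs in model '%s'", model$id,
           class = "tidegem_config_error")
  out <- weights[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fdr_threshold = attr(weights, "fdr_threshold"),
            class = c("de_weights", "data.frame"))
}

#' Extract the named weight vector from a de_weights table
#' @param weights A `de_weights` object (or a named numeric vector, returned
#'   as is).
#' @return Named numeric vector gene -> weight.
#' @export
de_weight_vector <- function(weights) {
  if (is.numeric(weights) && !is.null(names(weights))) return(weights)
  stopifnot(inherits(weights, "de_weights"))
  stats::setNames(weights$weight, weights$gene)
}
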
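#' Mean-based TF activity from a CPM matrix
#'
#' The TF's activity in each sample is the unweighted mean of its target
#' genes' CPM values in that sample. On the intron layer only
#' intron-bearing targets enter the mean (an intronless gene cannot yield
#' intronic reads, so including its structural zeros would dilute the
#' estimate). On the exon and total layers all targets are kept by default;
#' set \code{matched_gene_set = TRUE} to restrict every layer to
#' intron-bearing targets so that layer comparisons use identical gene
#' sets.
#'
#' @param cpm_mat genes x samples CPM matrix (from \code{\link{cpm}} or
#'   \code{\link{total_cpm}}; any per-gene expression matrix works if its
#'   \code{layer} attribute is set or \code{layer} is passed).
#' @param targets character vector of target gene ids (the TF's regulon).
#' @param gene_has_intron named logical vector flagging intron-bearing
#'   genes (see \code{\link{has_intron}}); required for the intron layer
#'   and for \code{matched_gene_set}.
#' @param layer overrides the matrix's \code{layer} attribute.
#' @param matched_gene_set restrict all layers to intron-bearing targets.
#' @param tf TF name used in messages.
#' @return Named numeric vector of activities over samples, with
#'   attributes \code{method = "mean"}, \code{layer} and \code{n_targets}.
#' @export
tfa_mean <- function(cpm_mat, targets, gene_has_intron = NULL,
                     layer = attr(cpm_mat, "layer"),
                     matched_gene_set = FALSE, tf = "TF") {
  if (is.null(layer)) stop("layer must be given (matrix has no layer attribute)")
  present <- targets %in% rownames(cpm_mat)
  if (any(!present))
    warning(tf, ": target(s) absent from the expression matrix, dropped: ",
            paste(targets[!present], collapse = ", "))
  eligible <- targets[present]
  if (layer == "intron" || matched_gene_set) {
    if (is.null(gene_has_intron))
      stop("gene_has_intron is required for the intron layer")
    eligible <- eligible[gene_has_intron[eligible]]
  }
  if (length(eligible) == 0)
    stop("no eligible target of ", tf, " on the ", layer, " layer")
  act <- colMeans(cpm_mat[eligible, , drop = FALSE])
  structure(act, method = "mean", layer = layer,
            n_targets = length(eligible))
}

#' Mean-based activity matrix for many TFs
#'
#' Convenience wrapper applying \code{\link{tfa_mean}} to every TF of a
#' regulon set; TFs with no eligible target on the requested layer are
#' dropped with a warning.
#'
#' @inheritParams tfa_mean
#' @param regulons a \code{regulon_set}.
#' @param tfs TFs to score (default: all in \code{regulons}).
#' @param max_grade,activation_only passed to \code{\link{filter_regulon}}.
#' @return TFs x samples activity matrix with attributes \code{method} and
#'   \code{layer}.
#' @export
tfa_matrix <- function(cpm_mat, regulons, gene_has_intron = NULL,
                       tfs = sort(unique(regulons$tf)), max_grade = "B",
                       activation_only = TRUE,
                       layer = attr(cpm_mat, "layer"),
                       matched_gene_set = FALSE) {
  rows <- list()
  for (tf in tfs) {
    targets <- filter_regulon(regulons, tf, max_grade, activation_only)
    act <- tryCatch(
      suppressWarnings(tfa_mean(cpm_mat, targets, gene_has_intron,
                                layer = layer,
                                matched_gene_set = matched_gene_set,
                                tf = tf)),
      error = function(e) NULL)
    if (is.null(act)) {
      warning("TF ", tf, " has no eligible target on the ", layer,
              " layer; dropped")
    } else rows[[tf]] <- act
  }
  out <- do.call(rbind, rows)
  structure(out, method = "mean", layer = layer)
}

#' Rank-based (recovery-curve AUC) activity score
#'
#' Ranks all genes of one sample by decreasing expression (ties broken by
#' gene id so the ranking is deterministic), walks down the top
#' \code{top_fraction} of the ranking counting regulon genes recovered, and
#' returns the area under that recovery curve normalised by the maximal
#' achievable area. A score of 1 means the regulon occupies the very top of
#' the ranking; the expected score for an uninformative ranking is about
#' 0.5 when the regulon is small relative to the universe.
#'
#' @param expression named numeric vector: one sample's expression over the
#'   whole gene universe.
#' @param targets character vector of regulon genes.
#' @param top_fraction fraction of the ranking to integrate over (0, 1].
#' @return Scalar score in [0, 1]; 0 with a warning when no target is in
#'   the universe.
#' @export
tfa_rank_auc <- function(expression, targets, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (is.null(names(expression))) stop("expression must be named by gene")
  hits_genes <- intersect(targets, names(expression))
  if (length(hits_genes) == 0) {
    warning("no regulon target in the expression universe; score 0")
    return(0)
  }
  ord <- order(-expression, names(expression))
  n_top <- max(1L, floor(top_fraction * length(expression)))
  is_hit <- names(expression)[ord[seq_len(n_top)]] %in% hits_genes
  recovery <- cumsum(is_hit)
  max_area <- sum(pmin(seq_len(n_top), length(hits_genes)))
  sum(recovery) / max_area
}

#' Z-score normalise an activity series
#'
#' @param x numeric vector over ordered samples (length >= 2).
#' @return \code{(x - mean(x)) / sd(x)}; a constant series yields an
#'   all-zero vector with a warning rather than NaN.
#' @export
zscore_series <- function(x) {
  if (length(x) < 2) stop("zscore_series needs at least 2 samples")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant series: z-scores set to 0")
    return(stats::setNames(rep(0, length(x)), names(x)))
  }
  (x - mean(x)) / s
}

#' Peak fold-change of an activity series
#'
#' @param x numeric activity vector over samples.
#' @param baseline_index index of the baseline sample (default first).
#' @return \code{max(x) / x[baseline_index]}.
#' @export
fold_change <- function(x, baseline_index = 1) {
  b <- x[baseline_index]
  if (!is.finite(b) || b <= 0) stop("baseline activity must be positive")
  max(x) / b
}

#' Empirical percentile and p-value against a null distribution
#'
#' One-sided empirical p-value with the add-one rule,
#' \code{p = (1 + #\{null >= actual\}) / (1 + n_null)}, and the mid-rank
#' percentile of the actual statistic within the null sample.
#'
#' @param actual scalar statistic from the real regulon.
#' @param null_stats numeric vector of the statistic under random regulons
#'   (at least 100 values).
#' @return List with \code{percentile} (0-100) and \code{p_value}.
#' @export
null_percentile <- function(actual, null_stats) {
  null_stats <- null_stats[is.finite(null_stats)]
  n <- length(null_stats)
  if (n < 100) stop("null_percentile needs at least 100 null values")
  list(percentile = 100 * (sum(null_stats < actual) +
                             0.5 * sum(null_stats == actual)) / n,
       p_value = (1 + sum(null_stats >= actual)) / (1 + n))
}

#' Keep only TFs whose own gene is expressed
#'
#' A TF is retained when its gene's intron CPM plus exon CPM is greater
#' than zero in at least one sample. TFs absent from the matrix are treated
#' as unexpressed (warning).
#'
#' @param intron_cpm,exon_cpm genes x samples CPM matrices.
#' @param tfs character vector of TF gene ids.
#' @return Subset of \code{tfs}.
#' @export
expressed_tf_filter <- function(intron_cpm, exon_cpm, tfs) {
  present <- tfs %in% rownames(intron_cpm) & tfs %in% rownames(exon_cpm)
  if (any(!present))
    warning("TF gene(s) absent from the matrix, treated as unexpressed: ",
            paste(tfs[!present], collapse = ", "))
  keep <- vapply(tfs[present], function(tf)
    any(intron_cpm[tf, ] + exon_cpm[tf, ] > 0), logical(1))
  tfs[present][keep]
}
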
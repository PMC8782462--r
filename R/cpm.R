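#' Counts-per-million on a shared intron+exon library size
#'
#' For gene g and sample j,
#' \deqn{CPM_{layer}(g, j) = 10^6 \; count_{layer}(g, j) / D_j,}
#' where the denominator \eqn{D_j} is the intron-level plus exon-level read
#' count summed over all genes of sample j. The denominator is shared
#' between the two layers, so per sample the intron CPMs and exon CPMs of
#' all genes together sum to exactly one million. No gene-length
#' normalisation is applied: intronic reads can arise from priming inside
#' introns, so the effective intronic length is unknown.
#'
#' @param x a count container from \code{\link{count_matrix}}.
#' @param layer \code{"intron"} or \code{"exon"}.
#' @return A genes x samples numeric matrix with attribute \code{layer}.
#' @export
#' @examples
#' cm <- count_matrix(matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'                    matrix(c(40, 50), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'                    has_intron = c(TRUE, FALSE))
#' cpm(cm, "intron")["a", ]  # 1e5: 10 reads over a library of 100
cpm <- function(x, layer = c("intron", "exon")) {
  layer <- match.arg(layer)
  i <- intron_counts(x)
  e <- exon_counts(x)
  denom <- colSums(i) + colSums(e)
  if (any(denom <= 0))
    stop("zero library size (intron + exon) in sample(s): ",
         paste(colnames(x)[denom <= 0], collapse = ", "))
  m <- if (layer == "intron") i else e
  out <- sweep(m, 2, denom, "/") * 1e6
  attr(out, "layer") <- layer
  out
}

#' Total (intron plus exon) CPM
#'
#' Per-gene sum of the intron-layer and exon-layer CPM values, both computed
#' on the shared library-size denominator of \code{\link{cpm}}.
#'
#' @inheritParams cpm
#' @return A genes x samples matrix with attribute \code{layer = "total"}.
#' @export
total_cpm <- function(x) {
  out <- cpm(x, "intron") + cpm(x, "exon")
  attr(out, "layer") <- "total"
  out
}

#' Average expression columns by group (e.g. biological replicates)
#'
#' Averaging is done on normalised (CPM) values, not raw counts, so that
#' replicates with different sequencing depths contribute equally.
#'
#' @param mat genes x samples matrix (typically a CPM matrix).
#' @param groups per-sample grouping vector (e.g. time point); averaged
#'   columns are named by the group level, ordered by first appearance.
#' @return A genes x groups matrix; the \code{layer} attribute is carried
#'   over.
#' @export
average_replicates <- function(mat, groups) {
  if (length(groups) != ncol(mat))
    stop("groups must have one entry per column")
  lev <- unique(groups)
  out <- vapply(lev, function(g)
    rowMeans(mat[, groups == g, drop = FALSE]), numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), as.character(lev))
  attr(out, "layer") <- attr(mat, "layer")
  out
}
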
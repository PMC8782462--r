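#' Build a paired intron/exon count container
#'
#' Wraps per-gene, per-sample intron and exon read counts in a
#' \code{SummarizedExperiment} with two assays (\code{"intron"},
#' \code{"exon"}), a per-gene \code{has_intron} flag in \code{rowData}, and
#' optional per-sample \code{time} and \code{replicate} in \code{colData}.
#' Genes without annotated introns must have an all-zero intron row; the
#' flag (not the zeros) is what downstream exclusion rules consult.
#'
#' @param intron,exon non-negative integer matrices of identical dimension
#'   and dimnames (genes x samples).
#' @param has_intron logical per-gene flag; default derived as "any intron
#'   read observed" only if not supplied (supply it explicitly when an
#'   intron-bearing gene may have all-zero counts).
#' @param time optional numeric per-sample time.
#' @param replicate optional per-sample replicate label.
#'
#' @return A \code{SummarizedExperiment}.
#' @export
count_matrix <- function(intron, exon, has_intron = NULL, time = NULL,
                         replicate = NULL) {
  intron <- as.matrix(intron)
  exon <- as.matrix(exon)
  if (!identical(dim(intron), dim(exon)))
    stop("intron and exon count matrices must have identical dimensions")
  if (is.null(rownames(intron)) || is.null(colnames(intron)))
    stop("count matrices need gene (row) and sample (column) names")
  if (!identical(dimnames(intron), dimnames(exon)))
    stop("intron and exon dimnames must agree")
  if (anyDuplicated(rownames(intron)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(intron)[duplicated(rownames(intron))]),
               collapse = ", "))
  for (nm in c("intron", "exon")) {
    m <- get(nm)
    if (any(!is.finite(m)) || any(m < 0)) {
      bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative or non-finite %s count for gene %s, sample %s",
                   nm, rownames(m)[bad[1]], colnames(m)[bad[2]]))
    }
  }
  if (is.null(has_intron)) has_intron <- rowSums(intron) > 0
  has_intron <- as.logical(has_intron)
  if (length(has_intron) != nrow(intron))
    stop("has_intron must have one entry per gene")
  if (any(!has_intron & rowSums(intron) > 0))
    stop("genes flagged intronless must have all-zero intron counts: ",
         paste(rownames(intron)[!has_intron & rowSums(intron) > 0],
               collapse = ", "))
  cd <- S4Vectors::DataFrame(row.names = colnames(intron))
  if (!is.null(time)) cd$time <- time
  if (!is.null(replicate)) cd$replicate <- replicate
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intron = intron, exon = exon),
    rowData = S4Vectors::DataFrame(has_intron = has_intron,
                                   row.names = rownames(intron)),
    colData = cd)
}

#' @rdname count_matrix
#' @param x a count container built by \code{count_matrix}.
#' @export
intron_counts <- function(x) SummarizedExperiment::assay(x, "intron")

#' @rdname count_matrix
#' @export
exon_counts <- function(x) SummarizedExperiment::assay(x, "exon")

#' @rdname count_matrix
#' @export
has_intron <- function(x) {
  v <- SummarizedExperiment::rowData(x)$has_intron
  names(v) <- rownames(x)
  v
}

#' Read a paired intron/exon count table
#'
#' The TSV dialect ("paired-v1") has a header row and columns
#' \code{gene_id}, \code{has_intron} (TRUE/FALSE), then one
#' \code{<sample>__intron} and \code{<sample>__exon} column pair per sample.
#' An optional sample-information TSV (\code{sample_id}, \code{time},
#' \code{replicate}) attaches per-sample metadata.
#'
#' @param path path to the counts TSV.
#' @param sample_info optional path to a sample metadata TSV.
#' @return A \code{SummarizedExperiment} (see \code{\link{count_matrix}}).
#' @export
read_count_table <- function(path, sample_info = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("gene_id", "has_intron")
  if (!all(req %in% names(tab)))
    stop("count table must have columns gene_id and has_intron: ", path)
  datacols <- setdiff(names(tab), req)
  m <- regmatches(datacols, regexec("^(.*)__(intron|exon)$", datacols))
  ok <- lengths(m) == 3
  if (!all(ok))
    stop("unrecognised column(s) in count table: ",
         paste(datacols[!ok], collapse = ", "))
  samples <- unique(vapply(m, `[`, "", 2))
  need <- c(outer(samples, c("intron", "exon"), paste, sep = "__"))
  if (!all(need %in% datacols))
    stop("each sample needs both an __intron and an __exon column")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  pick <- function(layer) {
    mm <- as.matrix(tab[, paste0(samples, "__", layer), drop = FALSE])
    dimnames(mm) <- list(tab$gene_id, samples)
    mm
  }
  time <- replicate <- NULL
  if (!is.null(sample_info)) {
    si <- utils::read.delim(sample_info, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(si))
      stop("sample_info needs a sample_id column")
    idx <- match(samples, si$sample_id)
    if (anyNA(idx)) stop("sample_info is missing samples: ",
                         paste(samples[is.na(idx)], collapse = ", "))
    if ("time" %in% names(si)) time <- si$time[idx]
    if ("replicate" %in% names(si)) replicate <- si$replicate[idx]
  }
  count_matrix(pick("intron"), pick("exon"),
               has_intron = as.logical(tab$has_intron),
               time = time, replicate = replicate)
}

#' Write a paired intron/exon count table
#'
#' Inverse of \code{\link{read_count_table}} (dialect "paired-v1").
#'
#' @param x a count container built by \code{\link{count_matrix}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(x, path) {
  i <- intron_counts(x)
  e <- exon_counts(x)
  out <- data.frame(gene_id = rownames(x),
                    has_intron = has_intron(x),
                    check.names = FALSE)
  for (s in colnames(x)) {
    out[[paste0(s, "__intron")]] <- i[, s]
    out[[paste0(s, "__exon")]] <- e[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
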
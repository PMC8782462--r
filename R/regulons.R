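REGULON_GRADES <- c("A", "B", "C", "D", "E")
REGULON_MODES <- c("activation", "repression")

#' Load a regulon table
#'
#' Reads a DoRothEA-style TSV with columns \code{tf}, \code{target},
#' \code{mode} (\code{activation}/\code{repression}) and \code{confidence}
#' (curation grade A-E, A most confident).
#'
#' @param path path to the regulon TSV.
#' @return A data.frame of class \code{regulon_set}.
#' @export
load_regulons <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  regulon_set(tab)
}

#' @rdname load_regulons
#' @param entries data.frame with columns tf, target, mode, confidence.
#' @export
regulon_set <- function(entries) {
  req <- c("tf", "target", "mode", "confidence")
  if (!all(req %in% names(entries)))
    stop("regulon table needs columns: ", paste(req, collapse = ", "))
  entries <- entries[req]
  bad <- !entries$mode %in% REGULON_MODES
  if (any(bad))
    stop("unknown regulation mode: ",
         paste(unique(entries$mode[bad]), collapse = ", "))
  bad <- !entries$confidence %in% REGULON_GRADES
  if (any(bad))
    stop("unknown confidence grade: ",
         paste(unique(entries$confidence[bad]), collapse = ", "))
  dup <- duplicated(entries[c("tf", "target")])
  if (any(dup))
    stop("duplicate (tf, target) pair(s): ",
         paste(unique(paste(entries$tf[dup], entries$target[dup], sep = "->")),
               collapse = ", "))
  class(entries) <- c("regulon_set", "data.frame")
  entries
}

#' Extract one TF's target list by confidence and mode
#'
#' The default reproduces the standard regulon rule: only targets activated
#' by the TF with confidence grade A or B. Loosening \code{max_grade} to
#' \code{"C"} admits third-grade links (needed e.g. for TFs whose regulon is
#' only curated at that level).
#'
#' @param regulons a \code{regulon_set}.
#' @param tf TF identifier.
#' @param max_grade most permissive confidence grade to admit (A < B < C <
#'   D < E).
#' @param activation_only drop repression-mode edges (default TRUE).
#' @return Character vector of target gene ids.
#' @export
filter_regulon <- function(regulons, tf, max_grade = "B",
                           activation_only = TRUE) {
  stopifnot(inherits(regulons, "regulon_set"))
  max_grade <- match.arg(max_grade, REGULON_GRADES)
  if (!tf %in% regulons$tf)
    stop("TF '", tf, "' not in regulon set; available: ",
         paste(sort(unique(regulons$tf)), collapse = ", "))
  sel <- regulons$tf == tf &
    match(regulons$confidence, REGULON_GRADES) <= match(max_grade, REGULON_GRADES)
  if (activation_only) sel <- sel & regulons$mode == "activation"
  regulons$target[sel]
}

#' Load an mRNA half-life table
#'
#' @param path TSV with columns \code{gene} and \code{half_life_min}.
#' @return Named numeric vector of half-lives (min).
#' @export
load_halflife_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "half_life_min") %in% names(tab)))
    stop("half-life table needs columns gene, half_life_min")
  if (any(tab$half_life_min <= 0))
    stop("half-lives must be positive")
  stats::setNames(tab$half_life_min, tab$gene)
}

#' Split a target list into short- and long-lived sub-regulons
#'
#' Median split on mRNA half-life among the targets that have half-life
#' data; targets without data are excluded. Targets are ordered by
#' (half-life, gene id) so ties at the median resolve deterministically;
#' the lower half (including the median element when the count is odd) goes
#' to the short-lived sub-regulon, so sizes differ by at most one.
#'
#' @param targets character vector of target gene ids.
#' @param half_lives named numeric vector (min), as from
#'   \code{\link{load_halflife_table}}.
#' @return List with elements \code{short} and \code{long}.
#' @export
split_by_halflife <- function(targets, half_lives) {
  hl <- half_lives[intersect(targets, names(half_lives))]
  if (length(hl) < 2)
    stop("split_by_halflife needs at least 2 targets with half-life data")
  ord <- names(hl)[order(hl, names(hl))]
  n_short <- ceiling(length(ord) / 2)
  list(short = ord[seq_len(n_short)],
       long = ord[-seq_len(n_short)])
}

#' Sample random regulons for a null model
#'
#' Uniform samples without replacement from the gene universe minus an
#' exclusion list (typically the true regulon, so the null never contains a
#' genuine target).
#'
#' @param universe character vector of candidate genes.
#' @param exclude genes to remove from the universe before sampling.
#' @param size regulon size for each draw.
#' @param n number of regulons (the standard null uses 1000).
#' @param seed optional integer seed.
#' @return List of \code{n} character vectors of length \code{size}.
#' @export
random_regulons <- function(universe, exclude = character(), size,
                            n = 1000, seed = NULL) {
  pool <- setdiff(unique(universe), exclude)
  if (length(pool) < size)
    stop("universe minus exclusions (", length(pool),
         " genes) is smaller than the requested regulon size ", size)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) sample(pool, size))
}

#' Load a TSS table
#'
#' Accepts either a TSV with columns \code{gene}, \code{chrom},
#' \code{strand}, \code{tss} (0-based transcription start coordinate), or
#' a GTF file (via \pkg{rtracklayer}), from which the 5'-most annotated
#' start per \code{gene_id} is taken and converted to 0-based.
#'
#' @param path TSS TSV or GTF path.
#' @return data.frame with columns gene, chrom, strand, tss.
#' @export
load_tss_table <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes")
    d <- data.frame(gene = gr$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr))
    tss <- do.call(rbind, lapply(split(d, d$gene), function(g) {
      # 5'-most start; GTF is 1-based closed, output is 0-based
      pos <- if (g$strand[1] == "-") max(g$end) - 1 else min(g$start) - 1
      data.frame(gene = g$gene[1], chrom = g$chrom[1],
                 strand = g$strand[1], tss = pos)
    }))
    rownames(tss) <- NULL
    return(tss)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "strand", "tss")
  if (!all(req %in% names(tab)))
    stop("TSS table needs columns: ", paste(req, collapse = ", "))
  if (any(tab$tss < 0)) stop("TSS coordinates must be non-negative")
  if (anyDuplicated(tab$gene)) stop("TSS table has duplicate genes")
  tab[req]
}

#' Load ChIP peaks from a BED3 file
#'
#' @param path BED3 file (chrom, start, end; 0-based half-open).
#' @return data.frame with columns chrom, start, end.
#' @export
load_peaks_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns")
  tab <- stats::setNames(tab[, 1:3], c("chrom", "start", "end"))
  if (any(tab$start >= tab$end))
    stop("BED intervals must satisfy start < end")
  tab
}

#' Refine a target list by ChIP-peak proximity to the TSS
#'
#' Keeps targets whose TSS lies within \code{window} bp of a peak, i.e.
#' inside \code{[peak_start - window, peak_end + window)} (0-based
#' half-open, strand-agnostic) on the same chromosome. Targets without a
#' TSS entry are dropped with a warning.
#'
#' @param targets character vector of target gene ids.
#' @param tss TSS table (see \code{\link{load_tss_table}}).
#' @param peaks peak table (see \code{\link{load_peaks_bed}}).
#' @param window flank in bp (default 2000, the "TSS within +/- 2 kb" rule).
#' @return Character vector, a subset of \code{targets}.
#' @export
refine_by_peaks <- function(targets, tss, peaks, window = 2000) {
  if (window < 0) stop("window must be non-negative")
  idx <- match(targets, tss$gene)
  if (anyNA(idx)) {
    warning("no TSS for target(s), dropped: ",
            paste(targets[is.na(idx)], collapse = ", "))
    targets <- targets[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  if (length(targets) == 0 || nrow(peaks) == 0) return(character())
  # 0-based TSS t overlaps iff start - window <= t < end + window;
  # in 1-based closed coordinates: [start - window + 1, end + window].
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom[idx],
    IRanges::IRanges(start = tss$tss[idx] + 1, width = 1))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = pmax(peaks$start - window + 1, 1),
                     end = peaks$end + window))
  hit <- GenomicRanges::countOverlaps(tss_gr, peak_gr) > 0
  targets[hit]
}
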
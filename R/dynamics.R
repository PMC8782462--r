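#' Fixed-period cosinor rhythmicity test
#'
#' Fits \eqn{x(t) = m + a\cos(2\pi t/P) + b\sin(2\pi t/P)} by least squares
#' at a fixed period P (default 24 h) and tests \eqn{(a,b) = 0} with the
#' F-test on 2 and n-3 degrees of freedom. The amplitude is
#' \eqn{\sqrt{a^2+b^2}} and the phase is the fitted peak time
#' \eqn{P \cdot \mathrm{atan2}(b,a)/(2\pi)} mapped into [0, P).
#'
#' @param x numeric series.
#' @param times sampling times (h), same length as \code{x}; replicated
#'   time points are allowed.
#' @param period fixed period (h).
#' @return A list of class \code{rhythm_result}: \code{p_value},
#'   \code{amplitude}, \code{phase}, \code{period}, \code{mesor}. A
#'   constant series returns p = 1, amplitude 0 and phase NA with a
#'   warning.
#' @export
cosinor_test <- function(x, times, period = 24) {
  if (length(x) != length(times)) stop("x and times lengths differ")
  if (length(x) < 5) stop("cosinor_test needs at least 5 time points")
  if (diff(range(times)) < period / 2)
    stop("sampling must span at least half a period")
  res <- structure(list(p_value = NA_real_, amplitude = NA_real_,
                        phase = NA_real_, period = period,
                        mesor = mean(x)),
                   class = "rhythm_result")
  if (stats::sd(x) == 0) {
    warning("constant series: p = 1, amplitude 0")
    res$p_value <- 1
    res$amplitude <- 0
    return(res)
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  fit <- stats::lm.fit(X, x)
  a <- unname(fit$coefficients[2])
  b <- unname(fit$coefficients[3])
  rss <- sum(fit$residuals^2)
  tss <- sum((x - mean(x))^2)
  df2 <- length(x) - 3
  f <- ((tss - rss) / 2) / (rss / df2)
  res$p_value <- if (rss <= .Machine$double.eps * tss) 0 else
    stats::pf(f, 2, df2, lower.tail = FALSE)
  res$amplitude <- sqrt(a^2 + b^2)
  res$phase <- (atan2(b, a) / (2 * pi) * period) %% period
  res$mesor <- unname(fit$coefficients[1])
  res
}

#' Rhythmicity for every row of an activity matrix
#'
#' @param activity TFs x samples matrix.
#' @param times per-sample times (h).
#' @param period fixed period (h).
#' @return data.frame with one row per TF: p_value, amplitude, phase,
#'   period.
#' @export
rhythm_table <- function(activity, times, period = 24) {
  rows <- lapply(rownames(activity), function(tf) {
    r <- suppressWarnings(cosinor_test(activity[tf, ], times, period))
    data.frame(tf = tf, p_value = r$p_value, amplitude = r$amplitude,
               phase = r$phase, period = r$period)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a TF by which layer detects its rhythm
#'
#' Class 1: rhythmic in both intron- and exon-based activity; class 2:
#' intron only; class 3: exon only; none otherwise.
#'
#' @param intron,exon \code{rhythm_result} objects (or anything with a
#'   \code{p_value} element) for the same TF.
#' @param alpha significance threshold on the raw p-value.
#' @return One of \code{"class1"}, \code{"class2"}, \code{"class3"},
#'   \code{"none"}.
#' @export
classify_tf <- function(intron, exon, alpha = 0.05) {
  ri <- intron$p_value < alpha
  re <- exon$p_value < alpha
  if (ri && re) "class1" else if (ri) "class2" else if (re) "class3" else "none"
}

#' Signed circular phase difference (exon minus intron)
#'
#' Wraps \code{phase_exon - phase_intron} into (-period/2, period/2], so a
#' positive value means the exon-based activity lags behind (peaks after)
#' the intron-based activity.
#'
#' @param phase_exon,phase_intron peak phases in [0, period).
#' @param period period (h).
#' @return Signed offset(s) in (-period/2, period/2].
#' @export
phase_difference <- function(phase_exon, phase_intron, period = 24) {
  d <- (phase_exon - phase_intron) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Piecewise-linear resampling of a time series
#'
#' @param x series values.
#' @param times sampling times.
#' @param target_times times to resample at; must lie within
#'   [min(times), max(times)] (no extrapolation).
#' @return Values at \code{target_times}; original sample points are
#'   reproduced exactly.
#' @export
interpolate_linear <- function(x, times, target_times) {
  if (any(target_times < min(times)) || any(target_times > max(times)))
    stop("interpolate_linear does not extrapolate outside [",
         min(times), ", ", max(times), "]")
  stats::approx(times, x, xout = target_times, ties = mean)$y
}

#' Pearson correlation of two series on a shared interpolation grid
#'
#' Both series are linearly interpolated onto a shared grid (default: 0.5 h
#' spacing over the overlapping time range) before correlating; this
#' handles activity and surrogate measurements sampled at different times.
#'
#' @param activity,activity_times the activity series and its times.
#' @param surrogate,surrogate_times the surrogate series (e.g. measured TF
#'   DNA-binding or nuclear localisation) and its times.
#' @param grid_times explicit shared grid; overrides \code{by}.
#' @param by grid spacing (h) when \code{grid_times} is NULL.
#' @return List with \code{r}, \code{n} (grid points used) and
#'   \code{grid_times}.
#' @export
correlate_with_surrogate <- function(activity, activity_times,
                                     surrogate, surrogate_times,
                                     grid_times = NULL, by = 0.5) {
  if (is.null(grid_times)) {
    lo <- max(min(activity_times), min(surrogate_times))
    hi <- min(max(activity_times), max(surrogate_times))
    if (hi <= lo) stop("series do not overlap in time")
    grid_times <- seq(lo, hi, by = by)
  }
  if (length(grid_times) < 3)
    stop("need at least 3 shared grid points")
  a <- interpolate_linear(activity, activity_times, grid_times)
  s <- interpolate_linear(surrogate, surrogate_times, grid_times)
  list(r = stats::cor(a, s), n = length(grid_times),
       grid_times = grid_times)
}

#' Per-gene intron vs exon tracking of a TF activity surrogate
#'
#' For each high-expressing gene (mean intron CPM and mean exon CPM both
#' above \code{min_cpm}), correlates its intron-layer and exon-layer
#' expression with the surrogate series over the same samples. Genes whose
#' two correlations are both positive get the performance ratio
#' \code{r_intron / r_exon}, and that ratio is finally correlated with mRNA
#' half-life.
#'
#' @param intron_cpm,exon_cpm genes x samples matrices (same samples as
#'   \code{surrogate}).
#' @param surrogate per-sample surrogate series.
#' @param half_lives named half-life vector (min); genes without data are
#'   kept in the per-gene table but excluded from the association.
#' @param min_cpm high-expression threshold on the per-layer mean CPM.
#' @return List with \code{per_gene} (gene, r_intron, r_exon, ratio,
#'   half_life) and \code{association} (Pearson r, p, n of ratio vs
#'   half-life; NA when fewer than 3 genes qualify).
#' @export
per_gene_performance <- function(intron_cpm, exon_cpm, surrogate,
                                 half_lives = NULL, min_cpm = 1) {
  if (ncol(intron_cpm) < 3) stop("need at least 3 time points")
  hi <- rowMeans(intron_cpm) > min_cpm & rowMeans(exon_cpm) > min_cpm
  genes <- rownames(intron_cpm)[hi]
  if (length(genes) == 0) {
    warning("no gene passes the high-expression filter")
    return(list(per_gene = data.frame(), association = list(
      r = NA_real_, p = NA_real_, n = 0L)))
  }
  ri <- apply(intron_cpm[genes, , drop = FALSE], 1, stats::cor, y = surrogate)
  re <- apply(exon_cpm[genes, , drop = FALSE], 1, stats::cor, y = surrogate)
  ratio <- ifelse(ri > 0 & re > 0, ri / re, NA_real_)
  hl <- if (is.null(half_lives)) rep(NA_real_, length(genes)) else
    unname(half_lives[genes])
  per_gene <- data.frame(gene = genes, r_intron = ri, r_exon = re,
                         ratio = ratio, half_life = hl, row.names = NULL)
  ok <- is.finite(ratio) & is.finite(hl)
  if (sum(ok) >= 3) {
    ct <- stats::cor.test(ratio[ok], hl[ok])
    assoc <- list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  } else {
    if (!any(is.finite(ratio)))
      warning("no gene with double-positive correlations")
    assoc <- list(r = NA_real_, p = NA_real_, n = sum(ok))
  }
  list(per_gene = per_gene, association = assoc)
}

#' Robustness of a rhythm call to replicate composition
#'
#' Re-runs the cosinor test on replicate-averaged series over subsets of
#' the replicates (leave-one-out by default, or all proper subsets of size
#' >= 2) and reports the fraction of subsets in which the series is called
#' rhythmic.
#'
#' @param replicate_series replicates x times matrix of one TF's activity.
#' @param times per-column sampling times (h).
#' @param period fixed period (h).
#' @param alpha significance threshold.
#' @param subsets \code{"leave_one_out"} or \code{"all"}.
#' @return Fraction in [0, 1].
#' @export
replicate_robustness <- function(replicate_series, times, period = 24,
                                 alpha = 0.05,
                                 subsets = c("leave_one_out", "all")) {
  subsets <- match.arg(subsets)
  n_rep <- nrow(replicate_series)
  if (is.null(n_rep) || n_rep < 3)
    stop("replicate_robustness needs at least 3 replicates")
  sets <- if (subsets == "leave_one_out") {
    lapply(seq_len(n_rep), function(i) setdiff(seq_len(n_rep), i))
  } else {
    unlist(lapply(2:(n_rep - 1), function(k)
      utils::combn(n_rep, k, simplify = FALSE)), recursive = FALSE)
  }
  calls <- vapply(sets, function(idx) {
    avg <- colMeans(replicate_series[idx, , drop = FALSE])
    r <- suppressWarnings(cosinor_test(avg, times, period))
    r$p_value < alpha
  }, logical(1))
  mean(calls)
}

#' Partition TFs into co-varying modules by correlation clustering
#'
#' Computes pairwise Pearson correlation between TF activity series,
#' converts it to the distance 1 - r, builds an average-linkage
#' agglomerative tree and cuts it into k groups. Constant series are
#' excluded with a warning before clustering (their correlation is
#' undefined).
#'
#' @param activity TFs x samples matrix (>= 4 non-constant TFs, >= 3
#'   samples).
#' @param k number of modules (default 2).
#' @return List with \code{modules} (named integer vector of module
#'   labels) and \code{tree} (the \code{hclust} object).
#' @export
cluster_modules <- function(activity, k = 2) {
  if (ncol(activity) < 3) stop("cluster_modules needs at least 3 samples")
  keep <- apply(activity, 1, stats::sd) > 0
  if (any(!keep)) {
    warning("constant activity series excluded from clustering: ",
            paste(rownames(activity)[!keep], collapse = ", "))
    activity <- activity[keep, , drop = FALSE]
  }
  if (nrow(activity) < 4)
    stop("cluster_modules needs at least 4 non-constant TFs")
  d <- stats::as.dist(1 - stats::cor(t(activity)))
  tree <- stats::hclust(d, method = "average")
  modules <- stats::cutree(tree, k = k)
  list(modules = modules, tree = tree)
}

#' Association between phase differences and mean target intron length
#'
#' @param phase_diffs named vector of per-TF exon-minus-intron phase
#'   differences (h).
#' @param intron_lengths named vector of per-TF mean target intron length
#'   (bp); matched by TF name.
#' @return List with Pearson \code{r}, \code{p} and \code{n}.
#' @export
target_intron_length_association <- function(phase_diffs, intron_lengths) {
  tfs <- intersect(names(phase_diffs), names(intron_lengths))
  if (length(tfs) < 4) stop("need at least 4 TFs with both measures")
  ct <- stats::cor.test(phase_diffs[tfs], intron_lengths[tfs])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(tfs))
}
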
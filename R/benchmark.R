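# Pearson correlation of corresponding columns of two matrices; returns NA
# (with optional warning) for degenerate (zero-variance) columns rather than
# silently reporting 0.
col_cors <- function(a, b, warn = TRUE) {
  stopifnot(identical(dim(a), dim(b)))
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  va <- colSums(a^2)
  vb <- colSums(b^2)
  bad <- va == 0 | vb == 0
  r <- rep(NA_real_, ncol(a))
  r[!bad] <- colSums(a * b)[!bad] / sqrt(va[!bad] * vb[!bad])
  if (warn && any(bad))
    warning(sum(bad), " constant series: correlation reported as NA")
  r
}

#' Benchmark intron- vs exon-level TFA readouts on simulated cells
#'
#' Simulates one target gene per element of \code{half_lives} (kinetics
#' drawn by \code{\link{sample_gene_kinetics}}), all genes of a cell driven
#' by a shared TF realisation, and computes per-cell Pearson correlations of
#' each gene's unspliced (u) and spliced (s) levels with the cell's TF
#' input. The regulon-level readout averages u (or s) across genes at each
#' time before correlating, mirroring the mean-based TFA estimator. The
#' first waveform period is discarded as burn-in before correlating, so the
#' initial transient does not enter the oscillatory-regime comparison.
#'
#' @param half_lives numeric vector of target-gene mRNA half-lives (min);
#'   repeat values to average the kinetic-parameter draw within a half-life
#'   bin.
#' @param wf a \code{\link{waveform_params}} object.
#' @param grid a \code{\link{simulation_grid}} object.
#' @param n_cells number of simulated cells (stochastic mode).
#' @param mode \code{"stochastic"} (tau-leap, noisy TF) or
#'   \code{"deterministic"} (single noiseless ODE path per gene).
#' @param omega molecules per uM for the tau-leap.
#' @param detection_p optional capture efficiency; when given, u and s
#'   counts are binomially thinned before correlating (stochastic mode).
#' @param seed optional integer seed.
#'
#' @return A list with \code{per_gene} (gene-level correlation summaries),
#'   \code{by_halflife} (aggregated over genes sharing a half-life), and
#'   \code{regulon} (correlation of the across-gene mean of u and s with the
#'   TF input), plus the run settings.
#' @export
ensemble_benchmark <- function(half_lives, wf = waveform_params(),
                               grid = simulation_grid(),
                               n_cells = 100,
                               mode = c("stochastic", "deterministic"),
                               omega = 100, detection_p = NULL,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "stochastic" && n_cells < 2)
    stop("ensemble_benchmark needs n_cells >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(detection_p) && (detection_p < 0 || detection_p > 1))
    stop("detection_p must be in [0, 1]")
  keep <- grid$times > grid$t0 + wf$T  # burn-in: first period
  n_genes <- length(half_lives)
  kin <- lapply(half_lives, sample_gene_kinetics)

  if (mode == "deterministic") {
    tf_ref <- tf_waveform(wf, grid$times, noise = FALSE)[keep]
    um <- matrix(0, sum(keep), n_genes)
    sm <- matrix(0, sum(keep), n_genes)
    for (g in seq_len(n_genes)) {
      tr <- simulate_ode(kin[[g]], wf, grid)
      um[, g] <- tr$u[keep]
      sm[, g] <- tr$s[keep]
    }
    cu <- col_cors(um, matrix(tf_ref, sum(keep), n_genes))
    cs <- col_cors(sm, matrix(tf_ref, sum(keep), n_genes))
    per_gene <- data.frame(
      gene = seq_len(n_genes), half_life = half_lives,
      alpha = vapply(kin, `[[`, 0, "alpha"),
      Kd = vapply(kin, `[[`, 0, "Kd"),
      splicing_time = vapply(kin, `[[`, 0, "splicing_time"),
      corr_u = cu, corr_u_se = NA_real_,
      corr_s = cs, corr_s_se = NA_real_)
    reg <- data.frame(
      layer = c("unspliced", "spliced"),
      corr = c(stats::cor(rowMeans(um), tf_ref),
               stats::cor(rowMeans(sm), tf_ref)),
      se = NA_real_)
  } else {
    tfm <- tf_input_matrix(wf, grid, n_cells)
    tfb <- tfm[keep, , drop = FALSE]
    cu_cells <- matrix(NA_real_, n_cells, n_genes)
    cs_cells <- matrix(NA_real_, n_cells, n_genes)
    usum <- matrix(0, sum(keep), n_cells)
    ssum <- matrix(0, sum(keep), n_cells)
    for (g in seq_len(n_genes)) {
      sim <- simulate_tau_leap(kin[[g]], wf, grid, omega = omega,
                               n_cells = n_cells, tf_matrix = tfm)
      ug <- sim$u[keep, , drop = FALSE]
      sg <- sim$s[keep, , drop = FALSE]
      if (!is.null(detection_p)) {
        ug <- thin_detection(ug, detection_p)
        sg <- thin_detection(sg, detection_p)
      }
      cu_cells[, g] <- col_cors(ug, tfb, warn = FALSE)
      cs_cells[, g] <- col_cors(sg, tfb, warn = FALSE)
      usum <- usum + ug
      ssum <- ssum + sg
    }
    se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    per_gene <- data.frame(
      gene = seq_len(n_genes), half_life = half_lives,
      alpha = vapply(kin, `[[`, 0, "alpha"),
      Kd = vapply(kin, `[[`, 0, "Kd"),
      splicing_time = vapply(kin, `[[`, 0, "splicing_time"),
      corr_u = colMeans(cu_cells, na.rm = TRUE),
      corr_u_se = apply(cu_cells, 2, se),
      corr_s = colMeans(cs_cells, na.rm = TRUE),
      corr_s_se = apply(cs_cells, 2, se))
    ru <- col_cors(usum / n_genes, tfb, warn = FALSE)
    rs <- col_cors(ssum / n_genes, tfb, warn = FALSE)
    reg <- data.frame(
      layer = c("unspliced", "spliced"),
      corr = c(mean(ru, na.rm = TRUE), mean(rs, na.rm = TRUE)),
      se = c(se(ru), se(rs)))
  }
  by_hl <- do.call(rbind, lapply(split(per_gene, per_gene$half_life),
    function(d) data.frame(half_life = d$half_life[1],
                           corr_u = mean(d$corr_u, na.rm = TRUE),
                           corr_s = mean(d$corr_s, na.rm = TRUE),
                           n_genes = nrow(d))))
  by_hl <- by_hl[order(by_hl$half_life), ]
  rownames(by_hl) <- NULL
  list(per_gene = per_gene, by_halflife = by_hl, regulon = reg,
       mode = mode, n_cells = if (mode == "stochastic") n_cells else 1L,
       omega = omega, detection_p = detection_p, seed = seed)
}

#' Effect of capture efficiency on u/s correlation with TF activity
#'
#' Simulates one gene's stochastic trajectories once and applies nested
#' binomial thinning to realise a series of capture efficiencies: counts at
#' a lower p are obtained by further thinning the counts at the next higher
#' p (valid because thinning composes: Binom(Binom(x, p1), p2/p1) ~
#' Binom(x, p2)). The coupling removes between-level Monte-Carlo noise so
#' the degradation with falling p is measured on the same underlying cells.
#'
#' @param k a \code{\link{gene_kinetics}} object for the simulated gene.
#' @param p_values capture efficiencies in (0, 1].
#' @param wf,grid,omega,n_cells,seed as in \code{\link{ensemble_benchmark}}.
#' @return data.frame with one row per p: mean per-cell corr(u, TF),
#'   corr(s, TF), and their ratio, ordered by decreasing p.
#' @export
detection_sweep <- function(k, p_values, wf = waveform_params(),
                            grid = simulation_grid(), omega = 100,
                            n_cells = 50, seed = NULL) {
  if (any(p_values <= 0 | p_values > 1))
    stop("detection_sweep: p_values must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  keep <- grid$times > grid$t0 + wf$T
  sim <- simulate_tau_leap(k, wf, grid, omega = omega, n_cells = n_cells)
  tfb <- sim$tf[keep, , drop = FALSE]
  p_sorted <- sort(unique(p_values), decreasing = TRUE)
  ucur <- sim$u[keep, , drop = FALSE]
  scur <- sim$s[keep, , drop = FALSE]
  p_prev <- 1
  out <- lapply(p_sorted, function(p) {
    ucur <<- thin_detection(ucur, p / p_prev)
    scur <<- thin_detection(scur, p / p_prev)
    p_prev <<- p
    ru <- mean(col_cors(ucur, tfb, warn = FALSE), na.rm = TRUE)
    rs <- mean(col_cors(scur, tfb, warn = FALSE), na.rm = TRUE)
    data.frame(p = p, corr_u = ru, corr_s = rs, ratio = ru / rs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
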
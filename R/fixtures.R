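# Deterministic per-stage seed derivation from one top-level seed, kept
# within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

#' Configuration for the synthetic fixture generator
#'
#' Defines a planted-ground-truth dataset emulating a circadian bulk
#' RNA-seq design: TFs whose activity follows a basal-to-peak cosine over a
#' 24 h period (or stays flat), target genes whose unspliced/spliced
#' dynamics follow the transcription-splicing kinetics driven by their TF,
#' background genes at constant expression, and Poisson read counts at a
#' fixed sequencing depth. Defaults: 6 TFs (two modules of two rhythmic
#' TFs in antiphase at peak times 6 h and 18 h, plus two flat TFs), 8
#' targets per TF of which 2 are intronless, 40 background genes, samples
#' every 2 h from 0 to 22 h with 4 replicates, and target half-lives
#' log-normal around 300 min (typical of stable circadian-tissue mRNAs, and
#' long enough that exon-level dynamics lag visibly behind intron-level
#' dynamics).
#'
#' @param n_offtarget_genes number of constant background genes.
#' @param targets_per_tf targets per TF (including intronless ones).
#' @param intronless_per_tf how many of those targets lack introns.
#' @param times sampling times (h).
#' @param replicates biological replicates per time point.
#' @param period TF oscillation period (h).
#' @param tf_specs data.frame with columns \code{tf}, \code{rhythmic}
#'   (logical), \code{phase} (peak time, h) and \code{module}; NULL gives
#'   the default six-TF layout.
#' @param halflife_median,halflife_sdlog log-normal target half-life
#'   distribution (min).
#' @param depth expected library size (intron + exon reads) per sample.
#' @param detection_p capture efficiency applied to the counts (1 = none).
#' @param A_basal,A_max basal and peak TF activity (uM), as in
#'   \code{\link{waveform_params}}.
#' @param seed top-level seed; every stage derives its own stream from it.
#' @return A list of class \code{fixture_config}.
#' @export
fixture_config <- function(n_offtarget_genes = 40, targets_per_tf = 8,
                           intronless_per_tf = 2,
                           times = seq(0, 22, by = 2), replicates = 4,
                           period = 24, tf_specs = NULL,
                           halflife_median = 300, halflife_sdlog = 0.5,
                           depth = 2e6, detection_p = 1,
                           A_basal = 0.06, A_max = 0.5, seed = 1) {
  if (is.null(tf_specs))
    tf_specs <- data.frame(
      tf = paste0("TF", 1:6),
      rhythmic = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      phase = c(6, 6, 18, 18, NA, NA),
      module = c(1, 1, 2, 2, NA, NA))
  stopifnot(all(c("tf", "rhythmic", "phase") %in% names(tf_specs)))
  if (targets_per_tf <= intronless_per_tf)
    stop("need at least one intron-bearing target per TF")
  if (n_offtarget_genes < 0 || depth <= 0 || replicates < 1)
    stop("counts and depth must be positive")
  if (detection_p <= 0 || detection_p > 1)
    stop("detection_p must be in (0, 1]")
  structure(list(n_offtarget_genes = n_offtarget_genes,
                 targets_per_tf = targets_per_tf,
                 intronless_per_tf = intronless_per_tf,
                 times = times, replicates = replicates, period = period,
                 tf_specs = tf_specs, halflife_median = halflife_median,
                 halflife_sdlog = halflife_sdlog, depth = depth,
                 detection_p = detection_p,
                 A_basal = A_basal, A_max = A_max, seed = seed),
            class = "fixture_config")
}

# TF activity of one fixture TF at times t (noiseless): basal-to-peak
# cosine peaking at `phase`, or the midpoint level for flat TFs.
fixture_tf_activity <- function(cfg, spec, t) {
  if (isTRUE(spec$rhythmic)) {
    ph <- cos(2 * pi * (t - spec$phase) / cfg$period)
    cfg$A_basal * (1 - ph) / 2 + cfg$A_max * (1 + ph) / 2
  } else {
    rep((cfg$A_basal + cfg$A_max) / 2, length(t))
  }
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Per TF target, kinetics are drawn as in the simulator
#' (\code{\link{sample_gene_kinetics}}) with half-lives from the
#' configured log-normal; unspliced/spliced levels follow the ODE driven by
#' the TF's activity, integrated over one burn-in period before the first
#' sample so the oscillatory regime is reached. Background genes sit at the
#' steady state of a random constant TF level. Read counts are Poisson
#' around depth-scaled u (intron layer) and s (exon layer) — i.e. intronic
#' reads are taken as a proxy for unspliced mRNA — with optional binomial
#' thinning for capture efficiency. Intronless targets contribute exon
#' reads only. The regulon table carries the true activation edges (grades
#' A/B) plus decoy repression and C-grade edges to background genes, so
#' confidence filtering is exercised.
#'
#' @param cfg a \code{\link{fixture_config}}.
#' @param dir optional directory; when given, all tables are written there
#'   (counts.tsv, samples.tsv, regulons.tsv, halflife.tsv, tss.tsv,
#'   peaks.bed, surrogate.tsv, ground_truth.json).
#' @return List with \code{counts} (a \code{\link{count_matrix}} container),
#'   \code{regulons}, \code{half_lives}, \code{tss}, \code{peaks},
#'   \code{surrogate} (planted activity of the first rhythmic TF at the
#'   sample times), \code{truth} (per-TF and per-gene ground truth), and
#'   \code{paths} when \code{dir} was given.
#' @export
generate_fixture <- function(cfg = fixture_config(), dir = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(derive_seed(cfg$seed, "kinetics"))
  tfs <- cfg$tf_specs$tf
  genes <- list()
  truth_genes <- list()
  burn <- cfg$period  # one period of burn-in before the first sample
  tgrid <- seq(0, burn + max(cfg$times), by = 0.01)
  h <- 0.01
  at <- match(round(burn + cfg$times, 6), round(tgrid, 6))
  for (i in seq_along(tfs)) {
    spec <- cfg$tf_specs[i, ]
    hls <- stats::rlnorm(cfg$targets_per_tf, log(cfg$halflife_median),
                         cfg$halflife_sdlog)
    ks <- lapply(hls, sample_gene_kinetics)
    alpha <- vapply(ks, `[[`, 0, "alpha")
    Kd <- vapply(ks, `[[`, 0, "Kd")
    beta <- vapply(ks, `[[`, 0, "beta")
    gamma <- vapply(ks, `[[`, 0, "gamma")
    act <- fixture_tf_activity(cfg, spec, tgrid - burn)
    # Euler on a 0.01 h grid is ample: the stiffest rate (splicing,
    # ~28-55/h) gives per-step changes of a few percent
    ng <- cfg$targets_per_tf
    u <- matrix(0, length(tgrid), ng)
    s <- matrix(0, length(tgrid), ng)
    H1 <- act[1]^2 / (act[1]^2 + Kd^2)
    u[1, ] <- alpha * H1 / beta
    s[1, ] <- beta * u[1, ] / gamma
    for (m in seq_along(tgrid)[-1]) {
      Hm <- act[m - 1]^2 / (act[m - 1]^2 + Kd^2)
      u[m, ] <- u[m - 1, ] + h * (alpha * Hm - beta * u[m - 1, ])
      s[m, ] <- s[m - 1, ] + h * (beta * u[m - 1, ] - gamma * s[m - 1, ])
    }
    for (j in seq_len(ng)) {
      gene <- sprintf("%s_t%02d", spec$tf, j)
      genes[[gene]] <- list(u = u[at, j], s = s[at, j],
                            intronless = j > ng - cfg$intronless_per_tf)
      truth_genes[[gene]] <- data.frame(
        gene = gene, tf = spec$tf, half_life = hls[j],
        alpha = alpha[j], Kd = Kd[j],
        splicing_time = ks[[j]]$splicing_time,
        has_intron = !genes[[gene]]$intronless)
    }
  }
  if (cfg$n_offtarget_genes > 0) {
    for (j in seq_len(cfg$n_offtarget_genes)) {
      k <- sample_gene_kinetics(stats::rlnorm(1, log(cfg$halflife_median),
                                              cfg$halflife_sdlog))
      lvl <- stats::runif(1, cfg$A_basal, cfg$A_max)
      ss <- steady_state(k, lvl)
      gene <- sprintf("BG_%03d", j)
      genes[[gene]] <- list(u = rep(ss[["u"]], length(cfg$times)),
                            s = rep(ss[["s"]], length(cfg$times)),
                            intronless = stats::runif(1) < 0.2)
      truth_genes[[gene]] <- data.frame(
        gene = gene, tf = NA_character_, half_life = k$half_life,
        alpha = k$alpha, Kd = k$Kd, splicing_time = k$splicing_time,
        has_intron = !genes[[gene]]$intronless)
    }
  }
  gene_ids <- names(genes)
  n_t <- length(cfg$times)
  u_mat <- do.call(rbind, lapply(genes, `[[`, "u"))
  s_mat <- do.call(rbind, lapply(genes, `[[`, "s"))
  intronless <- vapply(genes, `[[`, logical(1), "intronless")
  u_mat[intronless, ] <- 0  # no intronic reads from intronless genes
  # Poisson counts with expected per-sample library size = depth
  lib_rate <- colSums(u_mat) + colSums(s_mat)
  scale <- cfg$depth / lib_rate
  sample_ids <- paste0("t", rep(cfg$times, each = cfg$replicates),
                       "_r", rep(seq_len(cfg$replicates), n_t))
  set.seed(derive_seed(cfg$seed, "counts"))
  draw <- function(rate_mat) {
    m <- matrix(0L, length(gene_ids), n_t * cfg$replicates,
                dimnames = list(gene_ids, sample_ids))
    for (ti in seq_len(n_t)) for (r in seq_len(cfg$replicates)) {
      col <- (ti - 1) * cfg$replicates + r
      m[, col] <- stats::rpois(length(gene_ids), rate_mat[, ti] * scale[ti])
    }
    if (cfg$detection_p < 1) m <- thin_detection(m, cfg$detection_p)
    m
  }
  counts <- count_matrix(draw(u_mat), draw(s_mat),
                         has_intron = !intronless,
                         time = rep(cfg$times, each = cfg$replicates),
                         replicate = rep(seq_len(cfg$replicates), n_t))
  # regulon table: true activation edges (A/B) + decoy edges
  set.seed(derive_seed(cfg$seed, "regulons"))
  truth_gene_tab <- do.call(rbind, truth_genes)
  reg_rows <- list()
  for (i in seq_along(tfs)) {
    tg <- truth_gene_tab$gene[truth_gene_tab$tf %in% tfs[i]]
    reg_rows[[length(reg_rows) + 1]] <- data.frame(
      tf = tfs[i], target = tg, mode = "activation",
      confidence = sample(c("A", "B"), length(tg), replace = TRUE))
    bg <- grep("^BG_", gene_ids, value = TRUE)
    if (length(bg) >= 2) {
      decoy <- sample(bg, 2)
      reg_rows[[length(reg_rows) + 1]] <- data.frame(
        tf = tfs[i], target = decoy,
        mode = c("repression", "activation"),
        confidence = c("B", "C"))
    }
  }
  regulons <- regulon_set(do.call(rbind, reg_rows))
  # half-life table (a random 10% of genes left unannotated)
  keep_hl <- stats::runif(nrow(truth_gene_tab)) > 0.1
  half_lives <- stats::setNames(truth_gene_tab$half_life,
                                truth_gene_tab$gene)[keep_hl]
  # synthetic annotation: TSS spaced along one chromosome; peaks at the
  # TSS of the first rhythmic TF's intron-bearing targets
  tss <- data.frame(gene = gene_ids, chrom = "chr1",
                    strand = rep(c("+", "-"), length.out = length(gene_ids)),
                    tss = seq_along(gene_ids) * 100000L)
  first_rhythmic <- tfs[which(cfg$tf_specs$rhythmic)[1]]
  peak_genes <- truth_gene_tab$gene[truth_gene_tab$tf %in% first_rhythmic &
                                      truth_gene_tab$has_intron]
  pk_tss <- tss$tss[match(peak_genes, tss$gene)]
  peaks <- data.frame(chrom = "chr1", start = pk_tss - 250L,
                      end = pk_tss + 250L)
  surrogate <- data.frame(
    time = cfg$times,
    value = fixture_tf_activity(cfg, cfg$tf_specs[
      match(first_rhythmic, tfs), ], cfg$times))
  truth <- list(tf = cfg$tf_specs, genes = truth_gene_tab,
                surrogate_tf = first_rhythmic, seed = cfg$seed)
  out <- list(counts = counts, regulons = regulons,
              half_lives = half_lives, tss = tss, peaks = peaks,
              surrogate = surrogate, truth = truth, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    write_count_table(counts, p("counts.tsv"))
    utils::write.table(
      data.frame(sample_id = colnames(counts),
                 time = rep(cfg$times, each = cfg$replicates),
                 replicate = rep(seq_len(cfg$replicates), n_t)),
      p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(regulons), p("regulons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = names(half_lives), half_life_min = half_lives),
      p("halflife.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tss, p("tss.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(peaks, p("peaks.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(surrogate, p("surrogate.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(tf = cfg$tf_specs, genes = truth_gene_tab,
                              surrogate_tf = first_rhythmic,
                              seed = cfg$seed),
                         p("ground_truth.json"), dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
    out$paths <- stats::setNames(
      vapply(c("counts.tsv", "samples.tsv", "regulons.tsv", "halflife.tsv",
               "tss.tsv", "peaks.bed", "surrogate.tsv",
               "ground_truth.json"), p, ""),
      c("counts", "samples", "regulons", "halflife", "tss", "peaks",
        "surrogate", "ground_truth"))
  }
  out
}
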
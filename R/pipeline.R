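write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full TFA pipeline on a dataset
#'
#' Executes quantification (shared-denominator CPM on intron, exon and
#' total layers, replicate averaging by time), regulon filtering, mean
#' TFA estimation per layer, fixed-period cosinor rhythmicity with TF
#' classification and exon-minus-intron phase differences, optional
#' surrogate correlation, and TF module clustering on the intron-layer
#' activities. Any stage failure aborts with the stage name.
#'
#' @param config a list or the path of a YAML file with entries:
#'   \code{counts} (counts TSV path), \code{sample_info} (optional),
#'   \code{regulons} (regulon TSV), \code{surrogate} (optional TSV with
#'   columns time, value), and optional settings \code{max_grade} ("B"),
#'   \code{period} (24), \code{alpha} (0.05), \code{k_modules} (2),
#'   \code{top_fraction} (0.05).
#' @param out_dir optional output directory; when given, writes
#'   activity_<layer>.tsv, rhythm.tsv, correlations.tsv, modules.tsv and
#'   report.json.
#' @return A list with the per-layer activity matrices, the rhythm/class
#'   table, surrogate correlations (or NULL), the module partition and the
#'   settings used.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(max_grade = "B", period = 24, alpha = 0.05,
                   k_modules = 2, sample_info = NULL, surrogate = NULL)
  config <- utils::modifyList(defaults, config)
  for (f in c("counts", "regulons")) {
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])
  }

  counts <- run_stage("quantify",
    read_count_table(config$counts, config$sample_info))
  layers <- run_stage("quantify", {
    l <- list(intron = cpm(counts, "intron"), exon = cpm(counts, "exon"),
              total = total_cpm(counts))
    cd <- SummarizedExperiment::colData(counts)
    if (!is.null(cd$time)) {
      l <- lapply(l, average_replicates, groups = cd$time)
      attr(l, "times") <- unique(cd$time)
    } else attr(l, "times") <- seq_len(ncol(counts))
    l
  })
  times <- attr(layers, "times")

  regulons <- run_stage("regulons", load_regulons(config$regulons))
  tf_list <- sort(unique(regulons$tf))
  if (any(tf_list %in% rownames(counts)))
    tf_list <- run_stage("regulons",
      expressed_tf_filter(layers$intron, layers$exon,
                          tf_list[tf_list %in% rownames(counts)]))

  hi <- has_intron(counts)
  activity <- run_stage("tfa", lapply(layers, function(m)
    suppressWarnings(
      tfa_matrix(m, regulons, gene_has_intron = hi,
                 max_grade = config$max_grade))))

  rhythm <- run_stage("rhythm", {
    ri <- rhythm_table(activity$intron, times, config$period)
    re <- rhythm_table(activity$exon, times, config$period)
    tfs <- intersect(ri$tf, re$tf)
    ii <- match(tfs, ri$tf)
    ie <- match(tfs, re$tf)
    data.frame(
      tf = tfs,
      p_intron = ri$p_value[ii], p_exon = re$p_value[ie],
      amplitude_intron = ri$amplitude[ii], amplitude_exon = re$amplitude[ie],
      phase_intron = ri$phase[ii], phase_exon = re$phase[ie],
      class = mapply(function(pi, pe)
        classify_tf(list(p_value = pi), list(p_value = pe), config$alpha),
        ri$p_value[ii], re$p_value[ie]),
      phase_diff = phase_difference(re$phase[ie], ri$phase[ii],
                                    config$period))
  })

  correlations <- NULL
  if (!is.null(config$surrogate)) {
    correlations <- run_stage("correlate", {
      surr <- utils::read.delim(config$surrogate)
      do.call(rbind, lapply(rownames(activity$intron), function(tf) {
        ci <- correlate_with_surrogate(activity$intron[tf, ], times,
                                       surr$value, surr$time)
        ce <- correlate_with_surrogate(activity$exon[tf, ], times,
                                       surr$value, surr$time)
        data.frame(tf = tf, r_intron = ci$r, r_exon = ce$r, n = ci$n)
      }))
    })
  }

  modules <- run_stage("cluster",
    if (nrow(activity$intron) >= 4)
      cluster_modules(activity$intron, k = config$k_modules) else NULL)

  result <- list(activity = activity, rhythm = rhythm,
                 correlations = correlations, modules = modules,
                 times = times, settings = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (layer in names(activity))
      write_tsv(data.frame(tf = rownames(activity[[layer]]),
                           activity[[layer]], check.names = FALSE),
                file.path(out_dir, paste0("activity_", layer, ".tsv")))
    write_tsv(rhythm, file.path(out_dir, "rhythm.tsv"))
    if (!is.null(correlations))
      write_tsv(correlations, file.path(out_dir, "correlations.tsv"))
    if (!is.null(modules))
      write_tsv(data.frame(tf = names(modules$modules),
                           module = modules$modules),
                file.path(out_dir, "modules.tsv"))
    jsonlite::write_json(
      list(settings = config[!vapply(config, is.null, TRUE)],
           n_genes = nrow(counts), n_samples = ncol(counts),
           n_tfs = nrow(rhythm),
           r_version = as.character(getRversion())),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}
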
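#' Per-gene transcription/splicing kinetic parameters
#'
#' Bundles the kinetic constants of one TF target gene. The splicing and
#' degradation rates are tied to the measurable time scales: splicing is
#' treated as exponential with 90% completion within the splicing time,
#' so \code{beta = log(10)/splicing_time}, and \code{gamma =
#' log(2)/half_life}. Both times are given in minutes; rates are per hour.
#'
#' @param alpha maximal transcription rate (1/h).
#' @param n Hill coefficient (>= 1).
#' @param Kd dissociation constant of the TF input function (uM).
#' @param half_life mRNA half-life (min).
#' @param splicing_time time for 90% of unspliced mRNA to be spliced (min).
#'
#' @return An object of class \code{gene_kinetics} with derived fields
#'   \code{beta} and \code{gamma} (1/h).
#' @export
gene_kinetics <- function(alpha, n = 2, Kd, half_life, splicing_time) {
  vals <- c(alpha = alpha, Kd = Kd, half_life = half_life,
            splicing_time = splicing_time)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("gene_kinetics: alpha, Kd, half_life and splicing_time must be positive")
  if (n < 1) stop("gene_kinetics: Hill coefficient n must be >= 1")
  structure(list(alpha = alpha, n = n, Kd = Kd,
                 half_life = half_life, splicing_time = splicing_time,
                 beta = log(10) / (splicing_time / 60),
                 gamma = log(2) / (half_life / 60)),
            class = "gene_kinetics")
}

#' Sample kinetic parameters for a target gene
#'
#' Draws parameters from the ranges used for the p53 in-silico study:
#' alpha ~ U(100, 200) per hour, Kd ~ U(0.05, 0.25) uM, splicing time
#' ~ U(5, 10) min, Hill coefficient fixed at 2. The half-life is supplied by
#' the caller (typically from a measured catalogue or the log-normal
#' surrogate in \code{\link{sample_half_lives}}).
#'
#' @param half_life mRNA half-life (min), positive scalar.
#' @return A \code{\link{gene_kinetics}} object. Uses the current RNG state.
#' @export
sample_gene_kinetics <- function(half_life) {
  if (!is.numeric(half_life) || length(half_life) != 1 || half_life <= 0)
    stop("sample_gene_kinetics: half_life must be a positive scalar")
  gene_kinetics(alpha = stats::runif(1, 100, 200),
                n = 2,
                Kd = stats::runif(1, 0.05, 0.25),
                half_life = half_life,
                splicing_time = stats::runif(1, 5, 10))
}

#' Log-normal surrogate for an mRNA half-life catalogue
#'
#' Experimental half-life catalogues are roughly log-normal; this surrogate
#' (median 100 min, sdlog 1) stands in when no measured table is supplied.
#'
#' @param n number of genes.
#' @param median_min median half-life (min).
#' @param sdlog log-scale standard deviation.
#' @return Numeric vector of half-lives (min).
#' @export
sample_half_lives <- function(n, median_min = 100, sdlog = 1) {
  stats::rlnorm(n, meanlog = log(median_min), sdlog = sdlog)
}

hill <- function(tf, k) {
  tfn <- tf^k$n
  tfn / (tfn + k$Kd^k$n)
}

#' Steady state of the transcription/splicing system
#'
#' For constant TF level, \code{u* = alpha * Hill(TF) / beta} and
#' \code{s* = beta * u* / gamma}.
#'
#' @param k a \code{\link{gene_kinetics}} object.
#' @param tf constant TF concentration (uM), non-negative.
#' @return Named numeric vector \code{c(u = ..., s = ...)}.
#' @export
steady_state <- function(k, tf) {
  stopifnot(inherits(k, "gene_kinetics"))
  if (any(tf < 0)) stop("steady_state: tf must be non-negative")
  u <- k$alpha * hill(tf, k) / k$beta
  c(u = u, s = k$beta * u / k$gamma)
}
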
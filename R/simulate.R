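#' Deterministic simulation of unspliced/spliced mRNA dynamics
#'
#' Integrates
#' \deqn{du/dt = \alpha \, TF^n / (TF^n + K_d^n) - \beta u, \qquad
#'       ds/dt = \beta u - \gamma s}
#' with the noiseless TF waveform as input, starting from the non-zero
#' steady state at the basal TF level. Integration uses an adaptive
#' stiff-capable solver (\code{deSolve::lsoda}, rtol 1e-8) and the solution
#' is reported on the grid times.
#'
#' @param k a \code{\link{gene_kinetics}} object.
#' @param wf a \code{\link{waveform_params}} object (noise is ignored; the
#'   deterministic path always uses the noiseless waveform).
#' @param grid a \code{\link{simulation_grid}} object.
#' @param rtol,atol solver tolerances.
#'
#' @return A \code{trajectory} list with \code{times}, \code{u}, \code{s}
#'   and \code{tf} (the noiseless input waveform), all of equal length.
#' @export
simulate_ode <- function(k, wf, grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(k, "gene_kinetics"), inherits(wf, "tf_waveform_params"),
            inherits(grid, "simulation_grid"))
  y0 <- steady_state(k, wf$A_basal)
  rhs <- function(t, y, parms) {
    tf <- tf_waveform(wf, t, noise = FALSE)
    du <- k$alpha * hill(tf, k) - k$beta * y[1]
    ds <- k$beta * y[1] - k$gamma * y[2]
    list(c(du, ds))
  }
  sol <- deSolve::lsoda(y = unname(y0), times = grid$times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf(paste0("ODE integration failed (alpha=%g, beta=%g, ",
                        "gamma=%g, Kd=%g)"), k$alpha, k$beta, k$gamma, k$Kd))
  structure(list(times = sol[, 1], u = sol[, 2], s = sol[, 3],
                 tf = tf_waveform(wf, sol[, 1], noise = FALSE)),
            class = "trajectory")
}

#' Stochastic tau-leap simulation of transcription and splicing
#'
#' Propagates integer molecule counts of unspliced (u) and spliced (s) mRNA
#' with Poisson-distributed event counts per reaction per step: production
#' \code{alpha * Hill(TF) * omega * dt}, splicing \code{beta * u * dt}, and
#' degradation \code{gamma * s * dt}. Concentrations are converted to counts
#' by the scale factor \code{omega} (molecules per uM). Initial counts are
#' the rounded steady state at the basal TF level. The TF input is evaluated
#' per step, with fresh Gaussian noise per cell when the waveform has noise
#' enabled (negative excursions clipped at zero). Multiple cells are
#' propagated in parallel (vectorised over cells).
#'
#' @param k a \code{\link{gene_kinetics}} object.
#' @param wf a \code{\link{waveform_params}} object.
#' @param grid a \code{\link{simulation_grid}} object.
#' @param omega molecules per concentration unit (must be positive).
#' @param n_cells number of independent cells.
#' @param tf_matrix optional precomputed TF input, a
#'   \code{length(grid$times) x n_cells} matrix. Use this to drive several
#'   genes of the same cell with a shared TF realisation.
#' @param warn_leap warn when the expected number of events in one step
#'   exceeds 10% of the current molecule count (tau-leap accuracy guard).
#'
#' @return A \code{cell_ensemble} list: \code{times} (length m), matrices
#'   \code{u}, \code{s}, \code{tf} of dimension m x n_cells (integer counts
#'   for u and s), and the \code{kinetics} used. Reproducible under a fixed
#'   RNG seed set by the caller.
#' @export
simulate_tau_leap <- function(k, wf, grid, omega = 100, n_cells = 1,
                              tf_matrix = NULL, warn_leap = TRUE) {
  stopifnot(inherits(k, "gene_kinetics"), inherits(wf, "tf_waveform_params"),
            inherits(grid, "simulation_grid"))
  if (!is.numeric(omega) || omega <= 0) stop("omega must be positive")
  nt <- length(grid$times)
  if (!is.null(tf_matrix)) {
    if (!is.matrix(tf_matrix) || nrow(tf_matrix) != nt ||
        ncol(tf_matrix) != n_cells)
      stop("tf_matrix must be a length(grid$times) x n_cells matrix")
  }
  dt <- grid$dt
  y0 <- round(omega * steady_state(k, wf$A_basal))
  u <- matrix(0L, nt, n_cells)
  s <- matrix(0L, nt, n_cells)
  tfm <- if (is.null(tf_matrix)) matrix(0, nt, n_cells) else tf_matrix
  u[1, ] <- y0[["u"]]
  s[1, ] <- y0[["s"]]
  if (is.null(tf_matrix))
    tfm[1, ] <- tf_waveform(wf, rep(grid$times[1], n_cells))
  ucur <- u[1, ]
  scur <- s[1, ]
  warned <- FALSE
  for (i in seq_len(nt - 1)) {
    tf_i <- if (is.null(tf_matrix))
      tf_waveform(wf, rep(grid$times[i], n_cells)) else tfm[i, ]
    if (is.null(tf_matrix)) tfm[i, ] <- tf_i
    lam_prod <- k$alpha * hill(tf_i, k) * omega * dt
    lam_spl <- k$beta * ucur * dt
    lam_deg <- k$gamma * scur * dt
    if (warn_leap && !warned &&
        (any(lam_spl > 0.1 * pmax(ucur, 1)) ||
         any(lam_deg > 0.1 * pmax(scur, 1)))) {
      warning("tau-leap step too coarse: expected events per step exceed ",
              "10% of current molecule count; reduce dt")
      warned <- TRUE
    }
    n_prod <- stats::rpois(n_cells, lam_prod)
    n_spl <- stats::rpois(n_cells, lam_spl)
    n_deg <- stats::rpois(n_cells, lam_deg)
    ucur <- pmax(ucur + n_prod - n_spl, 0L)
    scur <- pmax(scur + n_spl - n_deg, 0L)
    u[i + 1, ] <- ucur
    s[i + 1, ] <- scur
  }
  if (is.null(tf_matrix))
    tfm[nt, ] <- tf_waveform(wf, rep(grid$times[nt], n_cells))
  structure(list(times = grid$times, u = u, s = s, tf = tfm, kinetics = k,
                 omega = omega),
            class = "cell_ensemble")
}

#' Generate a shared TF input matrix for an ensemble of cells
#'
#' One TF realisation per cell on the grid times, so that several target
#' genes of the same cell can be driven by an identical input.
#'
#' @inheritParams simulate_tau_leap
#' @return A \code{length(grid$times) x n_cells} matrix.
#' @export
tf_input_matrix <- function(wf, grid, n_cells) {
  nt <- length(grid$times)
  base <- tf_waveform(wf, grid$times, noise = FALSE)
  m <- matrix(base, nt, n_cells)
  if (wf$noise_enabled && wf$sigma > 0)
    m <- pmax(m + matrix(stats::rnorm(nt * n_cells, 0, wf$sigma), nt, n_cells), 0)
  m
}

#' Binomial thinning of molecule counts (capture efficiency)
#'
#' Models incomplete mRNA capture/detection: each molecule is observed
#' independently with probability \code{p}, so a count \code{x} becomes a
#' Binomial(x, p) draw.
#'
#' @param counts vector or matrix of non-negative integer counts.
#' @param p capture (detection) efficiency in [0, 1].
#' @return Thinned counts with the same shape as the input.
#' @export
thin_detection <- function(counts, p) {
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1)
    stop("thin_detection: p must be a single probability in [0, 1]")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("thin_detection: counts must be non-negative integers")
  out <- stats::rbinom(length(counts), as.integer(round(counts)), p)
  if (is.matrix(counts)) dim(out) <- dim(counts)
  dimnames(out) <- dimnames(counts)
  out
}
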
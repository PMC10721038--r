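#' Simulate a circadian expression dataset with known rhythm parameters
#'
#' Generates a log-scale expression matrix in which each gene follows
#' `mesor + (A / 2) * waveform(theta - phase)` with a unit waveform of range
#' exactly `[-1, 1]`, so the true peak-to-trough amplitude equals `A`.
#' Waveforms: `"sinusoid"` (cosine), `"peaked"` (von-Mises-shaped bump,
#' concentration `kappa`), `"square"` (clipped, steepened sinusoid). Gaussian
#' noise is added with an optional mean-variance coupling in which dimmer
#' genes (lower mesor) are noisier, mimicking log-scale RNA-seq variance. In
#' count mode the expected log2-CPM matrix is mapped to negative-binomial
#' counts at a given library size.
#'
#' The default design mirrors a dense circadian course: 24 samples at 2-h
#' intervals over 48 h (two replicates per unique time modulo 24 h).
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (default 24).
#' @param interval_h Sampling interval in hours (default 2).
#' @param period Period tau (default 24).
#' @param frac_rhythmic Fraction of rhythmic genes in `[0, 1]` (default 0.5).
#' @param amp_meanlog,amp_sdlog Log-normal parameters of the rhythmic genes'
#'   peak-to-trough amplitudes in log2 units (default median 1, sdlog 0.7).
#' @param amplitudes,phases Optional explicit per-gene amplitude / phase
#'   vectors overriding the random draws (amplitudes of arrhythmic genes are
#'   forced to 0).
#' @param mesor_mean,mesor_sd Normal parameters of gene mesors (log2 units).
#' @param noise_sd Baseline residual SD in log2 units (default 0.3).
#' @param noise_coupling Strength of the mean-variance coupling (default 1):
#'   per-gene SD is `noise_sd * (1 + coupling * exp(-(mesor - min_mesor)/2))`.
#' @param waveforms Candidate waveform shapes sampled per gene.
#' @param kappa Concentration of the peaked waveform (default 2).
#' @param counts If `TRUE` return negative-binomial counts (`is_counts`
#'   experiment) instead of log-scale values.
#' @param lib_size Count-mode library size (default 1e7).
#' @param dispersion Count-mode negative-binomial dispersion (default 0.05).
#' @param seed Optional seed; fixed seed gives identical output.
#' @return List with `experiment` (a [rhythm_experiment()]) and `truth`, a
#'   data.frame of per-gene `mesor`, `amplitude` (true peak-to-trough),
#'   `phase` (peak phase, hours), `waveform`, `noise_sd`, `rhythmic`.
#' @examples
#' sim <- simulate_rhythm_data(n_genes = 20, seed = 1)
#' sim$truth[1:3, ]
#' @export
simulate_rhythm_data <- function(n_genes = 1000, n_samples = 24,
                                 interval_h = 2, period = 24,
                                 frac_rhythmic = 0.5,
                                 amp_meanlog = 0, amp_sdlog = 0.7,
                                 amplitudes = NULL, phases = NULL,
                                 mesor_mean = 6, mesor_sd = 2,
                                 noise_sd = 0.3, noise_coupling = 1,
                                 waveforms = c("sinusoid", "peaked", "square"),
                                 kappa = 2, counts = FALSE, lib_size = 1e7,
                                 dispersion = 0.05, seed = NULL) {
  if (!(frac_rhythmic >= 0 && frac_rhythmic <= 1))
    stop("'frac_rhythmic' must be in [0, 1]")
  if (n_samples < 8) stop("'n_samples' must be >= 8")
  if (!is.null(seed)) set.seed(seed)
  time <- (seq_len(n_samples) - 1) * interval_h
  n_rhy <- round(frac_rhythmic * n_genes)
  rhythmic <- c(rep(TRUE, n_rhy), rep(FALSE, n_genes - n_rhy))
  mesor <- stats::rnorm(n_genes, mesor_mean, mesor_sd)
  A <- if (is.null(amplitudes)) stats::rlnorm(n_genes, amp_meanlog, amp_sdlog)
       else rep_len(amplitudes, n_genes)
  A[!rhythmic] <- 0
  phase <- if (is.null(phases)) stats::runif(n_genes, 0, period)
           else rep_len(phases, n_genes) %% period
  shape <- sample(waveforms, n_genes, replace = TRUE)
  sd_g <- noise_sd * (1 + noise_coupling * exp(-(mesor - min(mesor)) / 2))

  unit_wave <- function(shape, theta) {
    switch(shape,
      sinusoid = cos(theta),
      peaked = {
        v <- exp(kappa * (cos(theta) - 1))
        lo <- exp(-2 * kappa)
        2 * (v - lo) / (1 - lo) - 1
      },
      square = pmax(-1, pmin(1, 2 * cos(theta))),
      stop("unknown waveform: ", shape))
  }

  theta <- 2 * pi * time / period
  expected <- matrix(0, n_genes, n_samples)
  for (g in seq_len(n_genes)) {
    w <- if (rhythmic[g] && A[g] > 0)
      unit_wave(shape[g], theta - 2 * pi * phase[g] / period) else 0
    expected[g, ] <- mesor[g] + (A[g] / 2) * w
  }

  if (counts) {
    cpm <- 2^expected
    cpm <- sweep(cpm, 2, colSums(cpm), "/") * 1e6
    mu <- cpm / 1e6 * lib_size
    y <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = n_genes)
  } else {
    y <- expected + matrix(stats::rnorm(n_genes * n_samples), n_genes) * sd_g
  }
  rownames(y) <- sprintf("gene_%04d", seq_len(n_genes))
  colnames(y) <- sprintf("sample_%02d", seq_len(n_samples))
  truth <- data.frame(feature_id = rownames(y), mesor = mesor, amplitude = A,
                      phase = ifelse(rhythmic, phase, NA_real_),
                      waveform = ifelse(rhythmic, shape, NA_character_),
                      noise_sd = sd_g, rhythmic = rhythmic)
  list(experiment = rhythm_experiment(y, time = time, period = period,
                                      is_counts = counts),
       truth = truth)
}
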
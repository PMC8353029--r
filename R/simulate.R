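#' Parameters of the batch-culture simulator
#'
#' Defaults reproduce the study conditions of the modelled experiment:
#' 0.04 g L^-1 inoculum of starved (PHB-free) cells in 25 mM succinate,
#' a lag of about 4 h, growth at 0.232 h^-1 with yield 48.4 g-DW mol^-1,
#' an instantaneous PHB burst to 78 mg g^-1 at the 0.5 h sample followed by
#' a constant content of about 7% of dry weight, duplicate measurements with
#' Gaussian noise of the magnitude printed in the experimental table
#' (relative on dry weight and PHB content, absolute on succinate).
#'
#' @param x0 Inoculum dry weight, g L^-1.
#' @param mu Specific growth rate, h^-1.
#' @param yield_xs Biomass yield on succinate, g-DW mol^-1.
#' @param s0 Initial succinate, mM.
#' @param lag Lag before exponential growth, h (hard offset).
#' @param phb_content PHB content during growth, mg per g dry weight.
#' @param accumulation_content Content reached by the zero-growth burst at
#'   0.5 h, mg per g dry weight.
#' @param noise_sd List with `dry_weight_rel`, `phb_rel` (relative sd) and
#'   `succinate_abs` (absolute sd, mM).
#' @param n_replicates Replicate measurements per time point.
#' @param seed Integer seed; identical seed gives identical output.
#' @return An object of class `"phb_culture_params"`.
#' @export
culture_params <- function(x0 = 0.04, mu = 0.232, yield_xs = 48.4, s0 = 25,
                           lag = 4, phb_content = 70,
                           accumulation_content = 78,
                           noise_sd = list(dry_weight_rel = 0.08,
                                           phb_rel = 0.09,
                                           succinate_abs = 0.5),
                           n_replicates = 2, seed = 1L) {
  stopifnot(x0 > 0, mu >= 0, yield_xs > 0, s0 > 0, lag >= 0,
            phb_content >= 0, accumulation_content >= 0, n_replicates >= 1)
  if (s0 / 1000 * yield_xs < x0) # not enough substrate for one doubling
    stop("s0 too small to support growth at the given yield")
  structure(list(x0 = x0, mu = mu, yield_xs = yield_xs, s0 = s0, lag = lag,
                 phb_content = phb_content,
                 accumulation_content = accumulation_content,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "phb_culture_params")
}

# deterministic truth: biomass flat through the lag, then exponential until
# substrate exhaustion; succinate coupled through the yield; PHB content 0 at
# t = 0 and at the burst level from 0.5 h on
culture_truth <- function(params, t) {
  exhaust_x <- params$x0 + params$s0 / 1000 * params$yield_xs
  t_exhaust <- if (params$mu > 0)
    params$lag + log(exhaust_x / params$x0) / params$mu else Inf
  x <- ifelse(t <= params$lag, params$x0,
              params$x0 * exp(params$mu * (pmin(t, t_exhaust) - params$lag)))
  s <- pmax(params$s0 - 1000 * (x - params$x0) / params$yield_xs, 0)
  phb <- ifelse(t <= 0, 0,
                ifelse(t < 0.5, params$accumulation_content * t / 0.5,
                       ifelse(t <= params$lag, params$accumulation_content,
                              params$phb_content)))
  list(dry_weight = x, succinate = s, phb_content = phb,
       t_exhaust = t_exhaust)
}

#' Simulate a batch-culture time series
#'
#' Generates replicate measurements around the deterministic truth of
#' [culture_params()] (exponential growth with a hard lag, substrate-biomass
#' coupling through the yield, an instantaneous PHB accumulation burst) with
#' Gaussian noise, and returns per-time-point means and standard deviations
#' in the same layout the kinetics functions consume.
#'
#' @param params A [culture_params()].
#' @param sample_times Increasing sampling times, h.
#' @return A `"phb_timeseries"` with `*_sd` columns.
#' @export
simulate_batch <- function(params, sample_times = c(0, 0.5, 2, 4, 7, 10, 12, 14, 16)) {
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("sample_times must be strictly increasing")
  truth <- culture_truth(params, sample_times)
  if (any(sample_times > truth$t_exhaust))
    warning("sample times beyond substrate exhaustion (",
            format(truth$t_exhaust, digits = 4),
            " h); values held at the exhaustion state", call. = FALSE)
  n <- length(sample_times); k <- params$n_replicates
  withr::with_seed(params$seed, {
    dw <- truth$dry_weight *
      matrix(1 + stats::rnorm(n * k, 0, params$noise_sd$dry_weight_rel), n, k)
    phb <- truth$phb_content *
      matrix(1 + stats::rnorm(n * k, 0, params$noise_sd$phb_rel), n, k)
    suc <- truth$succinate +
      matrix(stats::rnorm(n * k, 0, params$noise_sd$succinate_abs), n, k)
  })
  dw <- pmax(dw, 1e-6); phb <- pmax(phb, 0); suc <- pmax(suc, 0)
  sd_or_0 <- function(m) if (k > 1) apply(m, 1, stats::sd) else rep(0, n)
  df <- data.frame(time = sample_times,
                   dry_weight = rowMeans(dw), dry_weight_sd = sd_or_0(dw),
                   phb_content = rowMeans(phb), phb_content_sd = sd_or_0(phb),
                   succinate = rowMeans(suc), succinate_sd = sd_or_0(suc))
  # noise cannot defeat monotone time: sort-safety only, times already strict
  batch_timeseries(df)
}

#' Write a simulated series in the CSV dialect the kinetics reader consumes
#'
#' @param series A `"phb_timeseries"`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_batch_timeseries <- function(series, path) {
  out <- data.frame(time_h = series$time,
                    dry_weight_g_per_L = series$dry_weight,
                    phb_mg_per_g = series$phb_content,
                    succinate_mM = series$succinate)
  for (col in c("dry_weight", "phb_content", "succinate")) {
    sdc <- paste0(col, "_sd")
    if (sdc %in% names(series))
      out[[paste0(c(dry_weight = "dry_weight_g_per_L",
                    phb_content = "phb_mg_per_g",
                    succinate = "succinate_mM")[[col]], "_sd")]] <- series[[sdc]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parameter-recovery experiment
#'
#' Simulates many datasets, refits the growth rate and yield on each, and
#' reports bias, RMSE and 95% confidence-interval coverage against the
#' generating values.
#'
#' @param params A [culture_params()]; its `seed` seeds the whole experiment.
#' @param n_datasets Number of simulated datasets (>= 1).
#' @param sample_times Sampling grid passed to [simulate_batch()].
#' @param window Growth-window rule passed to [fit_growth_rate()].
#' @return List with per-parameter `bias`, `relative_bias`, `rmse` and
#'   `coverage` (NA, flagged, when `n_datasets` < 2) for `mu` and `yield_xs`.
#' @export
recovery_experiment <- function(params, n_datasets,
                                sample_times = c(0, 0.5, 2, 4, 7, 10, 12, 14, 16),
                                window = "auto") {
  stopifnot(n_datasets >= 1)
  seeds <- params$seed + seq_len(n_datasets) - 1L
  mu_hat <- mu_se <- y_hat <- y_se <- mu_df <- y_df <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    p <- params; p$seed <- seeds[i]
    sim <- simulate_batch(p, sample_times)
    g <- fit_growth_rate(sim, window)
    y <- fit_yield(sim)
    mu_hat[i] <- g$mu; mu_se[i] <- g$se; mu_df[i] <- length(g$window) - 2
    y_hat[i] <- y$yield_xs; y_se[i] <- y$se; y_df[i] <- nrow(sim) - 2
  }
  cover <- function(hat, se, truth, df) {
    if (n_datasets < 2) return(NA_real_)
    tcrit <- stats::qt(0.975, df)
    mean(truth >= hat - tcrit * se & truth <= hat + tcrit * se)
  }
  summarise <- function(hat, se, truth, df) list(
    truth = truth, mean_estimate = mean(hat),
    bias = mean(hat) - truth,
    relative_bias = (mean(hat) - truth) / truth,
    rmse = sqrt(mean((hat - truth)^2)),
    coverage = cover(hat, se, truth, df))
  list(n_datasets = n_datasets,
       mu = summarise(mu_hat, mu_se, params$mu, mu_df),
       yield_xs = summarise(y_hat, y_se, params$yield_xs, y_df),
       coverage_defined = n_datasets >= 2)
}
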
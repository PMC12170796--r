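#' Simulate a dyad's smile-intensity time series
#'
#' Each member emits spontaneous smile bursts as a Poisson process in time;
#' a burst is a half-cosine bump of configured width and amplitude on the
#' 0--100 intensity scale. Mimicry is modelled probabilistically: with
#' probability `coupling`, each spontaneous burst of one member seeds a
#' response burst in the partner after a uniform lag (default 0.2--1.0 s,
#' inside the +/- 1 s window within which most facial reactions to a partner
#' occur). Response bursts do not themselves trigger responses. With
#' probability `nonsmiler_prob` a member produces an all-zero series, the
#' behaviour of participants who stay neutral throughout, which downstream
#' eligibility filtering must handle.
#'
#' @param cfg A [sim_config()].
#' @param coupling Mimicry probability for this dyad, in `[0, 1]`.
#' @param seed Integer seed for this dyad's substream.
#'
#' @return A list with numeric vectors `a` and `b` of length
#'   `duration_s * smile_rate_hz`, values in `[0, 100]`; attributes
#'   `events_a`/`events_b` give the burst-centre times (seconds) of each
#'   member and `rate_hz` the sampling rate.
#' @export
#' @examples
#' cfg <- sim_config(nonsmiler_prob = 0)
#' sm <- simulate_smile_dyad(cfg, coupling = 1, seed = 7)
#' range(sm$a)
simulate_smile_dyad <- function(cfg, coupling, seed = cfg$seed) {
  validate_sim_config(cfg)
  stopifnot(coupling >= 0, coupling <= 1)
  n <- round(cfg$duration_s * cfg$smile_rate_hz)

  with_substream(seed, "smile", {
    smiler <- stats::runif(2) >= cfg$nonsmiler_prob
    spont <- lapply(1:2, function(i) {
      if (!smiler[i]) return(numeric(0))
      k <- stats::rpois(1, cfg$smile_burst_rate * cfg$duration_s / 60)
      sort(stats::runif(k, 0, cfg$duration_s))
    })
    # mimicry: spontaneous bursts of one member seed partner responses
    resp <- lapply(1:2, function(i) {
      j <- 3 - i
      if (!smiler[i] || length(spont[[j]]) == 0) return(numeric(0))
      hit <- stats::runif(length(spont[[j]])) < coupling
      lags <- stats::runif(sum(hit), cfg$mimicry_lag_s[1], cfg$mimicry_lag_s[2])
      spont[[j]][hit] + lags
    })
    events <- lapply(1:2, function(i) sort(c(spont[[i]], resp[[i]])))
    amps <- lapply(events, function(ev) {
      cfg$smile_burst_amp * stats::runif(length(ev), 0.5, 1)
    })
    series <- lapply(1:2, function(i) {
      render_bursts(events[[i]], amps[[i]], n, cfg$smile_rate_hz,
                    cfg$smile_burst_width_s)
    })
    out <- list(a = series[[1]], b = series[[2]])
    attr(out, "events_a") <- events[[1]]
    attr(out, "events_b") <- events[[2]]
    attr(out, "spont_a") <- spont[[1]]
    attr(out, "spont_b") <- spont[[2]]
    attr(out, "rate_hz") <- cfg$smile_rate_hz
    out
  })
}

# Superimpose half-cosine bursts (peak at the event time, zero at
# +/- width/2) on an n-sample grid and clip to the 0-100 intensity scale.
render_bursts <- function(centers, amps, n, rate_hz, width_s) {
  x <- numeric(n)
  if (length(centers) == 0) return(x)
  t <- (seq_len(n) - 1) / rate_hz
  half <- width_s / 2
  for (k in seq_along(centers)) {
    lo <- max(1L, floor((centers[k] - half) * rate_hz) + 1L)
    hi <- min(n, ceiling((centers[k] + half) * rate_hz) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    d <- t[idx] - centers[k]
    bump <- amps[k] * cos(pi * d / width_s)
    bump[abs(d) > half] <- 0
    x[idx] <- x[idx] + bump
  }
  clip(x, 0, 100)
}

#' Simulate a dyad's heart-rate time series
#'
#' Heart rate in bpm is modelled as a baseline plus an exponentially
#' decaying initial-arousal component shared by both members (participants
#' start exercises with elevated heart rate that declines to a stable
#' level), plus member-specific AR(1) fluctuations. Coupling enters through
#' the innovations: `e_i = sqrt(1 - c) * u_i + sqrt(c) * s` with `u_i`
#' member-specific and `s` shared white noise, so `c = 0` gives independent
#' members and `c = 1` identical fluctuations.
#'
#' @param cfg A [sim_config()].
#' @param coupling Shared-innovation weight `c` in `[0, 1]` for this dyad.
#' @param seed Integer seed for this dyad's substream.
#'
#' @return A list with numeric vectors `a` and `b` of length
#'   `duration_s * hr_rate_hz`, all values positive, and attribute `rate_hz`.
#' @export
#' @examples
#' cfg <- sim_config()
#' hr <- simulate_hr_dyad(cfg, coupling = 0, seed = 3)
#' mean(hr$a)
simulate_hr_dyad <- function(cfg, coupling, seed = cfg$seed) {
  validate_sim_config(cfg)
  stopifnot(coupling >= 0, coupling <= 1)
  if (abs(cfg$hr_ar_coef) >= 1) {
    stop("hr_ar_coef implies a non-stationary AR process (|coef| >= 1)")
  }
  n <- round(cfg$duration_s * cfg$hr_rate_hz)
  t <- (seq_len(n) - 1) / cfg$hr_rate_hz
  trend <- cfg$hr_baseline_bpm + cfg$hr_arousal_amp_bpm * exp(-t / cfg$hr_decay_tau_s)

  with_substream(seed, "hr", {
    s <- stats::rnorm(n, 0, cfg$hr_noise_sd)
    x <- lapply(1:2, function(i) {
      u <- stats::rnorm(n, 0, cfg$hr_noise_sd)
      e <- sqrt(1 - coupling) * u + sqrt(coupling) * s
      ar1_filter(e, cfg$hr_ar_coef)
    })
    out <- list(a = pmax(trend + x[[1]], 1), b = pmax(trend + x[[2]], 1))
    attr(out, "rate_hz") <- cfg$hr_rate_hz
    out
  })
}

# AR(1) recursion x_t = phi * x_{t-1} + e_t with stationary initialisation.
ar1_filter <- function(e, phi) {
  n <- length(e)
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  x[1] <- e[1] / sqrt(max(1 - phi^2, .Machine$double.eps))
  if (n > 1) {
    x[2:n] <- stats::filter(e[2:n], phi, method = "recursive",
                            init = x[1])
  }
  x
}
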
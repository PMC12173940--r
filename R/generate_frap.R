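#' Generate synthetic FRAP traces
#'
#' Emulates the published acquisition layout: three pre-bleach frames at 1 s
#' per frame, 1 s of bleach, and 35 post-bleach frames at 1 s per frame.
#' The bleach-ROI signal follows a pre-bleach plateau and a post-bleach
#' exponential recovery `A * (1 - exp(-t/tau)) + C` with
#' `tau = t_half / ln 2`; both ROIs are multiplied by a shared slow
#' mono-exponential acquisition-photobleaching decay, and Gaussian noise of
#' configurable SD is added.  Each trace's half-time is drawn from
#' `Normal(frap_t_half, frap_t_half_sd)` truncated positive.
#'
#' @param params a [state_params()] object (uses `frap_t_half`,
#'   `frap_t_half_sd`).
#' @param n number of traces.
#' @param seed integer seed.
#' @param n_pre,n_post frame counts (defaults 3 and 35).
#' @param frame_interval_s seconds per frame (default 1).
#' @param bleach_gap_s duration of the bleach itself (default 1 s; no frame
#'   is acquired during the bleach).
#' @param noise_sd additive Gaussian intensity noise (normalized units).
#' @param acq_bleach_tau_s time constant of acquisition photobleaching
#'   \[s\]; `Inf` disables the decay (control ROI then stays constant).
#' @param amplitude,offset recovery amplitude `A` and bleach-floor `C` of
#'   the underlying normalized curve.
#' @return tibble with one row per frame and columns `trace_id`, `frame`,
#'   `time_s`, `phase` (`"pre"`/`"post"`), `bleach_roi`, `control_roi`,
#'   `t_half_true_s`.  The first post-bleach frame of trace `k` is at
#'   `time_s = n_pre * frame_interval_s + bleach_gap_s`.
#' @export
#' @examples
#' tr <- generate_frap_traces(state_params("ESC"), n = 2, seed = 1)
#' dplyr::count(tr, trace_id, phase)
generate_frap_traces <- function(params, n, seed = NULL,
                                 n_pre = 3, n_post = 35,
                                 frame_interval_s = 1, bleach_gap_s = 1,
                                 noise_sd = 0.02, acq_bleach_tau_s = 300,
                                 amplitude = 0.65, offset = 0.2) {
  stopifnot(inherits(params, "state_params"), n >= 1, n_pre >= 1, n_post >= 5)
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.",
          class = "spindlescale_error_params")
  }
  stop_if_not_positive(params$frap_t_half, "frap_t_half")
  with_seed_if(seed, {
    t_pre <- (seq_len(n_pre) - 1) * frame_interval_s
    t_post0 <- n_pre * frame_interval_s + bleach_gap_s
    t_post <- t_post0 + (seq_len(n_post) - 1) * frame_interval_s
    times <- c(t_pre, t_post)
    purrr::map_dfr(seq_len(n), function(k) {
      t_half <- rnorm_trunc(1, params$frap_t_half, params$frap_t_half_sd,
                            lower = 0)
      tau <- t_half / log(2)
      recovery <- c(rep(1, n_pre),
                    amplitude * (1 - exp(-(t_post - t_post0) / tau)) + offset)
      decay <- if (is.finite(acq_bleach_tau_s)) {
        exp(-times / acq_bleach_tau_s)
      } else rep(1, length(times))
      bleach <- recovery * decay
      control <- decay
      if (noise_sd > 0) {
        bleach <- pmax(bleach + rnorm(length(times), 0, noise_sd), 0)
        control <- pmax(control + rnorm(length(times), 0, noise_sd), 1e-6)
      }
      tibble(trace_id = sprintf("frap_%03d", k),
             frame = seq_along(times),
             time_s = times,
             phase = rep(c("pre", "post"), c(n_pre, n_post)),
             bleach_roi = bleach,
             control_roi = control,
             t_half_true_s = t_half)
    })
  })
}
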
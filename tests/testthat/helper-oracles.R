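# Independent textbook oracles used across test files.

# Welch's t with Satterthwaite df and two-sided p, plus pooled-sd Cohen's d,
# written directly from the formulas (independent of compare_groups()).
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  s_pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  list(t = t, df = df, p = p, d = (mean(a) - mean(b)) / s_pooled)
}

# Rule-by-rule track retention oracle on per-track features.
oracle_keep <- function(duration, med_quality, first, last, rules) {
  duration >= rules$min_duration_s & duration <= rules$max_duration_s &
    med_quality >= rules$quality_range[1] &
    med_quality <= rules$quality_range[2] &
    first >= rules$start_end_window[1] & last <= rules$start_end_window[2]
}

# Build a minimal straight-line track tibble from per-track features.
make_track <- function(id, n_points, frame0, quality, interval = 0.4,
                       speed = 0.26, cell = "cellA", compartment = "bulk") {
  k <- seq_len(n_points) - 1
  tibble::tibble(
    cell_id = cell, track_id = id,
    frame = frame0 + k, time_s = (frame0 + k) * interval,
    x_um = speed * k * interval, y_um = 0,
    quality = quality, compartment = compartment,
    V_cell_um3 = 2000)
}
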
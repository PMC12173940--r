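#' Bin cell records by cell volume
#'
#' Assigns each record to a left-closed, right-open cell-volume bin
#' `[edge_i, edge_{i+1})`.  Records outside `[first, last)` go to an explicit
#' `"unbinned"` bucket; nothing is dropped silently.
#'
#' @param records tibble with a `V_cell_um3` column.
#' @param edges strictly increasing bin edges \[um^3\], length >= 2.  The
#'   published comparison uses 500-um^3 bins spanning 1,000-3,500 um^3
#'   (`seq(1000, 3500, 500)`).
#' @return the input tibble with columns `bin` (character, e.g.
#'   `"[2000,2500)"` or `"unbinned"`), `bin_low`, `bin_high` (`NA` for
#'   unbinned) appended.  Every record lands in exactly one bucket.
#' @export
#' @examples
#' df <- tibble::tibble(V_cell_um3 = c(900, 2499, 2500))
#' bin_by_cell_volume(df, seq(1000, 3500, 500))$bin
bin_by_cell_volume <- function(records, edges) {
  stopifnot(is.data.frame(records), "V_cell_um3" %in% names(records))
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE)) {
    abort("`edges` must be strictly increasing with at least two values.",
          class = "spindlescale_error_params")
  }
  v <- records$V_cell_um3
  idx <- findInterval(v, edges, rightmost.closed = FALSE, left.open = FALSE)
  inside <- idx >= 1 & idx < length(edges)
  labs <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  records <- as_tibble(records)
  records$bin <- ifelse(inside, labs[pmax(idx, 1)], "unbinned")
  records$bin_low <- ifelse(inside, edges[pmax(idx, 1)], NA_real_)
  records$bin_high <- ifelse(inside, edges[pmax(idx, 1) + 1L], NA_real_)
  records
}

#' Per-bin medians and interquartile ranges
#'
#' Summarises a binned variable the way the published binned comparisons are
#' drawn: median and interquartile range per cell-volume bin, with the bin
#' count.
#'
#' @param records tibble with `V_cell_um3` and the variable of interest.
#' @param edges bin edges passed to [bin_by_cell_volume()].
#' @param var name of the summarised column (default `"V_spindle_um3"`).
#' @param keep_unbinned include the `"unbinned"` bucket row (default FALSE).
#' @return tibble with `bin`, `bin_low`, `bin_high`, `n`, `median`,
#'   `iqr_low`, `iqr_high`.
#' @export
summarise_bins <- function(records, edges, var = "V_spindle_um3",
                           keep_unbinned = FALSE) {
  stopifnot(var %in% names(records))
  out <- bin_by_cell_volume(records, edges) %>%
    group_by(.data$bin, .data$bin_low, .data$bin_high) %>%
    summarise(n = dplyr::n(),
              median = median(.data[[var]]),
              iqr_low = quantile(.data[[var]], 0.25, names = FALSE),
              iqr_high = quantile(.data[[var]], 0.75, names = FALSE),
              .groups = "drop") %>%
    arrange(is.na(.data$bin_low), .data$bin_low)
  if (!keep_unbinned) out <- filter(out, .data$bin != "unbinned")
  out
}

#' Welch two-group comparison with effect size
#'
#' Welch's t-test for unequal variances (Satterthwaite degrees of freedom,
#' two-sided p) together with Cohen's d, `d = (mean_a - mean_b) / s_pooled`
#' with the (n-1)-weighted pooled standard deviation.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return one-row tibble: `t_statistic`, `df_welch`, `p_two_sided`,
#'   `cohens_d`, `n_a`, `n_b`.  If both groups have zero variance and equal
#'   means, returns `t = 0, p = 1, d = 0`; zero pooled variance with unequal
#'   means is signalled as degenerate.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(3, 4, 5))$cohens_d # -2
compare_groups <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Both groups need at least two finite observations.",
          class = "spindlescale_error_params")
  }
  na <- length(a); nb <- length(b)
  s2p <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (s2p == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(tibble(t_statistic = 0, df_welch = na + nb - 2,
                    p_two_sided = 1, cohens_d = 0, n_a = na, n_b = nb))
    }
    abort("Zero pooled variance with unequal means: comparison is degenerate.",
          class = "spindlescale_error_degenerate")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(t_statistic = unname(tt$statistic),
         df_welch = unname(tt$parameter),
         p_two_sided = tt$p.value,
         cohens_d = (mean(a) - mean(b)) / sqrt(s2p),
         n_a = na, n_b = nb)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; constant input vectors are
#' signalled rather than silently returning `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^3) # 1
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
          class = "spindlescale_error_params")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Fewer than 3 complete pairs.", class = "spindlescale_error_params")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation is undefined for a constant vector.",
          class = "spindlescale_error_degenerate")
  }
  cor(x, y, method = "spearman")
}

#' Binned median subscaling profile
#'
#' Per-bin percent deficit of the test group's median relative to the
#' reference, `100 * (median_ref - median_test) / median_ref`, matching the
#' published "median spindle volumes were up to 24% smaller" comparison.
#' Bins where either group has fewer than `min_n` records are flagged and
#' excluded from the reported maximum.
#'
#' @param bins_ref,bins_test bin summaries from [summarise_bins()] with
#'   matching bin edges.
#' @param min_n minimum per-bin count for an unflagged deficit (default 5,
#'   the smallest published bin count).
#' @return object of class `subscaling_profile`: list with `deficits`
#'   (tibble: `bin`, `bin_low`, `bin_high`, `n_ref`, `n_test`,
#'   `deficit_pct`, `flagged`) and `max_deficit_pct` (maximum over unflagged
#'   bins).
#' @export
subscaling_profile <- function(bins_ref, bins_test, min_n = 5) {
  need <- c("bin", "bin_low", "bin_high", "n", "median")
  stopifnot(all(need %in% names(bins_ref)), all(need %in% names(bins_test)))
  ref <- filter(bins_ref, .data$bin != "unbinned")
  tst <- filter(bins_test, .data$bin != "unbinned")
  if (!identical(ref$bin, tst$bin)) {
    abort("Reference and test summaries must share identical bin edges.",
          class = "spindlescale_error_params")
  }
  if (any(ref$median == 0)) {
    abort("Zero reference median: deficit undefined.",
          class = "spindlescale_error_degenerate")
  }
  deficits <- tibble(
    bin = ref$bin, bin_low = ref$bin_low, bin_high = ref$bin_high,
    n_ref = ref$n, n_test = tst$n,
    deficit_pct = 100 * (ref$median - tst$median) / ref$median,
    flagged = ref$n < min_n | tst$n < min_n)
  usable <- deficits$deficit_pct[!deficits$flagged]
  structure(list(deficits = deficits,
                 max_deficit_pct = if (length(usable)) max(usable) else NA_real_),
            class = "subscaling_profile")
}

#' @export
print.subscaling_profile <- function(x, ...) {
  cat("<subscaling_profile> max median deficit",
      sprintf("%.1f%%", x$max_deficit_pct), "over",
      sum(!x$deficits$flagged), "bins\n")
  print(x$deficits)
  invisible(x)
}

#' Volume occupancy in percent
#'
#' `100 * part / whole`; used for centrosome occupancy (summed centrosome
#' volume : cell volume) and spindle occupancy.
#'
#' @param part_volume,whole_volume volumes \[um^3\]; vectorized.
#' @return percent.  `part > whole` is signalled as an inconsistent record.
#' @export
#' @examples
#' occupancy(10, 1000) # 1
occupancy <- function(part_volume, whole_volume) {
  if (any(whole_volume <= 0)) {
    abort("`whole_volume` must be positive.",
          class = "spindlescale_error_record")
  }
  if (any(part_volume < 0)) {
    abort("`part_volume` must be non-negative.",
          class = "spindlescale_error_record")
  }
  if (any(part_volume > whole_volume)) {
    abort("Inconsistent record: part volume exceeds whole volume.",
          class = "spindlescale_error_record")
  }
  100 * part_volume / whole_volume
}

#' Fold change relative to a control group
#'
#' Divides each value by the control median, as in the normalized-to-control
#' panels of the osmotic and inhibitor comparisons.
#'
#' @param values numeric vector of the treated group.
#' @param control_values numeric vector of the control group (non-empty,
#'   non-zero median).
#' @return list with `fold` (normalized values), `median_fold` and
#'   `iqr` (interquartile range of the folds, length 2).
#' @export
#' @examples
#' fold_change_vs_control(c(2, 4), c(1, 2, 3))$median_fold # 1.5
fold_change_vs_control <- function(values, control_values) {
  if (!length(control_values)) {
    abort("Control group is empty.", class = "spindlescale_error_params")
  }
  m <- median(control_values)
  if (!is.finite(m) || m == 0) {
    abort("Zero (or non-finite) control median: fold change undefined.",
          class = "spindlescale_error_degenerate")
  }
  fold <- values / m
  list(fold = fold, median_fold = median(fold),
       iqr = unname(quantile(fold, c(0.25, 0.75))))
}

#' Intermitotic times of a tracked lineage
#'
#' Successive differences of ordered division times; the interval between
#' two division events is the cell-cycle duration.
#'
#' @param division_times_s strictly increasing division times \[s\] of one
#'   family.  Fewer than two events give an empty result, not an error.
#' @return numeric vector of positive intervals \[s\].
#' @export
#' @examples
#' intermitotic_times(c(0, 10, 25) * 3600) / 3600 # 10 15
intermitotic_times <- function(division_times_s) {
  if (length(division_times_s) < 2) return(numeric(0))
  if (is.unsorted(division_times_s, strictly = TRUE)) {
    abort("Division times must be strictly increasing.",
          class = "spindlescale_error_record")
  }
  diff(division_times_s)
}
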
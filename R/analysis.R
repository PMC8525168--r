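# Replicate summaries, the paired t test of resident vs disperser learning
# ability, and the season-length / dispersal-timing sweep experiments.

#' Default equilibrium window
#'
#' The trailing window over which trait means are averaged: the final 10%
#' of recorded generations, but at least 10 (capped at the series length).
#'
#' @param n_generations Length of the recorded series.
#' @return Integer window length.
#' @export
default_window <- function(n_generations) {
  max(min(10L, n_generations), as.integer(floor(n_generations / 10)))
}

#' Equilibrium trait means of one run
#'
#' Averages, over the final `window` recorded generations, the population
#' means of the resident-learning locus, the disperser-learning locus and
#' the dispersal-tendency locus (the quantities the sweep experiments
#' compare), plus the expressed-phenotype learning means as diagnostics.
#'
#' @param result A `sim_run`.
#' @param window Trailing window length in generations; defaults to
#'   [default_window()] of the series.
#' @return A one-row tibble with columns `mean_L_R_locus`,
#'   `mean_L_D_locus`, `mean_D`, `mean_L_expressed_residents`,
#'   `mean_L_expressed_dispersers` and `window`.
#' @export
trait_means_at_equilibrium <- function(result, window = NULL) {
  rec <- result$records
  n <- nrow(rec)
  if (n == 0) rlang::abort("run has no recorded generations")
  if (is.null(window)) window <- default_window(n)
  window <- as.integer(window)
  if (window < 1 || window > n) {
    rlang::abort(sprintf("window must lie in [1, %d]", n))
  }
  tail_rec <- rec[(n - window + 1):n, ]
  tibble::tibble(
    mean_L_R_locus = mean(tail_rec$mean_L_R_locus),
    mean_L_D_locus = mean(tail_rec$mean_L_D_locus),
    mean_D = mean(tail_rec$mean_D),
    mean_L_expressed_residents =
      mean(tail_rec$mean_L_expressed_residents, na.rm = TRUE),
    mean_L_expressed_dispersers =
      mean(tail_rec$mean_L_expressed_dispersers, na.rm = TRUE),
    window = window
  )
}

#' Paired t test
#'
#' Two-sided paired t test on replicate-matched samples: with differences
#' `d = x - y`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom. Degenerate cases follow the conventions: zero variance with a
#' non-zero mean difference gives `p = 0`; zero variance and zero mean
#' give `t = 0, p = 1`.
#'
#' @param x,y Paired numeric vectors (same length, `n >= 2`).
#' @param alpha Two-sided significance threshold (default 0.05).
#' @return An object of class `paired_comparison` with fields `t`, `df`,
#'   `p_value`, `significant`, `mean_diff`, `n` and the per-replicate
#'   pairs; has [tidy()] and [glance()] methods.
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  }
  structure(
    list(t = t_stat, df = n - 1L, p_value = p,
         significant = p < alpha, alpha = alpha,
         mean_diff = m, n = n,
         pairs = tibble::tibble(x = x, y = y)),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t test: t = %.4f, df = %d, p = %.4g (%ssignificant at alpha = %g)\n",
              x$t, x$df, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' @method tidy paired_comparison
#' @export
tidy.paired_comparison <- function(x, ...) {
  dplyr::mutate(x$pairs, diff = .data$x - .data$y,
                replicate = dplyr::row_number(), .before = 1)
}

#' @method glance paired_comparison
#' @export
glance.paired_comparison <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p_value = x$p_value,
                 significant = x$significant, mean_diff = x$mean_diff,
                 n = x$n)
}

sweep_cell <- function(cfg, n_replicates, base_seed, window, alpha,
                       cell_label) {
  runs <- run_replicates(cfg, n_replicates, base_seed)
  reps <- dplyr::bind_rows(lapply(seq_along(runs), function(k) {
    dplyr::mutate(trait_means_at_equilibrium(runs[[k]], window),
                  replicate = k, seed = runs[[k]]$seed,
                  extinct = runs[[k]]$extinct, .before = 1)
  }))
  test <- if (n_replicates >= 2) {
    paired_t_test(reps$mean_L_R_locus, reps$mean_L_D_locus, alpha = alpha)
  } else NULL
  summary <- tibble::tibble(
    mean_L_R_locus = mean(reps$mean_L_R_locus),
    sd_L_R_locus = sd(reps$mean_L_R_locus),
    mean_L_D_locus = mean(reps$mean_L_D_locus),
    sd_L_D_locus = sd(reps$mean_L_D_locus),
    mean_D = mean(reps$mean_D),
    sd_D = sd(reps$mean_D),
    t = if (is.null(test)) NA_real_ else test$t,
    df = if (is.null(test)) NA_integer_ else test$df,
    p_value = if (is.null(test)) NA_real_ else test$p_value,
    significant = if (is.null(test)) NA else test$significant,
    direction = dplyr::case_when(
      mean(reps$mean_L_R_locus) > mean(reps$mean_L_D_locus) ~ "L_R > L_D",
      mean(reps$mean_L_R_locus) < mean(reps$mean_L_D_locus) ~ "L_D > L_R",
      TRUE ~ "equal")
  )
  list(replicates = reps, summary = summary, test = test,
       label = cell_label)
}

#' Season-length sweep
#'
#' For each phase length `T` (with `t_before = t_after = T`, i.e. season
#' length `S = 2T`) runs `n_replicates` simulations, extracts equilibrium
#' means and performs the paired t test of the resident- vs the
#' disperser-learning locus means across replicates.
#'
#' @param phase_lengths Integer vector of phase lengths `T`.
#' @param n_replicates Replicates per season length (default 10).
#' @param base_seed Base seed; cell `i`, replicate `k` runs with seed
#'   `base_seed + (i - 1) * 1000 + k - 1`.
#' @param base_cfg Function mapping a phase length to a `sim_config`;
#'   defaults to [season_preset()].
#' @param window Equilibrium window (default: final 10%, min 10).
#' @param alpha Significance threshold for the paired test.
#' @return An object of class `sweep_result`; `tidy()` returns one row per
#'   (season length, replicate), `glance()` one summary row per season
#'   length including the test.
#' @export
season_length_sweep <- function(phase_lengths, n_replicates = 10,
                                base_seed = 1, base_cfg = season_preset,
                                window = NULL, alpha = 0.05) {
  cells <- lapply(seq_along(phase_lengths), function(i) {
    t_phase <- phase_lengths[i]
    cell <- sweep_cell(base_cfg(t_phase),
                       n_replicates,
                       base_seed + (i - 1L) * 1000L,
                       window, alpha,
                       cell_label = sprintf("S=%d", 2L * as.integer(t_phase)))
    cell$replicates <- dplyr::mutate(cell$replicates,
                                     season_length = 2L * as.integer(t_phase),
                                     .before = 1)
    cell$summary <- dplyr::mutate(cell$summary,
                                  season_length = 2L * as.integer(t_phase),
                                  .before = 1)
    cell
  })
  structure(list(cells = cells, sweep = "season_length",
                 base_seed = base_seed),
            class = "sweep_result")
}

#' Dispersal-timing sweep
#'
#' Runs replicate simulations for each `(t_before, t_after)` split of a
#' fixed total season length and summarises equilibrium means of the
#' learning loci and the dispersal tendency, to expose how mid-life versus
#' edge-of-life dispersal shapes disperser learning and dispersal tendency.
#'
#' @param timings A list of `c(t_before, t_after)` pairs (all summing to
#'   the same season length).
#' @param n_replicates Replicates per timing (default 10).
#' @param base_seed Base seed; seeded per cell as in
#'   [season_length_sweep()].
#' @param base_cfg Function mapping `t_before` to a `sim_config`; defaults
#'   to [timing_preset()].
#' @param window Equilibrium window.
#' @param alpha Significance threshold.
#' @return A `sweep_result` whose cells are labelled by the timing split.
#' @export
dispersal_timing_sweep <- function(timings, n_replicates = 10,
                                   base_seed = 1, base_cfg = timing_preset,
                                   window = NULL, alpha = 0.05) {
  S <- unique(vapply(timings, sum, numeric(1)))
  if (length(S) != 1) {
    rlang::abort("all timings must sum to the same season length")
  }
  cells <- lapply(seq_along(timings), function(i) {
    tb <- as.integer(timings[[i]][1]); ta <- as.integer(timings[[i]][2])
    cell <- sweep_cell(base_cfg(tb),
                       n_replicates,
                       base_seed + (i - 1L) * 1000L,
                       window, alpha,
                       cell_label = sprintf("(%d,%d)", tb, ta))
    cell$replicates <- dplyr::mutate(cell$replicates, t_before = tb,
                                     t_after = ta, .before = 1)
    cell$summary <- dplyr::mutate(cell$summary, t_before = tb,
                                  t_after = ta, .before = 1)
    cell
  })
  structure(list(cells = cells, sweep = "dispersal_timing",
                 base_seed = base_seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s> %d cell(s), base seed %d\n",
              x$sweep, length(x$cells), x$base_seed))
  print(glance(x))
  invisible(x)
}

#' Per-replicate rows of a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Tibble with one row per (cell, replicate).
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$cells, `[[`, "replicates"))
}

#' Per-cell summary of a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Tibble with one row per cell: means, SDs, and the paired test.
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$cells, `[[`, "summary"))
}

#' JSON-ready test report of a sweep
#'
#' @param x A `sweep_result`.
#' @return A list (one element per cell) with the cell label, t, df, p and
#'   direction, suitable for `jsonlite::write_json()`.
#' @export
sweep_test_report <- function(x) {
  lapply(x$cells, function(cell) {
    list(cell = cell$label,
         t = if (is.null(cell$test)) NA else cell$test$t,
         df = if (is.null(cell$test)) NA else cell$test$df,
         p = if (is.null(cell$test)) NA else cell$test$p_value,
         direction = cell$summary$direction)
  })
}
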
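#' Suggest which common taxa to exclude before entering rare mode
#'
#' At the switch to rare counting the observer is shown the taxa counted so
#' far in descending abundance order and picks those to stop counting. This
#' function reproduces that dialog's content: shares are computed on
#' full-phase counts only (no rare counts exist yet at the moment of the
#' decision), and a taxon is flagged for exclusion when its share exceeds
#' `threshold`. Field practice with diverse microfossil assemblages is to
#' switch after 1,000–2,000 specimens and exclude taxa above roughly 5%.
#'
#' @param tally A tally tibble from [tally()], or any data frame with
#'   `taxon_id` and `n_full` columns.
#' @param threshold Exclusion threshold as a proportion in (0, 1].
#' @return A tibble sorted by descending `n_full` (ties broken by
#'   `taxon_id`) with columns `taxon_id`, `n_full`, `share`, `excluded`.
#' @export
suggest_exclusions <- function(tally, threshold = 0.05) {
  check_tally(tally)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a proportion in (0, 1].")
  }
  full_total <- sum(tally$n_full)
  if (full_total <= 0) abort("No full-phase counts: nothing to rank.")
  tally |>
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      n_full = .data$n_full,
      share = .data$n_full / .env$full_total,
      excluded = .data$share > threshold
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_full), .data$taxon_id)
}

check_tally <- function(tally) {
  if (!is.data.frame(tally) || nrow(tally) == 0 ||
      !all(c("taxon_id", "n_full") %in% names(tally))) {
    abort("`tally` must be a non-empty data frame with taxon_id and n_full.")
  }
  invisible(tally)
}

#' Combine full- and rare-phase counts into abundance estimates
#'
#' The point of recording observational effort (tracks) in both phases is
#' that the unrecorded encounters with excluded common taxa can be
#' reconstructed afterwards. A taxon counted only in the full phase at a
#' per-track rate of `n_full / T_full` is assumed to have been encountered
#' at the same rate during the `T_rare` rare-phase tracks, so its estimated
#' total is
#' \deqn{\hat n_i = n_{full,i} \, (1 + T_{rare}/T_{full})}
#' while a non-excluded taxon's estimate is simply its raw total
#' `n_full + n_rare`. Estimated relative abundances are the estimates
#' normalized to sum to one. Fractional estimated counts are kept as-is;
#' raw counts remain available from [tally()] so the estimate is always
#' recomputable.
#'
#' @param session A completed [count_session].
#' @return A tibble with columns `taxon_id`, `n_full`, `n_rare`,
#'   `estimated_count`, `proportion`, `basis` (`"observed"` or
#'   `"effort_scaled"`).
#' @export
combined_estimates <- function(session) {
  check_session(session)
  tal <- tally(session)
  combine_counts(tal, session$exclusions,
                 tracks_full = session$tracks_full,
                 tracks_rare = session$tracks_rare)
}

# Core of the effort-scaled estimator, shared with SOD recomputation.
combine_counts <- function(tal, exclusions, tracks_full, tracks_rare) {
  has_rare <- tracks_rare > 0 && length(exclusions) > 0
  if (has_rare && tracks_full == 0) {
    abort(paste("Observational effort undefined: rare-phase tracks present",
                "but no full-phase tracks were recorded."))
  }
  scale <- if (has_rare) 1 + tracks_rare / tracks_full else 1
  out <- tal |>
    dplyr::mutate(
      excluded = .data$taxon_id %in% exclusions,
      estimated_count = ifelse(.data$excluded,
                               .data$n_full * scale,
                               .data$n_full + .data$n_rare),
      basis = ifelse(.data$excluded, "effort_scaled", "observed")
    )
  total <- sum(out$estimated_count)
  out$proportion <- if (total > 0) out$estimated_count / total else 0
  dplyr::select(out, "taxon_id", "n_full", "n_rare", "estimated_count",
                "proportion", "basis")
}

#' Relative standard error of an estimated proportion
#'
#' For a species with true relative abundance `p` estimated from a count of
#' `N` specimens, the binomial standard error of the estimated share is
#' `sqrt(p(1-p)/N)`; expressed relative to the abundance itself (epsilon),
#' \deqn{\epsilon = z \sqrt{p(1-p)/N} / p.}
#' This is the quantity behind the classic rule of thumb for choosing
#' rare-mode cut-offs: at `p = 5\%` and `N = 2000` the relative error is
#' just under 10%, i.e. a species truly at 5% is estimated between roughly
#' 4.5% and 5.5%.
#'
#' @param p Proportion(s) in (0, 1).
#' @param N Specimens counted in full mode (>= 1).
#' @param z Standard-normal multiplier; `z = 1` gives the standard error,
#'   `z = 1.96` a 95% band. Exposed explicitly because conventions differ.
#' @return A tibble with columns `p`, `N`, `z`, `epsilon`, recycled to a
#'   common length.
#' @export
relative_error <- function(p, N, z = 1) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must be in the open interval (0, 1).")
  }
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 1)) {
    abort("`N` must be >= 1.")
  }
  if (!is.numeric(z) || any(!is.finite(z)) || any(z <= 0)) {
    abort("`z` must be positive.")
  }
  out <- tibble(p = p, N = N, z = z)  # vctrs recycling
  out$epsilon <- out$z * sqrt(out$p * (1 - out$p) / out$N) / out$p
  out
}

#' Error landscape over a grid of abundance and sample size
#'
#' Evaluates [relative_error()] on the outer grid of `p_grid` by `n_grid`,
#' giving the landscape on which cut-off rules of thumb are read off: for a
#' candidate exclusion threshold `p`, how many specimens `N` must be counted
#' in full mode before the estimate of a taxon at that abundance is
#' acceptably precise.
#'
#' @param p_grid Proportions in (0, 1).
#' @param n_grid Sample sizes (>= 1).
#' @param z Standard-normal multiplier, see [relative_error()].
#' @return A tibble of class `error_landscape` with columns `p`, `N`, `z`,
#'   `epsilon`, one row per grid cell (p varying fastest).
#' @export
error_landscape <- function(p_grid, n_grid, z = 1) {
  if (length(p_grid) == 0 || length(n_grid) == 0) {
    abort("`p_grid` and `n_grid` must be non-empty.")
  }
  grid <- tidyr::expand_grid(N = as.numeric(n_grid), p = as.numeric(p_grid))
  out <- relative_error(grid$p, grid$N, z)
  class(out) <- c("error_landscape", class(out))
  out
}

#' Fraction of full-phase specimens eliminated by an exclusion set
#'
#' The payoff of rare mode is the share of encounters that no longer must be
#' recorded: the proportion of full-phase specimens belonging to the
#' excluded taxa. The higher this is, the more slide area can be scanned in
#' the same amount of counting time.
#'
#' @param tally A tally with `taxon_id` and `n_full` columns.
#' @param exclusions Character vector of excluded taxon_ids.
#' @return A single proportion in \[0, 1\].
#' @export
eliminated_fraction <- function(tally, exclusions) {
  check_tally(tally)
  n_total <- sum(tally$n_full)
  if (n_total <= 0) abort("No full-phase counts.")
  sum(tally$n_full[tally$taxon_id %in% exclusions]) / n_total
}

#' Threshold summary curves across a multi-sample dataset
#'
#' For each candidate exclusion threshold `p`, summarizes a collection of
#' per-sample relative-abundance tables with the three curves used to judge
#' a cut-off: the fraction of samples having at least one species above `p`
#' (a threshold is only usable if every sample has something to exclude),
#' the fraction of species exceeding `p` in at least one sample (how many
#' taxa an observer must hold in mind), and the distribution over samples of
#' the cumulative specimen proportion in species above `p` (the effort
#' saved). All three are non-increasing in `p`.
#'
#' @param dataset A long data frame with columns `sample`, `taxon_id` and
#'   `proportion`; proportions must sum to 1 within each sample.
#' @param p_grid Thresholds (proportions in \[0, 1)).
#' @return A tibble of class `threshold_summary` with columns `p`,
#'   `frac_samples` , `frac_species`, and the cumulative-proportion summary
#'   `cum_mean`, `cum_q25`, `cum_q75`, `cum_min`, `cum_max`.
#' @export
threshold_summary <- function(dataset, p_grid) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0 ||
      !all(c("sample", "taxon_id", "proportion") %in% names(dataset))) {
    abort("`dataset` must have columns sample, taxon_id, proportion.")
  }
  sums <- dataset |>
    dplyr::summarise(s = sum(.data$proportion), .by = "sample")
  if (any(abs(sums$s - 1) > 1e-6)) {
    abort("Proportions must sum to 1 within each sample.")
  }
  n_samples <- dplyr::n_distinct(dataset$sample)
  n_species <- dplyr::n_distinct(dataset$taxon_id)
  rows <- purrr::map(as.numeric(p_grid), function(p) {
    above <- dataset |>
      dplyr::summarise(
        any_above = any(.data$proportion > p),
        cum_above = sum(.data$proportion[.data$proportion > p]),
        .by = "sample"
      )
    species_above <- dataset |>
      dplyr::filter(.data$proportion > p) |>
      dplyr::pull("taxon_id") |>
      dplyr::n_distinct()
    tibble(
      p = p,
      frac_samples = mean(above$any_above),
      frac_species = species_above / n_species,
      cum_mean = mean(above$cum_above),
      cum_q25 = unname(stats::quantile(above$cum_above, 0.25)),
      cum_q75 = unname(stats::quantile(above$cum_above, 0.75)),
      cum_min = min(above$cum_above),
      cum_max = max(above$cum_above)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_samples") <- n_samples
  attr(out, "n_species") <- n_species
  class(out) <- c("threshold_summary", class(out))
  out
}

#' @describeIn error_landscape Filled-contour plot of epsilon over (N, p).
#' @param object An `error_landscape`.
#' @param ... Unused.
#' @export
autoplot.error_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$N, y = .data$p,
                                       z = .data$epsilon)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = "Specimens counted in full mode (N)",
                  y = "Relative abundance (p)",
                  fill = "relative error") +
    ggplot2::theme_minimal()
}

#' @describeIn threshold_summary Plot the three threshold-summary curves.
#' @param object A `threshold_summary`.
#' @param ... Unused.
#' @export
autoplot.threshold_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cum_q25,
                                      ymax = .data$cum_q75),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_mean,
                                    colour = "cumulative specimens")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$frac_samples,
                                    colour = "samples with species > p")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$frac_species,
                                    colour = "species > p in >= 1 sample")) +
    ggplot2::labs(x = "Exclusion threshold p", y = "Fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
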
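#' Collector's curve (species-accumulation curve) of an event sequence
#'
#' Cumulative number of distinct taxa seen against cumulative specimens
#' counted, one point per count event. Its flattening tells the observer how
#' complete the census of the sample is, and samples counted to the same
#' terminal slope are "fairly" sampled relative to one another.
#'
#' @param events A character vector of taxon ids in counting order, or an
#'   events tibble with a `taxon_id` column (see [session_events()]), or a
#'   [count_session].
#' @return A tibble of class `accumulation_curve` with columns `n`
#'   (specimens, 1..length) and `S` (distinct taxa among the first `n`).
#' @export
collector_curve <- function(events) {
  if (inherits(events, "count_session")) events <- session_events(events)
  if (is.data.frame(events)) events <- events$taxon_id
  events <- as.character(events)
  S <- cumsum(!duplicated(events))
  out <- tibble(n = seq_along(events), S = S)
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Expected richness under hypergeometric rarefaction (closed form)
#'
#' The expected number of distinct taxa in a random subsample of `n`
#' specimens drawn without replacement from a counted assemblage of
#' per-taxon counts \eqn{N_i} (total \eqn{N}):
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} \big/ \binom{N}{n}\right]}
#' Binomial coefficients are evaluated in log space so totals in the
#' 10^4–10^5 range do not overflow.
#'
#' @param counts Nonnegative integer vector of per-taxon counts.
#' @param n Subsample size, 0 <= n <= sum(counts).
#' @return A tibble of class `rarefaction_result` with columns `n`,
#'   `expected_S`, `sd` (`NA` for the closed form), `replicates` (0) and
#'   `seed` (`NA`).
#' @export
expected_richness <- function(counts, n) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    abort("`n` must be a single nonnegative integer.")
  }
  if (n > N) abort(sprintf("Subsample size n = %d exceeds total count N = %d.", n, N))
  es <- if (n == 0) 0 else {
    # log-space ratio; lchoose(N - Ni, n) = -Inf when N - Ni < n, term -> 1
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }
  out <- tibble(n = as.integer(n), expected_S = es, sd = NA_real_,
                replicates = 0L, seed = NA_integer_)
  class(out) <- c("rarefaction_result", class(out))
  out
}

check_counts <- function(counts) {
  if (is.data.frame(counts)) {
    nm <- intersect(c("estimated_count", "n_total", "count", "n"), names(counts))
    if (!length(nm)) abort("No count column found in `counts`.")
    counts <- counts[[nm[[1]]]]
  }
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be nonnegative numbers.")
  }
  counts <- counts[counts > 0]
  if (any(counts != floor(counts))) {
    abort("`counts` must be integers; round estimated counts first.")
  }
  if (!length(counts)) abort("All counts are zero.")
  counts
}

#' Monte-Carlo rarefaction
#'
#' Estimates expected subsample richness by repeatedly drawing `n` specimens
#' without replacement from the pooled assemblage and averaging the number
#' of distinct taxa. Agrees with the closed form [expected_richness()] to
#' within Monte-Carlo error; useful as a cross-check and for quantities with
#' no closed form.
#'
#' @inheritParams expected_richness
#' @param replicates Number of random subsamples (>= 1).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return A tibble of class `rarefaction_result` with `expected_S` the
#'   replicate mean and `sd` the replicate standard deviation.
#' @export
rarefy_mc <- function(counts, n, replicates = 1000, seed = 1) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    abort("`n` must be a single nonnegative integer.")
  }
  if (n > N) abort(sprintf("Subsample size n = %d exceeds total count N = %d.", n, N))
  if (replicates < 1) abort("`replicates` must be >= 1.")
  pool <- rep.int(seq_along(counts), counts)
  draws <- with_seed(seed, vapply(seq_len(replicates), function(i) {
    idx <- sample.int(N, n)
    sum(tabulate(pool[idx], nbins = length(counts)) > 0)
  }, numeric(1)))
  out <- tibble(n = as.integer(n), expected_S = mean(draws),
                sd = stats::sd(draws), replicates = as.integer(replicates),
                seed = as.integer(seed))
  class(out) <- c("rarefaction_result", class(out))
  out
}

#' Fit a hyperbolic saturation curve to an accumulation curve
#'
#' Fits the two-parameter hyperbola
#' \deqn{S(n) = S_{max} \, n / (b + n)}
#' to a collector's curve by bounded nonlinear least squares
#' (Levenberg–Marquardt via \pkg{minpack.lm}). The asymptote `S_max`
#' estimates species richness at infinite sample size; `b` is the
#' half-saturation constant, the sample size at which half the asymptotic
#' richness has been seen. Starting values are analytic: `S_max` at twice
#' the maximum observed richness and `b` at the sample size where richness
#' first reaches half its maximum.
#'
#' A fit is flagged `converged = FALSE` when the optimizer fails or when the
#' asymptote is unidentifiable — e.g. a perfectly linear curve (all
#' singletons, no curvature), recognized by a half-saturation estimate far
#' beyond the observed range.
#'
#' @param curve An `accumulation_curve` (or any data frame with `n` and `S`).
#' @return An object of class `decaprariis_fit` with elements `S_max`, `b`,
#'   `residual` (root-mean-square), `converged`, and `data`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
fit_decaprariis <- function(curve) {
  if (!is.data.frame(curve) || !all(c("n", "S") %in% names(curve))) {
    abort("`curve` must have columns n and S.")
  }
  pts <- dplyr::distinct(as_tibble(curve[, c("n", "S")]))
  if (nrow(pts) < 3) abort("Need at least 3 distinct (n, S) points to fit.")
  if (all(pts$S == pts$S[[1]])) {
    # zero-curvature limit: S is already saturated at its constant value
    k <- pts$S[[1]]
    if (k <= 0) abort("Constant curve at S = 0 cannot be fitted.")
    return(new_decaprariis_fit(S_max = k, b = 0, residual = 0,
                               converged = TRUE, data = pts))
  }
  s_max0 <- 2 * max(pts$S)
  b0 <- pts$n[which(pts$S >= max(pts$S) / 2)[[1]]]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      S ~ S_max * n / (b + n),
      data = pts,
      start = list(S_max = s_max0, b = max(b0, 1e-6)),
      lower = c(S_max = 1e-9, b = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_decaprariis_fit(S_max = NA_real_, b = NA_real_,
                               residual = NA_real_, converged = FALSE,
                               data = pts))
  }
  est <- coef(fit)
  rms <- sqrt(mean(resid(fit)^2))
  # an asymptote far beyond the sampled range is not identifiable from the data
  identifiable <- is.finite(est[["b"]]) && est[["b"]] <= 20 * max(pts$n) &&
    est[["S_max"]] >= max(pts$S) * 0.999
  new_decaprariis_fit(S_max = unname(est[["S_max"]]), b = unname(est[["b"]]),
                      residual = rms, converged = identifiable, data = pts)
}

new_decaprariis_fit <- function(S_max, b, residual, converged, data) {
  structure(list(S_max = S_max, b = b, residual = residual,
                 converged = converged, data = data),
            class = "decaprariis_fit")
}

#' @export
print.decaprariis_fit <- function(x, ...) {
  cat(sprintf(
    "<decaprariis_fit> S(n) = S_max n / (b + n)\n  S_max = %.4g, b = %.4g, RMS residual = %.4g, converged: %s\n",
    x$S_max, x$b, x$residual, x$converged
  ))
  invisible(x)
}

#' @describeIn fit_decaprariis One row per parameter (term, estimate).
#' @param x,object A `decaprariis_fit`.
#' @param ... Unused.
#' @export
tidy.decaprariis_fit <- function(x, ...) {
  tibble(term = c("S_max", "b"), estimate = c(x$S_max, x$b))
}

#' @describeIn fit_decaprariis One-row model summary.
#' @export
glance.decaprariis_fit <- function(x, ...) {
  tibble(S_max = x$S_max, b = x$b, residual = x$residual,
         converged = x$converged, n_points = nrow(x$data),
         S_observed = max(x$data$S))
}

#' @describeIn fit_decaprariis Observed curve, fitted hyperbola, asymptote.
#' @export
autoplot.decaprariis_fit <- function(object, ...) {
  grid <- tibble(n = seq(0, max(object$data$n), length.out = 200))
  grid$S <- object$S_max * grid$n / (object$b + grid$n)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$S)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_line(data = grid, colour = "grey60") +
    ggplot2::geom_hline(yintercept = object$S_max, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "Specimens counted", y = "Distinct taxa seen") +
    ggplot2::theme_minimal()
}

#' @describeIn collector_curve Line plot of the accumulation curve.
#' @param object An `accumulation_curve`.
#' @param ... Unused.
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$S)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Specimens counted", y = "Distinct taxa seen") +
    ggplot2::theme_minimal()
}

#' Percent richness improvement from rare-mode counting
#'
#' Quantifies what two-phase counting bought: how many more taxa were
#' observed than would have been found by spending the same total count in
#' ordinary single-phase counting. The single-phase expectation is obtained
#' by rarefaction from the reconstructed assemblage — the effort-scaled
#' combined estimates, rounded to integers for subsampling — at the actual
#' number of recorded events. The return value is
#' `100 * (S_obs - S_norare) / S_norare`.
#'
#' By definition the improvement is 0 when the session has no rare phase or
#' an empty exclusion set: the two counting regimes are then identical.
#'
#' @param session A completed [count_session].
#' @param replicates Rarefaction replicates (default 1000).
#' @param seed Integer seed for the Monte-Carlo subsampling.
#' @return A one-row tibble with `improvement_pct`, `S_obs`, `S_norare`,
#'   `n_actual`, `replicates`, `seed`.
#' @export
improvement_percent <- function(session, replicates = 1000, seed = 1) {
  check_session(session)
  ev <- session_events(session)
  n_actual <- nrow(ev)
  S_obs <- dplyr::n_distinct(ev$taxon_id)
  if (length(session$exclusions) == 0 || session$tracks_rare == 0) {
    return(tibble(improvement_pct = 0, S_obs = S_obs, S_norare = S_obs,
                  n_actual = n_actual, replicates = 0L,
                  seed = as.integer(seed)))
  }
  est <- combined_estimates(session)
  counts <- round(est$estimated_count)
  n_sub <- min(n_actual, sum(counts))
  rar <- rarefy_mc(counts, n_sub, replicates = replicates, seed = seed)
  S_norare <- rar$expected_S
  tibble(
    improvement_pct = 100 * (S_obs - S_norare) / S_norare,
    S_obs = S_obs, S_norare = S_norare, n_actual = n_actual,
    replicates = as.integer(replicates), seed = as.integer(seed)
  )
}

#' Write / read the diversity-vs-specimens history file
#'
#' The cumulative diversity versus number of counted specimens history is
#' saved as a simple two-column tab-text file, convenient for later curve
#' fitting in other software.
#'
#' @param curve An `accumulation_curve`.
#' @param path File path.
#' @return `path` invisibly (writer); an `accumulation_curve` (reader).
#' @export
write_diversity_history <- function(curve, path) {
  if (!is.data.frame(curve) || !all(c("n", "S") %in% names(curve))) {
    abort("`curve` must have columns n and S.")
  }
  readr::write_tsv(tibble(specimens = curve$n, cumulative_taxa = curve$S),
                   path)
  invisible(path)
}

#' @rdname write_diversity_history
#' @export
read_diversity_history <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ii", progress = FALSE)
  out <- tibble(n = raw[[1]], S = raw[[2]])
  class(out) <- c("accumulation_curve", class(out))
  out
}
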
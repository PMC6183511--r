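#' Generate a synthetic assemblage from a species-abundance model
#'
#' Builds a vector of true relative abundances for `S` species under one of
#' several classical species-abundance-distribution families, normalized to
#' sum to one and sorted in descending order. Real assemblages of
#' microfossils (and most ecological communities) are strongly uneven — a few
#' dominant species and a long tail of rare ones — and the `geometric`,
#' `log_series` and `lognormal` families reproduce that shape with different
#' tail weights.
#'
#' Families and their parameters:
#' \describe{
#'   \item{`geometric`}{rank-abundance ratio `k` in (0,1); species `i` gets
#'     weight `k^(i-1)`.}
#'   \item{`log_series`}{Fisher log-series terms `alpha * x^i / i` for
#'     `i = 1..S` with `alpha > 0`, `x` in (0,1). `alpha` cancels under
#'     normalization but is validated for interface fidelity.}
#'   \item{`lognormal`}{deterministic lognormal quantile spectrum with
#'     `sigma > 0`: weights are `qlnorm((i - 0.5)/S, 0, sigma)`.}
#'   \item{`uniform`}{all species equally abundant (perfect evenness).}
#'   \item{`explicit`}{`weights`, a vector of nonnegative values (at least one
#'     positive) normalized as given; `S` defaults to its length.}
#' }
#'
#' @param family One of `"geometric"`, `"log_series"`, `"lognormal"`,
#'   `"uniform"`, `"explicit"`.
#' @param S Integer species richness, >= 1.
#' @param k,alpha,x,sigma,weights Family-specific parameters, see Details.
#' @param taxon_ids Optional character vector of stable labels (recycled
#'   default `"sp001"...`). Labels follow the descending-abundance order.
#'
#' @return A tibble of class `synthetic_assemblage` with columns `taxon_id`
#'   and `proportion` (descending, summing to 1).
#' @examples
#' make_abundances("geometric", S = 3, k = 0.5)
#' @export
make_abundances <- function(family = c("geometric", "log_series", "lognormal",
                                       "uniform", "explicit"),
                            S = NULL, k = NULL, alpha = NULL, x = NULL,
                            sigma = NULL, weights = NULL, taxon_ids = NULL) {
  family <- match.arg(family)
  if (family == "explicit") {
    if (is.null(weights)) abort("`weights` is required for the explicit family.")
    if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights < 0) ||
        sum(weights) <= 0) {
      abort("`weights` must be finite, nonnegative, with a positive sum.")
    }
    S <- S %||% length(weights)
    if (S != length(weights)) abort("`S` must equal length(weights).")
  }
  if (is.null(S) || !is.numeric(S) || length(S) != 1 || !is.finite(S) ||
      S < 1 || S != floor(S)) {
    abort("`S` must be a single integer >= 1.")
  }
  S <- as.integer(S)
  check_param <- function(val, name, lo, hi) {
    if (is.null(val) || !is.numeric(val) || length(val) != 1 ||
        !is.finite(val) || val <= lo || val >= hi) {
      abort(sprintf("`%s` must be a finite number in (%s, %s).", name, lo, hi))
    }
    val
  }
  w <- switch(family,
    geometric = check_param(k, "k", 0, 1)^(seq_len(S) - 1),
    log_series = {
      alpha <- check_param(alpha, "alpha", 0, Inf)
      x <- check_param(x, "x", 0, 1)
      i <- seq_len(S)
      alpha * x^i / i
    },
    lognormal = {
      sigma <- check_param(sigma, "sigma", 0, Inf)
      qlnorm((seq_len(S) - 0.5) / S, meanlog = 0, sdlog = sigma)
    },
    uniform = rep(1, S),
    explicit = as.numeric(weights)
  )
  p <- sort(w / sum(w), decreasing = TRUE)
  if (is.null(taxon_ids)) {
    taxon_ids <- sprintf("sp%03d", seq_len(S))
  }
  if (length(taxon_ids) != S || anyDuplicated(taxon_ids)) {
    abort("`taxon_ids` must be unique and of length S.")
  }
  out <- tibble(taxon_id = as.character(taxon_ids), proportion = p)
  class(out) <- c("synthetic_assemblage", class(out))
  out
}

#' Draw a simulated counting stream from an assemblage
#'
#' Simulates the raw observation sequence a person scanning a microscope
#' slide would produce: i.i.d. multinomial draws of specimens from the
#' assemblage's true proportions, with a track marker interleaved after every
#' `specimens_per_track` specimens. A "track" is one traverse of the slide
#' and is the unit of observational effort in two-phase counting.
#'
#' @param assemblage A tibble with `taxon_id` and `proportion` columns
#'   (normally from [make_abundances()]).
#' @param n_specimens Number of specimens encountered, >= 0.
#' @param specimens_per_track Specimens scanned per track, >= 1.
#' @param seed Integer seed; the stream is reproducible for a fixed seed.
#'
#' @return A tibble with columns `kind` (`"count"` or `"track"`) and
#'   `taxon_id` (`NA` for track markers). The number of track markers is
#'   `floor(n_specimens / specimens_per_track)`.
#' @export
draw_stream <- function(assemblage, n_specimens, specimens_per_track = 100,
                        seed = 1) {
  check_assemblage(assemblage)
  if (!is.numeric(n_specimens) || length(n_specimens) != 1 ||
      n_specimens < 0 || n_specimens != floor(n_specimens)) {
    abort("`n_specimens` must be a single integer >= 0.")
  }
  if (!is.numeric(specimens_per_track) || specimens_per_track < 1 ||
      specimens_per_track != floor(specimens_per_track)) {
    abort("`specimens_per_track` must be an integer >= 1.")
  }
  n_specimens <- as.integer(n_specimens)
  if (n_specimens == 0) {
    return(tibble(kind = character(), taxon_id = character()))
  }
  ids <- with_seed(seed, sample(assemblage$taxon_id, n_specimens,
                                replace = TRUE, prob = assemblage$proportion))
  n_tracks <- n_specimens %/% specimens_per_track
  remainder <- n_specimens %% specimens_per_track
  kind <- c(rep(c(rep("count", specimens_per_track), "track"), n_tracks),
            rep("count", remainder))
  taxon <- rep(NA_character_, length(kind))
  taxon[kind == "count"] <- ids
  tibble(kind = kind, taxon_id = taxon)
}

check_assemblage <- function(assemblage) {
  if (!is.data.frame(assemblage) ||
      !all(c("taxon_id", "proportion") %in% names(assemblage)) ||
      nrow(assemblage) < 1) {
    abort("`assemblage` must be a data frame with taxon_id and proportion rows.")
  }
  if (abs(sum(assemblage$proportion) - 1) > 1e-9 || any(assemblage$proportion <= 0)) {
    abort("Assemblage proportions must be positive and sum to 1.")
  }
  invisible(assemblage)
}

#' Simulate a complete two-phase counting session
#'
#' Runs the full rare-count workflow against a synthetic assemblage: a full
#' phase of `n_full` specimens counted exhaustively, an exclusion step in
#' which every taxon whose full-phase share exceeds `threshold` is marked as
#' common, and a rare phase scanning `rare_tracks` further tracks during
#' which encounters with excluded taxa are skipped — they consume effort but
#' are not recorded, as a human counter mentally blocks out the common
#' species.
#'
#' @inheritParams draw_stream
#' @param n_full Specimens counted in the full phase (>= 0).
#' @param threshold Exclusion threshold on full-phase share, in (0, 1]. At
#'   `threshold = 1` nothing is excluded.
#' @param rare_tracks Number of tracks scanned in rare mode (>= 0).
#' @return A [count_session]: two-phase (in rare mode) when
#'   `rare_tracks > 0`, otherwise an ordinary single-phase count.
#' @export
simulate_session <- function(assemblage, n_full, threshold = 0.05,
                             rare_tracks = 0, specimens_per_track = 100,
                             seed = 1) {
  check_assemblage(assemblage)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1].")
  }
  if (rare_tracks < 0 || rare_tracks != floor(rare_tracks)) {
    abort("`rare_tracks` must be an integer >= 0.")
  }
  taxa <- tibble(
    taxon_id = assemblage$taxon_id,
    genus = assemblage$taxon_id, species = "",
    button = FALSE, button_label = "", category = ""
  )
  session <- count_session(taxa, metadata = list(
    observer = "simulator", fossil_group = "synthetic",
    sample_id = sprintf("SIM-seed%d", as.integer(seed))
  ))

  full <- draw_stream(assemblage, n_full, specimens_per_track, seed = seed)
  for (i in seq_len(nrow(full))) {
    session <- if (full$kind[i] == "count") {
      record_count(session, full$taxon_id[i])
    } else {
      increment_track(session)
    }
  }

  if (rare_tracks == 0) {
    return(session)
  }
  tal <- tally(session)
  excl <- suggest_exclusions(tal, threshold)
  excluded <- excl$taxon_id[excl$excluded]
  session <- enter_rare_mode(session, excluded, threshold = threshold)

  n_rare_draws <- rare_tracks * specimens_per_track
  rare <- draw_stream(assemblage, n_rare_draws, specimens_per_track,
                      seed = seed + 1L)
  for (i in seq_len(nrow(rare))) {
    if (rare$kind[i] == "track") {
      session <- increment_track(session)
    } else if (!(rare$taxon_id[i] %in% excluded)) {
      # excluded draws consume effort but are never recorded
      session <- record_count(session, rare$taxon_id[i])
    }
  }
  session
}
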
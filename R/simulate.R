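#' Configuration for synthetic transects
#'
#' The generator emulates scored drop-down video transects: reef presence
#' follows a two-state Markov chain along the tow (clustered occupancy,
#' the defining feature the K statistic targets), cover and elevation are
#' drawn per presence segment, and a fraction of segments is lost to
#' obscured seabed.
#'
#' Defaults describe a strongly clustered reef at moderate prevalence:
#' `stay_prob_presence = 0.9` (mean true run length 10 segments),
#' `stay_prob_absence = 67/70` so the stationary prevalence
#' `(1 - b) / ((1 - a) + (1 - b))` is 0.3, 120 segments (a 10-minute tow at
#' 5-s segments), 5% missing segments, cover uniform on (0, 100] and
#' elevation uniform on (0, 15) cm given presence.
#'
#' @param n_segments Number of 5-s segments per tow.
#' @param stay_prob_presence `a = P(1 -> 1)`, in `[0, 1)`.
#' @param stay_prob_absence `b = P(0 -> 0)`, in `[0, 1)`.
#' @param initial_presence_prob Probability the first segment is presence;
#'   defaults to the stationary prevalence.
#' @param missing_rate Probability a segment is unusable.
#' @param missing_mode `"iid"` (independent losses) or `"burst"` (losses
#'   arrive in runs, as obscured seabed does in real footage).
#' @param missing_burst_len Mean run length of missing segments in burst
#'   mode.
#' @param cover_fn Function `n -> n` cover percentages in `(0, 100]` for
#'   presence segments.
#' @param elevation_fn Function `n -> n` elevations (cm, `> 0`) for
#'   presence segments.
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_segments = 200, stay_prob_presence = 0.8)
#' stationary_prevalence(cfg)
simulation_config <- function(n_segments = 120,
                              stay_prob_presence = 0.9,
                              stay_prob_absence = 67 / 70,
                              initial_presence_prob = NULL,
                              missing_rate = 0.05,
                              missing_mode = c("iid", "burst"),
                              missing_burst_len = 3,
                              cover_fn = function(n) runif(n, 1e-9, 100),
                              elevation_fn = function(n) runif(n, 1e-9, 15)) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(
    n_segments = as.integer(n_segments),
    stay_prob_presence = stay_prob_presence,
    stay_prob_absence = stay_prob_absence,
    initial_presence_prob = initial_presence_prob,
    missing_rate = missing_rate,
    missing_mode = missing_mode,
    missing_burst_len = missing_burst_len,
    cover_fn = cover_fn,
    elevation_fn = elevation_fn
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg$initial_presence_prob <- cfg$initial_presence_prob %||%
    stationary_prevalence(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_segments < 1) abort("n_segments must be >= 1")
  prob01 <- function(p, name, open_top = FALSE) {
    if (is.null(p)) return(invisible())
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1 ||
        (open_top && p == 1))
      abort(paste0("`", name, "` must be a probability in [0, 1",
                   if (open_top) ")" else "]"))
  }
  prob01(cfg$stay_prob_presence, "stay_prob_presence", open_top = TRUE)
  prob01(cfg$stay_prob_absence, "stay_prob_absence", open_top = TRUE)
  prob01(cfg$initial_presence_prob, "initial_presence_prob")
  prob01(cfg$missing_rate, "missing_rate")
  if (cfg$missing_burst_len < 1) abort("missing_burst_len must be >= 1")
  invisible(cfg)
}

#' @rdname simulation_config
#' @param config A `simulation_config`.
#' @export
stationary_prevalence <- function(config) {
  a <- config$stay_prob_presence
  b <- config$stay_prob_absence
  (1 - b) / ((1 - a) + (1 - b))
}

#' Simulate a presence sequence
#'
#' Draws a two-state Markov chain of length `n_segments` (states: reef
#' present / absent), then independently replaces entries by missing at
#' `missing_rate` (or in bursts when `missing_mode = "burst"`).
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed.
#' @return Integer vector over `{0, 1, NA}`.
#' @export
#' @examples
#' table(simulate_presence(simulation_config(n_segments = 500), seed = 1),
#'       useNA = "ifany")
simulate_presence <- function(config = simulation_config(), seed = NULL) {
  validate_simulation_config(config)
  with_seed_if(seed, {
    n <- config$n_segments
    a <- config$stay_prob_presence
    b <- config$stay_prob_absence
    x <- integer(n)
    x[1] <- as.integer(runif(1) < (config$initial_presence_prob %||%
                                     stationary_prevalence(config)))
    u <- runif(n)
    for (i in seq_len(n)[-1]) {
      x[i] <- if (x[i - 1] == 1L) as.integer(u[i] < a)
        else as.integer(u[i] >= b)
    }
    miss <- simulate_missing_mask(config, n)
    x[miss] <- NA_integer_
    x
  })
}

simulate_missing_mask <- function(config, n) {
  if (config$missing_rate == 0) return(logical(n))
  if (config$missing_mode == "iid") {
    return(runif(n) < config$missing_rate)
  }
  # burst mode: two-state chain over (missing, visible) with mean missing
  # run length L and stationary missing probability = missing_rate
  L <- config$missing_burst_len
  p_stay_miss <- 1 - 1 / L
  r <- config$missing_rate
  # (1 - p_stay_vis) solves r = q / (q + 1/L) with q = P(vis -> miss)
  q <- r / (L * (1 - r))
  m <- logical(n)
  m[1] <- runif(1) < r
  u <- runif(n)
  for (i in seq_len(n)[-1]) {
    m[i] <- if (m[i - 1]) u[i] < p_stay_miss else u[i] < q
  }
  m
}

#' Simulate scored transects
#'
#' `simulate_transect()` builds one full segment table: presence from
#' [simulate_presence()], cover and elevation drawn from the configured
#' distributions for presence segments, cover 0 for absence segments,
#' `quality = "unusable"` for missing segments, and status classes assigned
#' through the reef structure matrix. `simulate_transects()` generates
#' several tows (`tow_id` `"T1"`, `"T2"`, ...) with per-tow sub-seeds
#' derived from the master seed, and binds them into one table.
#'
#' @param config A [simulation_config()].
#' @param tow_id,study_area Labels for the output table.
#' @param segment_duration_s Seconds per segment (default 5).
#' @param seed Optional integer seed; identical seed and config give a
#'   bitwise-identical table.
#' @param matrix A [reef_status_matrix()].
#' @param n_tows Number of tows to generate.
#' @return A scored segment table.
#' @export
#' @examples
#' simulate_transect(simulation_config(n_segments = 24), seed = 42)
simulate_transect <- function(config = simulation_config(), tow_id = "T1",
                              study_area = "A", segment_duration_s = 5,
                              seed = NULL, matrix = reef_status_matrix()) {
  validate_simulation_config(config)
  with_seed_if(seed, {
    presence <- simulate_presence(config)
    n <- length(presence)
    cover <- rep(NA_real_, n)
    elev <- rep(NA_real_, n)
    on <- !is.na(presence) & presence == 1L
    off <- !is.na(presence) & presence == 0L
    cover[off] <- 0
    if (any(on)) {
      cover[on] <- pmin(100, pmax(1e-9, config$cover_fn(sum(on))))
      elev[on] <- pmax(0, config$elevation_fn(sum(on)))
    }
    out <- tibble(
      tow_id = tow_id,
      study_area = study_area,
      segment_index = seq_len(n) - 1L,
      start_time_s = (seq_len(n) - 1L) * segment_duration_s,
      quality = ifelse(is.na(presence), "unusable", "ok"),
      cover_pct = cover,
      elevation_cm = elev
    )
    score_segments(out, matrix)
  })
}

#' @rdname simulate_transect
#' @export
simulate_transects <- function(n_tows, config = simulation_config(),
                               seed = NULL, study_area = "A",
                               segment_duration_s = 5,
                               matrix = reef_status_matrix()) {
  ids <- paste0("T", seq_len(n_tows))
  purrr::map_dfr(ids, function(tw) {
    simulate_transect(
      config, tow_id = tw, study_area = study_area,
      segment_duration_s = segment_duration_s,
      seed = if (is.null(seed)) NULL else tow_seed(seed, tw),
      matrix = matrix
    )
  })
}
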
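#' Per-tow condition and patchiness summary
#'
#' Condenses a classified segment table into one row per tow in the layout
#' used for reef condition reporting: the percentage of usable (non-missing)
#' segments in each status class, the number of patches, mean and median
#' patch length, the patch size range, and the true-patchiness statistic K
#' with its permutation p-value.
#'
#' Percentages are over non-missing segments and sum to 100. Patch
#' statistics come from [patch_sizes()] on the cleaned presence sequence;
#' K and the p-value from [k_statistic()]. When the presence sequence is
#' degenerate (all presence or all absence), the summary row is still
#' returned with the affected fields `NA` and a warning is raised.
#'
#' @param data A scored segment table (see [score_segments()]), one or many
#'   tows.
#' @param n_randomizations Randomizations for the K null (default 1,000).
#' @param seed Optional integer master seed; each tow gets a deterministic
#'   sub-seed derived from `(seed, tow_id)` so per-tow results do not depend
#'   on which other tows are in the table.
#' @param tie_corrected Passed to [k_statistic()].
#' @param order_by How to order the output rows: `"max_patch"` (descending
#'   largest patch, the conventional report order), `"tow_id"`, or `"none"`
#'   (input order).
#' @return A tibble with columns `tow_id`, `n_segments`, `n_missing`,
#'   `pct_no_reef`, `pct_not_reef`, `pct_low`, `pct_medium`, `pct_high`,
#'   `n_patches`, `mean_patch_len`, `median_patch_len`, `patch_size_min`,
#'   `patch_size_max`, `k`, `p_value`.
#' @export
#' @examples
#' simulate_transects(2, seed = 7) |>
#'   summarize_tows(n_randomizations = 200, seed = 7)
summarize_tows <- function(data, n_randomizations = 1000, seed = NULL,
                           tie_corrected = FALSE,
                           order_by = c("max_patch", "tow_id", "none")) {
  order_by <- match.arg(order_by)
  if (nrow(data) == 0) abort("empty segment table")
  if (!all(c("presence", "status") %in% names(data)))
    abort("segments must be scored first (see score_segments())")

  out <- data |>
    dplyr::group_by(.data$tow_id) |>
    dplyr::group_map(function(g, key) {
      summarize_one_tow(g, key$tow_id[[1]], n_randomizations,
                        if (is.null(seed)) NULL
                        else tow_seed(seed, key$tow_id[[1]]),
                        tie_corrected)
    }) |>
    dplyr::bind_rows()
  switch(order_by,
    max_patch = dplyr::arrange(out, dplyr::desc(
      tidyr::replace_na(.data$patch_size_max, 0L))),
    tow_id = dplyr::arrange(out, .data$tow_id),
    none = out
  )
}

summarize_one_tow <- function(g, tow_id, n_randomizations, seed,
                              tie_corrected) {
  usable <- !is.na(g$presence)
  n_usable <- sum(usable)
  pct <- function(class) {
    if (n_usable == 0) return(NA_real_)
    100 * sum(as.character(g$status[usable]) == class) / n_usable
  }
  presence <- g$presence
  sizes <- if (n_usable > 0) patch_sizes(clean_presence(presence))
    else integer(0)

  k <- p_value <- NA_real_
  if (n_usable > 0) {
    cleaned <- clean_presence(presence)
    if (sum(cleaned) %in% c(0L, length(cleaned))) {
      warn(paste0("tow ", tow_id,
                  ": presence sequence is degenerate; K not computed"))
    } else {
      ks <- k_statistic(cleaned, n_randomizations = n_randomizations,
                        seed = seed, tie_corrected = tie_corrected,
                        keep_null = FALSE)
      k <- ks$k
      p_value <- ks$p_value
    }
  }
  tibble(
    tow_id = tow_id,
    n_segments = nrow(g),
    n_missing = sum(!usable),
    pct_no_reef = pct("NoReef"),
    pct_not_reef = pct("NotAReef"),
    pct_low = pct("Low"),
    pct_medium = pct("Medium"),
    pct_high = pct("High"),
    n_patches = length(sizes),
    mean_patch_len = if (length(sizes)) mean(sizes) else NA_real_,
    median_patch_len = if (length(sizes)) stats::median(sizes) else NA_real_,
    patch_size_min = if (length(sizes)) min(sizes) else NA_integer_,
    patch_size_max = if (length(sizes)) max(sizes) else NA_integer_,
    k = k,
    p_value = p_value
  )
}

#' Write tow summaries and per-tow JSON reports
#'
#' `write_tow_summary()` writes the [summarize_tows()] table as CSV.
#' `write_tow_reports()` writes one machine-readable JSON report per tow
#' (full [k_statistic()] output, optionally including the randomized null
#' means) into a directory.
#'
#' @param summary A [summarize_tows()] tibble.
#' @param path Output CSV path.
#' @param data A scored segment table.
#' @param dir Output directory for JSON reports (created if needed).
#' @param keep_null Include the `null_means` vector in each report.
#' @inheritParams summarize_tows
#' @return The written path(s), invisibly.
#' @export
write_tow_summary <- function(summary, path) {
  readr::write_csv(summary, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_tow_summary
#' @export
write_tow_reports <- function(data, dir, n_randomizations = 1000,
                              seed = NULL, tie_corrected = FALSE,
                              keep_null = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tows <- unique(data$tow_id)
  paths <- purrr::map_chr(tows, function(tw) {
    g <- data[data$tow_id == tw, ]
    sub_seed <- if (is.null(seed)) NULL else tow_seed(seed, tw)
    report <- tryCatch({
      ks <- k_statistic(g$presence, n_randomizations = n_randomizations,
                        seed = sub_seed, tie_corrected = tie_corrected,
                        keep_null = keep_null)
      c(list(tow_id = tw), unclass(ks))
    }, error = function(e) {
      list(tow_id = tw, error = conditionMessage(e))
    })
    p <- file.path(dir, paste0(tw, ".json"))
    jsonlite::write_json(purrr::compact(report), p, auto_unbox = TRUE,
                         digits = NA, null = "null")
    p
  })
  invisible(paths)
}
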
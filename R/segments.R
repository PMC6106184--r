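#' Segment tables
#'
#' The unit of analysis is the scored 5-second video segment. A segment
#' table is a tibble with one row per segment and columns:
#'
#' * `tow_id` — tow (transect) label.
#' * `segment_index` — 0-based, contiguous within each tow.
#' * `start_time_s` — segment start, seconds from tow start.
#' * `quality` — `"ok"` or `"unusable"` (seabed obscured / footage unusable).
#' * `cover_pct` — percentage cover in `[0, 100]`; `NA` when unusable.
#' * `elevation_cm` — tube elevation; `NA` when unusable or cover is 0.
#' * `presence` — derived: `1` if cover > 0, `0` if cover = 0, `NA` if unusable.
#' * `status` — derived reef-status factor (see [classify_status()]).
#' * `lon`, `lat` — optional positions.
#'
#' `as_segment_table()` validates a data frame against this schema and
#' re-derives `presence` and `status` (they are pure functions of
#' `cover_pct`, `elevation_cm` and `quality` and are never trusted from
#' input). `score_segments()` is the pipe-friendly verb that adds or
#' refreshes the two derived columns.
#'
#' @param data A data frame with at least `tow_id`, `segment_index`,
#'   `quality`, `cover_pct`, `elevation_cm`.
#' @param matrix A [reef_status_matrix()].
#' @return A tibble with the full segment schema.
#' @export
#' @examples
#' tibble::tibble(
#'   tow_id = "T1", segment_index = 0:2, quality = "ok",
#'   cover_pct = c(0, 50, 15), elevation_cm = c(NA, 12, 3)
#' ) |>
#'   score_segments()
as_segment_table <- function(data, matrix = reef_status_matrix()) {
  needed <- c("tow_id", "segment_index", "quality", "cover_pct", "elevation_cm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    abort(paste0("segment table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("segment table is empty")
  if (!all(data$quality %in% c("ok", "unusable")))
    abort("`quality` must be \"ok\" or \"unusable\"")
  if (!("start_time_s" %in% names(data))) data$start_time_s <- NA_real_

  data <- dplyr::mutate(
    data,
    tow_id = as.character(.data$tow_id),
    segment_index = as.integer(.data$segment_index),
    cover_pct = as.numeric(.data$cover_pct),
    elevation_cm = as.numeric(.data$elevation_cm)
  )
  bad_idx <- data |>
    dplyr::group_by(.data$tow_id) |>
    dplyr::summarise(
      ok = all(.data$segment_index == seq(0L, dplyr::n() - 1L)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_idx))
    abort(paste0("segment_index must run 0,1,2,... within tow(s): ",
                 paste(bad_idx$tow_id, collapse = ", ")))
  usable <- data$quality == "ok"
  if (any(usable & is.na(data$cover_pct)))
    abort("quality=ok segments must have cover_pct")
  if (any(!is.na(data$cover_pct) &
          (data$cover_pct < 0 | data$cover_pct > 100)))
    abort("cover_pct out of [0, 100]")
  if (any(!is.na(data$elevation_cm) & data$elevation_cm < 0))
    abort("elevation_cm must be >= 0")
  data <- score_segments(data, matrix)
  canonical <- c("tow_id", "segment_index", "start_time_s", "quality",
                 "cover_pct", "elevation_cm", "presence", "status",
                 "lon", "lat")
  data[c(intersect(canonical, names(data)),
         setdiff(names(data), canonical))]
}

#' @rdname as_segment_table
#' @export
score_segments <- function(data, matrix = reef_status_matrix()) {
  data <- as_tibble(data)
  usable <- data$quality == "ok"
  cover <- ifelse(usable, data$cover_pct, NA_real_)
  elev <- ifelse(usable, data$elevation_cm, NA_real_)
  data$presence <- ifelse(is.na(cover), NA_integer_, as.integer(cover > 0))
  data$status <- classify_status(cover, elev, matrix)
  data$status[!usable] <- "Missing"
  data
}

#' Read and write segment tables as CSV
#'
#' One row per segment with the header
#' `tow_id,segment_index,start_time_s,quality,cover_pct,elevation_cm,presence,status,lon,lat`
#' (`lon`/`lat` optional, empty cell = absent, UTF-8, "." decimal separator).
#' `read_segments()` re-derives `presence` and `status` so that a table
#' written and read back is identical to the one in memory.
#'
#' @param path CSV file path.
#' @param data A segment table.
#' @param matrix A [reef_status_matrix()] used to re-derive `status`.
#' @return `read_segments()` a segment tibble; `write_segments()` `path`,
#'   invisibly.
#' @export
read_segments <- function(path, matrix = reef_status_matrix()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  parsers <- list(
    tow_id = readr::col_character(),
    segment_index = readr::col_integer(),
    quality = readr::col_character(),
    cover_pct = readr::col_double(),
    elevation_cm = readr::col_double(),
    presence = readr::col_integer(),
    status = readr::col_character()
  )
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  spec <- do.call(readr::cols, c(parsers[intersect(names(parsers), header)],
                                 .default = list(readr::col_double())))
  data <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if (nrow(data) == 0) abort(paste0("no segment rows in ", path))
  as_segment_table(data, matrix)
}

#' @rdname read_segments
#' @export
write_segments <- function(data, path) {
  cols <- intersect(
    c("tow_id", "segment_index", "start_time_s", "quality", "cover_pct",
      "elevation_cm", "presence", "status", "lon", "lat"),
    names(data)
  )
  out <- data[cols]
  out$status <- as.character(out$status)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Normalize a segment's cover estimate over fields of view
#'
#' Percentage cover is estimated once per newly observed area of seabed
#' within a segment; the segment's cover is the summed estimate divided by
#' the number of new fields of view, clamped to `[0, 100]`.
#'
#' @param view_estimates Numeric vector of per-view cover estimates, each in
#'   `[0, 100]`.
#' @param n_new_views Positive integer count of new fields of view.
#' @return A single percentage in `[0, 100]`.
#' @export
#' @examples
#' normalize_cover(c(60, 20), 2)
normalize_cover <- function(view_estimates, n_new_views) {
  if (length(n_new_views) != 1 || is.na(n_new_views) || n_new_views < 1)
    abort("`n_new_views` must be a single integer >= 1 (an unviewable segment should be quality = \"unusable\")")
  v <- as.numeric(view_estimates)
  if (any(is.na(v)) || any(v < 0 | v > 100))
    abort("view estimates must be percentages in [0, 100]")
  min(100, max(0, sum(v) / n_new_views))
}

#' Read an annotation log
#'
#' An annotation log is the raw per-event record an analyst produces before
#' binning: columns `time_s` (seconds from tow start), `kind` (one of
#' `cover_estimate`, `elevation_estimate`, `new_field_of_view`,
#' `quality_flag`) and `value` (a number for estimates; the flag payload,
#' e.g. `"unusable"`, for quality flags).
#'
#' @param path CSV file path.
#' @return A tibble with columns `time_s`, `kind`, `value` (character).
#' @export
read_annotations <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      time_s = readr::col_double(),
      kind = readr::col_character(),
      value = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(data) == 0) abort(paste0("no annotation rows in ", path))
  data
}

#' Bin raw annotations into fixed-duration segments
#'
#' Splits a tow of `tow_duration_s` seconds into contiguous half-open
#' intervals `[k d, (k+1) d)` of `segment_duration_s = d` seconds (0-based
#' `segment_index`); the final segment may be shorter and is kept when it is
#' at least 1 s long. Each event belongs to the interval containing its
#' time. Per segment, cover is [normalize_cover()] over the segment's cover
#' estimates and its count of `new_field_of_view` events (defaulting to one
#' view per cover estimate when no view events were logged); elevation is
#' the mean of elevation estimates (0 cm when cover is positive but no
#' elevation was measurable). A segment carrying an `unusable` quality flag,
#' or no cover estimate at all, is `quality = "unusable"`.
#'
#' @param events Annotation tibble as from [read_annotations()], sorted by
#'   `time_s`.
#' @param tow_duration_s Total tow duration, seconds.
#' @param segment_duration_s Segment length, seconds (default 5).
#' @param tow_id Tow label for the output table.
#' @param matrix A [reef_status_matrix()].
#' @return A scored segment table ([as_segment_table()] schema).
#' @export
#' @examples
#' events <- tibble::tibble(
#'   time_s = c(0, 7), kind = "cover_estimate", value = c("40", "0")
#' )
#' bin_annotations(events, tow_duration_s = 10, segment_duration_s = 5)
bin_annotations <- function(events, tow_duration_s, segment_duration_s = 5,
                            tow_id = "tow", matrix = reef_status_matrix()) {
  if (!all(c("time_s", "kind", "value") %in% names(events)))
    abort("events must have columns time_s, kind, value")
  if (tow_duration_s <= 0) abort("tow_duration_s must be > 0")
  if (segment_duration_s <= 0) abort("segment_duration_s must be > 0")
  t <- as.numeric(events$time_s)
  if (any(is.na(t)) || any(t < 0)) abort("event times must be >= 0")
  if (is.unsorted(t)) abort("events must be sorted by time_s")
  if (any(t >= tow_duration_s))
    abort("event time at or beyond tow_duration_s")

  n_seg <- ceiling(tow_duration_s / segment_duration_s)
  # drop a trailing sliver shorter than 1 s
  if (n_seg > 1 && tow_duration_s - (n_seg - 1) * segment_duration_s < 1)
    n_seg <- n_seg - 1
  seg_of <- pmin(n_seg - 1L, floor(t / segment_duration_s))

  per_segment <- function(k) {
    ev <- events[seg_of == k, ]
    flagged <- any(ev$kind == "quality_flag" &
                     tolower(ev$value) == "unusable")
    covers <- suppressWarnings(
      as.numeric(ev$value[ev$kind == "cover_estimate"]))
    elevs <- suppressWarnings(
      as.numeric(ev$value[ev$kind == "elevation_estimate"]))
    n_views <- sum(ev$kind == "new_field_of_view")
    if (flagged || length(covers) == 0) {
      tibble(quality = "unusable", cover_pct = NA_real_,
             elevation_cm = NA_real_)
    } else {
      cover <- normalize_cover(covers, max(n_views, length(covers)))
      elev <- if (cover == 0) NA_real_
        else if (length(elevs)) mean(elevs) else 0
      tibble(quality = "ok", cover_pct = cover, elevation_cm = elev)
    }
  }

  scored <- purrr::map_dfr(seq_len(n_seg) - 1L, per_segment)
  out <- dplyr::bind_cols(
    tibble(
      tow_id = tow_id,
      segment_index = seq_len(n_seg) - 1L,
      start_time_s = (seq_len(n_seg) - 1L) * segment_duration_s
    ),
    scored
  )
  as_segment_table(out, matrix)
}

#' Broad-scale habitat sections of a tow
#'
#' Collapses per-segment habitat labels into broad-scale sections: maximal
#' runs of an identical label, with any run shorter than `min_duration_s`
#' (default 60 s, i.e. habitat changes must persist for more than a minute
#' to count) merged into the preceding section and recorded as an
#' incidental patch. The first run is always kept as a section.
#'
#' @param data A segment table for one tow with a `habitat` character column.
#' @param min_duration_s Minimum persistence for a section, seconds.
#' @param segment_duration_s Seconds per segment.
#' @return A tibble of sections (`habitat`, `start_index`, `end_index`,
#'   `n_segments`, `duration_s`) with an `"incidental"` attribute tibble
#'   listing the merged sub-minute patches (`habitat`, `start_index`,
#'   `end_index`, `merged_into`).
#' @export
broadscale_segments <- function(data, min_duration_s = 60,
                                segment_duration_s = 5) {
  if (nrow(data) == 0) abort("empty segment table")
  if (!"habitat" %in% names(data))
    abort("broad-scale segmentation needs a `habitat` column")
  if (length(unique(data$tow_id)) > 1)
    abort("broadscale_segments() works on a single tow")

  r <- rle(as.character(data$habitat))
  ends <- cumsum(r$lengths)
  runs <- tibble(
    habitat = r$values,
    start_index = c(0L, head(ends, -1)),
    end_index = ends - 1L,
    n_segments = r$lengths
  )
  runs$duration_s <- runs$n_segments * segment_duration_s

  keep <- runs$duration_s >= min_duration_s
  keep[1] <- TRUE
  # a segment straddling a change is owned by its own run (majority-time
  # assignment happens upstream when labels are attached per segment)
  section_of <- cumsum(keep)
  incidental <- runs[!keep, c("habitat", "start_index", "end_index")]
  incidental$merged_into <- section_of[!keep]

  sections <- runs |>
    dplyr::mutate(section = section_of) |>
    dplyr::group_by(.data$section) |>
    dplyr::summarise(
      habitat = dplyr::first(.data$habitat),
      start_index = min(.data$start_index),
      end_index = max(.data$end_index),
      n_segments = sum(.data$n_segments),
      duration_s = sum(.data$duration_s),
      .groups = "drop"
    ) |>
    dplyr::select(-"section")
  # absorbing an incidental run can leave two same-label sections adjacent;
  # coalesce them so sections are maximal
  sections <- sections |>
    dplyr::mutate(block = cumsum(
      c(TRUE, .data$habitat[-1] != head(.data$habitat, -1)))) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      habitat = dplyr::first(.data$habitat),
      start_index = min(.data$start_index),
      end_index = max(.data$end_index),
      n_segments = sum(.data$n_segments),
      duration_s = sum(.data$duration_s),
      .groups = "drop"
    ) |>
    dplyr::select(-"block")
  attr(sections, "incidental") <- incidental
  sections
}

#' Export a segment table as GeoJSON
#'
#' Writes one `LineString` feature per tow (through the segment positions)
#' plus one `Point` feature per segment carrying `tow_id`, `segment_index`,
#' `status`, `cover_pct` and `elevation_cm` properties. Rows without
#' positions are skipped.
#'
#' @param data A segment table with `lon` and `lat` columns.
#' @param path Output file; if `NULL`, the GeoJSON list is returned instead.
#' @return `path` invisibly, or the GeoJSON structure when `path` is `NULL`.
#' @export
segments_geojson <- function(data, path = NULL) {
  if (!all(c("lon", "lat") %in% names(data)))
    abort("GeoJSON export needs `lon` and `lat` columns")
  pos <- data[!is.na(data$lon) & !is.na(data$lat), ]
  if (nrow(pos) == 0) abort("no positioned segments to export")

  lines <- pos |>
    dplyr::group_by(.data$tow_id) |>
    dplyr::group_map(function(g, key) {
      list(
        type = "Feature",
        geometry = list(
          type = "LineString",
          coordinates = unname(purrr::map2(g$lon, g$lat, c))
        ),
        properties = list(tow_id = key$tow_id[[1]])
      )
    })
  points <- purrr::pmap(
    list(pos$lon, pos$lat, pos$tow_id, pos$segment_index,
         as.character(pos$status), pos$cover_pct, pos$elevation_cm),
    function(lon, lat, tow, idx, status, cover, elev) {
      list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(lon, lat)),
        properties = list(
          tow_id = tow, segment_index = idx, status = status,
          cover_pct = cover, elevation_cm = elev
        )
      )
    }
  )
  gj <- list(type = "FeatureCollection", features = c(lines, points))
  if (is.null(path)) return(gj)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Trim a tow to start at the first reef observation
#'
#' Survey-design option for comparability between tows: drops every leading
#' segment before the first presence (`cover_pct > 0`) segment, so analysis
#' begins where reef aggregations are first observed.
#'
#' @param data A scored segment table.
#' @return The trimmed segment table, with `segment_index` and
#'   `start_time_s` rebased per tow.
#' @export
trim_to_first_presence <- function(data) {
  data |>
    dplyr::group_by(.data$tow_id) |>
    dplyr::group_modify(function(g, key) {
      first <- which(!is.na(g$presence) & g$presence == 1L)[1]
      if (is.na(first)) return(g[0, ])
      g <- g[first:nrow(g), ]
      g$segment_index <- seq(0L, nrow(g) - 1L)
      if ("start_time_s" %in% names(g))
        g$start_time_s <- g$start_time_s - g$start_time_s[1]
      g
    }) |>
    dplyr::ungroup()
}
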
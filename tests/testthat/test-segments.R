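test_that("cover normalization averages over new fields of view", {
  expect_equal(normalize_cover(c(60, 20), 2), 40)
  expect_equal(normalize_cover(35, 1), 35)
  expect_equal(normalize_cover(c(100, 100, 100), 3), 100)
  expect_error(normalize_cover(c(60, 20), 0), "unusable")
  expect_error(normalize_cover(c(60, 120), 2), "\\[0, 100\\]")
})

test_that("a 10-minute tow bins into 120 five-second segments", {
  events <- tibble::tibble(
    time_s = seq(0, 595, by = 5), kind = "cover_estimate", value = "10"
  )
  segs <- bin_annotations(events, tow_duration_s = 600)
  expect_equal(nrow(segs), 120)
  expect_equal(segs$segment_index, 0:119)
  expect_equal(segs$start_time_s, seq(0, 595, by = 5))
  expect_true(all(segs$quality == "ok"))
})

test_that("events land in the half-open interval containing their time", {
  events <- tibble::tibble(
    time_s = c(0, 7), kind = "cover_estimate", value = c("40", "0")
  )
  segs <- bin_annotations(events, tow_duration_s = 10, segment_duration_s = 5)
  expect_equal(segs$presence, c(1L, 0L))
  expect_equal(segs$cover_pct, c(40, 0))
  # t = 5 belongs to segment 1, not segment 0
  events2 <- tibble::tibble(
    time_s = c(0, 5), kind = "cover_estimate", value = c("0", "40")
  )
  segs2 <- bin_annotations(events2, 10, 5)
  expect_equal(segs2$presence, c(0L, 1L))
})

test_that("binning flags unusable segments and validates event streams", {
  events <- tibble::tibble(
    time_s = c(1, 2, 6),
    kind = c("cover_estimate", "quality_flag", "elevation_estimate"),
    value = c("40", "unusable", "5")
  )
  segs <- bin_annotations(events, tow_duration_s = 10)
  # segment 0 is flagged unusable despite its cover estimate;
  # segment 1 has no cover estimate at all
  expect_equal(segs$quality, c("unusable", "unusable"))
  expect_equal(segs$presence, c(NA_integer_, NA_integer_))
  expect_equal(as.character(segs$status), c("Missing", "Missing"))

  unsorted <- tibble::tibble(
    time_s = c(7, 0), kind = "cover_estimate", value = c("1", "2"))
  expect_error(bin_annotations(unsorted, 10), "sorted")
  negative <- tibble::tibble(
    time_s = -1, kind = "cover_estimate", value = "1")
  expect_error(bin_annotations(negative, 10), ">= 0")
})

test_that("cover divides by view count and elevation defaults sensibly", {
  events <- tibble::tibble(
    time_s = c(0, 1, 2, 3),
    kind = c("new_field_of_view", "cover_estimate", "new_field_of_view",
             "cover_estimate"),
    value = c("", "60", "", "20")
  )
  segs <- bin_annotations(events, tow_duration_s = 5)
  expect_equal(segs$cover_pct, 40)
  # positive cover but no measurable tubes records 0 cm (-> NotAReef)
  expect_equal(segs$elevation_cm, 0)
  expect_equal(as.character(segs$status), "NotAReef")
})

test_that("a trailing sliver under one second is dropped", {
  events <- tibble::tibble(time_s = 0, kind = "cover_estimate", value = "10")
  expect_equal(nrow(bin_annotations(events, tow_duration_s = 10.5)), 2)
  expect_equal(nrow(bin_annotations(events, tow_duration_s = 12)), 3)
})

test_that("segment tables round-trip through CSV byte-identically", {
  segs <- tiny_tow()
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_equal(back, segs)
})

test_that("presence and status are re-derived, never trusted from input", {
  raw <- tiny_tow()
  raw$presence <- c(1L, 0L, 1L, 0L) # deliberately corrupted
  raw$status <- factor("High", levels = status_levels())
  fixed <- as_segment_table(raw)
  expect_equal(fixed$presence, c(0L, 1L, NA, 1L))
  expect_equal(as.character(fixed$status),
               c("NoReef", "High", "Missing", "Low"))
})

test_that("schema violations are rejected with informative errors", {
  expect_error(as_segment_table(tibble::tibble(tow_id = "T")), "lacks")
  bad_idx <- tibble::tibble(
    tow_id = "T", segment_index = c(0, 2), quality = "ok",
    cover_pct = c(1, 1), elevation_cm = c(3, 3)
  )
  expect_error(as_segment_table(bad_idx), "segment_index")
  bad_quality <- tibble::tibble(
    tow_id = "T", segment_index = 0, quality = "meh",
    cover_pct = 1, elevation_cm = 3
  )
  expect_error(as_segment_table(bad_quality), "quality")
  no_cover <- tibble::tibble(
    tow_id = "T", segment_index = 0, quality = "ok",
    cover_pct = NA_real_, elevation_cm = 3
  )
  expect_error(as_segment_table(no_cover), "cover_pct")
})

test_that("broad-scale sections keep >1 min runs and flag short ones", {
  tow <- function(labels) {
    tibble::tibble(
      tow_id = "T", segment_index = seq_along(labels) - 1L,
      quality = "ok", cover_pct = 0, elevation_cm = NA_real_,
      habitat = labels
    ) |> as_segment_table()
  }
  # 200 s X then 300 s Y -> two sections
  two <- broadscale_segments(tow(c(rep("X", 40), rep("Y", 60))))
  expect_equal(two$habitat, c("X", "Y"))
  expect_equal(two$n_segments, c(40L, 60L))

  # 200 s X, 30 s Y, 200 s X -> one X section, Y incidental
  merged <- broadscale_segments(tow(c(rep("X", 40), rep("Y", 6), rep("X", 40))))
  expect_equal(merged$habitat, "X")
  expect_equal(merged$n_segments, 86L)
  inc <- attr(merged, "incidental")
  expect_equal(inc$habitat, "Y")
  expect_equal(inc$start_index, 40L)
  expect_equal(inc$end_index, 45L)

  # uniform label -> one section spanning the tow
  uniform <- broadscale_segments(tow(rep("X", 50)))
  expect_equal(nrow(uniform), 1)
  expect_equal(uniform$n_segments, 50L)

  # a short first run is kept (never merged backwards into nothing)
  shortfirst <- broadscale_segments(tow(c(rep("Y", 5), rep("X", 40))))
  expect_equal(shortfirst$habitat, c("Y", "X"))
})

test_that("GeoJSON export writes one line per tow plus one point per segment", {
  segs <- dplyr::bind_rows(tiny_tow("T1"), tiny_tow("T2"))
  path <- withr::local_tempfile(fileext = ".geojson")
  segments_geojson(segs, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  types <- vapply(gj$features, function(f) f$geometry$type, character(1))
  expect_equal(sum(types == "LineString"), 2)
  expect_equal(sum(types == "Point"), 8)
  pt <- gj$features[[which(types == "Point")[2]]]
  expect_equal(pt$properties$status, "High")
  expect_equal(pt$properties$cover_pct, 50)
})

test_that("trimming to first presence drops leading absence and rebases", {
  segs <- tibble::tibble(
    tow_id = "T", segment_index = 0:4, quality = "ok",
    cover_pct = c(0, 0, 30, 0, 10), elevation_cm = c(NA, NA, 3, NA, 3)
  ) |> as_segment_table()
  trimmed <- trim_to_first_presence(segs)
  expect_equal(nrow(trimmed), 3)
  expect_equal(trimmed$segment_index, 0:2)
  expect_equal(trimmed$presence, c(1L, 0L, 1L))
})
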
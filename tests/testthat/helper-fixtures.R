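# small fixtures built in code

tow_seed_for_test <- function(seed, tow_id) reefpatch:::tow_seed(seed, tow_id)

# the printed worked-example sequences
worked_seq <- c(1, 0, 0, 1, 1, 1, 0, 0, 1, 1, 0)
worked_seq_missing <- c(0, 1, NA, 1, 1, 0)

# a hand-built three-segment tow covering all quality branches
tiny_tow <- function(tow_id = "T1") {
  tibble::tibble(
    tow_id = tow_id,
    segment_index = 0:3,
    start_time_s = c(0, 5, 10, 15),
    quality = c("ok", "ok", "unusable", "ok"),
    cover_pct = c(0, 50, NA, 15),
    elevation_cm = c(NA, 12, NA, 3),
    lon = c(1.1, 1.2, 1.3, 1.4),
    lat = c(53.1, 53.2, 53.3, 53.4)
  ) |> reefpatch::as_segment_table()
}

# independent reference: mean patch size by scanning the vector directly,
# written without rle() so it does not share code with patch_sizes()
ref_patch_sizes <- function(x) {
  sizes <- integer(0)
  run <- 0L
  for (v in x) {
    if (v == 1L) {
      run <- run + 1L
    } else if (run > 0L) {
      sizes <- c(sizes, run)
      run <- 0L
    }
  }
  if (run > 0L) sizes <- c(sizes, run)
  sizes
}

# independent reference null: enumerate arrangements via recursion over
# 0/1 strings (not combn), so exact_null() has a second, separate oracle
ref_exact_null <- function(x) {
  n <- length(x)
  k <- sum(x)
  seqs <- list(integer(0))
  for (i in seq_len(n)) {
    seqs <- c(lapply(seqs, c, 0L), lapply(seqs, c, 1L))
  }
  seqs <- Filter(function(s) sum(s) == k, seqs)
  means <- vapply(seqs, function(s) mean(ref_patch_sizes(s)), numeric(1))
  p_o <- mean(ref_patch_sizes(x))
  list(p_r = mean(means), p_value = mean(means > p_o),
       n_arrangements = length(seqs))
}
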
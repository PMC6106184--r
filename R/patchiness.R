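#' Presence sequences and their cleaning
#'
#' Along-transect patchiness works on the per-segment presence variable:
#' 1 where reef cover was positive, 0 where cover was zero, `NA` where the
#' segment was unusable (seabed obscured). `clean_presence()` applies the
#' missing-value rule: missing entries are deleted and the remainder
#' concatenated in order, so a gap between two presence runs bridges them
#' into one patch.
#'
#' `parse_presence()` reads a compact sequence literal such as
#' `"10011100110"` or `"01.110"` (any of `.`, `*`, `N` marks a missing
#' value); `format_presence()` is its inverse.
#'
#' @param x Presence values: an integer/numeric vector over `{0, 1, NA}`,
#'   or for `parse_presence()` a single string.
#' @param missing_chars Characters accepted as missing markers.
#' @return `clean_presence()`: integer vector over `{0, 1}`.
#'   `parse_presence()`: integer vector over `{0, 1, NA}`.
#'   `format_presence()`: a string.
#' @export
#' @examples
#' clean_presence(c(0, 1, NA, 1, 1, 0))
#' parse_presence("01.110")
clean_presence <- function(x) {
  x <- check_presence(x)
  out <- x[!is.na(x)]
  if (length(out) == 0) abort("no usable segments: presence is all missing")
  out
}

#' @rdname clean_presence
#' @export
parse_presence <- function(x, missing_chars = c(".", "*", "N")) {
  stopifnot(is.character(x), length(x) == 1)
  ch <- strsplit(gsub("[ ,]", "", x), "")[[1]]
  if (length(ch) == 0) abort("empty presence literal")
  bad <- !(ch %in% c("0", "1", missing_chars))
  if (any(bad))
    abort(paste0("unrecognized presence symbol(s): ",
                 paste(unique(ch[bad]), collapse = " ")))
  out <- rep(NA_integer_, length(ch))
  out[ch == "0"] <- 0L
  out[ch == "1"] <- 1L
  out
}

#' @rdname clean_presence
#' @export
format_presence <- function(x) {
  x <- check_presence(x)
  paste(ifelse(is.na(x), ".", as.character(x)), collapse = "")
}

check_presence <- function(x) {
  if (length(x) == 0) abort("presence sequence is empty")
  x <- as.integer(round(as.numeric(x)))
  if (!all(x %in% c(0L, 1L) | is.na(x)))
    abort("presence values must be 0, 1 or missing")
  x
}

check_binary <- function(x) {
  x <- check_presence(x)
  if (anyNA(x))
    abort("sequence still contains missing values; clean_presence() first")
  x
}

#' Extract patch sizes from a binary presence sequence
#'
#' A patch is a maximal run of consecutive 1s, ended by a 0 or by the end
#' of the sequence (so trailing presence still counts as a patch and the
#' patch sizes always sum to the number of presence segments).
#'
#' @param x Binary vector over `{0, 1}` with no missing values.
#' @return Integer vector of patch sizes in transect order (length 0 when
#'   no presence was observed).
#' @export
#' @examples
#' patch_sizes(c(1, 0, 0, 1, 1, 1, 0, 0, 1, 1, 0))
patch_sizes <- function(x) {
  x <- check_binary(x)
  r <- rle(x)
  as.integer(r$lengths[r$values == 1L])
}

#' @rdname patch_sizes
#' @export
n_patches <- function(x) length(patch_sizes(x))

#' Mean observed patch size
#'
#' @param sizes Integer vector of patch sizes, as from [patch_sizes()].
#' @return The arithmetic mean patch size, in segments.
#' @export
#' @examples
#' mean_patch_size(c(1, 3, 2))
mean_patch_size <- function(sizes) {
  if (length(sizes) == 0)
    abort("mean patch size undefined: no presence observed")
  mean(sizes)
}

# mean patch size of a binary vector without materialising rle():
# patches = 1s whose predecessor is 0 (or sequence start)
mean_patch_size_fast <- function(x) {
  k <- sum(x)
  starts <- sum(x == 1L & c(1L, x[-length(x)]) == 0L) + (x[1] == 1L)
  k / starts
}

#' Mean patch size under random arrangement
#'
#' Estimates `p_r`, the mean patch size expected if the presence
#' observations were randomly arranged along the transect, by randomizing
#' the cleaned binary sequence `n_randomizations` times (uniform
#' permutations, preserving the counts of 1s and 0s), computing the mean
#' patch size of each, and averaging.
#'
#' @param x Binary vector over `{0, 1}`; must contain at least one 1 and
#'   one 0 (a constant sequence has a degenerate null: every permutation is
#'   identical).
#' @param n_randomizations Number of random permutations (default 1,000).
#' @param seed Optional integer seed; the caller's RNG state is left
#'   untouched when it is supplied.
#' @return A list with `p_r` (the estimate) and `null_means` (the
#'   `n_randomizations` randomized mean patch sizes).
#' @export
#' @examples
#' randomized_null(c(1, 1, 0, 0, 1, 0), n_randomizations = 200, seed = 1)$p_r
randomized_null <- function(x, n_randomizations = 1000, seed = NULL) {
  x <- check_binary(x)
  if (n_randomizations < 1) abort("n_randomizations must be >= 1")
  k <- sum(x)
  if (k == 0 || k == length(x))
    abort("null degenerate: sequence is constant, all permutations identical")
  # permute a canonical arrangement of the multiset so that sequences with
  # the same counts of 1s and 0s share an identical null under a shared seed
  canon <- c(rep(1L, k), rep(0L, length(x) - k))
  null_means <- with_seed_if(seed, {
    vapply(seq_len(n_randomizations),
           function(i) mean_patch_size_fast(sample(canon)),
           numeric(1))
  })
  list(p_r = mean(null_means), null_means = null_means)
}

#' Exact enumeration null for small sequences
#'
#' Brute-force oracle for the randomization null: enumerates every distinct
#' arrangement of the sequence's 1s and 0s (each equally likely under
#' uniform permutation), giving the exact `p_r` and the exact
#' strictly-greater p-value. Only feasible for small sequences; the number
#' of distinct arrangements `choose(n, k)` must not exceed `cap`.
#'
#' @inheritParams randomized_null
#' @param cap Maximum number of arrangements to enumerate.
#' @return A list with `p_r` (exact), `p_value` (exact, strictly greater),
#'   `n_arrangements`, and `means` (mean patch size per arrangement).
#' @export
#' @examples
#' exact_null(c(1, 1, 0))$p_r # 5/3
exact_null <- function(x, cap = 1e6) {
  x <- check_binary(x)
  n <- length(x)
  k <- sum(x)
  if (k == 0 || k == n)
    abort("null degenerate: sequence is constant, all permutations identical")
  n_arr <- choose(n, k)
  if (n_arr > cap)
    abort(paste0("choose(", n, ", ", k, ") = ", n_arr,
                 " arrangements exceeds cap; use randomized_null()"))
  ones_at <- combn(n, k)
  # mean size = k / number of runs of ones; runs = gaps among sorted positions
  means <- apply(ones_at, 2, function(pos) {
    k / (1 + sum(diff(pos) > 1))
  })
  p_o <- mean_patch_size_fast(x)
  list(
    p_r = mean(means),
    p_value = mean(means > p_o),
    n_arrangements = n_arr,
    means = means
  )
}

#' The true-patchiness statistic K
#'
#' Quantifies the propensity of reef presence to be clustered along a
#' transect rather than arranged at random: `K = p_o / p_r`, where `p_o` is
#' the observed mean patch size and `p_r` the mean patch size under random
#' arrangement of the same presence counts ([randomized_null()]). `K > 1`
#' indicates patchiness. The permutation p-value tests the null hypothesis
#' of random arrangement and is the proportion of randomizations whose mean
#' patch size exceeds the observed value (strictly greater); the number of
#' ties is reported, and `tie_corrected = TRUE` switches to the
#' `(greater + ties + 1) / (n + 1)` variant.
#'
#' Missing values are deleted before both patch extraction and
#' randomization, so the null operates on the same cleaned string as the
#' observed statistic.
#'
#' @param x Presence sequence over `{0, 1, NA}` (cleaned internally).
#' @param n_randomizations Number of random permutations (default 1,000).
#' @param seed Optional integer seed for reproducibility.
#' @param tie_corrected Use the tie-and-identity corrected p-value instead
#'   of the plain strictly-greater proportion (default `FALSE`).
#' @param exact If `TRUE`, replace the randomized null with the exhaustive
#'   [exact_null()] (small sequences only).
#' @param keep_null Keep the vector of randomized means in the result.
#' @return An object of class `k_statistic`: a list with `p_o`, `p_r`, `k`,
#'   `p_value`, `p_value_mid` (the mid-p variant, ties counted half, which
#'   is the calibrated choice for this discrete statistic), `n_ties`,
#'   `n_randomizations`, `seed`, `patch_sizes`, `n_ones`, `n_zeros`,
#'   `n_missing`, and (if kept) `null_means`.
#' @seealso [tidy.k_statistic()], [glance.k_statistic()],
#'   [autoplot.k_statistic()]
#' @export
#' @examples
#' k_statistic(parse_presence("10011100110"), seed = 1)
k_statistic <- function(x, n_randomizations = 1000, seed = NULL,
                        tie_corrected = FALSE, exact = FALSE,
                        keep_null = TRUE) {
  raw <- check_presence(x)
  cleaned <- clean_presence(raw)
  k <- sum(cleaned)
  if (k == length(cleaned))
    abort("K undefined: reef present in every usable segment (no zeros)")
  if (k == 0)
    abort("K undefined: no reef presence in any usable segment")

  sizes <- patch_sizes(cleaned)
  p_o <- mean_patch_size(sizes)
  if (exact) {
    null <- exact_null(cleaned)
    null_means <- null$means
    n_rand <- null$n_arrangements
  } else {
    null <- randomized_null(cleaned, n_randomizations, seed)
    null_means <- null$null_means
    n_rand <- n_randomizations
  }
  n_greater <- sum(null_means > p_o)
  n_ties <- sum(null_means == p_o)
  p_value <- if (tie_corrected) {
    (n_greater + n_ties + 1) / (n_rand + 1)
  } else {
    n_greater / n_rand
  }
  structure(
    list(
      p_o = p_o,
      p_r = null$p_r,
      k = p_o / null$p_r,
      p_value = p_value,
      # mid-p: ties split evenly; the calibrated variant for the discrete
      # mean-patch-size statistic (see the methods vignette)
      p_value_mid = (n_greater + 0.5 * n_ties) / n_rand,
      tie_corrected = tie_corrected,
      n_ties = n_ties,
      n_randomizations = n_rand,
      exact = exact,
      seed = seed,
      patch_sizes = sizes,
      n_ones = k,
      n_zeros = length(cleaned) - k,
      n_missing = sum(is.na(raw)),
      null_means = if (keep_null) null_means
    ),
    class = "k_statistic"
  )
}

#' @export
print.k_statistic <- function(x, ...) {
  cat("True patchiness (randomization test)\n")
  cat(sprintf("  segments: %d present, %d absent, %d missing (excluded)\n",
              x$n_ones, x$n_zeros, x$n_missing))
  cat(sprintf("  patches:  %d (sizes %s)\n", length(x$patch_sizes),
              paste(x$patch_sizes, collapse = ", ")))
  cat(sprintf("  p_o = %.4g   p_r = %.4g (%s, n = %d)\n",
              x$p_o, x$p_r,
              if (x$exact) "exact enumeration" else "randomized",
              x$n_randomizations))
  cat(sprintf("  K = %.4g   p = %.4g%s\n", x$k, x$p_value,
              if (x$tie_corrected) " (tie-corrected)" else ""))
  invisible(x)
}

#' Tidy a K-statistic result
#'
#' `tidy()` returns one row per observed patch; `glance()` returns the
#' one-row model summary (`p_o`, `p_r`, `k`, `p_value`, counts).
#'
#' @param x A [k_statistic()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy k_statistic
#' @export
tidy.k_statistic <- function(x, ...) {
  tibble(
    patch = seq_along(x$patch_sizes),
    size = x$patch_sizes
  )
}

#' @rdname tidy.k_statistic
#' @method glance k_statistic
#' @export
glance.k_statistic <- function(x, ...) {
  tibble(
    p_o = x$p_o, p_r = x$p_r, k = x$k, p_value = x$p_value,
    n_patches = length(x$patch_sizes), n_ties = x$n_ties,
    n_ones = x$n_ones, n_zeros = x$n_zeros, n_missing = x$n_missing,
    n_randomizations = x$n_randomizations
  )
}
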
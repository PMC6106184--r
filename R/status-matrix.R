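#' The reef structure matrix
#'
#' A reef structure matrix maps a segment's percentage cover band and tube
#' elevation band to an ordinal reef-status class. The default is the
#' modified Gubbay-style matrix used for *Sabellaria spinulosa* condition
#' assessment: cover bands `<10`, `10-20`, `20-30`, `>30` (%) crossed with
#' elevation bands `<2`, `2-5`, `5-10`, `>10` (cm). Any segment with cover
#' below 10% or elevation below 2 cm is "Not a reef"; the remaining cells
#' grade Low / Medium / High. Zero cover is the separate class `NoReef`,
#' handled by [classify_status()] before the matrix is consulted.
#'
#' Band edges are left-closed, right-open (`[10, 20)` etc.), so a printed
#' band "10-20" owns its lower edge. Cover lives on `[0, 100]`, elevation on
#' `[0, Inf)`.
#'
#' @param cover_breaks Numeric vector of 5 increasing cover band edges,
#'   starting at 0 and ending at 100.
#' @param elevation_breaks Numeric vector of 5 increasing elevation band
#'   edges, starting at 0 and ending at `Inf`.
#' @param cells 4 x 4 character matrix of status classes, rows indexed by
#'   cover band (low to high), columns by elevation band (low to high).
#'   Entries must be among `"NotAReef"`, `"Low"`, `"Medium"`, `"High"` and
#'   non-decreasing along both rows and columns.
#' @return An object of class `reef_status_matrix`.
#' @seealso [classify_status()], [read_status_matrix()]
#' @export
#' @examples
#' m <- reef_status_matrix()
#' m$cells[">30%", ">10"]
reef_status_matrix <- function(cover_breaks = c(0, 10, 20, 30, 100),
                               elevation_breaks = c(0, 2, 5, 10, Inf),
                               cells = default_matrix_cells()) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  m <- structure(
    list(
      cover_breaks = as.numeric(cover_breaks),
      elevation_breaks = as.numeric(elevation_breaks),
      cells = cells
    ),
    class = "reef_status_matrix"
  )
  validate_status_matrix(m)
  m
}

default_matrix_cells <- function() {
  cells <- rbind(
    c("NotAReef", "NotAReef", "NotAReef", "NotAReef"),
    c("NotAReef", "Low",      "Low",      "Low"),
    c("NotAReef", "Low",      "Medium",   "Medium"),
    c("NotAReef", "Low",      "Medium",   "High")
  )
  dimnames(cells) <- list(
    cover = c("<10%", "10-20%", "20-30%", ">30%"),
    elevation = c("<2", "2-5", "5-10", ">10")
  )
  cells
}

validate_status_matrix <- function(m) {
  ok_classes <- c("NotAReef", "Low", "Medium", "High")
  if (length(m$cover_breaks) != 5 || is.unsorted(m$cover_breaks, strictly = TRUE))
    abort("`cover_breaks` must be 5 strictly increasing values.")
  if (m$cover_breaks[1] != 0 || m$cover_breaks[5] != 100)
    abort("`cover_breaks` must span [0, 100].")
  if (length(m$elevation_breaks) != 5 ||
      is.unsorted(m$elevation_breaks, strictly = TRUE))
    abort("`elevation_breaks` must be 5 strictly increasing values.")
  if (m$elevation_breaks[1] != 0 || !is.infinite(m$elevation_breaks[5]))
    abort("`elevation_breaks` must span [0, Inf).")
  if (!identical(dim(m$cells), c(4L, 4L)))
    abort("`cells` must be a 4 x 4 matrix.")
  if (!all(m$cells %in% ok_classes))
    abort(paste0("matrix cells must be among: ",
                 paste(ok_classes, collapse = ", ")))
  r <- matrix(status_rank(m$cells), 4, 4)
  if (any(apply(r, 1, is.unsorted)) || any(apply(r, 2, is.unsorted)))
    abort("matrix cells must be ordinal-monotone in both cover and elevation.")
  invisible(m)
}

#' @export
print.reef_status_matrix <- function(x, ...) {
  cat("Reef structure matrix (cover bands x elevation bands)\n")
  cat("cover edges (%):   ", paste(x$cover_breaks, collapse = ", "), "\n")
  cat("elevation edges (cm):", paste(x$elevation_breaks, collapse = ", "), "\n")
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' Read or write a reef structure matrix as a YAML config
#'
#' The on-disk format has three keys: `cover_breaks`, `elevation_breaks`
#' (the band edges; `.inf` for the open elevation top), and `cells`, a list
#' of four 4-element character vectors ordered by increasing cover band.
#' The matrix is validated on load, so an edited config that breaks band
#' contiguity or class monotonicity is rejected with an informative error.
#'
#' @param path File path.
#' @param matrix A `reef_status_matrix`.
#' @return `read_status_matrix()` returns a `reef_status_matrix`;
#'   `write_status_matrix()` returns `path` invisibly.
#' @export
read_status_matrix <- function(path) {
  cfg <- yaml::read_yaml(path)
  cells <- do.call(rbind, lapply(cfg$cells, as.character))
  dimnames(cells) <- dimnames(default_matrix_cells())
  reef_status_matrix(
    cover_breaks = as.numeric(cfg$cover_breaks),
    elevation_breaks = as.numeric(cfg$elevation_breaks),
    cells = cells
  )
}

#' @rdname read_status_matrix
#' @export
write_status_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "reef_status_matrix"))
  yaml::write_yaml(
    list(
      cover_breaks = matrix$cover_breaks,
      elevation_breaks = matrix$elevation_breaks,
      cells = apply(matrix$cells, 1, identity, simplify = FALSE)
    ),
    path
  )
  invisible(path)
}

#' Band a cover or elevation value
#'
#' `cover_band()` returns the 0-based index of the cover band holding each
#' value; `elevation_band()` does the same for tube elevation. Bands are
#' left-closed, right-open except the topmost, which is closed above by 100
#' (cover) or open (elevation).
#'
#' @param cover_pct Percentage cover in `[0, 100]`.
#' @param elevation_cm Tube elevation in cm, `>= 0`.
#' @param matrix A [reef_status_matrix()].
#' @return Integer vector of band indices in `0:3` (`NA` in, `NA` out).
#' @export
#' @examples
#' cover_band(c(5, 10, 100))
#' elevation_band(c(1.5, 5, 12))
cover_band <- function(cover_pct, matrix = reef_status_matrix()) {
  x <- as.numeric(cover_pct)
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad))
    abort(paste0("cover_pct out of [0, 100]: ", paste(x[bad], collapse = ", ")))
  band <- findInterval(x, matrix$cover_breaks[2:4])
  as.integer(band)
}

#' @rdname cover_band
#' @export
elevation_band <- function(elevation_cm, matrix = reef_status_matrix()) {
  x <- as.numeric(elevation_cm)
  bad <- !is.na(x) & x < 0
  if (any(bad))
    abort(paste0("elevation_cm must be >= 0: ", paste(x[bad], collapse = ", ")))
  band <- findInterval(x, matrix$elevation_breaks[2:4])
  as.integer(band)
}

#' Classify segments on the reef structure matrix
#'
#' Maps percentage cover and tube elevation to a reef-status class.
#' Zero cover is `NoReef` (reef absent, not merely sub-reef structure);
#' any missing input yields `Missing`, never a silent `NoReef`. Otherwise
#' the class is the matrix cell at the cover and elevation bands.
#'
#' @inheritParams cover_band
#' @return Factor with [status_levels()], same length as the inputs.
#' @export
#' @examples
#' classify_status(c(50, 25, 35, 5, 0), c(12, 3, 7, 12, NA))
classify_status <- function(cover_pct, elevation_cm,
                            matrix = reef_status_matrix()) {
  n <- max(length(cover_pct), length(elevation_cm))
  cover <- rep_len(as.numeric(cover_pct), n)
  elev <- rep_len(as.numeric(elevation_cm), n)

  out <- rep(NA_character_, n)
  zero <- !is.na(cover) & cover == 0
  out[zero] <- "NoReef"
  scored <- !is.na(cover) & cover > 0 & !is.na(elev)
  if (any(scored)) {
    cb <- cover_band(cover[scored], matrix)
    eb <- elevation_band(elev[scored], matrix)
    out[scored] <- matrix$cells[cbind(cb + 1L, eb + 1L)]
  }
  out[is.na(out)] <- "Missing"
  status_factor(out)
}
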
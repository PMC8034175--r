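# Per-map complexity measures: alphabet entropy H(A), representation count v
# and entropy H(B) = log2(v), and the log2(m) uncertainty-rate baseline.

#' Pad candidate codes to a common length
#'
#' Right-pads every code with `pad` up to the length of the longest code in
#' the set, so the candidates form an m-by-n character matrix (one row per
#' code, one column per character position). The pad symbol is treated as an
#' ordinary alphabet symbol downstream: a position that some candidates lack
#' is genuine uncertainty about code length.
#'
#' @param codes Character vector of distinct candidate codes.
#' @param pad Single padding character, must not occur in any code.
#' @return A character matrix of single characters with one row per code
#'   (rownames are the original codes).
#' @examples
#' pad_codes(c("1234", "123"))
#' @export
pad_codes <- function(codes, pad = "~") {
  codes <- as.character(codes)
  if (length(codes) == 0L) abort("no codes to pad")
  if (anyDuplicated(codes)) abort("candidate codes must be distinct")
  if (nchar(pad) != 1L) abort("pad must be a single character")
  if (any(vapply(codes, function(cd) grepl(pad, cd, fixed = TRUE), FALSE))) {
    abort(paste0("pad symbol \"", pad, "\" occurs in a code"))
  }
  n <- max(nchar(codes))
  padded <- stringr::str_pad(codes, n, side = "right", pad = pad)
  mat <- do.call(rbind, stringr::str_split(padded, ""))
  rownames(mat) <- codes
  mat
}

#' Shannon entropy of one column of a padded code matrix
#'
#' The entropy, in bits, of the empirical symbol distribution in character
#' position `j` across the map's candidate codes: `-sum(p * log2(p))` with
#' `p` the relative frequency of each distinct symbol (each candidate code
#' weighted equally; `0 * log2(0)` taken as 0).
#'
#' @param mat Character matrix from [pad_codes()].
#' @param j Column (character position) index, `1 <= j <= ncol(mat)`.
#' @return Entropy in bits (non-negative scalar).
#' @export
column_entropy <- function(mat, j) {
  stopifnot(is.matrix(mat), j >= 1L, j <= ncol(mat))
  p <- table(mat[, j]) / nrow(mat)
  -sum(p * log2(p))
}

#' Alphabet entropy H(A) of a code map
#'
#' Sums [column_entropy()] over all character positions of the padded
#' candidate-code matrix. High values mean the candidate codes disagree in
#' many positions, so translating the source code demands documentation
#' detailed enough to pin down every varying character.
#'
#' @param map A [code_map()] with at least one candidate (`m >= 1`).
#' @param pad Padding character, see [pad_codes()].
#' @return H(A) in bits; exactly 0 when `m = 1`.
#' @export
h_alpha <- function(map, pad = "~") {
  check_measurable(map)
  if (map$m == 1L) return(0)
  mat <- pad_codes(map$candidates, pad)
  sum(vapply(seq_len(ncol(mat)), function(j) column_entropy(mat, j), 0))
}

check_measurable <- function(map) {
  stopifnot(inherits(map, "code_map"))
  if (map$m == 0L) {
    abort(paste0(
      "measures are undefined for map ", map$source_code,
      ": no candidate codes (no-map codes are excluded)"
    ))
  }
}

#' Enumerate every valid representation of a source code
#'
#' Brute-force oracle for the representation count `v`: one singleton set per
#' stand-alone candidate, plus, for each scenario, every element of the
#' Cartesian product of its choice lists (one code per choice list).
#' Representations are deduplicated as sets.
#'
#' @param map A [code_map()] with `m >= 1`.
#' @param cap Abort if the nominal representation count exceeds this.
#' @return A list of character vectors (each sorted), one per distinct
#'   representation.
#' @seealso [count_representations()] for the closed-form count.
#' @export
enumerate_representations <- function(map, cap = 1e6) {
  check_measurable(map)
  nominal <- map$m0 + sum(vapply(
    map$scenarios, function(sc) prod(lengths(sc)), 0
  ))
  if (nominal > cap) {
    abort(paste0("representation count ", nominal, " exceeds cap ", cap))
  }
  reps <- lapply(map$standalone, function(cd) cd)
  for (sc in map$scenarios) {
    grid <- expand.grid(sc, stringsAsFactors = FALSE)
    reps <- c(reps, lapply(seq_len(nrow(grid)), function(i) {
      sort(unique(as.character(grid[i, ])))
    }))
  }
  unique(reps)
}

#' Count the valid representations v of a source code
#'
#' `v = m0 + sum over scenarios of prod over choice lists of list size`:
#' the stand-alone candidates each count once, and each scenario contributes
#' the size of the Cartesian product of its choice lists.
#'
#' @inheritParams enumerate_representations
#' @return Integer-valued count `v >= 0`.
#' @export
count_representations <- function(map) {
  check_measurable(map)
  map$m0 + sum(vapply(map$scenarios, function(sc) prod(lengths(sc)), 0))
}

#' Representation entropy H(B) of a code map
#'
#' `log2(v)` with `v` from [count_representations()]: the uncertainty, in
#' bits, over which of the map's valid representations translates the source
#' code. When the map has no combination entries `v = m` and H(B) reduces to
#' the [ur_measure()] baseline.
#'
#' @inheritParams enumerate_representations
#' @return H(B) in bits.
#' @export
h_beta <- function(map) {
  log2(count_representations(map))
}

#' Uncertainty-rate baseline log2(m)
#'
#' The candidate-count entropy under a uniform choice among the `m`
#' candidate codes, ignoring both alphabet variation and combination
#' structure. Included as the prior-work baseline the entropic measures are
#' compared against.
#'
#' @inheritParams enumerate_representations
#' @return UR in bits.
#' @export
ur_measure <- function(map) {
  check_measurable(map)
  log2(map$m)
}

#' Compute all per-map measures for a collection of maps
#'
#' Applies [h_alpha()], [count_representations()], [h_beta()] and
#' [ur_measure()] to every map with at least one candidate code. Maps with
#' `m = 0` (no-map codes) are excluded and counted in the `n_excluded`
#' attribute, mirroring the exclusion of unmatched codes from the published
#' summary statistics.
#'
#' @param maps A `code_map_tbl` from [build_code_maps()], or a list of
#'   [code_map()] objects.
#' @param pad Padding character for [h_alpha()].
#' @return A `measure_tbl` tibble with columns `source_code`, `m`, `m0`,
#'   `v`, `h_a`, `h_b`, `ur`; attributes `direction` and `n_excluded`.
#' @export
compute_measures <- function(maps, pad = "~") {
  direction <- attr(maps, "direction", exact = TRUE) %||% ""
  if (is.data.frame(maps)) maps <- maps$map
  stopifnot(all(vapply(maps, inherits, FALSE, "code_map")))
  keep <- vapply(maps, function(mp) mp$m >= 1L, FALSE)
  out <- tibble(
    source_code = vapply(maps[keep], `[[`, "", "source_code"),
    m = vapply(maps[keep], `[[`, 0L, "m"),
    m0 = vapply(maps[keep], `[[`, 0L, "m0"),
    v = vapply(maps[keep], count_representations, 0),
    h_a = vapply(maps[keep], h_alpha, 0, pad = pad),
    ur = vapply(maps[keep], ur_measure, 0)
  ) %>% mutate(h_b = log2(.data$v), .before = "ur")
  attr(out, "direction") <- direction
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- unique(c("measure_tbl", class(out)))
  out
}
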
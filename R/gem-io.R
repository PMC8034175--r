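# Reading, validating and writing GEM-style crosswalk files, and assembly of
# per-source-code maps (candidate sets plus scenario / choice-list structure).

#' Parse a five-digit GEM flag string
#'
#' Each crosswalk record carries a supplemental five-digit flag. Digit 1 marks
#' an approximate (rather than exact) equivalence, digit 2 marks a source code
#' with no counterpart in the target system, digit 3 marks membership in a
#' combination (one-to-many) entry, and digits 4 and 5 identify the scenario
#' and the choice list within that scenario to which the row's target code
#' belongs.
#'
#' @param flags Character vector of raw 5-digit flag strings.
#' @return A tibble with integer columns `approximate`, `no_map`,
#'   `combination`, `scenario`, `choice_list`, one row per input flag.
#'   Malformed flags (wrong length or non-digit characters) yield `NA` rows.
#' @examples
#' parse_gem_flags(c("00000", "10111"))
#' @export
parse_gem_flags <- function(flags) {
  ok <- stringr::str_detect(flags, "^[0-9]{5}$")
  ok[is.na(ok)] <- FALSE
  dig <- function(k) {
    out <- rep(NA_integer_, length(flags))
    out[ok] <- as.integer(stringr::str_sub(flags[ok], k, k))
    out
  }
  tibble(
    approximate = dig(1), no_map = dig(2), combination = dig(3),
    scenario = dig(4), choice_list = dig(5)
  )
}

#' Read a GEM-style crosswalk file
#'
#' Expects one record per line with at least three whitespace-separated
#' tokens: source code, target code, 5-digit flag. Codes are uppercased and
#' stripped of decimal points; exact duplicate (source, target, flag) triples
#' are dropped. Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the crosswalk text file (UTF-8).
#' @param direction Free-text label for the mapping direction, stored as the
#'   `direction` attribute of the result (default: the file name).
#' @param strict If `TRUE`, a malformed flag or short line aborts with the
#'   offending line number; otherwise such rows are skipped with a warning.
#' @return A `gem_crosswalk` tibble with columns `source`, `target`,
#'   `approximate`, `no_map`, `combination`, `scenario`, `choice_list`.
#' @seealso [write_gem_file()], [build_code_maps()]
#' @export
parse_gem_file <- function(path, direction = basename(path), strict = FALSE) {
  if (!file.exists(path)) abort(paste0("GEM file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  toks <- stringr::str_split(stringr::str_trim(lines), "\\s+")

  short <- lengths(toks) < 3L
  if (any(short)) {
    if (strict) {
      abort(paste0("line ", lineno[short][1L], ": fewer than 3 fields"))
    }
    warn(paste0(sum(short), " line(s) with fewer than 3 fields skipped"))
    toks <- toks[!short]
    lineno <- lineno[!short]
  }

  src <- normalize_code(vapply(toks, `[[`, "", 1L))
  tgt <- normalize_code(vapply(toks, `[[`, "", 2L))
  raw_flag <- vapply(toks, `[[`, "", 3L)
  flag <- parse_gem_flags(raw_flag)

  bad <- is.na(flag$approximate)
  if (any(bad)) {
    if (strict) {
      abort(paste0(
        "line ", lineno[bad][1L], ": malformed flag \"", raw_flag[bad][1L], "\""
      ))
    }
    warn(paste0(sum(bad), " row(s) with malformed flags skipped"))
  }

  xw <- dplyr::bind_cols(tibble(source = src, target = tgt), flag)[!bad, ]
  n_before <- nrow(xw)
  xw <- distinct(xw)
  n_dup <- n_before - nrow(xw)

  conflicts <- xw %>%
    count(.data$source, .data$target) %>%
    filter(n > 1L)
  if (nrow(conflicts) > 0L) {
    warn(paste0(
      nrow(conflicts), " source/target pair(s) appear with conflicting flags; all kept"
    ))
  }
  inform(paste0(
    "read ", nrow(xw), " rows from ", path,
    " (", n_dup, " duplicate(s) dropped)"
  ))
  new_gem_crosswalk(xw, direction)
}

new_gem_crosswalk <- function(rows, direction = "") {
  out <- as_tibble(rows)
  attr(out, "direction") <- direction
  class(out) <- unique(c("gem_crosswalk", class(out)))
  out
}

#' Assemble a crosswalk from in-memory rows
#'
#' @param rows Data frame with columns `source`, `target` and either a
#'   character `flag` column of 5-digit strings or the five parsed digit
#'   columns (see [parse_gem_flags()]).
#' @param direction Free-text mapping-direction label.
#' @return A `gem_crosswalk` tibble.
#' @export
gem_crosswalk <- function(rows, direction = "") {
  rows <- as_tibble(rows)
  if ("flag" %in% names(rows)) {
    rows <- dplyr::bind_cols(
      select(rows, "source", "target"),
      parse_gem_flags(rows$flag)
    )
  }
  need <- c("source", "target", "approximate", "no_map", "combination",
            "scenario", "choice_list")
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0L) {
    abort(paste0("missing crosswalk columns: ", paste(missing, collapse = ", ")))
  }
  rows$source <- normalize_code(rows$source)
  rows$target <- normalize_code(rows$target)
  new_gem_crosswalk(distinct(rows[need]), direction)
}

normalize_code <- function(x) {
  toupper(gsub("\\.", "", as.character(x)))
}

#' Write a crosswalk back to GEM text format
#'
#' Emits one line per row, `source target flag`, so that
#' `parse_gem_file(write_gem_file(x, path))` round-trips `x` exactly.
#'
#' @param xwalk A `gem_crosswalk` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gem_file <- function(xwalk, path) {
  flag <- sprintf(
    "%d%d%d%d%d", xwalk$approximate, xwalk$no_map, xwalk$combination,
    xwalk$scenario, xwalk$choice_list
  )
  readr::write_lines(sprintf("%s %s %s", xwalk$source, xwalk$target, flag), path)
  invisible(path)
}

#' Construct a single code map
#'
#' A map collects everything the crosswalk says about one source code: the
#' distinct candidate target codes (the rows of the map matrix), which of
#' them are stand-alone (each one alone is a valid translation), and the
#' scenario structure, where each scenario is a list of choice lists and a
#' valid translation picks exactly one code from every choice list.
#'
#' @param source_code Source code string.
#' @param standalone Character vector of stand-alone candidate codes.
#' @param scenarios List of scenarios; each scenario is a list of character
#'   vectors (the choice lists).
#' @param has_no_map `TRUE` for a source code with no counterpart in the
#'   target system (then both `standalone` and `scenarios` must be empty).
#' @return A `code_map` object with fields `source_code`, `candidates`,
#'   `standalone`, `scenarios`, `has_no_map`, `m` (number of candidates) and
#'   `m0` (number of stand-alone codes).
#' @examples
#' code_map("0052", standalone = character(),
#'          scenarios = list(list(c("A", "B"), c("C"))))
#' @export
code_map <- function(source_code, standalone = character(),
                     scenarios = list(), has_no_map = FALSE) {
  # stored sorted so maps do not depend on input row order
  standalone <- sort(unique(normalize_code(standalone)))
  scenarios <- lapply(scenarios, function(sc) {
    sc <- lapply(sc, function(cl) sort(unique(normalize_code(cl))))
    if (any(lengths(sc) == 0L)) abort("empty choice list in scenario")
    sc
  })
  candidates <- sort(unique(c(standalone, unlist(scenarios, use.names = FALSE))))
  if (has_no_map && length(candidates) > 0L) {
    abort("a no-map code cannot have candidate codes")
  }
  structure(
    list(
      source_code = normalize_code(source_code),
      candidates = candidates,
      standalone = standalone,
      scenarios = scenarios,
      has_no_map = has_no_map,
      m = length(candidates),
      m0 = length(standalone)
    ),
    class = "code_map"
  )
}

#' @export
print.code_map <- function(x, ...) {
  cat("<code_map> ", x$source_code, ": m = ", x$m, ", m0 = ", x$m0,
      ", scenarios = ", length(x$scenarios),
      if (x$has_no_map) " [no map]" else "", "\n", sep = "")
  invisible(x)
}

#' Build per-source-code maps from a crosswalk
#'
#' Groups crosswalk rows by source code and assembles one [code_map()] per
#' code: `m` distinct candidate targets, of which `m0` occur only in
#' non-combination rows (stand-alone codes), plus the scenario / choice-list
#' structure read off the flag digits. A source code whose every row is
#' flagged no-map yields an empty map with `has_no_map = TRUE`; a code mixing
#' no-map and mapped rows keeps the mapped rows with a warning.
#'
#' @param xwalk A `gem_crosswalk` tibble.
#' @return A `code_map_tbl` tibble with columns `source_code`, `m`, `m0`,
#'   `n_scenarios`, `has_no_map` and a list-column `map` of [code_map()]
#'   objects, ordered by `source_code`.
#' @export
build_code_maps <- function(xwalk) {
  stopifnot(is.data.frame(xwalk))
  split_rows <- split(
    as_tibble(xwalk)[c("target", "no_map", "combination", "scenario", "choice_list")],
    xwalk$source
  )
  mixed <- 0L
  maps <- lapply(names(split_rows), function(src) {
    rows <- split_rows[[src]]
    nm <- rows$no_map == 1L
    if (all(nm)) {
      return(code_map(src, has_no_map = TRUE))
    }
    if (any(nm)) {
      mixed <<- mixed + 1L
      rows <- rows[!nm, ]
    }
    standalone_rows <- rows$combination == 0L
    comb <- rows[!standalone_rows, ]
    scen <- lapply(split(comb, comb$scenario), function(s) {
      unname(lapply(split(s$target, s$choice_list), unique))
    })
    standalone <- setdiff(unique(rows$target[standalone_rows]),
                          unique(comb$target))
    code_map(src, standalone = standalone, scenarios = unname(scen))
  })
  if (mixed > 0L) {
    warn(paste0(
      mixed, " source code(s) had both no-map and mapped rows; no-map rows ignored"
    ))
  }
  out <- tibble(
    source_code = vapply(maps, `[[`, "", "source_code"),
    m = vapply(maps, `[[`, 0L, "m"),
    m0 = vapply(maps, `[[`, 0L, "m0"),
    n_scenarios = vapply(maps, function(mp) length(mp$scenarios), 0L),
    has_no_map = vapply(maps, `[[`, FALSE, "has_no_map"),
    map = maps
  ) %>% arrange(.data$source_code)
  attr(out, "direction") <- attr(xwalk, "direction", exact = TRUE) %||% ""
  class(out) <- unique(c("code_map_tbl", class(out)))
  out
}
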
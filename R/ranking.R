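# Normalization, frequency weighting, descriptive summaries, clinical-class
# aggregation and ranking, rank agreement, and outlier isolation.

measure_cols <- c(h_a = "z_alpha", h_b = "z_beta", ur = "z_ur")

#' Z-normalize the entropic measures of one mapping direction
#'
#' Centers each of `h_a`, `h_b`, `ur` and divides by its sample standard
#' deviation (n - 1 denominator), producing `z_alpha`, `z_beta`, `z_ur`.
#' Normalization is computed across all included maps of one mapping
#' direction, before any class grouping, so a map's Z score states how
#' unusual its complexity is within that direction. A zero-variance column
#' normalizes to all zeros.
#'
#' @param table A `measure_tbl` from [compute_measures()] with at least two
#'   records.
#' @return The table with `z_alpha`, `z_beta`, `z_ur` columns filled.
#' @export
normalize_measures <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 2L) abort("normalization needs at least 2 records")
  for (raw in names(measure_cols)) {
    x <- table[[raw]]
    s <- sd(x)
    table[[measure_cols[[raw]]]] <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  }
  attr(table, "normalized") <- TRUE
  table
}

#' Weight normalized measures by empirical concept probabilities
#'
#' Multiplies each Z column by the probability of the corresponding source
#' code (e.g. its historical share of visits in a facility), so that
#' complexity a facility never encounters stops competing for attention.
#' Codes absent from the frequency table get probability 0; their count is
#' reported via a message.
#'
#' @param table A normalized `measure_tbl`.
#' @param freqs Data frame with columns `code` and `probability`
#'   (each in `[0, 1]`), or a named numeric vector.
#' @return The table with Z columns scaled and a `probability` column added.
#' @export
weight_by_probability <- function(table, freqs) {
  if (!isTRUE(attr(table, "normalized"))) abort("normalize the table first")
  if (is.numeric(freqs)) {
    freqs <- tibble(code = names(freqs), probability = unname(freqs))
  }
  stopifnot(all(c("code", "probability") %in% names(freqs)))
  if (any(freqs$probability < 0 | freqs$probability > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  p <- freqs$probability[match(table$source_code, normalize_code(freqs$code))]
  n_missing <- sum(is.na(p))
  if (n_missing > 0L) {
    inform(paste0(n_missing, " code(s) missing from the frequency table; probability 0 used"))
    p[is.na(p)] <- 0
  }
  for (zc in measure_cols) table[[zc]] <- table[[zc]] * p
  table$probability <- p
  attr(table, "weighted") <- TRUE
  table
}

#' Descriptive statistics of the entropic measures
#'
#' Count, mean, sample standard deviation, minimum, quartiles (linear
#' interpolation) and maximum of each measure across the included maps of
#' one direction.
#'
#' @param table A `measure_tbl` (normalization not required).
#' @return A tibble with one row per measure (`h_a`, `h_b`, `ur`) and
#'   columns `count`, `mean`, `std`, `min`, `q25`, `median`, `q75`, `max`.
#' @export
describe_measures <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  purrr::map_dfr(names(measure_cols), function(mc) {
    x <- table[[mc]]
    q <- quantile(x, c(.25, .5, .75), type = 7, names = FALSE)
    tibble(
      measure = mc, count = length(x), mean = mean(x),
      std = if (length(x) > 1L) sd(x) else 0,
      min = min(x), q25 = q[1], median = q[2], q75 = q[3], max = max(x)
    )
  })
}

#' Load clinical-class definitions from YAML
#'
#' A class definition is a list of rules, each either a lexicographic code
#' range (`kind: range`, fields `lo`, `hi`, optional `prefix_len`) or a
#' first-character set (`kind: first_char`, field `chars`). The first
#' matching rule wins; unmatched codes fall into `"Unclassified"`.
#'
#' @param path YAML file: a list of `{label, kind, ...}` entries.
#' @return A `class_defs` tibble with columns `label`, `kind`, `lo`, `hi`,
#'   `prefix_len`, `chars` (list-column).
#' @export
read_class_defs <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- purrr::map_dfr(raw, function(r) {
    tibble(
      label = r$label,
      kind = r$kind,
      lo = normalize_code(r$lo %||% NA_character_),
      hi = normalize_code(r$hi %||% NA_character_),
      prefix_len = as.integer(r$prefix_len %||% NA_integer_),
      chars = list(normalize_code(as.character(r$chars %||% character())))
    )
  })
  bad <- defs$kind == "range" & (is.na(defs$lo) | is.na(defs$hi) | defs$lo > defs$hi)
  if (any(bad)) abort(paste0("malformed range rule for label: ", defs$label[bad][1L]))
  class(defs) <- unique(c("class_defs", class(defs)))
  defs
}

#' Built-in clinical-class definitions
#'
#' Chapter-level groupings shipped with the package: ICD-9-CM Vol. 3
#' procedure chapters, ICD-9-CM diagnosis chapters (numeric plus E/V
#' supplementary ranges), ICD-10-CM chapters, and ICD-10-PCS sections
#' (first character). Each is an editable YAML file under
#' `system.file("extdata/classes", package = "gementropy")`.
#'
#' @param system One of `"icd9_vol3"`, `"icd9_dx"`, `"icd10_cm"`,
#'   `"icd10_pcs"`.
#' @return A `class_defs` tibble, see [read_class_defs()].
#' @export
default_class_defs <- function(system = c("icd9_vol3", "icd9_dx",
                                          "icd10_cm", "icd10_pcs")) {
  system <- match.arg(system)
  read_class_defs(system.file(
    "extdata", "classes", paste0(system, ".yaml"),
    package = "gementropy", mustWork = TRUE
  ))
}

#' Assign source codes to clinical classes
#'
#' @param codes Character vector of (normalized or raw) codes.
#' @param defs A `class_defs` tibble.
#' @return Character vector of class labels; codes matching no rule get
#'   `"Unclassified"`.
#' @export
assign_class <- function(codes, defs) {
  stopifnot(nrow(defs) > 0L)
  codes <- normalize_code(codes)
  out <- rep("Unclassified", length(codes))
  todo <- rep(TRUE, length(codes))
  for (i in seq_len(nrow(defs))) {
    if (!any(todo)) break
    hit <- if (defs$kind[i] == "first_char") {
      substr(codes, 1L, 1L) %in% defs$chars[[i]]
    } else {
      pl <- defs$prefix_len[i]
      if (is.na(pl)) pl <- nchar(defs$lo[i])
      pre <- substr(codes, 1L, pl)
      pre >= defs$lo[i] & pre <= defs$hi[i]
    }
    out[todo & hit] <- defs$label[i]
    todo <- todo & !hit
  }
  out
}

#' Aggregate normalized measures into ranked clinical classes
#'
#' Sums each Z column within every class (the quantity the class rankings
#' are built from) and records the member count and per-measure
#' interquartile range. Because Z scores sum to zero over the whole
#' direction, a positive class sum marks above-average information gain in
#' the target system and a negative sum little or none.
#'
#' @param table A normalized `measure_tbl`.
#' @param defs A `class_defs` tibble.
#' @return A `class_score_tbl` tibble with columns `label`, `n`,
#'   `sum_z_alpha`, `sum_z_beta`, `sum_z_ur`, `iqr_z_alpha`, `iqr_z_beta`,
#'   `iqr_z_ur`, sorted by total sum; empty classes are absent.
#' @export
class_scores <- function(table, defs) {
  if (!isTRUE(attr(table, "normalized"))) abort("normalize the table first")
  iqr <- function(x) diff(quantile(x, c(.25, .75), type = 7, names = FALSE))
  out <- table %>%
    mutate(label = assign_class(.data$source_code, defs)) %>%
    group_by(.data$label) %>%
    summarise(
      n = dplyr::n(),
      sum_z_alpha = sum(.data$z_alpha),
      sum_z_beta = sum(.data$z_beta),
      sum_z_ur = sum(.data$z_ur),
      iqr_z_alpha = iqr(.data$z_alpha),
      iqr_z_beta = iqr(.data$z_beta),
      iqr_z_ur = iqr(.data$z_ur),
      .groups = "drop"
    ) %>%
    arrange(.data$sum_z_alpha + .data$sum_z_beta + .data$sum_z_ur)
  class(out) <- unique(c("class_score_tbl", class(out)))
  out
}

#' Kendall rank agreement between two class scorings
#'
#' Tie-corrected Kendall tau-b between two score vectors over the same set
#' of class labels. Values near 1 mean the two measures rank the classes
#' almost identically; -1 means full reversal.
#'
#' @param a,b Named numeric vectors (names are class labels), or two-column
#'   data frames (`label`, score).
#' @return Tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(a, b) {
  as_scores <- function(x) {
    if (is.data.frame(x)) setNames(x[[2L]], x[[1L]]) else x
  }
  a <- as_scores(a)
  b <- as_scores(b)
  if (!is.null(names(a)) || !is.null(names(b))) {
    if (is.null(names(a)) || is.null(names(b)) ||
        !setequal(names(a), names(b))) {
      abort("the two rankings must cover the same label set")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    abort("the two rankings must cover the same label set")
  }
  cor(a, b, method = "kendall")
}

#' Pairwise Kendall tau among the three normalized measures
#'
#' @param scores A `class_score_tbl` from [class_scores()].
#' @return A 3x3 symmetric matrix of tau-b values with dimnames
#'   `z_alpha`, `z_beta`, `z_ur`. The diagonal is 1; an off-diagonal entry
#'   is `NA` when a score column is constant (tau-b undefined under
#'   all-tied rankings).
#' @export
tau_matrix <- function(scores) {
  cols <- c("sum_z_alpha", "sum_z_beta", "sum_z_ur")
  m <- suppressWarnings(cor(as.matrix(scores[cols]), method = "kendall"))
  diag(m) <- 1
  dimnames(m) <- list(c("z_alpha", "z_beta", "z_ur"),
                      c("z_alpha", "z_beta", "z_ur"))
  m
}

#' Isolate outlier maps on one normalized measure
#'
#' Flags the concepts most likely to pose transition challenges: either all
#' records with a Z score strictly above `threshold`, or the
#' `ceiling(top_fraction * n)` records with the largest Z scores. Exactly
#' one selector must be given.
#'
#' @param table A normalized `measure_tbl`.
#' @param measure `"z_alpha"`, `"z_beta"` or `"z_ur"`.
#' @param threshold Absolute Z cutoff (records with `z > threshold`).
#' @param top_fraction Proportion of records to flag, in `(0, 1]`.
#' @return The flagged rows of `table`, sorted by the chosen measure,
#'   decreasing.
#' @export
flag_outliers <- function(table, measure = c("z_alpha", "z_beta", "z_ur"),
                          threshold = NULL, top_fraction = NULL) {
  if (!isTRUE(attr(table, "normalized"))) abort("normalize the table first")
  measure <- match.arg(measure)
  if (is.null(threshold) == is.null(top_fraction)) {
    abort("give exactly one of threshold / top_fraction")
  }
  z <- table[[measure]]
  ord <- order(z, decreasing = TRUE)
  if (!is.null(threshold)) {
    idx <- ord[z[ord] > threshold]
  } else {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    idx <- head(ord, ceiling(top_fraction * nrow(table)))
  }
  out <- table[idx, ]
  attr(out, "measure") <- measure
  out
}
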
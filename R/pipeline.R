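# End-to-end pipeline: parse -> maps -> measures -> normalize -> (weight) ->
# describe -> class scores -> rank agreement -> outliers -> (themes),
# with CSV / GraphML outputs.

#' Run the full complexity-analysis pipeline
#'
#' Executes, for each supplied crosswalk direction: GEM parsing, map
#' assembly, computation of the entropic measures, z-normalization, optional
#' frequency weighting, descriptive summaries, clinical-class aggregation,
#' Kendall rank agreement among the three measures, outlier isolation, and
#' (when descriptions are supplied) a word co-occurrence network over the
#' outlier-map descriptions. All tabular results are written as CSV under
#' `out_dir`, the word graph also as GraphML.
#'
#' @param gem_files Named character vector of crosswalk file paths; names
#'   label the directions (e.g. `c(forward = "...", backward = "...")`).
#' @param class_defs A `class_defs` tibble, a YAML path, or the name of a
#'   built-in definition set (see [default_class_defs()]). May be a list
#'   named like `gem_files` to use different classes per direction.
#' @param descriptions Optional path to a two-column delimited file
#'   (code, description) or a data frame; enables the themes stage.
#' @param frequencies Optional path to a two-column CSV (code, probability)
#'   or a data frame; enables the weighting stage.
#' @param outlier_measure,threshold,top_fraction Outlier selector passed to
#'   [flag_outliers()] (default: top 1% per the published analysis).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param pad Padding character for [h_alpha()].
#' @param strict Passed to [parse_gem_file()].
#' @return A named list (one element per direction) of lists with elements
#'   `measures`, `summary`, `class_scores`, `tau`, `outliers`, and
#'   optionally `word_graph`; invisibly returns the same with
#'   `attr(, "out_dir")` set.
#' @export
run_pipeline <- function(gem_files,
                         class_defs = "icd9_vol3",
                         descriptions = NULL,
                         frequencies = NULL,
                         outlier_measure = "z_alpha",
                         threshold = NULL,
                         top_fraction = if (is.null(threshold)) 0.01 else NULL,
                         out_dir = NULL,
                         pad = "~",
                         strict = FALSE) {
  if (is.null(names(gem_files))) {
    names(gem_files) <- paste0("direction", seq_along(gem_files))
  }
  resolve_defs <- function(cd) {
    if (is.data.frame(cd)) return(cd)
    if (file.exists(cd)) read_class_defs(cd) else default_class_defs(cd)
  }
  if (!is.null(descriptions) && !is.data.frame(descriptions)) {
    descriptions <- readr::read_delim(
      descriptions, col_names = c("code", "description"),
      show_col_types = FALSE, trim_ws = TRUE
    )
  }
  if (!is.null(frequencies) && !is.data.frame(frequencies)) {
    frequencies <- readr::read_csv(frequencies, show_col_types = FALSE)
    names(frequencies)[1:2] <- c("code", "probability")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  emit <- function(df, name, dir_label) {
    if (!is.null(out_dir)) {
      readr::write_csv(df, file.path(out_dir, paste0(dir_label, "_", name, ".csv")))
    }
  }

  results <- purrr::imap(gem_files, function(path, dir_label) {
    xw <- parse_gem_file(path, direction = dir_label, strict = strict)
    maps <- build_code_maps(xw)
    tbl <- compute_measures(maps, pad = pad) %>% normalize_measures()
    inform(paste0(
      dir_label, ": ", nrow(tbl), " maps measured, ",
      attr(tbl, "n_excluded"), " no-map code(s) excluded"
    ))
    if (!is.null(frequencies)) tbl <- weight_by_probability(tbl, frequencies)
    summary_tbl <- describe_measures(tbl)
    defs <- if (is.list(class_defs) && !is.data.frame(class_defs)) {
      resolve_defs(class_defs[[dir_label]])
    } else {
      resolve_defs(class_defs)
    }
    scores <- class_scores(tbl, defs)
    tau <- tau_matrix(scores)
    outliers <- flag_outliers(tbl, outlier_measure,
                              threshold = threshold,
                              top_fraction = top_fraction)
    emit(tbl, "measures", dir_label)
    emit(summary_tbl, "summary", dir_label)
    emit(scores, "class_scores", dir_label)
    emit(as_tibble(tau, rownames = "measure"), "kendall_tau", dir_label)
    emit(outliers, "outliers", dir_label)
    out <- list(measures = tbl, summary = summary_tbl, class_scores = scores,
                tau = tau, outliers = outliers)
    if (!is.null(descriptions) && nrow(outliers) > 0L) {
      toks <- tokenize_descriptions(
        dplyr::semi_join(descriptions %>% mutate(code = normalize_code(.data$code)),
                         tibble(code = outliers$source_code), by = "code")
      )
      if (nrow(toks) > 0L) {
        wg <- cooccurrence_graph(toks)
        if (!is.null(out_dir)) {
          write_word_graph(wg, file.path(out_dir, paste0(dir_label, "_words")))
        }
        out$word_graph <- wg
      }
    }
    out
  })
  attr(results, "out_dir") <- out_dir
  invisible(results)
}

#' Recompute the published full-data statistics from local CMS GEM files
#'
#' Given a directory containing the four 2015 CMS general equivalence
#' mapping text files (`gem_i9pcs.txt`, `gem_pcsi9.txt`, `2015_I9gem.txt`,
#' `2015_I10gem.txt` — procedure forward/backward and diagnosis
#' forward/backward; alternative conventional file names are searched too),
#' recomputes the headline quantities of the published analysis: record
#' counts per direction, mean H(A) for the forward directions, the (m, v)
#' signatures of maps 0050 and 688, the normalized scores of map 0052, and
#' the forward-procedure Kendall tau between the representation measure and
#' the baseline.
#'
#' The CMS files are not distributed with the package; download them from
#' the CMS ICD-10 archive and drop them into `gem_dir`.
#'
#' @param gem_dir Directory holding the four GEM text files.
#' @return A named list of computed quantities.
#' @export
reproduce_published_statistics <- function(gem_dir) {
  find_file <- function(patterns) {
    for (p in patterns) {
      hits <- list.files(gem_dir, pattern = p, ignore.case = TRUE,
                         full.names = TRUE)
      if (length(hits) > 0L) return(hits[1L])
    }
    abort(paste0(
      "no file matching ", paste(patterns, collapse = " / "),
      " in ", gem_dir,
      " (download the 2015 GEMs from the CMS ICD-10 archive)"
    ))
  }
  if (!dir.exists(gem_dir)) {
    abort(paste0(
      "GEM directory not found: ", gem_dir,
      " (download the 2015 CMS GEM files and place them there)"
    ))
  }
  paths <- c(
    pcs_forward = find_file(c("gem_i9pcs", "i9pcs")),
    pcs_backward = find_file(c("gem_pcsi9", "pcsi9")),
    cm_forward = find_file(c("2015_I9gem", "i9gem", "I9gem")),
    cm_backward = find_file(c("2015_I10gem", "i10gem", "I10gem"))
  )
  tables <- purrr::imap(paths, function(p, lbl) {
    parse_gem_file(p, direction = lbl) %>%
      build_code_maps() %>%
      compute_measures() %>%
      normalize_measures()
  })
  fwd_maps <- build_code_maps(parse_gem_file(paths[["pcs_forward"]]))
  map_of <- function(src) fwd_maps$map[[match(src, fwd_maps$source_code)]]
  scores <- class_scores(tables$pcs_forward, default_class_defs("icd9_vol3"))
  rec_0052 <- filter(tables$pcs_forward, .data$source_code == "0052")
  list(
    counts = vapply(tables, nrow, 0L),
    mean_h_a_pcs_forward = mean(tables$pcs_forward$h_a),
    mean_h_a_cm_forward = mean(tables$cm_forward$h_a),
    v_0050 = count_representations(map_of("0050")),
    v_688 = count_representations(map_of("688")),
    z_alpha_0052 = rec_0052$z_alpha,
    z_beta_0052 = rec_0052$z_beta,
    tau_beta_ur_pcs_forward = kendall_tau(
      setNames(scores$sum_z_beta, scores$label),
      setNames(scores$sum_z_ur, scores$label)
    )
  )
}
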
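# Word co-occurrence network over the descriptions of outlier maps, with
# frequency and eigenvector-centrality annotations.

#' Default English stopword list
#'
#' A compact standard English stopword list shipped with the package
#' (`inst/extdata/stopwords_en.txt`), one word per line.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  readr::read_lines(system.file(
    "extdata", "stopwords_en.txt", package = "gementropy", mustWork = TRUE
  ))
}

#' Default residual-word list
#'
#' Coding-manual filler words that carry no clinical theme and are removed
#' alongside stopwords: `other`, `unspecified`, `nec`, `nos`, `procedure`,
#' `procedures`.
#'
#' @return Character vector of residual words.
#' @export
default_residuals <- function() {
  c("other", "unspecified", "nec", "nos", "procedure", "procedures")
}

#' Tokenize code descriptions
#'
#' Lowercases, extracts purely alphabetic tokens, and drops stopwords,
#' residual words and tokens of length 2 or less.
#'
#' @param descriptions Data frame with columns `code` and `description`, or
#'   a named character vector (names are codes).
#' @param stopwords,residuals Words to remove (defaults:
#'   [default_stopwords()], [default_residuals()]).
#' @return A tibble with columns `code` and `token`, one row per retained
#'   token occurrence (duplicate tokens within one description collapse to
#'   one row).
#' @examples
#' tokenize_descriptions(
#'   c("0052" = "Implantation or replacement of transvenous electrode")
#' )
#' @export
tokenize_descriptions <- function(descriptions,
                                  stopwords = default_stopwords(),
                                  residuals = default_residuals()) {
  if (!is.data.frame(descriptions)) {
    descriptions <- tibble(
      code = names(descriptions) %||% as.character(seq_along(descriptions)),
      description = unname(descriptions)
    )
  }
  stopifnot(all(c("code", "description") %in% names(descriptions)))
  drop <- unique(tolower(c(stopwords, residuals)))
  descriptions %>%
    mutate(
      code = normalize_code(.data$code),
      token = stringr::str_extract_all(tolower(.data$description), "[a-z]+")
    ) %>%
    select("code", "token") %>%
    tidyr::unnest("token") %>%
    filter(nchar(.data$token) > 2L, !.data$token %in% drop) %>%
    distinct()
}

#' Build a word co-occurrence network
#'
#' Two words are linked if they appear in the same description; the edge
#' weight counts the descriptions containing both. Words occurring in only
#' one-token descriptions are kept as isolated nodes.
#'
#' @param tokens Tibble with columns `code`, `token` from
#'   [tokenize_descriptions()].
#' @return A `word_graph` object: list with `nodes` (tibble `word`, `freq`,
#'   `centrality`), `edges` (tibble `word1`, `word2`, `weight`) and `graph`
#'   (the underlying igraph object). `freq` counts the descriptions a word
#'   occurs in; `centrality` is weight-aware eigenvector centrality on the
#'   largest connected component, scaled to a maximum of 1 (0 outside the
#'   component).
#' @export
cooccurrence_graph <- function(tokens) {
  stopifnot(all(c("code", "token") %in% names(tokens)))
  tokens <- distinct(tokens)
  nodes <- tokens %>%
    count(.data$token, name = "freq") %>%
    rename(word = "token") %>%
    arrange(dplyr::desc(.data$freq), .data$word)
  pairs <- tokens %>%
    dplyr::inner_join(tokens, by = "code", relationship = "many-to-many") %>%
    filter(.data$token.x < .data$token.y) %>%
    count(word1 = .data$token.x, word2 = .data$token.y, name = "weight") %>%
    arrange(dplyr::desc(.data$weight), .data$word1, .data$word2)
  g <- igraph::graph_from_data_frame(
    pairs, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  nodes$centrality <- unname(word_centrality(g)[nodes$word])
  structure(
    list(nodes = nodes, edges = pairs, graph = g),
    class = "word_graph"
  )
}

# Weight-aware eigenvector centrality on the largest connected component,
# scaled so the maximum score is 1; vertices outside the component score 0.
# Deterministic power iteration on the shifted adjacency matrix A + I (the
# shift keeps the Perron vector but breaks the +/- eigenvalue symmetry of
# bipartite components that would make plain iteration oscillate).
word_centrality <- function(g, tol = 1e-8, max_iter = 1000L) {
  out <- setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  comp <- igraph::components(g)
  if (comp$no == 0L) return(out)
  main <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize))
  )
  nv <- igraph::vcount(main)
  if (nv == 1L) {
    out[igraph::V(main)$name] <- 1
    return(out)
  }
  adj <- igraph::as_adjacency_matrix(
    main, sparse = FALSE,
    attr = if (igraph::ecount(main) > 0L) "weight" else NULL
  )
  m <- adj + diag(nv)
  x <- rep(1 / sqrt(nv), nv)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    xn <- as.vector(m %*% x)
    xn <- xn / sqrt(sum(xn^2))
    if (max(abs(xn - x)) < tol) {
      x <- xn
      converged <- TRUE
      break
    }
    x <- xn
  }
  if (!converged) {
    abort(paste0("eigenvector centrality did not converge in ", max_iter,
                 " iterations"))
  }
  out[colnames(adj)] <- x / max(x)
  out
}

#' @export
print.word_graph <- function(x, ...) {
  cat("<word_graph> ", nrow(x$nodes), " words, ", nrow(x$edges),
      " co-occurrence edges\n", sep = "")
  top <- head(arrange(x$nodes, dplyr::desc(.data$centrality)), 6L)
  cat("most central:", paste(top$word, collapse = ", "), "\n")
  invisible(x)
}

#' Export a word graph for external network tools
#'
#' Writes the weighted edge list and the node attributes (frequency,
#' centrality) as CSV, plus a GraphML file usable by external
#' community-detection or layout tools.
#'
#' @param graph A `word_graph`.
#' @param prefix Output path prefix; writes `<prefix>_edges.csv`,
#'   `<prefix>_nodes.csv`, `<prefix>.graphml`.
#' @return The three paths, invisibly.
#' @export
write_word_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "word_graph"))
  paths <- c(
    edges = paste0(prefix, "_edges.csv"),
    nodes = paste0(prefix, "_nodes.csv"),
    graphml = paste0(prefix, ".graphml")
  )
  readr::write_csv(graph$edges, paths[["edges"]])
  readr::write_csv(graph$nodes, paths[["nodes"]])
  g <- graph$graph
  igraph::V(g)$freq <- graph$nodes$freq[match(igraph::V(g)$name, graph$nodes$word)]
  igraph::V(g)$centrality <-
    graph$nodes$centrality[match(igraph::V(g)$name, graph$nodes$word)]
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
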
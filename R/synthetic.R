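# Seeded generator of GEM-format crosswalks with recorded ground truth, and
# a catalogue of small fixture maps reproducing published (m, v) signatures.

#' Specification for a synthetic crosswalk
#'
#' Describes the structure of a generated crosswalk: how many source codes,
#' the distribution of candidate counts m, how often multi-code maps use
#' combination (scenario / choice-list) structure, and the geometry of the
#' codes themselves. Defaults emulate a procedure-coding transition of the
#' ICD-9 Vol.3 to ICD-10-PCS kind: short numeric source codes, longer
#' alphanumeric target codes, a mapped-code majority of one-to-one and small
#' one-to-many maps with an occasional no-map code and a minority of
#' combination maps.
#'
#' @param n_source_codes Number of distinct source codes.
#' @param m_distribution Named numeric vector: probability of each candidate
#'   count m (names "0", "1", ... ; m = 0 yields a no-map code).
#' @param p_combination Probability that a map with `m >= 4` uses scenario
#'   structure rather than stand-alone candidates only.
#' @param scenario_count_range Integer range (within 1-9) for the number of
#'   scenarios in a combination map.
#' @param choice_list_count_range Integer range (within 2-9) for choice
#'   lists per scenario.
#' @param choice_list_size_range Integer range for codes per choice list.
#' @param source_length_range,target_length_range Code lengths, within 2-7.
#' @param source_alphabet,target_alphabet Symbol sets for code characters.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_source_codes = 500,
                           m_distribution = c("0" = 0.05, "1" = 0.55,
                                              "2" = 0.15, "3" = 0.10,
                                              "4" = 0.05, "6" = 0.05,
                                              "8" = 0.05),
                           p_combination = 0.6,
                           scenario_count_range = c(1L, 3L),
                           choice_list_count_range = c(2L, 3L),
                           choice_list_size_range = c(1L, 3L),
                           source_length_range = c(3L, 4L),
                           target_length_range = c(7L, 7L),
                           source_alphabet = strsplit("0123456789", "")[[1]],
                           target_alphabet = strsplit("0123456789ABCDEFGHJKLMNPQRSTVWXYZ", "")[[1]],
                           seed = 1L) {
  m_distribution <- m_distribution / sum(m_distribution)
  stopifnot(
    all(as.integer(names(m_distribution)) >= 0L),
    p_combination >= 0, p_combination <= 1,
    scenario_count_range[1] >= 1L, scenario_count_range[2] <= 9L,
    choice_list_count_range[1] >= 1L, choice_list_count_range[2] <= 9L,
    choice_list_size_range[1] >= 1L,
    source_length_range[1] >= 2L, source_length_range[2] <= 7L,
    target_length_range[1] >= 2L, target_length_range[2] <= 7L
  )
  structure(
    list(
      n_source_codes = n_source_codes, m_distribution = m_distribution,
      p_combination = p_combination,
      scenario_count_range = scenario_count_range,
      choice_list_count_range = choice_list_count_range,
      choice_list_size_range = choice_list_size_range,
      source_length_range = source_length_range,
      target_length_range = target_length_range,
      source_alphabet = source_alphabet, target_alphabet = target_alphabet,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

rand_codes <- function(n, len_range, alphabet, rng) {
  # draw until n distinct codes; error if the alphabet cannot supply them
  max_pool <- sum(length(alphabet)^(len_range[1]:len_range[2]))
  if (n > max_pool) {
    abort(paste0("alphabet permits at most ", max_pool, " distinct codes, ",
                 n, " requested"))
  }
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    len <- rng$int(len_range[1], len_range[2])
    out <- unique(c(out, paste(alphabet[rng$int(1L, length(alphabet),
                                                k = len)], collapse = "")))
    tries <- tries + 1L
    if (tries > 1000L * n) abort("unable to draw enough distinct codes")
  }
  out
}

# small closure-based RNG wrapper so all draws go through one seeded stream
make_rng <- function(seed) {
  env <- new.env()
  assign("state", {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  }, envir = env)
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", get("state", env), globalenv())
    on.exit({
      assign("state", get(".Random.seed", globalenv()), env)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    int = function(lo, hi, k = 1L) with_state(function() {
      if (lo == hi) rep(lo, k) else sample(seq.int(lo, hi), k, replace = TRUE)
    }),
    unif = function(k = 1L) with_state(function() stats::runif(k)),
    pick = function(x, k) with_state(function() sample(x, k)),
    draw_m = function(dist) with_state(function() {
      as.integer(sample(names(dist), 1L, prob = dist))
    })
  )
}

#' Generate a synthetic crosswalk with ground truth
#'
#' For each source code, draws a candidate count m from the spec's
#' distribution. m = 0 produces a no-map record; otherwise the candidates
#' are split between stand-alone codes and scenario choice lists. Code
#' pools of distinct scenarios (and the stand-alone pool) are kept
#' disjoint within a map, so the representation count is exactly
#' `m0 + sum over scenarios of the product of its choice-list sizes` and
#' representations from different scenarios can never coincide.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `crosswalk` (a `gem_crosswalk` tibble) and
#'   `ground_truth` (tibble: `source_code`, `m`, `m0`, `n_scenarios`, `v`,
#'   `has_no_map`).
#' @export
generate_crosswalk <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- make_rng(spec$seed)
  sources <- sort(rand_codes(spec$n_source_codes, spec$source_length_range,
                             spec$source_alphabet, rng))
  rows <- list()
  truth <- list()
  for (src in sources) {
    m <- rng$draw_m(spec$m_distribution)
    if (m == 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        source = src, target = "NOMAP", approximate = 1L, no_map = 1L,
        combination = 0L, scenario = 0L, choice_list = 0L
      )
      truth[[length(truth) + 1L]] <- tibble(
        source_code = src, m = 0L, m0 = 0L, n_scenarios = 0L, v = 0,
        has_no_map = TRUE
      )
      next
    }
    targets <- rand_codes(m, spec$target_length_range, spec$target_alphabet, rng)
    use_comb <- m >= 4L && rng$unif() < spec$p_combination
    approx <- as.integer(m > 1L)
    if (!use_comb) {
      rows[[length(rows) + 1L]] <- tibble(
        source = src, target = targets, approximate = approx, no_map = 0L,
        combination = 0L, scenario = 0L, choice_list = 0L
      )
      truth[[length(truth) + 1L]] <- tibble(
        source_code = src, m = m, m0 = m, n_scenarios = 0L, v = as.numeric(m),
        has_no_map = FALSE
      )
      next
    }
    # combination map: reserve >= 4 codes for scenarios, the rest stand-alone
    s_max <- min(spec$scenario_count_range[2], m %/% 4L)
    s <- rng$int(min(spec$scenario_count_range[1], s_max), s_max)
    pool <- targets
    m0_max <- m - 4L * s
    m0 <- if (m0_max > 0L) rng$int(0L, m0_max) else 0L
    standalone <- if (m0 > 0L) pool[seq_len(m0)] else character()
    pool <- setdiff(pool, standalone)
    # split the remaining pool across scenarios as evenly as possible
    sc_sizes <- rep(length(pool) %/% s, s)
    extra <- length(pool) %% s
    if (extra > 0L) sc_sizes[seq_len(extra)] <- sc_sizes[seq_len(extra)] + 1L
    scenario_rows <- list()
    v <- m0
    sizes_rec <- character(s)
    for (i in seq_len(s)) {
      sc_pool <- pool[seq_len(sc_sizes[i])]
      pool <- pool[-seq_len(sc_sizes[i])]
      # partition the scenario pool into 2..9 non-empty choice lists
      n_cl <- min(
        max(spec$choice_list_count_range[1], 2L),
        spec$choice_list_count_range[2], length(sc_pool)
      )
      n_cl <- if (n_cl < length(sc_pool)) {
        rng$int(n_cl, min(spec$choice_list_count_range[2], length(sc_pool)))
      } else n_cl
      cut <- sort(rng$pick(seq_len(length(sc_pool) - 1L), n_cl - 1L))
      cl_sizes <- diff(c(0L, cut, length(sc_pool)))
      cl <- split(sc_pool, rep(seq_along(cl_sizes), cl_sizes))
      v <- v + prod(lengths(cl))
      sizes_rec[i] <- paste(lengths(cl), collapse = "x")
      scenario_rows[[i]] <- tibble(
        source = src, target = unlist(cl, use.names = FALSE),
        approximate = 1L, no_map = 0L, combination = 1L, scenario = i,
        choice_list = rep(seq_along(cl), lengths(cl))
      )
    }
    standalone_rows <- if (m0 > 0L) {
      tibble(source = src, target = standalone, approximate = approx,
             no_map = 0L, combination = 0L, scenario = 0L, choice_list = 0L)
    } else NULL
    rows[[length(rows) + 1L]] <- bind_rows(c(list(standalone_rows), scenario_rows))
    truth[[length(truth) + 1L]] <- tibble(
      source_code = src, m = m, m0 = m0, n_scenarios = s, v = v,
      has_no_map = FALSE
    )
  }
  list(
    crosswalk = new_gem_crosswalk(bind_rows(rows), direction = "synthetic"),
    ground_truth = bind_rows(truth)
  )
}

#' Fixture maps with published complexity signatures
#'
#' Small hand-built maps reproducing the (m, v) signatures of the worked
#' cases discussed for the 2015 procedure transition. The code strings are
#' synthetic; only the structural signature matches the published maps.
#'
#' \describe{
#'   \item{`"one-to-one"`}{m = 1; every measure is 0.}
#'   \item{`"721-like"`}{two 7-character codes differing in 6 positions,
#'     combined in a single scenario of two singleton choice lists:
#'     H(A) = 6 bits but v = 1 so H(B) = 0.}
#'   \item{`"7392-like"`}{three stand-alone codes whose alphabet variation
#'     is as small as distinctness permits (two positions each split 1/3 vs
#'     2/3): UR = log2(3) = 1.59 exceeds H(A)'s per-column contributions.}
#'   \item{`"0052-like"`}{m = 8 candidates, v = 9 representations:
#'     UR = 3 bits slightly understates H(B) = log2(9).}
#'   \item{`"0050-like"`}{m = 16 but v = 216: scenario products 36 + 180.}
#'   \item{`"688-like"`}{m = 16 but v = 2: two scenarios of eight singleton
#'     choice lists each.}
#' }
#'
#' @param kind Fixture name, see Details.
#' @return A [code_map()].
#' @export
make_worked_map <- function(kind = c("one-to-one", "721-like", "7392-like",
                                     "0052-like", "0050-like", "688-like")) {
  kind <- match.arg(kind)
  cd <- function(prefix, i, width = 7L) {
    stringr::str_pad(paste0(prefix, i), width, side = "right", pad = "Z")
  }
  switch(kind,
    "one-to-one" = code_map("1111", standalone = "0XY0000"),
    "721-like" = code_map(
      "721",
      scenarios = list(list("10D07Z3", "0W8NXZZ"))
    ),
    "7392-like" = code_map(
      "7392", standalone = c("10S0XZZ", "10S1XZZ", "10S1XZA")
    ),
    "0052-like" = {
      a <- cd("A", 1:2); b <- cd("B", 1:4); c6 <- cd("C", 1:2)
      code_map("0052", scenarios = list(
        list(a, b),                       # 2 x 4 = 8 pair representations
        list(c6[1], c6[2], a[1])          # one triple representation
      ))
    },
    "0050-like" = {
      p <- cd("P", 1:6); q <- cd("Q", 1:6); r <- cd("R", 1:4)
      # scenario 1: 6 x 6 = 36 pairs; scenario 2: 3 x 3 x 4 x 5 = 180
      # quadruples; codes recur across scenarios so the union stays at 16,
      # and the two scenarios' representations differ in cardinality
      code_map("0050", scenarios = list(
        list(p, q),
        list(p[1:3], p[4:6], r, q[1:5])
      ))
    },
    "688-like" = {
      g <- cd("G", 1:8); h <- cd("H", 1:8)
      code_map("688", scenarios = list(
        as.list(g),   # one fixed combination of 8 codes
        as.list(h)    # one alternative fixed combination
      ))
    }
  )
}
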
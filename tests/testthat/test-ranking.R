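# Normalization, weighting, summaries, class aggregation, rank agreement,
# outliers.

toy_measures <- function(h_a, h_b = h_a, ur = h_a,
                         codes = sprintf("%04d", seq_along(h_a))) {
  tbl <- tibble::tibble(
    source_code = codes, m = 2L, m0 = 2L, v = 2,
    h_a = h_a, h_b = h_b, ur = ur
  )
  class(tbl) <- unique(c("measure_tbl", class(tbl)))
  tbl
}

test_that("z-normalization centers and scales with the sample sd", {
  tbl <- normalize_measures(toy_measures(c(0, 2)))
  expect_equal(tbl$z_alpha, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(mean(tbl$z_alpha), 0, tolerance = 1e-12)
  expect_equal(sd(tbl$z_alpha), 1, tolerance = 1e-12)

  flat <- normalize_measures(toy_measures(c(1, 1, 1)))
  expect_equal(flat$z_alpha, c(0, 0, 0))

  expect_error(normalize_measures(toy_measures(1)), "at least 2")
})

test_that("z columns have mean 0 and unit sample sd on synthetic data", {
  sim <- generate_crosswalk(synthetic_spec(n_source_codes = 300, seed = 2))
  tbl <- normalize_measures(compute_measures(build_code_maps(sim$crosswalk)))
  for (zc in c("z_alpha", "z_beta", "z_ur")) {
    expect_lt(abs(mean(tbl[[zc]])), 1e-9)
    expect_equal(sd(tbl[[zc]]), 1, tolerance = 1e-9)
  }
})

test_that("normalization is idempotent on already-normalized columns", {
  sim <- generate_crosswalk(synthetic_spec(n_source_codes = 200, seed = 4))
  tbl <- normalize_measures(compute_measures(build_code_maps(sim$crosswalk)))
  renorm <- tbl
  renorm$h_a <- tbl$z_alpha
  renorm$h_b <- tbl$z_beta
  renorm$ur <- tbl$z_ur
  renorm <- normalize_measures(renorm)
  expect_equal(renorm$z_alpha, tbl$z_alpha, tolerance = 1e-9)
  expect_equal(renorm$z_beta, tbl$z_beta, tolerance = 1e-9)
})

test_that("probability weighting scales z scores linearly", {
  tbl <- normalize_measures(toy_measures(c(0, 1, 2, 5)))
  zero <- suppressMessages(weight_by_probability(
    tbl, tibble::tibble(code = tbl$source_code, probability = 0)
  ))
  expect_true(all(zero$z_alpha == 0))

  ident <- weight_by_probability(
    tbl, tibble::tibble(code = tbl$source_code, probability = 1)
  )
  expect_equal(ident$z_alpha, tbl$z_alpha)

  quarter <- weight_by_probability(
    tbl, tibble::tibble(code = tbl$source_code, probability = 0.25)
  )
  expect_equal(quarter$z_alpha, tbl$z_alpha / 4)

  expect_message(
    part <- weight_by_probability(
      tbl, tibble::tibble(code = tbl$source_code[1:2], probability = 0.5)
    ),
    "missing"
  )
  expect_equal(part$z_alpha[3:4], c(0, 0))
  expect_error(
    weight_by_probability(tbl, tibble::tibble(code = "0001", probability = 1.5)),
    "\\[0, 1\\]"
  )
})

test_that("descriptive statistics use linear-interpolation quartiles", {
  one <- describe_measures(toy_measures(3))
  expect_equal(one$q25, rep(3, 3))
  expect_equal(one$median, rep(3, 3))
  expect_equal(one$q75, rep(3, 3))

  d <- describe_measures(toy_measures(c(0, 1, 2, 10)))
  row <- d[d$measure == "h_a", ]
  expect_equal(row$count, 4L)
  expect_equal(row$mean, 3.25)
  expect_equal(row$std, sd(c(0, 1, 2, 10)))
  expect_equal(row$q25, 0.75)   # type-7 interpolation
  expect_equal(row$median, 1.5)
  expect_equal(row$q75, 4)
  expect_equal(row$max, 10)
})

test_that("summary count equals the number of included maps", {
  sim <- generate_crosswalk(synthetic_spec(n_source_codes = 250, seed = 6))
  maps <- build_code_maps(sim$crosswalk)
  tbl <- compute_measures(maps)
  d <- describe_measures(tbl)
  expect_equal(unique(d$count), sum(maps$m >= 1L))
})

test_that("codes are assigned to the first matching class rule", {
  v3 <- default_class_defs("icd9_vol3")
  expect_equal(assign_class("7721", v3),
               "Operations on the Musculoskeletal System (76-84)")
  expect_equal(assign_class("0052", v3),
               "Procedures And Interventions, Not Elsewhere Classified (00)")
  pcs <- default_class_defs("icd10_pcs")
  expect_equal(assign_class("00Z999", pcs), "Medical and Surgical (0)")
  expect_equal(assign_class("ZZZZ", pcs), "Unclassified")
  cm <- default_class_defs("icd10_cm")
  expect_equal(assign_class("O9A12", cm),
               "Pregnancy, childbirth and the puerperium (O00-O9A)")
  expect_equal(assign_class("T79A1XA", cm),
               "Injury, poisoning and certain other consequences of external causes (S00-T88)")
  dx <- default_class_defs("icd9_dx")
  expect_equal(assign_class("E8889", dx),
               "Supplementary Classification Of External Causes Of Injury And Poisoning (E000-E999)")
  expect_equal(assign_class("80010", dx), "Injury And Poisoning (800-999)")
})

test_that("class scores sum to zero overall and order classes by construction", {
  sim <- generate_crosswalk(synthetic_spec(n_source_codes = 300, seed = 8))
  tbl <- normalize_measures(compute_measures(build_code_maps(sim$crosswalk)))
  scores <- class_scores(tbl, default_class_defs("icd9_vol3"))
  expect_equal(sum(scores$n), nrow(tbl))
  expect_lt(abs(sum(scores$sum_z_alpha)), 1e-6)
  expect_lt(abs(sum(scores$sum_z_beta)), 1e-6)
  expect_lt(abs(sum(scores$sum_z_ur)), 1e-6)
  expect_true(all(scores$n > 0L))

  # one class holding every record sums to ~0
  all_in_one <- class_scores(tbl, tibble::as_tibble(list(
    label = "Everything", kind = "range", lo = "0", hi = "Z",
    prefix_len = 1L, chars = list(character())
  )))
  expect_equal(nrow(all_in_one), 1L)
  expect_lt(abs(all_in_one$sum_z_alpha), 1e-6)

  # complex maps concentrated in one class push its sum above the other
  xw <- gem_crosswalk(tibble::tibble(
    source = c("1001", "1002", rep("9001", 2), rep("9002", 2)),
    target = c("AAA0000", "AAA0000", "BBB1111", "CCC2222", "DDD3333", "EEE4444"),
    flag = c("00000", "00000", "10000", "10000", "10000", "10000")
  ))
  tbl2 <- normalize_measures(compute_measures(build_code_maps(xw)))
  defs <- tibble::tibble(
    label = c("Low", "High"), kind = "range",
    lo = c("1", "9"), hi = c("1", "9"), prefix_len = 1L,
    chars = list(character(), character())
  )
  sc2 <- class_scores(tbl2, defs)
  expect_gt(sc2$sum_z_alpha[sc2$label == "High"], 0)
  expect_lt(sc2$sum_z_alpha[sc2$label == "Low"], 0)
})

test_that("rank agreement is tie-corrected Kendall tau-b", {
  expect_equal(kendall_tau(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3)), 1)
  expect_equal(kendall_tau(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1)), -1)
  expect_equal(kendall_tau(c(a = 1, b = 2, c = 3), c(a = 1, b = 3, c = 2)),
               1 / 3, tolerance = 1e-12)
  # label matching, not position matching
  expect_equal(
    kendall_tau(c(a = 1, b = 2, c = 3), c(c = 3, a = 1, b = 2)), 1
  )
  expect_error(kendall_tau(c(a = 1, b = 2), c(a = 1, d = 2)), "label set")

  set.seed(99)
  for (i in 1:20) {
    x <- sample(0:3, 8, replace = TRUE)
    y <- sample(0:3, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau(x, y), oracle_tau_b(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau(x, y), kendall_tau(y, x))
    expect_gte(kendall_tau(x, y), -1)
    expect_lte(kendall_tau(x, y), 1)
  }
})

test_that("the tau matrix is symmetric with a unit diagonal", {
  sim <- generate_crosswalk(synthetic_spec(n_source_codes = 300, seed = 10))
  tbl <- normalize_measures(compute_measures(build_code_maps(sim$crosswalk)))
  tm <- tau_matrix(class_scores(tbl, default_class_defs("icd9_vol3")))
  expect_equal(diag(tm), c(z_alpha = 1, z_beta = 1, z_ur = 1))
  expect_equal(tm, t(tm))
  expect_true(all(tm >= -1 & tm <= 1))
})

test_that("outlier selection honours threshold and top-fraction rules", {
  h <- c(rep(0, 995), 1, 2, 3, 4, 50)
  tbl <- normalize_measures(toy_measures(h))
  top <- flag_outliers(tbl, "z_alpha", top_fraction = 0.01)
  expect_equal(nrow(top), 10L)
  expect_gte(min(top$z_alpha), max(tbl$z_alpha[!tbl$source_code %in% top$source_code]))

  expect_equal(nrow(flag_outliers(tbl, "z_alpha", threshold = Inf)), 0L)

  injected <- flag_outliers(tbl, "z_alpha", top_fraction = 1 / nrow(tbl))
  expect_equal(injected$h_a, 50)

  f_small <- flag_outliers(tbl, "z_alpha", top_fraction = 0.002)
  f_big <- flag_outliers(tbl, "z_alpha", top_fraction = 0.01)
  expect_true(all(f_small$source_code %in% f_big$source_code))

  expect_error(flag_outliers(tbl, "z_alpha"), "exactly one")
  expect_error(flag_outliers(tbl, "z_alpha", threshold = 1, top_fraction = 0.1),
               "exactly one")
  thr <- flag_outliers(tbl, "z_alpha", threshold = 2.7)
  expect_true(all(thr$z_alpha > 2.7))
})
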
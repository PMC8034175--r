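# Independent oracles used across tests.

# Brute-force alphabet entropy: pad codes right with `pad` to the max
# length, then sum per-column -sum(p log2 p) computed via table().
oracle_h_alpha <- function(codes, pad = "~") {
  n <- max(nchar(codes))
  padded <- vapply(codes, function(cd) {
    paste0(cd, strrep(pad, n - nchar(cd)))
  }, "")
  chars <- do.call(rbind, strsplit(padded, ""))
  sum(apply(chars, 2, function(col) {
    p <- as.numeric(table(col)) / length(col)
    -sum(p * log2(p))
  }))
}

# Pair-counting Kendall tau-b.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0) tx <- tx + 1   # pairs tied in both count in both terms
      if (dy == 0) ty <- ty + 1
      if (dx != 0 && dy != 0) {
        if (dx == dy) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

write_gem_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

expect_setequal_reps <- function(reps, expected) {
  canon <- function(x) sort(vapply(x, function(r) paste(sort(r), collapse = "+"), ""))
  expect_identical(canon(reps), canon(expected))
}
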
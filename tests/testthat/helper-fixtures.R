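# Programmatic fixtures: small delimited files in the two UCI Wisconsin
# layouts (synthetic contents, real dialect) plus shared toy datasets.

# Synthetic file in the WBC (Original) layout: ID, 9 integer features,
# class 2 = benign / 4 = malignant, "?" marks missing cells.
write_wbc_style_file <- function(path, n = 12L, n_missing_rows = 2L,
                                 seed = 101L) {
  set.seed(seed)
  ids <- 1000000L + seq_len(n)
  feats <- matrix(sample(1:10, n * 9L, replace = TRUE), n, 9L)
  cls <- ifelse(seq_len(n) %% 3L == 0L, 4L, 2L)
  lines <- vapply(seq_len(n), function(i)
    paste(c(ids[i], feats[i, ], cls[i]), collapse = ","), character(1L))
  # plant missing markers in the 6th feature of the first rows
  for (i in seq_len(n_missing_rows)) {
    parts <- strsplit(lines[i], ",")[[1L]]
    parts[7L] <- "?"
    lines[i] <- paste(parts, collapse = ",")
  }
  writeLines(lines, path)
  list(n = n, missing_cells = n_missing_rows,
       n_malignant = sum(cls == 4L), n_benign = sum(cls == 2L))
}

# Synthetic file in the WDBC (Diagnostic) layout: ID, M/B diagnosis,
# 30 real features.
write_wdbc_style_file <- function(path, n = 10L, seed = 202L) {
  set.seed(seed)
  ids <- 84000L + seq_len(n)
  cls <- ifelse(seq_len(n) %% 2L == 0L, "M", "B")
  feats <- matrix(round(runif(n * 30L, 0.01, 2500), 4L), n, 30L)
  lines <- vapply(seq_len(n), function(i)
    paste(c(ids[i], cls[i], feats[i, ]), collapse = ","), character(1L))
  writeLines(lines, path)
  list(n = n, n_malignant = sum(cls == "M"), n_benign = sum(cls == "B"))
}

toy_dataset <- function(n = 40L, d = 6L, seed = 9L) {
  set.seed(seed)
  tabular_dataset(matrix(rnorm(n * d), n, d),
                  labels = rep_len(c(0L, 1L), n))
}

# Independent permutation enumerator for ordering oracles: plain loops,
# no shared code with the package's search.
all_permutations <- function(d) {
  if (d == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(d - 1L)) {
    for (pos in seq_len(d)) {
      out[[length(out) + 1L]] <- append(p, d, after = pos - 1L)
    }
  }
  out
}

naive_path_cost <- function(order, ranks) {
  s <- 0
  for (k in seq_len(length(order) - 1L)) {
    i <- order[k]; j <- order[k + 1L]
    s <- s + (ranks[i, j] + ranks[j, i]) / 2
  }
  s
}
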
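test_that("bar-graph geometry follows psi*d + gamma*(d+1) and hand rasterization", {
  expect_equal(bar_graph_width(10, 1, 2), 32L)
  expect_equal(bar_graph_width(30, 1, 2), 92L)
  expect_equal(bar_graph_width(9, 2, 2), 38L)
  # d = 1, psi = 1, gamma = 2, x = 1: 5x5 with the middle column full
  img <- encode_bar_graph(1, encoding_config("bar"))$pixels[, , 1]
  oracle <- matrix(0, 5, 5); oracle[, 3] <- 1
  expect_equal(img, oracle)
  # all-zero record draws nothing
  expect_equal(sum(encode_bar_graph(rep(0, 7), encoding_config("bar"))$pixels), 0)
  # out-of-range and empty records are rejected
  expect_error(encode_bar_graph(c(0.5, 1.2), encoding_config("bar")), "0, 1")
  expect_error(encode_bar_graph(numeric(0), encoding_config("bar")), "at least")
})

test_that("bar-graph foreground pixel count equals sum(round(x_k * W)) * psi", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(3:20, 1)
    psi <- sample(c(1L, 2L, 4L), 1)
    x <- runif(d)
    cfg <- encoding_config("bar", px = psi)
    w <- bar_graph_width(d, psi, 2)
    img <- encode_bar_graph(x, cfg)$pixels
    expect_equal(dim(img)[1:2], c(w, w))
    expect_equal(sum(img), sum(round(x * w)) * psi)
    expect_true(all(img %in% c(0, 1)))
  }
})

test_that("distance matrix is the max-normalized pairwise |x_i - x_j| with replication upscaling", {
  m <- encode_distance_matrix(c(0, 0.5, 1),
                              encoding_config("dist", upscale = 1))$pixels[, , 1]
  expect_equal(m, rbind(c(0, 0.5, 1), c(0.5, 0, 0.5), c(1, 0.5, 0)))
  # constant record -> all zeros, not NaN
  z <- encode_distance_matrix(rep(0.4, 5), encoding_config("dist"))$pixels
  expect_equal(sum(z), 0)
  # upscaling replicates each pixel into a 3x3 constant block
  up <- encode_distance_matrix(c(0, 0.5, 1), encoding_config("dist"))$pixels[, , 1]
  expect_equal(dim(up), c(9L, 9L))
  expect_equal(up, kronecker(m, matrix(1, 3, 3)))
  # symmetry, zero diagonal, and max 1 for any non-constant record
  for (seed in 1:5) {
    set.seed(seed)
    x <- runif(sample(2:25, 1))
    mm <- encode_distance_matrix(x, encoding_config("dist", upscale = 1))$pixels[, , 1]
    expect_equal(mm, t(mm))
    expect_equal(diag(mm), rep(0, length(x)))
    expect_equal(max(mm), 1)
    expect_true(all(mm >= 0 & mm <= 1))
  }
  expect_error(encode_distance_matrix(0.3, encoding_config("dist")), "at least 2")
})

test_that("combined encoding stacks distance, cropped bars and the row-wise copy", {
  x <- c(0.2, 0.8)
  img <- encode_combined(x, encoding_config("combined"))
  expect_equal(dim(img$pixels), c(6L, 6L, 3L))
  # channel 3: rows 1-3 constant at x_1, rows 4-6 at x_2
  expect_equal(img$pixels[1:3, , 3], matrix(0.2, 3, 6))
  expect_equal(img$pixels[4:6, , 3], matrix(0.8, 3, 6))
  # channel 1 is exactly the upscaled distance matrix
  expect_equal(img$pixels[, , 1],
               encode_distance_matrix(x, encoding_config("dist"))$pixels[, , 1])
  # channel 2 is the native bar graph minus its one-pixel border
  bar <- encode_bar_graph(x, encoding_config("bar"))$pixels[, , 1]
  expect_equal(img$pixels[, , 2], bar[2:7, 2:7])
  # constant record: channel 1 all zero, channel 3 constant
  flat <- encode_combined(rep(0.5, 4), encoding_config("combined"))$pixels
  expect_equal(sum(flat[, , 1]), 0)
  expect_equal(unique(as.vector(flat[, , 3])), 0.5)
})

test_that("all encoders emit square deterministic images with intensities in [0,1]", {
  set.seed(77)
  x <- runif(12)
  for (method in c("bar", "dist", "combined")) {
    cfg <- encoding_config(method)
    a <- encode_record(x, cfg)
    b <- encode_record(x, cfg)
    expect_identical(a$pixels, b$pixels)
    dm <- dim(a$pixels)
    expect_equal(dm[1], dm[2])
    expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  }
})

test_that("field order is applied before encoding and commutes with permuting the record", {
  set.seed(5)
  x <- runif(8)
  ord <- sample(8)
  cfg_ord <- encoding_config("combined", field_order = ord)
  cfg_plain <- encoding_config("combined")
  expect_identical(encode_record(x, cfg_ord)$pixels,
                   encode_record(x[ord], cfg_plain)$pixels)
  expect_error(encode_record(x, encoding_config("bar", field_order = c(1, 1, 2))),
               "permutation")
})

test_that("dataset encoding writes one PNG per record plus a readable manifest", {
  dir <- withr::local_tempdir()
  ds <- minmax_normalize(toy_dataset(n = 6L, d = 5L))
  manifest <- encode_dataset(ds, encoding_config("combined"), dir)
  expect_equal(nrow(manifest), 6L)
  expect_true(all(file.exists(file.path(dir, manifest$filename))))
  back <- read_encoded_dataset(dir)
  expect_equal(dim(back$images), c(15L, 15L, 3L, 6L))
  expect_equal(back$labels, ds$labels)
  # 8-bit quantization on disk: within half a level of the in-memory image
  first <- encode_record(ds$features[1, ], encoding_config("combined"))$pixels
  expect_lt(max(abs(back$images[, , , 1] - first)), 0.5 / 255 + 1e-9)
})
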
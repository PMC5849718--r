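test_that("default filter bank has the 17-dimensional Lab structure", {
  bank <- default_filter_bank()
  expect_length(bank$kernels, 17L)  # 9 Gaussians + 4 LoG + 4 derivatives
  types <- vapply(bank$kernels, `[[`, "", "type")
  expect_equal(sum(types == "gaussian"), 9L)
  expect_equal(sum(types == "log"), 4L)
  expect_equal(sum(types %in% c("dx", "dy")), 4L)
  # Gaussians cover all three Lab channels; LoG and derivatives use L only
  expect_setequal(vapply(bank$kernels[types == "gaussian"], `[[`, 0L, "channel"), 1:3)
  expect_true(all(vapply(bank$kernels[types != "gaussian"], `[[`, 0L, "channel") == 1L))
  for (k in bank$kernels) {
    expect_true(all(dim(k$kernel) %% 2 == 1))
    s <- sum(k$kernel)
    if (k$type == "gaussian") expect_equal(s, 1, tolerance = 1e-6)
    else expect_lt(abs(s), 1e-6)  # zero-mean LoG / derivative kernels
  }
})

test_that("descriptors of a constant image are the expected constants", {
  img <- array(0, dim = c(12, 14, 3))
  img[, , 1] <- 120; img[, , 2] <- 80; img[, , 3] <- 60
  bank <- default_filter_bank()
  desc <- compute_descriptors(img, bank)
  lab <- rgb_to_lab(img)
  for (j in seq_along(bank$kernels)) {
    k <- bank$kernels[[j]]
    expected <- if (k$type == "gaussian") lab[1, 1, k$channel] else 0
    expect_equal(as.vector(desc[, , j]), rep(expected, 12 * 14), tolerance = 1e-8)
  }
})

test_that("convolution matches a brute-force reflect-padded oracle", {
  set.seed(31)
  x <- matrix(runif(9 * 11), 9, 11)
  for (k in list(gaussian_kernel(1), deriv_gaussian_kernel(2, "x"),
                 matrix(c(0, 0, 0, 1, 0, 0, 0, 0, 0), 3, 3))) {
    expect_equal(conv2_reflect(x, k), brute_conv2_reflect(x, k), tolerance = 1e-10)
  }
  # impulse image: the response reproduces the kernel around the impulse
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  g <- gaussian_kernel(1)
  out <- conv2_reflect(imp, g)
  expect_equal(out[5:11, 5:11], g, tolerance = 1e-10)
})

test_that("descriptors are translation-equivariant away from borders", {
  set.seed(5)
  img <- array(runif(40 * 40 * 3, 0, 255), dim = c(40, 40, 3))
  shifted <- img[c(3:40, 1:2), c(2:40, 1), ]  # shift by (-2, -1)
  bank <- default_filter_bank(gauss_sigmas = c(1, 2), log_sigmas = 2,
                              deriv_sigmas = 2)
  d1 <- compute_descriptors(img, bank)
  d2 <- compute_descriptors(shifted, bank)
  # interior: rows 10..28 of the shifted image = rows 12..30 of the original
  expect_equal(d2[10:28, 10:28, ], d1[12:30, 11:29, ], tolerance = 1e-8)
})

test_that("codebook fitting matches closed forms and exhaustive assignment", {
  set.seed(8)
  x <- matrix(rnorm(50 * 3), 50, 3)
  cb1 <- build_codebook(x, size = 1, seed = 1)
  # single centroid = mean of the standardized descriptors (zero by centering)
  expect_equal(as.vector(cb1$centroids), rep(0, 3), tolerance = 1e-10)

  # two well-separated clouds on <= 10 points: exhaustive 2-means oracle
  pts <- rbind(matrix(rnorm(5 * 2, mean = 0, sd = 0.05), 5, 2),
               matrix(rnorm(5 * 2, mean = 4, sd = 0.05), 5, 2))
  cb2 <- build_codebook(pts, size = 2, seed = 3)
  xs <- sweep(sweep(pts, 2, cb2$center), 2, cb2$scale, "/")
  best <- Inf; best_centers <- NULL
  for (split in 0:(2^10 - 1)) {  # every 2-colouring of the 10 points
    grp <- as.logical(bitwAnd(split, 2^(0:9)))
    if (!any(grp) || all(grp)) next
    c1 <- colMeans(xs[grp, , drop = FALSE]); c2 <- colMeans(xs[!grp, , drop = FALSE])
    cost <- sum(sweep(xs[grp, , drop = FALSE], 2, c1)^2) +
      sum(sweep(xs[!grp, , drop = FALSE], 2, c2)^2)
    if (cost < best) { best <- cost; best_centers <- rbind(c1, c2) }
  }
  reorder <- if (sum((cb2$centroids[1, ] - best_centers[1, ])^2) <
                 sum((cb2$centroids[1, ] - best_centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(cb2$centroids), unname(best_centers[reorder, ]),
               tolerance = 1e-6)

  # as many words as distinct descriptors: zero quantization error
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  cb4 <- build_codebook(d, size = 4, seed = 1)
  w <- quantize_descriptors(d, cb4)
  xs <- sweep(sweep(d, 2, cb4$center), 2, cb4$scale, "/")
  expect_equal(max(rowSums((xs - cb4$centroids[w, ])^2)), 0, tolerance = 1e-12)

  expect_error(build_codebook(matrix(1, 5, 2), size = 2), "distinct")
})

test_that("quantization matches an exhaustive scan and breaks ties low", {
  set.seed(12)
  x <- matrix(rnorm(25 * 4), 25, 4)
  cb <- build_codebook(x, size = 4, seed = 2)
  field <- array(rnorm(5 * 5 * 4), dim = c(5, 5, 4))
  words <- quantize_descriptors(field, cb)
  expect_equal(as.vector(words), brute_quantize(descriptor_matrix(field), cb))

  # exact centroid recovers its own index (idempotence on centroids)
  cents_raw <- sweep(sweep(cb$centroids, 2, cb$scale, "*"), 2, cb$center, "+")
  expect_equal(as.vector(quantize_descriptors(cents_raw, cb)), 1:4)

  # equidistant descriptor goes to the lower index
  cb_tie <- cb
  cb_tie$centroids <- matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, 3, 0, 0, 0), 3, 4,
                             byrow = TRUE)
  cb_tie$center <- rep(0, 4); cb_tie$scale <- rep(1, 4)
  mid <- matrix(c(0, 0, 0, 0), 1, 4)
  expect_equal(as.vector(quantize_descriptors(mid, cb_tie)), 1L)

  expect_error(quantize_descriptors(matrix(0, 2, 3), cb), "dimension")
})
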
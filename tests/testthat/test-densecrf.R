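random_problem <- function(h, w, K = 3) {
  img <- array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
  g0 <- matrix(rgamma(h * w * K, 1), ncol = K)
  list(image = img,
       unary = array(-log(g0 / rowSums(g0)), dim = c(h, w, K)))
}

test_that("unary energies are the negative log posterior", {
  post <- array(1 / 3, dim = c(4, 5, 3))
  expect_equal(unary_from_posterior(post),
               array(log(3), dim = c(4, 5, 3)), tolerance = 1e-12)
  p <- array(c(0.7, 0.3), dim = c(1, 1, 2))
  expect_equal(as.vector(unary_from_posterior(p)), c(-log(0.7), -log(0.3)),
               tolerance = 1e-12)
  # monotone: larger probability, strictly smaller energy
  set.seed(4)
  q <- matrix(rgamma(30, 1), 10, 3); q <- q / rowSums(q)
  u <- unary_from_posterior(array(q, dim = c(10, 1, 3)))
  um <- matrix(u, 10, 3)
  for (i in 1:10) expect_equal(order(um[i, ]), order(q[i, ], decreasing = TRUE))
  expect_error(unary_from_posterior(array(0, dim = c(2, 2, 2))), "zero prob")
})

test_that("zero pairwise weights reduce mean-field to softmax of the unary", {
  set.seed(10)
  pr <- random_problem(6, 7)
  params <- crf_params(w_appearance = 0, w_smoothness = 0, n_iterations = 7)
  out <- mean_field(pr$unary, pr$image, params)
  U <- matrix(pr$unary, 42, 3)
  expected <- exp(-U) / rowSums(exp(-U))
  expect_equal(out, array(expected, dim = dim(pr$unary)), tolerance = 1e-12)
})

test_that("uniform unary on a constant image stays uniform (Potts symmetry)", {
  u <- array(log(3), dim = c(8, 8, 3))
  img <- array(128, dim = c(8, 8, 3))
  for (eng in c("lattice", "exact")) {
    out <- mean_field(u, img, crf_params(n_iterations = 4), engine = eng)
    expect_equal(as.vector(out), rep(1 / 3, 8 * 8 * 3), tolerance = 1e-9)
  }
})

test_that("marginals stay normalized and engines match the brute-force oracle", {
  set.seed(77)
  pr <- random_problem(10, 12)
  params <- crf_params(n_iterations = 4)
  oracle <- brute_mean_field(pr$unary, pr$image, params, iters = 4)
  qe <- mean_field(pr$unary, pr$image, params, engine = "exact")
  qf <- mean_field(pr$unary, pr$image, params, engine = "lattice")
  expect_equal(apply(qf, c(1, 2), sum), matrix(1, 10, 12), tolerance = 1e-9)
  expect_equal(qe, oracle, tolerance = 1e-6)   # same math, independent code
  expect_equal(max(abs(qf - qe)), 0, tolerance = 1e-3)
})

test_that("engines agree within 1e-3 on random 32x32 problems", {
  set.seed(123)
  for (trial in 1:3) {
    pr <- random_problem(32, 32)
    params <- crf_params(n_iterations = 3)
    qe <- mean_field(pr$unary, pr$image, params, engine = "exact")
    qf <- mean_field(pr$unary, pr$image, params, engine = "lattice")
    expect_lt(max(abs(qf - qe)), 1e-3)
  }
})

test_that("MAP labelling is an argmax with low-index tie-breaking", {
  one_hot <- array(0, dim = c(2, 2, 3))
  one_hot[1, 1, 2] <- 1; one_hot[1, 2, 3] <- 1
  one_hot[2, 1, 1] <- 1; one_hot[2, 2, 2] <- 1
  expect_equal(map_labels(one_hot), matrix(c(2L, 1L, 3L, 2L), 2, 2))
  tie <- array(0.5, dim = c(1, 1, 2))
  expect_equal(map_labels(tie)[1, 1], 1L)
  set.seed(3)
  m <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  lab <- map_labels(m)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(lab[i, j], which(m[i, j, ] == max(m[i, j, ]))[1])
  }
})

test_that("shape mismatches and oversized exact problems are rejected", {
  pr <- random_problem(4, 4)
  expect_error(mean_field(pr$unary, array(0, dim = c(5, 4, 3)), crf_params()),
               "extents")
  big_u <- array(1, dim = c(100, 100, 2))
  big_i <- array(1, dim = c(100, 100, 3))
  expect_error(mean_field(big_u, big_i, crf_params(), engine = "exact"),
               "quadratic")
})
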
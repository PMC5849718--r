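# Fully connected CRF refinement by mean-field inference.
#
# The unary energy comes from the LDA pixel posterior; the pairwise energy
# couples every pixel pair through two Gaussian kernels under a Potts
# compatibility: an appearance (bilateral) kernel over position and RGB
# colour, and a spatial smoothness kernel. Two engines share one contract:
# an exact O(N^2) reference for small images, and a lattice engine that
# approximates the bilateral Gaussian transform by B-spline splatting onto
# a regular 5-D grid, separable blurring with a spectrally deconvolved
# kernel, and slicing. The smoothness kernel lives on the integer pixel
# grid, where separable convolution is exact, so only the bilateral term is
# approximated.

#' Parameters of the fully connected CRF
#'
#' @param w_appearance Weight w1 of the appearance (bilateral) kernel.
#' @param w_smoothness Weight w2 of the spatial smoothness kernel.
#' @param theta_alpha Spatial standard deviation of the appearance kernel
#'   (pixels).
#' @param theta_beta Colour standard deviation of the appearance kernel
#'   (intensity units, raw RGB in `[0, 255]`).
#' @param theta_gamma Spatial standard deviation of the smoothness kernel
#'   (pixels).
#' @param n_iterations Mean-field iterations (parallel updates).
#' @return An object of class `crf_params`. Compatibility is Potts:
#'   `mu(a, b) = 1` iff `a != b`.
#' @export
crf_params <- function(w_appearance = 10, w_smoothness = 3,
                       theta_alpha = 60, theta_beta = 20, theta_gamma = 3,
                       n_iterations = 10L) {
  stopifnot(w_appearance >= 0, w_smoothness >= 0,
            theta_alpha > 0, theta_beta > 0, theta_gamma > 0,
            is_count(n_iterations))
  structure(list(w_appearance = w_appearance, w_smoothness = w_smoothness,
                 theta_alpha = theta_alpha, theta_beta = theta_beta,
                 theta_gamma = theta_gamma,
                 n_iterations = as.integer(n_iterations)),
            class = "crf_params")
}

#' Unary energies from a pixel posterior
#'
#' `energies = -log(probs)`, elementwise; lower energy means more likely.
#'
#' @param posterior H x W x K array of per-pixel class probabilities
#'   (strictly positive; see the smoothing in [lda_posterior()]).
#' @return H x W x K array of finite unary energies.
#' @export
unary_from_posterior <- function(posterior) {
  stopifnot(is.array(posterior), length(dim(posterior)) == 3L)
  if (any(posterior <= 0)) {
    stop("infinite energy: posterior contains zero probabilities; use a positive eps",
         call. = FALSE)
  }
  -log(posterior)
}

# Deconvolved 1-D blur taps for the lattice engine: the discrete kernel b
# whose composition with B-spline splat and slice reproduces exp(-x^2/2),
# solved in the frequency domain (b_hat = g_hat / sinc^(2(order+1))).
lattice_blur_taps <- function(spacing, order, radius = ceiling(5 / spacing),
                              n = 20001L) {
  th <- seq(0, pi, length.out = n)
  sincv <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  integrand <- sqrt(2 * pi) / spacing * exp(-th^2 / (2 * spacing^2)) /
    sincv(th / 2)^(2 * (order + 1))
  vapply(0:radius, function(t) {
    f <- integrand * cos(th * t)
    (1 / pi) * sum((f[-1L] + f[-n]) / 2 * diff(th))
  }, numeric(1))
}

# Splat order and lattice spacing by problem size: small problems get a
# near-exact transform (the regime where the exact engine can certify the
# lattice), large ones trade accuracy for near-linear cost. The choice is
# deterministic in the pixel count only.
lattice_policy <- function(n_pixels) {
  if (n_pixels <= 1024L) {
    list(order = 7L, spacing = 0.5)
  } else if (n_pixels <= 20000L) {
    list(order = 3L, spacing = 0.7)
  } else {
    list(order = 2L, spacing = 0.7)
  }
}

# Bilateral message via the lattice engine, excluding the self term.
lattice_message <- function(feat, q, order, spacing, taps) {
  g <- lattice_gauss_transform_cpp(feat, q, spacing, taps, order)
  g$values - g$self_weight * q
}

# Exact spatial Gaussian message on the pixel grid (zero boundary),
# excluding the self term; truncation radius 5 theta keeps the neglected
# tail below 4e-6 per pair.
spatial_message <- function(q, height, width, theta) {
  R <- ceiling(5 * theta)
  taps <- exp(-(0:R)^2 / (2 * theta^2))
  K <- ncol(q)
  out <- matrix(0, height * width, K)
  for (k in seq_len(K)) {
    m <- matrix(q[, k], height, width)
    m2 <- matrix(0, height, width)
    for (t in -R:R) {
      lo <- max(1L, 1L - t); hi <- min(height, height - t)
      if (lo > hi) next
      rs <- lo:hi
      m2[rs, ] <- m2[rs, ] + taps[abs(t) + 1L] * m[rs + t, , drop = FALSE]
    }
    m3 <- matrix(0, height, width)
    for (t in -R:R) {
      lo <- max(1L, 1L - t); hi <- min(width, width - t)
      if (lo > hi) next
      cs <- lo:hi
      m3[, cs] <- m3[, cs] + taps[abs(t) + 1L] * m2[, cs + t, drop = FALSE]
    }
    out[, k] <- as.vector(m3) - q[, k]
  }
  out
}

#' Mean-field inference for the fully connected CRF
#'
#' Initializes the marginals as `softmax(-unary)` and applies
#' `n_iterations` parallel updates: message passing under the appearance
#' and smoothness kernels (excluding each pixel's self-contribution), Potts
#' compatibility transform, addition of the unary energies, and
#' renormalization.
#'
#' @param unary H x W x K array of unary energies, e.g.
#'   [unary_from_posterior()].
#' @param image H x W x 3 RGB array in `[0, 255]` supplying the colour
#'   features of the appearance kernel.
#' @param params A [crf_params()].
#' @param engine `"lattice"` (default, near-linear time) or `"exact"` (the
#'   O(N^2) reference, small images only).
#' @return H x W x K array of mean-field marginals (class probabilities,
#'   rows summing to one).
#' @export
mean_field <- function(unary, image, params = crf_params(),
                       engine = c("lattice", "exact")) {
  engine <- match.arg(engine)
  check_rgb(image)
  stopifnot(is.array(unary), length(dim(unary)) == 3L,
            inherits(params, "crf_params"))
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (dim(unary)[1L] != h || dim(unary)[2L] != w) {
    stop("invalid input: unary and image extents differ", call. = FALSE)
  }
  K <- dim(unary)[3L]
  N <- h * w
  U <- matrix(unary, N, K)
  if (any(!is.finite(U))) stop("invalid input: unary energies must be finite",
                               call. = FALSE)
  q <- softmax_neg(U)
  if (params$w_appearance == 0 && params$w_smoothness == 0) {
    # no messages: softmax(-unary) is the fixed point at any iteration count
    return(array(q, dim = dim(unary)))
  }
  pos <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  featA <- cbind(pos / params$theta_alpha,
                 cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                       as.vector(image[, , 3L])) / params$theta_beta)
  if (engine == "exact") {
    if (N > 8192L) {
      stop("invalid input: the exact engine is quadratic in the pixel count; ",
           "use engine = \"lattice\" for images larger than 8192 pixels",
           call. = FALSE)
    }
    KA <- exp(-as.matrix(stats::dist(featA))^2 / 2); diag(KA) <- 0
    KS <- exp(-as.matrix(stats::dist(pos / params$theta_gamma))^2 / 2)
    diag(KS) <- 0
  } else {
    pol <- lattice_policy(N)
    ord <- pol$order
    spacing <- pol$spacing
    taps <- lattice_blur_taps(spacing, ord)
  }
  for (it in seq_len(params$n_iterations)) {
    if (engine == "exact") {
      mA <- KA %*% q
      mS <- KS %*% q
    } else {
      mA <- lattice_message(featA, q, ord, spacing, taps)
      mS <- spatial_message(q, h, w, params$theta_gamma)
    }
    M <- params$w_appearance * mA + params$w_smoothness * mS
    # Potts compatibility: energy for label l sums messages of all other labels
    pairwise <- matrix(rowSums(M), N, K) - M
    q <- softmax_neg(U + pairwise)
  }
  array(q, dim = dim(unary))
}

#' Maximum a posteriori labels from marginals
#'
#' Per-pixel argmax; exact ties go to the lowest label index.
#'
#' @param marginals H x W x K array, e.g. from [mean_field()].
#' @return Integer H x W matrix of labels in `1..K`.
#' @export
map_labels <- function(marginals) {
  stopifnot(is.array(marginals), length(dim(marginals)) == 3L)
  d <- dim(marginals)
  m <- matrix(marginals, d[1L] * d[2L], d[3L])
  matrix(max.col(m, ties.method = "first"), d[1L], d[2L])
}
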
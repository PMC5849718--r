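# Per-pixel filter-bank descriptors and visual-word quantization.

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

gaussian_kernel <- function(sigma) {
  g <- gaussian_kernel_1d(sigma)
  outer(g, g)
}

log_kernel <- function(sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  x <- (-radius):radius
  r2 <- outer(x^2, x^2, "+")
  k <- ((r2 - 2 * sigma^2) / sigma^4) * exp(-r2 / (2 * sigma^2))
  k - mean(k)  # enforce exact zero response to constants
}

deriv_gaussian_kernel <- function(sigma, axis = c("x", "y")) {
  axis <- match.arg(axis)
  radius <- max(1L, ceiling(3 * sigma))
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  d <- -x / sigma^2 * g
  # rows index y (image rows), columns index x (image columns)
  k <- if (axis == "x") outer(g, d) else outer(d, g)
  k / sum(abs(k)) * 2  # scale-normalize; still sums to zero by antisymmetry
}

#' The default 17-dimensional filter bank
#'
#' The standard texton filter bank over CIELab: Gaussians at three scales
#' applied to all three channels (9 responses), Laplacians of Gaussian at
#' four scales on L (4), and x/y first derivatives of Gaussian at two scales
#' on L (4), for a 17-dimensional per-pixel descriptor.
#'
#' @param gauss_sigmas,log_sigmas,deriv_sigmas Gaussian standard deviations
#'   (pixels) for the three kernel families.
#' @return An object of class `filter_bank`: a list of kernels, each a list
#'   with elements `kernel` (odd-sized matrix), `channel` (1 = L, 2 = a,
#'   3 = b), `type` and `sigma`.
#' @export
default_filter_bank <- function(gauss_sigmas = c(1, 2, 4),
                                log_sigmas = c(1, 2, 4, 8),
                                deriv_sigmas = c(2, 4)) {
  kernels <- list()
  for (s in gauss_sigmas) {
    for (ch in 1:3) {
      kernels[[length(kernels) + 1L]] <-
        list(kernel = gaussian_kernel(s), channel = ch, type = "gaussian", sigma = s)
    }
  }
  for (s in log_sigmas) {
    kernels[[length(kernels) + 1L]] <-
      list(kernel = log_kernel(s), channel = 1L, type = "log", sigma = s)
  }
  for (s in deriv_sigmas) {
    kernels[[length(kernels) + 1L]] <-
      list(kernel = deriv_gaussian_kernel(s, "x"), channel = 1L, type = "dx", sigma = s)
  }
  for (s in deriv_sigmas) {
    kernels[[length(kernels) + 1L]] <-
      list(kernel = deriv_gaussian_kernel(s, "y"), channel = 1L, type = "dy", sigma = s)
  }
  structure(list(kernels = kernels), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank: %d kernels>\n", length(x$kernels)))
  invisible(x)
}

#' Convert an RGB array to CIELab
#'
#' @param image H x W x 3 array with values in `[0, 255]` (sRGB).
#' @return H x W x 3 array of L, a, b planes.
#' @export
rgb_to_lab <- function(image) {
  check_rgb(image)
  d <- dim(image)
  rgb <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
               as.vector(image[, , 3L])) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

# 2-D convolution with reflect padding (edge pixel duplicated), FFT-backed.
conv2_reflect <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L) {
    stop("invalid input: kernel support must be odd-sized", call. = FALSE)
  }
  h <- nrow(x); w <- ncol(x)
  ri <- c(rev(seq_len(min(kr, h))), seq_len(h), rev(seq_len(h))[seq_len(min(kr, h))])
  ci <- c(rev(seq_len(min(kc, w))), seq_len(w), rev(seq_len(w))[seq_len(min(kc, w))])
  # if the kernel radius exceeds the image, tile the reflection
  while (length(ri) < h + 2L * kr) ri <- c(rev(ri)[seq_len(min(kr, length(ri)))], ri)
  while (length(ci) < w + 2L * kc) ci <- c(ci, rev(ci)[seq_len(min(kc, length(ci)))])
  padded <- x[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[kr + seq_len(h), kc + seq_len(w), drop = FALSE]
}

#' Compute per-pixel filter-bank descriptors
#'
#' Converts the image to CIELab and convolves each kernel of the bank with
#' its assigned channel using reflect padding, yielding one descriptor per
#' pixel (dense sampling: the local patch is the filter support centred on
#' the pixel).
#'
#' @param image H x W x 3 RGB array in `[0, 255]`.
#' @param bank A [default_filter_bank()] or compatible `filter_bank`.
#' @return H x W x D numeric array of filter responses (D = number of
#'   kernels).
#' @export
compute_descriptors <- function(image, bank = default_filter_bank()) {
  check_rgb(image)
  stopifnot(inherits(bank, "filter_bank"), length(bank$kernels) >= 1L)
  lab <- rgb_to_lab(image)
  d <- length(bank$kernels)
  out <- array(0, dim = c(dim(image)[1L], dim(image)[2L], d))
  for (j in seq_len(d)) {
    kj <- bank$kernels[[j]]
    out[, , j] <- conv2_reflect(lab[, , kj$channel], kj$kernel)
  }
  out
}

descriptor_matrix <- function(descriptors) {
  if (is.list(descriptors) && !is.array(descriptors)) {
    return(do.call(rbind, lapply(descriptors, descriptor_matrix)))
  }
  if (is.array(descriptors) && length(dim(descriptors)) == 3L) {
    d <- dim(descriptors)
    return(matrix(descriptors, d[1L] * d[2L], d[3L]))
  }
  if (is.matrix(descriptors)) return(descriptors)
  stop("invalid input: descriptors must be an H x W x D array, a matrix, or a list of them",
       call. = FALSE)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) {
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' Build a visual-word codebook by K-means
#'
#' Descriptors are standardized per dimension (zero mean, unit variance)
#' and clustered by Lloyd's K-means with k-means++ initialization from the
#' given seed. The standardization parameters and the iteration cap are
#' stored in the codebook so quantization is self-contained.
#'
#' @param descriptors H x W x D array from [compute_descriptors()], an
#'   N x D matrix, or a list of arrays pooled from several images.
#' @param size Codebook size W (number of visual words).
#' @param seed Integer seed for the initialization.
#' @param iter_max Lloyd iteration cap.
#' @return An object of class `codebook` with elements `centroids`
#'   (size x D, in standardized space), `center`, `scale`, `size`, `seed`,
#'   `iter_max` and `iterations` (iterations actually used).
#' @export
build_codebook <- function(descriptors, size = 64L, seed = 1L, iter_max = 100L) {
  x <- descriptor_matrix(descriptors)
  if (!is_count(size)) stop("invalid input: size must be a positive integer", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("invalid input: descriptors must be finite", call. = FALSE)
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct < size) {
    stop(sprintf("degenerate input: only %d distinct descriptors for %d words",
                 n_distinct, size), call. = FALSE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  km <- NULL
  for (attempt in 0:4) {
    init <- with_seed(seed + attempt, kmeanspp_init(xs, size))
    km <- tryCatch(
      suppressWarnings(stats::kmeans(xs, centers = init, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("degenerate input: k-means failed to produce ", size,
                        " non-empty clusters", call. = FALSE)
  structure(list(
    centroids = unname(km$centers), center = mu, scale = sdv,
    size = as.integer(size), seed = as.integer(seed),
    iter_max = as.integer(iter_max), iterations = km$iter
  ), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook: %d words, %d-dimensional descriptors>\n",
              x$size, ncol(x$centroids)))
  invisible(x)
}

#' Quantize descriptors into visual words
#'
#' Maps each pixel's descriptor to the nearest codebook centroid in
#' Euclidean distance (after the codebook's standardization). Ties are
#' broken by the lowest centroid index.
#'
#' @param descriptors H x W x D array (or N x D matrix).
#' @param codebook A [build_codebook()] result.
#' @return Integer H x W matrix (or length-N vector for matrix input) of
#'   word indices in `1..size`, with the codebook size attached as attribute
#'   `n_words`.
#' @export
quantize_descriptors <- function(descriptors, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  was_array <- is.array(descriptors) && length(dim(descriptors)) == 3L
  dims <- if (was_array) dim(descriptors) else NULL
  x <- descriptor_matrix(descriptors)
  if (ncol(x) != ncol(codebook$centroids)) {
    stop("invalid input: descriptor dimension does not match the codebook", call. = FALSE)
  }
  xs <- sweep(sweep(x, 2L, codebook$center), 2L, codebook$scale, "/")
  cc <- codebook$centroids
  # squared distances via the expansion |x|^2 - 2 x.c + |c|^2
  d2 <- matrix(rowSums(xs^2), nrow(xs), nrow(cc)) -
    2 * xs %*% t(cc) +
    matrix(rowSums(cc^2), nrow(xs), nrow(cc), byrow = TRUE)
  words <- max.col(-d2, ties.method = "first")
  if (was_array) words <- matrix(as.integer(words), dims[1L], dims[2L])
  attr(words, "n_words") <- codebook$size
  words
}
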
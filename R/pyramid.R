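# Single-layer and multi-resolution segmentation drivers.
#
# The multi-resolution variant builds a Gaussian image pyramid (each level
# half the previous in both axes), segments the coarsest level first, and
# passes each level's labelling down to the next finer level as a soft
# annotation prior mixed into that level's unary energy. Small highlight
# and shadow patches shrink away at low resolution, so the coarse
# labelling is less distracted by them; the fine levels restore boundary
# detail.

#' Pipeline configuration
#'
#' Collects the tunables of every stage with their defaults.
#'
#' @param codebook_size Visual-word count W of the K-means codebook.
#' @param region_size Document region side r in pixels (finest level).
#' @param stride Document anchor spacing; default `floor(r / 2)` (50%
#'   overlap).
#' @param k_classes Number of LDA topics = CRF labels (3 for
#'   fruit/leaf/background naming).
#' @param alpha,beta,burn_in,n_samples LDA hyperparameters, see
#'   [lda_hyper()]; the Gibbs chain starts from the codebook-geometry word
#'   grouping of [word_topic_init()].
#' @param posterior_eps Smoothing mass of the pixel posterior.
#' @param crf A [crf_params()].
#' @param engine Mean-field engine, `"lattice"` or `"exact"`.
#' @param n_levels Pyramid levels for [segment_multiresolution()].
#' @param lambda Mixing weight of the propagated annotation prior in
#'   `[0, 1]`: the combined unary is
#'   `lambda * (-log prior) + (1 - lambda) * (-log own posterior)`.
#' @param softness Probability mass the annotation prior spreads over the
#'   non-propagated labels.
#' @param min_region_size Lower bound for the per-level region side (the
#'   region shrinks with resolution, halving per level).
#' @param seed Master seed; level l of the pyramid uses `seed + l - 1` so
#'   the finest level reproduces the single-layer run exactly.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(codebook_size = 64L, region_size = 20L, stride = NULL,
                       k_classes = 3L, alpha = 0.2, beta = 0.01,
                       burn_in = 300L, n_samples = 20L, posterior_eps = 1e-2,
                       crf = crf_params(), engine = c("lattice", "exact"),
                       n_levels = 3L, lambda = 0.5, softness = 0.1,
                       min_region_size = 8L, seed = 1L) {
  engine <- match.arg(engine)
  if (is.null(stride)) stride <- max(1L, floor(region_size / 2))
  stopifnot(is_count(codebook_size), is_count(region_size), is_count(stride),
            is_count(k_classes), k_classes >= 2, is_count(n_levels),
            lambda >= 0, lambda <= 1, softness >= 0, softness < 1,
            is_count(min_region_size))
  structure(list(
    codebook_size = as.integer(codebook_size),
    region_size = as.integer(region_size), stride = as.integer(stride),
    k_classes = as.integer(k_classes), alpha = alpha, beta = beta,
    burn_in = as.integer(burn_in), n_samples = as.integer(n_samples),
    posterior_eps = posterior_eps, crf = crf, engine = engine,
    n_levels = as.integer(n_levels), lambda = lambda, softness = softness,
    min_region_size = as.integer(min_region_size), seed = as.integer(seed)
  ), class = "seg_config")
}

#' Build a Gaussian image pyramid
#'
#' Level 1 is the original image; each further level applies a Gaussian
#' anti-alias blur (sigma = 1) and decimates by 2 per axis, keeping odd
#' rows/columns so dimensions follow `ceil(n / 2)`. A 200 x 300 image thus
#' yields 100 x 150 and 50 x 75 levels.
#'
#' @param image H x W x 3 RGB array.
#' @param n_levels Number of levels (>= 1); the coarsest level must remain
#'   at least 8 x 8.
#' @return An object of class `image_pyramid`: a list of images, element 1
#'   the original, the last the coarsest.
#' @export
build_pyramid <- function(image, n_levels = 3L) {
  check_rgb(image)
  stopifnot(is_count(n_levels))
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (ceiling(h / 2^(n_levels - 1L)) < 8L || ceiling(w / 2^(n_levels - 1L)) < 8L) {
    stop("invalid input: image too small for ", n_levels, " pyramid levels",
         call. = FALSE)
  }
  levels <- vector("list", n_levels)
  levels[[1L]] <- image
  if (n_levels > 1L) {
    g <- gaussian_kernel(1)
    for (l in 2:n_levels) {
      prev <- levels[[l - 1L]]
      blurred <- prev
      for (ch in 1:3) blurred[, , ch] <- conv2_reflect(prev[, , ch], g)
      levels[[l]] <- blurred[seq(1L, dim(prev)[1L], by = 2L),
                             seq(1L, dim(prev)[2L], by = 2L), , drop = FALSE]
    }
  }
  structure(levels, class = "image_pyramid")
}

#' Propagate a coarse labelling to a finer level as a soft prior
#'
#' Nearest-neighbour upsamples the coarse labels (each coarse pixel maps to
#' its 2 x 2 block) and converts them into a soft distribution giving
#' `1 - softness` to the propagated label and `softness / (K - 1)` to each
#' other label.
#'
#' @param upper_labels Integer label matrix of the coarser level.
#' @param lower_dim Length-2 integer vector `c(height, width)` of the finer
#'   level; must be within the ceil-halving relation of the upper extent.
#' @param k_classes Number of labels K.
#' @param softness Off-label probability mass in `[0, 1)`.
#' @return H x W x K array of prior probabilities (rows sum to one).
#' @export
propagate_annotation <- function(upper_labels, lower_dim, k_classes,
                                 softness = 0.1) {
  stopifnot(is.matrix(upper_labels), length(lower_dim) == 2L,
            softness >= 0, softness < 1, k_classes >= 2L)
  h <- as.integer(lower_dim[1L]); w <- as.integer(lower_dim[2L])
  if (nrow(upper_labels) != ceiling(h / 2) || ncol(upper_labels) != ceiling(w / 2)) {
    stop("invalid input: upper level extent is not ceil(lower / 2)", call. = FALSE)
  }
  up <- upper_labels[ceiling(seq_len(h) / 2), ceiling(seq_len(w) / 2), drop = FALSE]
  prior <- array(softness / (k_classes - 1L), dim = c(h, w, k_classes))
  for (k in seq_len(k_classes)) {
    plane <- prior[, , k]
    plane[up == k] <- 1 - softness
    prior[, , k] <- plane
  }
  prior
}

# Permute the prior's class planes so they best agree with this level's own
# posterior (topics of independently fitted LDA runs are arbitrary
# relabelings of each other). Maximizes sum_p sum_k post[p,k] prior[p,perm[k]].
align_prior <- function(prior, posterior) {
  K <- dim(prior)[3L]
  n <- dim(prior)[1L] * dim(prior)[2L]
  P <- matrix(prior, n, K)
  Q <- matrix(posterior, n, K)
  agree <- crossprod(Q, P)  # agree[k, j] = sum_p Q[p,k] P[p,j]
  perms <- permutations_of(K)
  scores <- apply(perms, 1L, function(pm) sum(agree[cbind(seq_len(K), pm)]))
  best <- perms[which.max(scores), ]
  prior[, , best, drop = FALSE]
}

segment_stage <- function(image, config, region_size, stride, seed) {
  bank <- default_filter_bank()
  desc <- compute_descriptors(image, bank)
  codebook <- build_codebook(desc, size = config$codebook_size, seed = seed)
  word_map <- quantize_descriptors(desc, codebook)
  layout <- layout_documents(dim(image)[1L], dim(image)[2L], region_size, stride)
  hyper <- lda_hyper(k_topics = config$k_classes, alpha = config$alpha,
                     beta = config$beta, burn_in = config$burn_in,
                     n_samples = config$n_samples, seed = seed)
  init <- word_topic_init(codebook, config$k_classes, seed = seed)
  posterior <- run_lda(word_map, layout, hyper, eps = config$posterior_eps,
                       init_topics = init)
  list(posterior = posterior, word_map = word_map)
}

finish_segmentation <- function(image, labels, marginals, posterior, word_map,
                                config, mode, per_level_labels = NULL) {
  roles <- NULL
  if (config$k_classes == 3L) {
    st <- class_stats(image, labels)
    if (nrow(st) == 3L) {
      roles <- assign_roles(st)
    } else {
      warning("only ", nrow(st), " of 3 classes survive in the labelling; ",
              "roles not assigned", call. = FALSE)
    }
  }
  structure(list(labels = labels, marginals = marginals, posterior = posterior,
                 roles = roles, word_map = word_map, mode = mode,
                 per_level_labels = per_level_labels, config = config),
            class = "segmentation_result")
}

#' Single-layer unsupervised CRF segmentation
#'
#' The full pipeline at the image's native resolution: filter-bank
#' descriptors, K-means codebook, visual-word quantization, overlapped
#' document layout, collapsed-Gibbs LDA, unary energies from the pixel
#' posterior, fully connected CRF mean-field refinement, MAP labels, and
#' (for three classes) colour-statistics role naming. Reproducible from
#' `config$seed`.
#'
#' @param image H x W x 3 RGB array in `[0, 255]`.
#' @param config A [seg_config()].
#' @return An object of class `segmentation_result` with elements `labels`,
#'   `marginals`, `posterior`, `roles`, `word_map`, `mode` and `config`.
#' @export
segment_single <- function(image, config = seg_config()) {
  check_rgb(image)
  stopifnot(inherits(config, "seg_config"))
  stage <- segment_stage(image, config, config$region_size, config$stride,
                         config$seed)
  unary <- unary_from_posterior(stage$posterior)
  marginals <- mean_field(unary, image, config$crf, engine = config$engine)
  labels <- map_labels(marginals)
  finish_segmentation(image, labels, marginals, stage$posterior,
                      stage$word_map, config, mode = "single")
}

#' Multi-resolution unsupervised CRF segmentation
#'
#' Runs the single-layer stages on the coarsest pyramid level, then walks
#' down the pyramid: each finer level mixes the upsampled soft annotation
#' prior from the level above (aligned to this level's own topics, since
#' independently fitted LDA topics are arbitrarily permuted) with its own
#' LDA posterior in negative-log space,
#' `U = lambda (-log prior) + (1 - lambda) (-log posterior)`, and refines
#' with the CRF at that resolution. With `lambda = 0` the finest level
#' reproduces [segment_single()] exactly.
#'
#' @inheritParams segment_single
#' @return A `segmentation_result`; `per_level_labels` holds each level's
#'   label matrix (element 1 = finest = final).
#' @export
segment_multiresolution <- function(image, config = seg_config()) {
  check_rgb(image)
  stopifnot(inherits(config, "seg_config"), config$n_levels >= 2L)
  pyr <- build_pyramid(image, config$n_levels)
  n_levels <- length(pyr)
  per_level <- vector("list", n_levels)
  upper_labels <- NULL
  final <- NULL
  for (lev in seq.int(n_levels, 1L)) {
    img_l <- pyr[[lev]]
    r_l <- max(config$min_region_size,
               as.integer(floor(config$region_size / 2^(lev - 1L))))
    r_l <- min(r_l, dim(img_l)[1L], dim(img_l)[2L])
    s_l <- max(1L, as.integer(floor(r_l / 2)))
    stage <- segment_stage(img_l, config, r_l, s_l, config$seed + lev - 1L)
    unary <- unary_from_posterior(stage$posterior)
    if (!is.null(upper_labels) && config$lambda > 0) {
      prior <- propagate_annotation(upper_labels, dim(img_l)[1:2],
                                    config$k_classes, config$softness)
      prior <- align_prior(prior, stage$posterior)
      unary <- config$lambda * (-log(prior)) + (1 - config$lambda) * unary
    }
    marginals <- mean_field(unary, img_l, config$crf, engine = config$engine)
    labels <- map_labels(marginals)
    per_level[[lev]] <- labels
    upper_labels <- labels
    if (lev == 1L) {
      final <- finish_segmentation(img_l, labels, marginals, stage$posterior,
                                   stage$word_map, config, mode = "multi",
                                   per_level_labels = per_level)
    }
  }
  final
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %s mode, %d x %d pixels, %d classes>\n",
              x$mode, nrow(x$labels), ncol(x$labels), dim(x$marginals)[3L]))
  if (!is.null(x$roles)) {
    cat("  roles:", paste(sprintf("%s=%s", names(x$roles), x$roles), collapse = ", "),
        "\n")
  }
  invisible(x)
}
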
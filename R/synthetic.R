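#' Specification of a synthetic greenhouse scene
#'
#' Describes a simulated greenhouse tomato scene: a bright, low-saturation
#' background, overlapping green textured leaves, and red fruits drawn on
#' top. The generated scenes emulate the colour regime that the
#' colour-statistics class naming relies on (red-dominant fruit, green
#' leaves, near-achromatic bright background) and come with pixel-exact
#' ground-truth labels, so every stage of the segmentation pipeline can be
#' validated without photographs.
#'
#' @param height,width Scene size in pixels.
#' @param n_fruits Number of fruit disks.
#' @param fruit_radius_range Length-2 vector, min/max fruit radius in pixels.
#' @param n_leaves Number of leaf ellipses.
#' @param leaf_scale_range Length-2 vector, min/max leaf major-axis length in
#'   pixels.
#' @param fruit_color_mean,leaf_color_mean,background_color_mean Mean RGB
#'   triples in `[0, 255]`.
#' @param color_noise_sd Standard deviation of per-pixel Gaussian colour
#'   noise (intensity units).
#' @param highlight_fraction,shadow_fraction Approximate fraction of pixels
#'   covered by specular highlight / shadow ellipses (see
#'   [add_photometric_artifacts()]).
#' @param leaf_texture_amp Amplitude of the sinusoidal luminance modulation
#'   applied to leaves so that leaf regions carry texture the filter bank can
#'   respond to.
#' @param seed Integer seed; identical specs generate identical scenes.
#'
#' @return An object of class `scene_spec`.
#' @seealso [generate_scene()]
#' @export
scene_spec <- function(height = 200L, width = 300L,
                       n_fruits = 4L, fruit_radius_range = c(15, 35),
                       n_leaves = 12L, leaf_scale_range = c(25, 70),
                       fruit_color_mean = c(205, 45, 40),
                       leaf_color_mean = c(55, 150, 60),
                       background_color_mean = c(235, 235, 228),
                       color_noise_sd = 10,
                       highlight_fraction = 0,
                       shadow_fraction = 0,
                       leaf_texture_amp = 12,
                       seed = 1L) {
  if (!is_count(height) || !is_count(width)) {
    stop("invalid spec: height and width must be positive integers", call. = FALSE)
  }
  stopifnot(
    n_fruits >= 0, n_leaves >= 0,
    length(fruit_radius_range) == 2L, fruit_radius_range[1L] <= fruit_radius_range[2L],
    fruit_radius_range[1L] > 0,
    length(leaf_scale_range) == 2L, leaf_scale_range[1L] <= leaf_scale_range[2L],
    leaf_scale_range[1L] > 0,
    color_noise_sd >= 0, leaf_texture_amp >= 0
  )
  for (cm in list(fruit_color_mean, leaf_color_mean, background_color_mean)) {
    if (length(cm) != 3L || any(cm < 0) || any(cm > 255)) {
      stop("invalid spec: color means must be RGB triples in [0, 255]", call. = FALSE)
    }
  }
  if (highlight_fraction < 0 || highlight_fraction > 1 ||
      shadow_fraction < 0 || shadow_fraction > 1) {
    stop("invalid spec: highlight/shadow fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_fruits = as.integer(n_fruits),
    fruit_radius_range = as.numeric(fruit_radius_range),
    n_leaves = as.integer(n_leaves),
    leaf_scale_range = as.numeric(leaf_scale_range),
    fruit_color_mean = as.numeric(fruit_color_mean),
    leaf_color_mean = as.numeric(leaf_color_mean),
    background_color_mean = as.numeric(background_color_mean),
    color_noise_sd = as.numeric(color_noise_sd),
    highlight_fraction = as.numeric(highlight_fraction),
    shadow_fraction = as.numeric(shadow_fraction),
    leaf_texture_amp = as.numeric(leaf_texture_amp),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# Rasterize a rotated ellipse; returns a logical H x W mask.
ellipse_mask <- function(height, width, cr, cc, a, b, angle) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(height, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(width, ceiling(cc + a))
  mask <- matrix(FALSE, height, width)
  if (r1 < r0 || c1 < c0) return(mask)
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  mask[rows, cols] <- (u / a)^2 + (v / b)^2 <= 1
  mask
}

#' Generate a synthetic greenhouse scene with ground truth
#'
#' Paints the scene back to front: background first, then `n_leaves`
#' randomly placed rotated leaf ellipses carrying a sinusoidal luminance
#' texture, then `n_fruits` fruit disks on top (occluding leaves, as fruits
#' in front of foliage do). Per-pixel Gaussian colour noise is added last.
#' The ground-truth label of a pixel is the topmost painted class.
#'
#' Class indices are 1 = background, 2 = leaf, 3 = fruit; the `roles` field
#' records this mapping explicitly so that downstream evaluation never
#' relies on raw indices.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `synthetic_scene`: a list with elements
#'   `image` (H x W x 3 array in `[0, 255]`), `labels` (H x W integer matrix),
#'   `roles` (named character vector mapping class index to role),
#'   `fruits` / `leaves` (data frames with the sampled shape parameters),
#'   and `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    image <- array(rep(spec$background_color_mean, each = h * w), dim = c(h, w, 3L))
    labels <- matrix(1L, h, w)

    leaves <- data.frame(row = numeric(0), col = numeric(0), a = numeric(0),
                         b = numeric(0), angle = numeric(0),
                         wavelength = numeric(0), orient = numeric(0),
                         phase = numeric(0))
    if (spec$n_leaves > 0L) {
      for (i in seq_len(spec$n_leaves)) {
        cr <- stats::runif(1, 1, h); cc <- stats::runif(1, 1, w)
        a <- stats::runif(1, spec$leaf_scale_range[1L], spec$leaf_scale_range[2L]) / 2
        b <- a * stats::runif(1, 0.35, 0.7)
        angle <- stats::runif(1, 0, pi)
        wavelength <- stats::runif(1, 6, 14)
        orient <- stats::runif(1, 0, pi)
        phase <- stats::runif(1, 0, 2 * pi)
        leaves[i, ] <- list(cr, cc, a, b, angle, wavelength, orient, phase)
        mask <- ellipse_mask(h, w, cr, cc, a, b, angle)
        if (!any(mask)) next
        idx <- which(mask)
        rows <- (idx - 1L) %% h + 1L
        cols <- (idx - 1L) %/% h + 1L
        tex <- spec$leaf_texture_amp *
          sin(2 * pi * (rows * cos(orient) + cols * sin(orient)) / wavelength + phase)
        for (ch in 1:3) {
          plane <- image[, , ch]
          plane[idx] <- spec$leaf_color_mean[ch] + tex
          image[, , ch] <- plane
        }
        labels[idx] <- 2L
      }
    }

    fruits <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
    if (spec$n_fruits > 0L) {
      for (i in seq_len(spec$n_fruits)) {
        r <- stats::runif(1, spec$fruit_radius_range[1L], spec$fruit_radius_range[2L])
        # keep fruits wholly in frame when the scene is large enough
        rlo <- min(r + 1, h / 2); rhi <- max(h - r, h / 2)
        clo <- min(r + 1, w / 2); chi <- max(w - r, w / 2)
        cr <- stats::runif(1, rlo, rhi); cc <- stats::runif(1, clo, chi)
        fruits[i, ] <- list(cr, cc, r)
        mask <- ellipse_mask(h, w, cr, cc, r, r, 0)
        if (!any(mask)) next
        idx <- which(mask)
        for (ch in 1:3) {
          plane <- image[, , ch]
          plane[idx] <- spec$fruit_color_mean[ch]
          image[, , ch] <- plane
        }
        labels[idx] <- 3L
      }
    }

    if (spec$color_noise_sd > 0) {
      image <- image + array(stats::rnorm(h * w * 3L, 0, spec$color_noise_sd),
                             dim = c(h, w, 3L))
    }
    image <- clip01(image)

    structure(list(
      image = image, labels = labels,
      roles = c(`1` = "background", `2` = "leaf", `3` = "fruit"),
      fruits = fruits, leaves = leaves, spec = spec
    ), class = "synthetic_scene")
  })
}

#' Add highlight and shadow artifacts to a synthetic scene
#'
#' Emulates the specular reflections and leaf-shadow regions of real
#' greenhouse photographs: randomly placed ellipses covering approximately
#' `highlight_fraction` of the pixels have their intensity multiplied by
#' `highlight_gain` (> 1) and, independently, ellipses covering
#' approximately `shadow_fraction` are multiplied by `shadow_gain` (< 1).
#' Intensities are clipped to `[0, 255]`. Ground-truth labels are untouched:
#' the artifacts perturb appearance only.
#'
#' @param sample A `synthetic_scene` from [generate_scene()].
#' @param spec Scene spec carrying the fractions; defaults to the sample's
#'   own spec.
#' @param highlight_gain,shadow_gain Multiplicative intensity factors.
#' @return The modified `synthetic_scene`.
#' @export
add_photometric_artifacts <- function(sample, spec = sample$spec,
                                      highlight_gain = 1.5, shadow_gain = 0.55) {
  stopifnot(inherits(sample, "synthetic_scene"))
  if (spec$highlight_fraction < 0 || spec$highlight_fraction > 1 ||
      spec$shadow_fraction < 0 || spec$shadow_fraction > 1) {
    stop("invalid spec: highlight/shadow fractions must lie in [0, 1]", call. = FALSE)
  }
  h <- spec$height; w <- spec$width
  if (spec$highlight_fraction == 0 && spec$shadow_fraction == 0) return(sample)
  # distinct stream from generate_scene so artifacts do not reshuffle geometry
  with_seed(spec$seed + 1L, {
    image <- sample$image
    for (kind in c("highlight", "shadow")) {
      frac <- if (kind == "highlight") spec$highlight_fraction else spec$shadow_fraction
      gain <- if (kind == "highlight") highlight_gain else shadow_gain
      if (frac <= 0) next
      target <- round(frac * h * w)
      covered <- matrix(FALSE, h, w)
      tries <- 0L
      while (sum(covered) < target && tries < 200L) {
        tries <- tries + 1L
        area <- max(25, target / 4)
        a <- sqrt(area / pi) * stats::runif(1, 0.7, 1.6)
        b <- sqrt(area / pi) * stats::runif(1, 0.4, 1.0)
        covered <- covered | ellipse_mask(h, w,
                                          stats::runif(1, 1, h), stats::runif(1, 1, w),
                                          a, b, stats::runif(1, 0, pi))
      }
      idx <- which(covered)
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[idx] <- plane[idx] * gain
        image[, , ch] <- plane
      }
    }
    sample$image <- clip01(image)
    sample
  })
}
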
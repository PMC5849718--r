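# Naming the anonymous clusters as fruit / leaf / background from RGB
# statistics, and extracting the fruit image.
#
# In greenhouse scenes the background (sky, glass, white facility surfaces)
# is bright and nearly achromatic, so its three channel means are close
# together and their variance is minimal; fruits are red-dominant and
# leaves green-dominant.

#' Per-class RGB statistics
#'
#' For every non-empty class, the mean of each RGB channel over the class's
#' pixels and the population variance of those three means.
#'
#' @param image H x W x 3 RGB array in `[0, 255]`.
#' @param labels Integer H x W label matrix.
#' @return Data frame with columns `class_index`, `mean_r`, `mean_g`,
#'   `mean_b`, `variance_of_means`, `n_pixels`, one row per non-empty
#'   class in increasing index order.
#' @export
class_stats <- function(image, labels) {
  check_rgb(image)
  stopifnot(is.matrix(labels), all(dim(labels) == dim(image)[1:2]))
  classes <- sort(unique(as.vector(labels)))
  r <- as.vector(image[, , 1L]); g <- as.vector(image[, , 2L])
  b <- as.vector(image[, , 3L]); lv <- as.vector(labels)
  out <- do.call(rbind, lapply(classes, function(k) {
    idx <- lv == k
    means <- c(mean(r[idx]), mean(g[idx]), mean(b[idx]))
    data.frame(class_index = k, mean_r = means[1L], mean_g = means[2L],
               mean_b = means[3L],
               variance_of_means = mean((means - mean(means))^2),
               n_pixels = sum(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Name the three classes from their colour statistics
#'
#' The background is the class whose three channel means have the smallest
#' variance (ties: lowest class index). Of the remaining two classes, the
#' fruit is the one whose red mean exceeds its green and blue means; when
#' both or neither remaining class is red-dominant, the larger red-dominance
#' margin `mean_r - max(mean_g, mean_b)` decides (ties: lowest class
#' index). The other class is the leaf.
#'
#' @param stats A [class_stats()] data frame with exactly three rows.
#' @return Named character vector mapping class index (as name) to
#'   `"fruit"`, `"leaf"` or `"background"`.
#' @export
assign_roles <- function(stats) {
  stopifnot(is.data.frame(stats))
  if (nrow(stats) != 3L) {
    stop("unsupported configuration: role naming requires exactly 3 classes, got ",
         nrow(stats), call. = FALSE)
  }
  bg_row <- which.min(stats$variance_of_means)  # first minimum on ties
  rest <- stats[-bg_row, ]
  margin <- rest$mean_r - pmax(rest$mean_g, rest$mean_b)
  red_dominant <- margin > 0
  fruit_row <- if (sum(red_dominant) == 1L) {
    which(red_dominant)
  } else {
    which.max(margin)
  }
  roles <- character(3L)
  names(roles) <- as.character(stats$class_index)
  roles[as.character(stats$class_index[bg_row])] <- "background"
  roles[as.character(rest$class_index[fruit_row])] <- "fruit"
  roles[as.character(rest$class_index[-fruit_row])] <- "leaf"
  roles[order(as.integer(names(roles)))]
}

#' Extract the fruit image
#'
#' Keeps the pixels whose class role is `"fruit"` and zeroes the RGB values
#' of all other pixels.
#'
#' @param image H x W x 3 RGB array.
#' @param labels Integer H x W label matrix.
#' @param roles Named role vector from [assign_roles()] covering all labels
#'   present.
#' @return H x W x 3 array with non-fruit pixels set to `(0, 0, 0)`.
#' @export
extract_fruit <- function(image, labels, roles) {
  check_rgb(image)
  present <- unique(as.vector(labels))
  if (!all(as.character(present) %in% names(roles))) {
    stop("invalid input: roles do not cover all labels present", call. = FALSE)
  }
  fruit_classes <- as.integer(names(roles)[roles == "fruit"])
  mask <- matrix(labels %in% fruit_classes, nrow(labels), ncol(labels))
  out <- image
  for (ch in 1:3) out[, , ch] <- out[, , ch] * mask
  out
}

# Map a label matrix into canonical role codes (1 = background, 2 = leaf,
# 3 = fruit) using a role assignment; used by the evaluation metrics so
# that raw cluster indices never get compared across segmentations.
role_codes <- function(labels, roles) {
  code <- c(background = 1L, leaf = 2L, fruit = 3L)
  lut <- integer(max(as.integer(names(roles))))
  lut[as.integer(names(roles))] <- code[roles]
  matrix(lut[labels], nrow(labels), ncol(labels))
}
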
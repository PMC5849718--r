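# Image and label-map I/O.
#
# Images are H x W x 3 numeric arrays in [0, 255]. Label maps are written
# as single-channel 8-bit PNGs holding `label - 1` (lossless round-trip)
# with a JSON sidecar (`<path>.json`) carrying the class-to-role mapping
# and the display palette; a colour overlay PNG can be written alongside.

#' Read an RGB image
#'
#' Reads PNG (or JPEG when the `jpeg` package is installed), promotes
#' grayscale to three identical channels and drops any alpha channel.
#'
#' @param path File path.
#' @return H x W x 3 numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("jpg", "jpeg")) {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("the jpeg package is required for JPEG input")
      }
      jpeg::readJPEG(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) {
    stop("I/O error: cannot decode ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  img * 255
}

#' Write an RGB image as PNG
#'
#' @param image H x W x 3 array in `[0, 255]`.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  png::writePNG(clip01(image) / 255, target = path)
  invisible(path)
}

role_palette <- function() {
  list(fruit = c(255, 0, 0), leaf = c(0, 200, 0), background = c(255, 255, 255))
}

#' Colour rendering of a label map
#'
#' @param labels Integer H x W label matrix.
#' @param roles Optional named role vector; fruit renders red, leaf green,
#'   background white, unnamed classes gray shades.
#' @return H x W x 3 array in `[0, 255]`.
#' @export
label_to_rgb <- function(labels, roles = NULL) {
  classes <- sort(unique(as.vector(labels)))
  pal <- role_palette()
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  for (k in classes) {
    colr <- if (!is.null(roles) && as.character(k) %in% names(roles)) {
      pal[[roles[[as.character(k)]]]]
    } else {
      rep(60 + (k * 60) %% 180, 3L)
    }
    idx <- labels == k
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- colr[ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Write a label map (and sidecar metadata)
#'
#' @param labels Integer H x W label matrix (values `1..K`).
#' @param path Output PNG path; the sidecar is written to `<path>.json`.
#' @param roles Optional named role vector stored in the sidecar.
#' @param overlay_path Optional path for a colour overlay PNG.
#' @export
write_label_map <- function(labels, path, roles = NULL, overlay_path = NULL) {
  stopifnot(is.matrix(labels), all(labels >= 1L), all(labels <= 256L))
  png::writePNG((labels - 1L) / 255, target = path)
  meta <- list(classes = sort(unique(as.vector(labels))))
  if (!is.null(roles)) meta$roles <- as.list(roles)
  meta$palette <- role_palette()
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(overlay_path)) write_image(label_to_rgb(labels, roles), overlay_path)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path PNG path.
#' @return Integer label matrix with the sidecar roles (if present)
#'   attached as attribute `roles`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1L]
  labels <- matrix(as.integer(round(img * 255)) + 1L, nrow(img), ncol(img))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$roles)) {
      attr(labels, "roles") <- unlist(meta$roles)
    }
  }
  labels
}
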
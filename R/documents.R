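# Overlapped spatial documents for latent Dirichlet allocation.
#
# Visual words that are close in space belong to the same object more often
# than not, so the image is covered with overlapping square regions and each
# region becomes one document. With 50% overlap every object of diameter
# smaller than the region side falls wholly inside at least one region.
#
# Coordinates are 1-based (row, col); pixel linear indices are column-major
# (R's native order); region rectangles are inclusive on both ends.

anchor_positions <- function(n, region, stride) {
  last <- n - region + 1L
  a <- seq.int(1L, last, by = stride)
  if (a[length(a)] != last) a <- c(a, last)
  as.integer(a)
}

#' Lay out overlapped square documents on an image grid
#'
#' Region anchors sit at `1, 1 + stride, 1 + 2 stride, ...` on both axes,
#' plus a final anchor flush with the far edge when the stride pattern would
#' otherwise leave a strip uncovered. Every pixel is covered by at least one
#' region; with `stride == region_size` the regions tile the image
#' disjointly.
#'
#' @param height,width Image size in pixels.
#' @param region_size Side length r of the square regions.
#' @param stride Anchor spacing s, `1 <= s <= r`. Default `floor(r / 2)`
#'   (50% overlap).
#' @return An object of class `document_layout` with a data frame `regions`
#'   (columns `top`, `left`, `bottom`, `right`, inclusive) in row-major
#'   anchor order.
#' @export
layout_documents <- function(height, width, region_size,
                             stride = max(1L, floor(region_size / 2))) {
  stopifnot(is_count(height), is_count(width), is_count(region_size), is_count(stride))
  if (region_size > min(height, width)) {
    stop("invalid input: region_size exceeds the image extent", call. = FALSE)
  }
  if (stride > region_size) {
    stop("invalid input: stride must not exceed region_size", call. = FALSE)
  }
  ra <- anchor_positions(as.integer(height), as.integer(region_size), as.integer(stride))
  ca <- anchor_positions(as.integer(width), as.integer(region_size), as.integer(stride))
  regions <- data.frame(
    top = rep(ra, each = length(ca)),
    left = rep(ca, times = length(ra))
  )
  regions$bottom <- pmin.int(regions$top + region_size - 1L, height)
  regions$right <- pmin.int(regions$left + region_size - 1L, width)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    region_size = as.integer(region_size), stride = as.integer(stride),
    regions = regions
  ), class = "document_layout")
}

#' @export
print.document_layout <- function(x, ...) {
  cat(sprintf("<document_layout: %d regions of %dx%d, stride %d, on %dx%d>\n",
              nrow(x$regions), x$region_size, x$region_size, x$stride,
              x$height, x$width))
  invisible(x)
}

#' Enumerate (document, pixel, word) tokens
#'
#' Emits one token per (region, pixel-in-region) pair carrying that pixel's
#' visual word, so a pixel covered by several overlapping regions
#' contributes one token to each of them.
#'
#' @param word_map Integer H x W matrix of visual words (1-based), e.g. from
#'   [quantize_descriptors()].
#' @param layout A [layout_documents()] result matching the word map's
#'   extent.
#' @param n_words Codebook size; defaults to the word map's `n_words`
#'   attribute (or its maximum).
#' @return An object of class `token_table`: integer vectors `doc`, `pixel`
#'   (column-major linear index), `word`, plus `n_docs`, `n_words`,
#'   `n_pixels`, `pixel_cover` (per-pixel token counts) and the image
#'   extent.
#' @export
build_tokens <- function(word_map, layout, n_words = NULL) {
  stopifnot(inherits(layout, "document_layout"), is.matrix(word_map))
  h <- nrow(word_map); w <- ncol(word_map)
  if (h != layout$height || w != layout$width) {
    stop("invalid input: word map extent does not match the layout", call. = FALSE)
  }
  if (is.null(n_words)) {
    n_words <- attr(word_map, "n_words")
    if (is.null(n_words)) n_words <- max(word_map)
  }
  reg <- layout$regions
  per_region <- lapply(seq_len(nrow(reg)), function(i) {
    rows <- reg$top[i]:reg$bottom[i]
    cols <- reg$left[i]:reg$right[i]
    as.integer(outer(rows, (cols - 1L) * h, "+"))
  })
  pixel <- unlist(per_region, use.names = FALSE)
  doc <- rep.int(seq_len(nrow(reg)), vapply(per_region, length, 1L))
  cover <- tabulate(pixel, nbins = h * w)
  if (any(cover == 0L)) {
    stop("internal error: document layout leaves pixels uncovered", call. = FALSE)
  }
  structure(list(
    doc = doc, pixel = pixel, word = as.integer(word_map[pixel]),
    n_docs = nrow(reg), n_words = as.integer(n_words), n_pixels = h * w,
    pixel_cover = cover, height = h, width = w
  ), class = "token_table")
}

#' @export
print.token_table <- function(x, ...) {
  cat(sprintf("<token_table: %d tokens, %d documents, %d words, %dx%d image>\n",
              length(x$doc), x$n_docs, x$n_words, x$height, x$width))
  invisible(x)
}
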
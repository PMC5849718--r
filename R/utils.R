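# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never disturbs user randomness.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Row-wise softmax of -E with overflow protection; E is an N x K matrix of
# energies, the result has rows summing to one.
softmax_neg <- function(E) {
  m <- apply(E, 1L, min)
  P <- exp(-(E - m))
  P / rowSums(P)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_rgb_array <- function(image) {
  is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L &&
    dim(image)[1L] >= 1L && dim(image)[2L] >= 1L && all(is.finite(image))
}

check_rgb <- function(image, what = "image") {
  if (!is_rgb_array(image)) {
    stop(sprintf("invalid input: %s must be a non-empty H x W x 3 numeric array", what),
         call. = FALSE)
  }
  invisible(image)
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# All permutations of 1..n (n small), rows = permutations, deterministic order.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
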
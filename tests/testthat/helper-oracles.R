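# Shared fixtures and independent brute-force oracles used across tests.

# Aliases for internal helpers exercised directly by the tests.
conv2_reflect <- phenoseg:::conv2_reflect
gaussian_kernel <- phenoseg:::gaussian_kernel
deriv_gaussian_kernel <- phenoseg:::deriv_gaussian_kernel
descriptor_matrix <- phenoseg:::descriptor_matrix
role_codes_export <- phenoseg:::role_codes
# The oracles deliberately re-derive quantities from first principles
# (nested loops, exhaustive scans) rather than calling the implementation.

tiny_scene <- function(seed = 1L, height = 48L, width = 64L, ...) {
  generate_scene(scene_spec(height = height, width = width,
                            n_fruits = 2L, fruit_radius_range = c(6, 9),
                            n_leaves = 4L, leaf_scale_range = c(12, 24),
                            seed = seed, ...))
}

# Direct 2-D convolution with edge-duplicating reflect padding.
brute_conv2_reflect <- function(x, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  reflect <- function(i, n) {
    # scipy-style reflect: ... 2 1 | 1 2 ... n | n n-1 ...
    while (any(i < 1L | i > n)) {
      i <- ifelse(i < 1L, 1L - i, i)
      i <- ifelse(i > n, 2L * n + 1L - i, i)
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (u in -kr:kr) {
        for (v in -kc:kc) {
          acc <- acc + k[u + kr + 1L, v + kc + 1L] *
            x[reflect(i - u, h), reflect(j - v, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Exhaustive nearest-centroid scan in standardized space.
brute_quantize <- function(x, codebook) {
  xs <- sweep(sweep(x, 2L, codebook$center), 2L, codebook$scale, "/")
  apply(xs, 1L, function(row) {
    d2 <- colSums((t(codebook$centroids) - row)^2)
    which(d2 == min(d2))[1L]
  })
}

# Brute-force membership test of every pixel against every region.
brute_coverage <- function(layout) {
  reg <- layout$regions
  counts <- matrix(0L, layout$height, layout$width)
  for (i in seq_len(nrow(reg))) {
    for (r in seq_len(layout$height)) {
      for (cc in seq_len(layout$width)) {
        if (r >= reg$top[i] && r <= reg$bottom[i] &&
            cc >= reg$left[i] && cc <= reg$right[i]) {
          counts[r, cc] <- counts[r, cc] + 1L
        }
      }
    }
  }
  counts
}

# Recount LDA sufficient statistics from the assignment vector.
brute_recount <- function(z, tokens, k) {
  ndk <- matrix(0L, tokens$n_docs, k)
  nkw <- matrix(0L, k, tokens$n_words)
  for (i in seq_along(z)) {
    ndk[tokens$doc[i], z[i]] <- ndk[tokens$doc[i], z[i]] + 1L
    nkw[z[i], tokens$word[i]] <- nkw[z[i], tokens$word[i]] + 1L
  }
  list(n_dk = ndk, n_kw = nkw, n_k = rowSums(nkw))
}

# Hand evaluation of the collapsed Gibbs conditional for token i.
brute_conditional <- function(state, tokens, hyper, i) {
  k_topics <- state$k_topics
  ndk <- state$n_dk; nkw <- state$n_kw; nk <- state$n_k
  d <- tokens$doc[i]; w <- tokens$word[i]; kold <- state$z[i]
  ndk[d, kold] <- ndk[d, kold] - 1L
  nkw[kold, w] <- nkw[kold, w] - 1L
  nk[kold] <- nk[kold] - 1L
  p <- numeric(k_topics)
  for (k in seq_len(k_topics)) {
    p[k] <- (ndk[d, k] + hyper$alpha) * (nkw[k, w] + hyper$beta) /
      (nk[k] + tokens$n_words * hyper$beta)
  }
  p / sum(p)
}

# Pixel-by-pixel metric counting.
brute_metrics <- function(pred_codes, gt_codes) {
  k <- 0L; l_fruit <- 0L; a <- 0L; p_over <- 0L; p_under <- 0L
  for (i in seq_along(pred_codes)) {
    if (pred_codes[i] == gt_codes[i]) k <- k + 1L
    pf <- pred_codes[i] == 3L; gf <- gt_codes[i] == 3L
    if (gf) a <- a + 1L
    if (pf && gf) l_fruit <- l_fruit + 1L
    if (pf && !gf) p_over <- p_over + 1L
    if (!pf && gf) p_under <- p_under + 1L
  }
  list(acc_seg = k / length(pred_codes),
       acc_fruit = if (a > 0) l_fruit / a else NA_real_,
       seg_over = if (a + p_over > 0) p_over / (a + p_over) else NA_real_,
       seg_under = if (a + p_over > 0) p_under / (a + p_over) else NA_real_,
       k = k, l_fruit = l_fruit, a = a, p_over = p_over, p_under = p_under)
}

# Reference mean-field with dense O(N^2) message passing, independent of
# the package's engines (recomputes kernels from definitions each call).
brute_mean_field <- function(unary, image, params, iters = params$n_iterations) {
  h <- dim(unary)[1L]; w <- dim(unary)[2L]; K <- dim(unary)[3L]
  N <- h * w
  U <- matrix(unary, N, K)
  pos <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  col <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  KA <- matrix(0, N, N); KS <- matrix(0, N, N)
  for (i in seq_len(N)) {
    dp <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
    dc <- rowSums(sweep(col, 2L, col[i, ])^2)
    KA[i, ] <- exp(-dp / (2 * params$theta_alpha^2) - dc / (2 * params$theta_beta^2))
    KS[i, ] <- exp(-dp / (2 * params$theta_gamma^2))
  }
  diag(KA) <- 0; diag(KS) <- 0
  sm <- function(E) { E <- E - apply(E, 1, min); P <- exp(-E); P / rowSums(P) }
  q <- sm(U)
  for (it in seq_len(iters)) {
    M <- params$w_appearance * KA %*% q + params$w_smoothness * KS %*% q
    q <- sm(U + matrix(rowSums(M), N, K) - M)
  }
  array(q, dim = dim(unary))
}
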
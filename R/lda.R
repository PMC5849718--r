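# Latent Dirichlet allocation over spatial documents, fitted by collapsed
# Gibbs sampling. Topics are identified with object classes (default three:
# fruit, leaf, background), and the per-pixel topic posterior aggregated
# over retained sweeps becomes the initial soft labelling of the image.

#' LDA hyperparameters
#'
#' @param k_topics Number of topics K (>= 2). Topics play the role of
#'   object classes, so the default is 3: fruit, leaf, background.
#' @param alpha Dirichlet prior on document-topic mixtures. The default is
#'   a sparse symmetric prior (0.2): spatial documents are small image
#'   regions dominated by one or two classes, and a weak prior lets them
#'   be nearly pure. Large values (e.g. the classic `50 / K`) favour mixed
#'   documents and empirically drive the sampler into modes that split the
#'   dominant class while merging minority classes.
#' @param beta Dirichlet prior on topic-word distributions.
#' @param burn_in Discarded Gibbs sweeps before sampling.
#' @param n_samples Retained sweeps averaged into the pixel posterior.
#'   Averaging over several sweeps damps the sampling noise a single Gibbs
#'   state carries.
#' @param seed Integer seed driving initialization and all sweeps.
#' @return An object of class `lda_hyper`.
#' @export
lda_hyper <- function(k_topics = 3L, alpha = 0.2, beta = 0.01,
                      burn_in = 300L, n_samples = 20L, seed = 1L) {
  stopifnot(is_count(k_topics), k_topics >= 2, alpha > 0, beta > 0,
            burn_in >= 0, is_count(n_samples))
  structure(list(k_topics = as.integer(k_topics), alpha = alpha, beta = beta,
                 burn_in = as.integer(burn_in), n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "lda_hyper")
}

count_state <- function(z, tokens, k_topics) {
  ndk <- matrix(tabulate((tokens$doc - 1L) * k_topics + z,
                         nbins = tokens$n_docs * k_topics),
                nrow = tokens$n_docs, ncol = k_topics, byrow = TRUE)
  nkw <- matrix(tabulate((tokens$word - 1L) * k_topics + z,
                         nbins = tokens$n_words * k_topics),
                nrow = k_topics, ncol = tokens$n_words)
  list(n_dk = ndk, n_kw = nkw, n_k = rowSums(nkw))
}

#' Initialize a collapsed Gibbs state
#'
#' Assigns each token a topic drawn uniformly from `1..K` under the
#' hyperparameters' seed and builds the count matrices.
#'
#' @param tokens A [build_tokens()] result.
#' @param hyper An [lda_hyper()].
#' @return An object of class `lda_state` with elements `z`, `n_dk`
#'   (documents x K), `n_kw` (K x words), `n_k`.
#' @export
lda_init <- function(tokens, hyper) {
  stopifnot(inherits(tokens, "token_table"), inherits(hyper, "lda_hyper"))
  if (length(tokens$doc) == 0L) {
    stop("invalid input: empty token table", call. = FALSE)
  }
  z <- with_seed(hyper$seed, sample.int(hyper$k_topics, length(tokens$doc),
                                        replace = TRUE))
  counts <- count_state(z, tokens, hyper$k_topics)
  structure(c(list(z = z, k_topics = hyper$k_topics), counts), class = "lda_state")
}

check_state <- function(state, tokens) {
  ok <- sum(state$n_k) == length(tokens$doc) &&
    all(state$n_k == rowSums(state$n_kw)) &&
    all(rowSums(state$n_dk) == tabulate(tokens$doc, tokens$n_docs)) &&
    all(state$n_dk >= 0L) && all(state$n_kw >= 0L)
  if (!ok) stop("corrupted state: count matrices are inconsistent with the tokens",
                call. = FALSE)
  invisible(TRUE)
}

#' One collapsed Gibbs sweep
#'
#' Resamples every token once, in the fixed token order of the table, from
#' the collapsed conditional
#' `p(z_i = k | z_-i, w) \propto (n_dk + alpha) (n_kw + beta) / (n_k + W beta)`
#' (counts excluding token i). Uses R's current RNG stream; seed via
#' [with_seed()]-style wrappers or `set.seed()`.
#'
#' @param state An `lda_state`.
#' @param tokens The token table the state was built from.
#' @param hyper An [lda_hyper()].
#' @return The updated `lda_state`.
#' @export
lda_sweep <- function(state, tokens, hyper) {
  stopifnot(inherits(state, "lda_state"))
  check_state(state, tokens)
  res <- lda_sweep_cpp(state$z - 1L, tokens$doc - 1L, tokens$word - 1L,
                       state$n_dk, state$n_kw, state$n_k,
                       hyper$alpha, hyper$beta)
  structure(list(z = res$z + 1L, k_topics = state$k_topics,
                 n_dk = res$n_dk, n_kw = res$n_kw, n_k = res$n_k),
            class = "lda_state")
}

#' Collapsed conditional distribution of one token
#'
#' Returns the normalized topic distribution for token `i` given all other
#' assignments (token `i` removed from the counts).
#'
#' @inheritParams lda_sweep
#' @param i Token index (1-based).
#' @return Numeric vector of length K summing to one.
#' @export
lda_conditional <- function(state, tokens, hyper, i) {
  stopifnot(i >= 1L, i <= length(tokens$doc))
  lda_conditional_cpp(state$z - 1L, tokens$doc - 1L, tokens$word - 1L,
                      state$n_dk, state$n_kw, state$n_k,
                      hyper$alpha, hyper$beta, as.integer(i) - 1L)
}

#' Aggregate per-pixel topic posteriors from Gibbs samples
#'
#' For each pixel, counts how often any token covering it was assigned each
#' topic, summed over all given samples and covering documents, adds the
#' smoothing mass `eps`, and normalizes.
#'
#' @param states An `lda_state` or list of states (post burn-in samples).
#' @param tokens The token table.
#' @param eps Smoothing constant added to every topic count so no
#'   probability is exactly zero (keeps unary energies finite).
#' @return H x W x K array; each pixel's K values sum to one.
#' @export
lda_posterior <- function(states, tokens, eps = 1e-2) {
  if (inherits(states, "lda_state")) states <- list(states)
  stopifnot(length(states) >= 1L, eps >= 0)
  k_topics <- states[[1L]]$k_topics
  acc <- numeric(tokens$n_pixels * k_topics)
  for (s in states) {
    if (length(s$z) != length(tokens$pixel)) {
      stop("invalid input: state and token table sizes differ", call. = FALSE)
    }
    acc <- acc + tabulate((tokens$pixel - 1L) * k_topics + s$z,
                          nbins = tokens$n_pixels * k_topics)
  }
  probs <- matrix(acc, nrow = tokens$n_pixels, ncol = k_topics, byrow = TRUE) + eps
  probs <- probs / rowSums(probs)
  array(probs, dim = c(tokens$height, tokens$width, k_topics))
}

#' Topic initialization from the codebook geometry
#'
#' Groups the codebook centroids into K clusters by K-means (seeded, in the
#' codebook's standardized descriptor space) so that every visual word gets
#' a plausible starting topic. Entirely unsupervised: it uses only the
#' descriptor geometry, no labels.
#'
#' @param codebook A [build_codebook()] result.
#' @param k_topics Number of topics.
#' @param seed Integer seed for the K-means restarts.
#' @return Integer vector of length `codebook$size` with values in `1..K`.
#' @export
word_topic_init <- function(codebook, k_topics, seed = 1L) {
  stopifnot(inherits(codebook, "codebook"), is_count(k_topics))
  if (codebook$size < k_topics) {
    stop("invalid input: fewer words than topics", call. = FALSE)
  }
  with_seed(seed,
            stats::kmeans(codebook$centroids, centers = k_topics,
                          nstart = 10)$cluster)
}

posterior_from_counts <- function(counts, height, width, eps) {
  probs <- counts + eps
  probs <- probs / rowSums(probs)
  array(probs, dim = c(height, width, ncol(counts)))
}

#' Run LDA end to end on a word map
#'
#' Builds tokens from the overlapped document layout, initializes the
#' collapsed Gibbs state, performs `burn_in` sweeps, retains `n_samples`
#' further sweeps, and aggregates the retained assignments into a smoothed
#' per-pixel topic posterior. Fully reproducible from `hyper$seed`.
#'
#' @param word_map Integer H x W matrix of visual words.
#' @param layout A [layout_documents()] result.
#' @param hyper An [lda_hyper()].
#' @param eps Posterior smoothing constant, see [lda_posterior()].
#' @param init_topics Optional integer vector of length `n_words` giving a
#'   starting topic for every visual word (e.g. a K-means grouping of the
#'   codebook centroids, see [word_topic_init()]); tokens start at their
#'   word's topic instead of a uniform draw. A uniform start frequently
#'   converges to degenerate modes on images with one dominant class.
#' @return H x W x K posterior array (rows sum to one), with the final
#'   `lda_state` attached as attribute `state`.
#' @export
run_lda <- function(word_map, layout, hyper = lda_hyper(), eps = 1e-2,
                    init_topics = NULL) {
  tokens <- build_tokens(word_map, layout)
  if (!is.null(init_topics) &&
      (length(init_topics) < tokens$n_words ||
       any(init_topics < 1L) || any(init_topics > hyper$k_topics))) {
    stop("invalid input: init_topics must map every word to a topic in 1..K",
         call. = FALSE)
  }
  with_seed(hyper$seed, {
    z <- if (is.null(init_topics)) {
      sample.int(hyper$k_topics, length(tokens$doc), replace = TRUE)
    } else {
      as.integer(init_topics)[tokens$word]
    }
    counts <- count_state(z, tokens, hyper$k_topics)
    res <- lda_run_cpp(z - 1L, tokens$doc - 1L, tokens$word - 1L,
                       tokens$pixel - 1L,
                       counts$n_dk, counts$n_kw, counts$n_k,
                       hyper$alpha, hyper$beta,
                       hyper$burn_in, hyper$n_samples, tokens$n_pixels)
    post <- posterior_from_counts(res$pixel_topic, tokens$height, tokens$width, eps)
    attr(post, "state") <- structure(
      list(z = res$z + 1L, k_topics = hyper$k_topics,
           n_dk = res$n_dk, n_kw = res$n_kw, n_k = res$n_k),
      class = "lda_state")
    post
  })
}
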
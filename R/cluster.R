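#' Unsupervised structure of the score matrix
#'
#' Agglomerative hierarchical clustering (average linkage on Euclidean
#' distances) of objects and, separately, of markers, plus a deterministic
#' two-dimensional t-SNE embedding of the objects. DNA is excluded by
#' construction (the score matrix holds protein scores only). With the seed
#' fixed the embedding is exactly reproducible; perplexity defaults to
#' `min(30, floor((n - 1) / 3))`.
#'
#' @param sm a `score_matrix` with at least 2 objects.
#' @param seed integer seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param max_iter gradient-descent iterations.
#' @return list: `object_hclust`, `marker_hclust` (stats::hclust objects) and
#'   `embedding` (n x 2 matrix, rows named by ROI id).
#' @export
cluster_objects <- function(sm, seed = 1L, perplexity = 30, max_iter = 500L) {
  stopifnot(inherits(sm, "score_matrix"))
  x <- sm$scores
  if (nrow(x) < 2) stop("validation error: need at least 2 objects")
  oh <- stats::hclust(stats::dist(x), method = "average")
  mh <- stats::hclust(stats::dist(t(x)), method = "average")
  perp <- min(perplexity, floor((nrow(x) - 1) / 3))
  emb <- with_seed(seed, tsne_exact(x, perplexity = max(perp, 1),
    max_iter = max_iter))
  rownames(emb) <- rownames(x)
  list(object_hclust = oh, marker_hclust = mh, embedding = emb)
}

# Exact-gradient t-SNE (no Barnes-Hut approximation): suited to the few
# hundred objects of an IMC cohort and fully deterministic given the RNG
# state. Standard formulation: Gaussian input affinities calibrated per
# point to the target perplexity by bisection, Student-t low-dimensional
# kernel, early exaggeration, momentum gradient descent.
tsne_exact <- function(x, perplexity = 30, max_iter = 500L,
                       eta = 100, exaggeration = 12, exagg_iter = 100L,
                       momentum = c(0.5, 0.8), tol = 1e-5) {
  x <- as.matrix(x)
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2

  # per-point bandwidths by bisection on the Shannon perplexity
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20
    hi <- 1e20
    beta <- 1
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) {
        hi <- beta
        beta <- (lo + hi) / 2
        next
      }
      pj <- w / sw
      h <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      if (abs(h - target) < tol) break
      if (h > target) lo <- beta else hi <- beta
      beta <- if (is.finite(hi) && hi < 1e19) (lo + hi) / 2 else beta * 2
    }
    p[i, -i] <- pj
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  for (iter in seq_len(max_iter)) {
    pe <- if (iter <= exagg_iter) p * exaggeration else p
    sumy <- rowSums(y^2)
    num <- 1 / (1 + outer(sumy, sumy, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    stiff <- 4 * (pe - q) * num
    grad <- (diag(rowSums(stiff)) - stiff) %*% y
    mom <- if (iter <= 250) momentum[1] else momentum[2]
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  colnames(y) <- c("tsne1", "tsne2")
  y
}
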
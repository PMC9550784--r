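#' Drop the minimum and maximum replicate value
#'
#' Before embedding, each molecule's replicate STR vector is trimmed by
#' removing exactly one minimal and one maximal element (its most extreme
#' replicates), so six replicates become a four-dimensional feature vector.
#' Ties drop a single instance each. The median of an even-length input is
#' unchanged.
#'
#' @param values Numeric vector, length >= 4.
#' @return The trimmed vector (length reduced by 2), in original order.
#' @export
trim_minmax <- function(values) {
  if (length(values) < 4) {
    stop("need at least four values to trim the extremes", call. = FALSE)
  }
  drop <- c(which.min(values), which.max(values))
  if (drop[1] == drop[2]) drop <- c(drop[1], setdiff(seq_along(values), drop[1])[1])
  values[-drop]
}

## Exact (dense) t-SNE for small point sets.
##
## Conditional probabilities are calibrated per point by bisection on the
## Gaussian precision so that the perplexity of each row matches the
## requested value; the symmetrized, normalized affinities are then matched
## against Student-t similarities of the 2-D embedding by momentum gradient
## descent with early exaggeration. O(n^2) per iteration, intended for
## panels of tens of molecules.
## The step size is deliberately small: with tens of points the affinities
## p_ij are O(1/n^2) large (unlike the huge-n regime), and larger rates make
## the early-exaggeration attraction overshoot and diverge.
tsne_exact <- function(X, perplexity = 5, n_iter = 1000, eta = 0.1) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- 1e-12; hi <- 1e12; beta <- 1
    for (it in 1:60) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { H <- 0 } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < 1e-7) break
      if (H > target) lo <- beta else hi <- beta
      beta <- (lo + hi) / 2
    }
    w <- exp(-d * beta)
    sw <- sum(w)
    P[i, -i] <- if (sw < .Machine$double.xmin) 1 / (n - 1) else w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  exag <- 4
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    G <- 4 * (Pe - Q) * num
    grad <- matrix(0, n, 2)
    for (k in 1:2) {
      grad[, k] <- rowSums(G * outer(Y[, k], Y[, k], "-"))
    }
    mom <- if (it <= 250) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed replicate STR vectors in two dimensions
#'
#' Reduces each molecule's replicate STR vector to a point in the plane
#' with t-SNE on Euclidean distances, so that molecules with similar STR
#' profiles — candidate members of the same cascade — appear close
#' together. Coordinates are reproducible for a fixed seed but have no
#' absolute meaning (any rotation/reflection/translation is equivalent);
#' interpret only relative distances and cluster structure.
#'
#' @param vectors Named list of equal-length numeric vectors (one per
#'   molecule, typically [trim_minmax()]-trimmed replicate STRs), or a
#'   numeric matrix with one row per molecule and molecule ids as rownames.
#' @param perplexity t-SNE perplexity; must be smaller than the number of
#'   molecules. Default 5, suited to panels of ~20 molecules.
#' @param n_iter Gradient-descent iterations, default 1000.
#' @param seed Optional seed for the random initialization.
#' @return Tibble with `molecule_id`, `x`, `y`.
#' @export
embed_str_vectors <- function(vectors, perplexity = 5, n_iter = 1000,
                              seed = NULL) {
  if (is.list(vectors)) {
    if (length(unique(lengths(vectors))) != 1) {
      stop("all STR vectors must have equal length", call. = FALSE)
    }
    X <- do.call(rbind, vectors)
    rownames(X) <- names(vectors)
  } else {
    X <- as.matrix(vectors)
  }
  n <- nrow(X)
  if (n < 3) stop("need at least three vectors to embed", call. = FALSE)
  if (perplexity >= n) {
    stop("`perplexity` must be smaller than the number of vectors", call. = FALSE)
  }
  run <- function() tsne_exact(X, perplexity = perplexity, n_iter = n_iter)
  Y <- if (is.null(seed)) run() else with_seed(seed, run())
  tibble::tibble(molecule_id = rownames(X) %||% as.character(seq_len(n)),
                 x = Y[, 1], y = Y[, 2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster separation of an embedding
#'
#' Mean silhouette coefficient of the embedded points under the given
#' labels (e.g. cascade membership): near 1 when label groups form tight,
#' well-separated clusters, near 0 when labels are interleaved. Labels with
#' a single point are excluded with a warning; degenerate embeddings where
#' all pairwise distances vanish score 0 by convention.
#'
#' @param coords Tibble from [embed_str_vectors()] (columns `x`, `y`) or a
#'   two-column matrix.
#' @param labels Vector of group labels, one per point (at least two groups
#'   with >= 2 points each).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
cluster_separation <- function(coords, labels) {
  if (is.data.frame(coords)) coords <- cbind(coords$x, coords$y)
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels))
  sizes <- table(labels)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding single-point label(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
    keep <- !(labels %in% drop)
    coords <- coords[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) {
    stop("need at least two labels with two or more points", call. = FALSE)
  }
  d <- stats::dist(coords)
  if (max(d) < 1e-12) return(0)
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  widths <- sil[, "sil_width"]
  widths[!is.finite(widths)] <- 0
  mean(widths)
}
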
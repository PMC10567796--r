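#' Sample motif-position pairs from training sequences
#'
#' Draws `m` pairs uniformly over (sequence, valid window start); each pair
#' is a one-hot window nPFM together with its start position mapped to the
#' unit half-circle. Used to seed anchor initialisation, where `m` should be
#' much larger than the number of anchors.
#'
#' @param data List of `encoded_seq`, all of length >= `k`.
#' @param m Number of pairs to draw.
#' @param k Motif length.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `motifs` (`m` x \eqn{|A| k} matrix of flattened
#'   windows), `positions` (`m` x 2 matrix of circle positions), and the
#'   integer indices `seq_idx`, `win_idx` of each draw.
#' @export
sample_pairs <- function(data, m, k, seed = NULL) {
  if (length(data) == 0L) stop("cannot sample from an empty dataset")
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- vapply(data, `[[`, integer(1), "length")
  if (any(lens < k)) stop("all sequences must have length >= k")
  n_win <- lens - k + 1L
  seq_idx <- sample.int(length(data), m, replace = TRUE)
  win_idx <- vapply(seq_idx, function(s) sample.int(n_win[s], 1L), integer(1))
  d <- nrow(data[[1]]$matrix)
  motifs <- matrix(0, m, d * k)
  positions <- matrix(0, m, 2)
  for (i in seq_len(m)) {
    s <- data[[seq_idx[i]]]
    p <- win_idx[i]
    motifs[i, ] <- as.vector(s$matrix[, p:(p + k - 1L)])
    positions[i, ] <- map_position(p, s$length)
  }
  list(motifs = motifs, positions = positions,
       seq_idx = seq_idx, win_idx = win_idx)
}

# k-means++ seeding: first centre uniform, then distance-squared proportional
kmeanspp_centers <- function(x, n) {
  m <- nrow(x)
  centers <- integer(n)
  centers[1] <- sample.int(m, 1L)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  if (n > 1L) {
    for (i in 2:n) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) <= 0) {
        # all remaining points coincide with a centre: pick uniformly
        centers[i] <- sample.int(m, 1L)
      } else {
        centers[i] <- sample.int(m, 1L, prob = prob)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[i], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' Initialise anchor points by constrained k-means
#'
#' Clusters sampled motif-position pairs (concatenated flattened motif and
#' circle position vectors) with euclidean k-means using k-means++ seeding,
#' then enforces the nPFM and half-circle constraints on the cluster centres
#' via [constraint_project()].
#'
#' @param pairs Output of [sample_pairs()].
#' @param n Number of anchors.
#' @param alphabet_size Number of residue symbols \eqn{|A|}.
#' @param k Motif length.
#' @param seed Optional RNG seed.
#' @param iter_max Maximum k-means iterations.
#' @return An `anchor_set`: list with `n`, `motifs` (`n` x \eqn{|A| k}),
#'   `positions` (`n` x 2), `alphabet_size`, `k`, `trainable`.
#' @export
init_anchors <- function(pairs, n, alphabet_size, k, seed = NULL,
                         iter_max = 100L) {
  m <- nrow(pairs$motifs)
  if (n > m) stop(sprintf("cannot place %d anchors from %d sampled pairs", n, m))
  if (!is.null(seed)) set.seed(seed)
  x <- cbind(pairs$motifs, pairs$positions)
  centers <- kmeanspp_centers(x, n)
  centers <- centers + 0  # drop names
  fit <- suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = iter_max,
                  algorithm = "Lloyd")
  )
  d <- ncol(pairs$motifs)
  centers <- unname(fit$centers)
  anchors <- structure(
    list(n = n,
         motifs = centers[, seq_len(d), drop = FALSE],
         positions = centers[, d + 1:2, drop = FALSE],
         alphabet_size = as.integer(alphabet_size), k = as.integer(k),
         trainable = TRUE),
    class = "anchor_set")
  constraint_project(anchors)
}

#' Project anchors back onto their constraint sets
#'
#' Motif blocks: entries clamped to >= 0 column-wise, then each
#' \eqn{|A|}-vector column rescaled to unit l2 norm; a column that clamps to
#' all zeros becomes the uniform unit-norm column. Positions: second
#' coordinate clamped to >= 0, then the 2-vector rescaled to unit norm (a
#' zero vector becomes (0, 1)). Total and idempotent; applied after k-means
#' and after every optimiser step so that anchors always remain valid
#' motif-position pairs.
#'
#' @param anchors An `anchor_set` with arbitrary real parameters.
#' @return The projected `anchor_set`.
#' @export
constraint_project <- function(anchors) {
  d <- anchors$alphabet_size
  k <- anchors$k
  M <- pmax(anchors$motifs, 0)
  for (i in seq_len(anchors$n)) {
    w <- matrix(M[i, ], nrow = d, ncol = k)
    nrm <- sqrt(colSums(w^2))
    zero <- nrm < 1e-12
    if (any(zero)) {
      w[, zero] <- 1 / sqrt(d)
      nrm[zero] <- 1
    }
    M[i, ] <- as.vector(sweep(w, 2, nrm, "/"))
  }
  P <- anchors$positions
  P[, 2] <- pmax(P[, 2], 0)
  nrm <- sqrt(rowSums(P^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    P[zero, ] <- rep(c(0, 1), each = sum(zero))
    nrm[zero] <- 1
  }
  anchors$motifs <- M
  anchors$positions <- P / nrm
  anchors
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %d anchors, |A|=%d, k=%d%s\n", x$n,
              x$alphabet_size, x$k,
              if (isTRUE(x$trainable)) ", trainable" else ""))
  invisible(x)
}

#' Retrieve one anchor's nPFM
#' @param anchors An `anchor_set`.
#' @param i Anchor index.
#' @return An \eqn{|A| \times k} nPFM matrix.
#' @export
anchor_npfm <- function(anchors, i) {
  matrix(anchors$motifs[i, ], nrow = anchors$alphabet_size, ncol = anchors$k)
}

# Gram matrix of K0 over the anchors (unit diagonal by construction)
anchor_gram <- function(anchors, params) {
  M <- anchors$motifs %*% t(anchors$motifs)
  P <- anchors$positions %*% t(anchors$positions)
  cpos <- params$beta / (2 * params$sigma^2)
  G <- exp(params$alpha * (M - params$k) + cpos * (P - 1))
  (G + t(G)) / 2
}

anchor_signature <- function(anchors) {
  sum(anchors$motifs * seq_along(anchors$motifs)) +
    sum(anchors$positions * seq_along(anchors$positions))
}

#' Anchor Gram matrix and its inverse square root
#'
#' Computes \eqn{K_{ZZ}}, the Gram matrix of \eqn{K_0} over the anchor
#' points, and its (pseudo-)inverse square root via a symmetric
#' eigendecomposition with eigenvalues floored at `epsilon`. The result
#' parametrises the subspace projection \eqn{\psi(z) = K_{ZZ}^{-1/2} K_Z(z)}.
#'
#' @param anchors An `anchor_set`.
#' @param params A [pam_params()] object (its `k` must match the anchors).
#' @param epsilon Eigenvalue floor (default `1e-6`).
#' @return A `nystrom_state`: list with `K_ZZ`, `K_ZZ_inv_sqrt`, `epsilon`
#'   and an internal anchor fingerprint used for staleness checks.
#' @export
gram_inverse_sqrt <- function(anchors, params, epsilon = 1e-6) {
  stopifnot(params$k == anchors$k)
  G <- anchor_gram(anchors, params)
  if (!all(is.finite(G))) stop("non-finite entries in the anchor Gram matrix")
  eig <- eigen(G, symmetric = TRUE)
  lam <- pmax(eig$values, epsilon)
  inv_sqrt <- eig$vectors %*% (t(eig$vectors) / sqrt(lam))
  inv_sqrt <- (inv_sqrt + t(inv_sqrt)) / 2
  structure(list(K_ZZ = G, K_ZZ_inv_sqrt = inv_sqrt, epsilon = epsilon,
                 signature = anchor_signature(anchors)),
            class = "nystrom_state")
}

check_state <- function(state, anchors) {
  if (abs(state$signature - anchor_signature(anchors)) > 1e-10) {
    stop("stale nystrom_state: anchors changed since gram_inverse_sqrt()")
  }
  invisible(state)
}

#' Project one motif-position pair onto the anchor subspace
#'
#' \eqn{\psi(w) = K_{ZZ}^{-1/2} (K_0(z_1, w), \dots, K_0(z_n, w))^T}: the
#' explicit finite-dimensional feature map of the Nystroem approximation.
#' Inner products of projected pairs approximate \eqn{K_0}, exactly so on
#' the anchors themselves when \eqn{K_{ZZ}} has full rank.
#'
#' @param w A list with `npfm` (\eqn{|A| \times k} matrix) and `position`
#'   (circle 2-vector).
#' @param state A `nystrom_state` from [gram_inverse_sqrt()].
#' @param anchors The `anchor_set` the state was computed from.
#' @param params A [pam_params()] object.
#' @return A numeric vector of length `anchors$n`.
#' @export
project_window <- function(w, state, anchors, params) {
  check_state(state, anchors)
  check_npfm(w$npfm, "window motif")
  check_circle_position(w$position, "window position")
  wv <- as.vector(w$npfm)
  kz <- exp(params$alpha * (drop(anchors$motifs %*% wv) - params$k) +
            params$beta / (2 * params$sigma^2) *
              (drop(anchors$positions %*% w$position) - 1))
  drop(state$K_ZZ_inv_sqrt %*% kz)
}

#' Kernel-layer feature map of a whole sequence
#'
#' Applies the subspace projection to every length-`k` window of `x`:
#' row `p` of the result is [project_window()] of the window starting at
#' position `p`. Implemented with dense matrix products (window/anchor
#' motif inner products, precomputed position cosines, elementwise
#' exponentiation, multiplication by \eqn{K_{ZZ}^{-1/2}}) and agrees with
#' the per-window reference path to tight tolerance.
#'
#' @param x An `encoded_seq` of length >= `k`.
#' @param state A `nystrom_state`.
#' @param anchors The matching `anchor_set`.
#' @param params A [pam_params()] object.
#' @return A \eqn{(|x|-k+1) \times n} matrix.
#' @export
forward_sequence <- function(x, state, anchors, params) {
  check_state(state, anchors)
  W <- sequence_windows(x, params$k)
  P <- map_position(seq_len(nrow(W)), x$length)
  if (nrow(W) == 1L) P <- matrix(P, nrow = 1)
  K0 <- exp(params$alpha * (W %*% t(anchors$motifs) - params$k) +
            params$beta / (2 * params$sigma^2) *
              (P %*% t(anchors$positions) - 1))
  K0 %*% state$K_ZZ_inv_sqrt
}
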
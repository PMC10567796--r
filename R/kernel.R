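#' Kernel hyperparameters
#'
#' Bundles the hyperparameters of the position-aware motif kernel:
#' `alpha` controls how sharply the motif comparison decays with mismatch,
#' `beta` rescales positional distance after the unit-circle mapping (the
#' convenience rule `beta = L^2 / 10` compensates the mapping for sequences
#' of length `L`), `sigma` is the positional uncertainty bandwidth, and `k`
#' is the motif length in residues.
#'
#' @param k Motif length (integer >= 1).
#' @param alpha Motif sharpness, > 0.
#' @param beta Position scaling, > 0, or `"auto"` to use \eqn{L^2/10} where
#'   `L` must then be supplied.
#' @param sigma Positional uncertainty, > 0.
#' @param L Sequence length, only used to resolve `beta = "auto"`.
#' @return A `pam_params` object.
#' @examples
#' pam_params(k = 5, alpha = 1, beta = "auto", sigma = 4, L = 100)  # beta 1000
#' @export
pam_params <- function(k, alpha = 1, beta = 1, sigma = 4, L = NULL) {
  if (identical(beta, "auto")) {
    if (is.null(L)) stop("beta = \"auto\" requires the sequence length L")
    beta <- L^2 / 10
  }
  stopifnot(k >= 1, k == as.integer(k), alpha > 0, beta > 0, sigma > 0)
  structure(list(k = as.integer(k), alpha = alpha, beta = beta, sigma = sigma),
            class = "pam_params")
}

#' @export
print.pam_params <- function(x, ...) {
  cat(sprintf("<pam_params> k=%d alpha=%g beta=%g sigma=%g (C=%g)\n",
              x$k, x$alpha, x$beta, x$sigma, pam_constant(x)))
  invisible(x)
}

#' Normalisation constant of the sequence kernel
#'
#' \eqn{C = \sqrt{\pi^2 \sigma^2 / (2 \alpha \beta)}}, the factor arising
#' when the sequence-level kernel is written as an inner product of
#' motif-function representatives.
#'
#' @param params A [pam_params()] object.
#' @return A positive scalar.
#' @export
pam_constant <- function(params) {
  sqrt(pi^2 * params$sigma^2 / (2 * params$alpha * params$beta))
}

#' Validate a normalised position frequency matrix
#'
#' An nPFM is a non-negative \eqn{|A| \times k} matrix whose columns have
#' unit l2 norm; its flattened (column-concatenated) form therefore has
#' squared norm `k`. One-hot sequence windows are trivially valid nPFMs,
#' which puts input windows and learned anchors in the same space.
#'
#' @param m Numeric matrix.
#' @param tol Tolerance on the column norms.
#' @return `TRUE` or `FALSE`.
#' @export
is_npfm <- function(m, tol = 1e-9) {
  is.matrix(m) && all(is.finite(m)) && all(m >= 0) &&
    all(abs(sqrt(colSums(m^2)) - 1) <= tol)
}

check_npfm <- function(m, what = "motif") {
  if (!is_npfm(m)) stop(what, " is not a valid nPFM ",
                        "(non-negative with unit l2-norm columns)")
  invisible(m)
}

#' Position comparison kernel
#'
#' \eqn{K_{pos}(p, q) = \exp\{\beta/(2\sigma^2)(\tilde p^T \tilde q - 1)\}}
#' on positions mapped to the upper unit half-circle (see
#' [map_position()]). Equals 1 iff the positions coincide and decays with
#' angular distance.
#'
#' @param p,q Circle positions (2-vectors from [map_position()]).
#' @param params A [pam_params()] object.
#' @return A scalar in (0, 1].
#' @export
k_position <- function(p, q, params) {
  check_circle_position(p, "p")
  check_circle_position(q, "q")
  exp(params$beta / (2 * params$sigma^2) * (sum(p * q) - 1))
}

#' Motif comparison kernel
#'
#' \eqn{K_{nPFM}(\omega, \omega') = \exp\{\alpha(\omega^T\omega' - k)\}} on
#' flattened nPFMs. Equals 1 iff the motifs match exactly and approaches 0
#' with increasing difference, at a rate set by `alpha`.
#'
#' @param w1,w2 nPFMs (\eqn{|A| \times k} matrices) over the same alphabet.
#' @param params A [pam_params()] object.
#' @return A scalar in (0, 1].
#' @export
k_npfm <- function(w1, w2, params) {
  if (!all(dim(w1) == dim(w2))) {
    stop("nPFM dimension mismatch: ", paste(dim(w1), collapse = "x"),
         " vs ", paste(dim(w2), collapse = "x"))
  }
  check_npfm(w1, "w1"); check_npfm(w2, "w2")
  exp(params$alpha * (sum(w1 * w2) - ncol(w1)))
}

#' Single-pair kernel on motif-position pairs
#'
#' The product kernel \eqn{K_0(z, z') = K_{nPFM} \cdot K_{pos}} over
#' motif-position pairs `z = (npfm, position)`. This is the kernel whose
#' RKHS the network's first layer projects into; \eqn{K_0(z, z) = 1}.
#'
#' @param z1,z2 Lists with elements `npfm` and `position`.
#' @param params A [pam_params()] object.
#' @return A scalar in (0, 1].
#' @export
k0 <- function(z1, z2, params) {
  k_npfm(z1$npfm, z2$npfm, params) *
    k_position(z1$position, z2$position, params)
}

# one-hot windows of an encoded sequence, flattened column-major:
# row p holds the |A|*k entries of the window starting at position p
sequence_windows <- function(x, k) {
  L <- x$length
  if (L < k) stop(sprintf("sequence '%s' shorter than motif length (%d < %d)",
                          x$id, L, k))
  d <- nrow(x$matrix)
  n_win <- L - k + 1L
  v <- as.vector(x$matrix)
  idx <- outer(seq_len(n_win) - 1L, seq_len(d * k), function(p, j) p * d + j)
  matrix(v[idx], nrow = n_win, ncol = d * k)
}

#' Position-aware motif kernel between two sequences
#'
#' Sums \eqn{K_0} over every pair of length-`k` windows of the two sequences
#' (window starts \eqn{p = 1 \dots |x|-k+1}, each window's circle position
#' taken at its start), scaled by the constant [pam_constant()]:
#' \deqn{K_{PAM}(x, x') = C \sum_p \sum_q K_0((\omega_p, p), (\omega_q, q)).}
#'
#' @param x,y `encoded_seq` objects over the same alphabet.
#' @param params A [pam_params()] object.
#' @return A positive scalar.
#' @export
k_pam <- function(x, y, params) {
  if (!identical(x$kind, y$kind)) stop("sequences use different alphabets")
  k <- params$k
  Wx <- sequence_windows(x, k)
  Wy <- sequence_windows(y, k)
  Px <- map_position(seq_len(nrow(Wx)), x$length)
  Py <- map_position(seq_len(nrow(Wy)), y$length)
  if (nrow(Wx) == 1L) Px <- matrix(Px, nrow = 1)
  if (nrow(Wy) == 1L) Py <- matrix(Py, nrow = 1)
  M <- Wx %*% t(Wy)
  P <- Px %*% t(Py)
  cpos <- params$beta / (2 * params$sigma^2)
  pam_constant(params) * sum(exp(params$alpha * (M - k) + cpos * (P - 1)))
}

#' Gram matrix of the sequence kernel
#'
#' @param data List of `encoded_seq`.
#' @param params A [pam_params()] object.
#' @return A symmetric `length(data)` x `length(data)` matrix.
#' @export
pam_gram <- function(data, params) {
  n <- length(data)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      G[i, j] <- G[j, i] <- k_pam(data[[i]], data[[j]], params)
    }
  }
  dimnames(G) <- list(vapply(data, `[[`, "", "id"),
                      vapply(data, `[[`, "", "id"))
  G
}
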
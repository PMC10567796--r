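#' Kernel-layer neuron importances for one class
#'
#' Backward recursion over the positive-weight edges of the linear head.
#' A neuron whose positive successors intersect the output layer in exactly
#' the class node scores 1; in a different output set (another class node,
#' or several output nodes) it scores 0; an interior neuron scores the
#' positive-weight-weighted sum of its successors' scores. Only strictly
#' positive weights define edges, so importances are non-negative by
#' construction.
#'
#' @param model A trained `pam_model` (or any list with `W1`, `W2`).
#' @param class_index 0-based class.
#' @return Numeric vector over the kernel-layer output neurons, ordered
#'   position-major (the `n` anchors of window position 1 first).
#' @export
neuron_importance <- function(model, class_index) {
  n_classes <- nrow(model$W2)
  if (class_index < 0 || class_index >= n_classes) {
    stop("class_index out of range")
  }
  pos2 <- model$W2 > 0
  # hidden neuron scores: 1 iff positively connected to exactly this output
  h <- as.numeric(pos2[class_index + 1L, ] & colSums(pos2) == 1L)
  drop(crossprod(pmax(model$W1, 0), h))
}

#' Per-position class importance profile
#'
#' Averages [neuron_importance()] over the `n` anchors at each window
#' position, giving one importance value per sequence window position and
#' class.
#'
#' @param model A trained `pam_model`.
#' @param class_index 0-based class, or `NULL` for all classes.
#' @return A \eqn{(L-k+1) \times} classes matrix of importances (a plain
#'   vector when `class_index` is given).
#' @export
position_importance <- function(model, class_index = NULL) {
  classes <- if (is.null(class_index)) seq_len(model$config$n_classes) - 1L
             else class_index
  out <- vapply(classes, function(cl) {
    iota <- neuron_importance(model, cl)
    rowMeans(matrix(iota, nrow = model$L_out, ncol = model$anchors$n,
                    byrow = TRUE))
  }, numeric(model$L_out))
  if (!is.null(class_index)) drop(out) else {
    colnames(out) <- paste0("class", classes)
    out
  }
}

#' Sliding-window peak detection on an importance profile
#'
#' For each position, subtracts the mean importance over a centred window
#' (length `window`, truncated at the profile boundaries) from the position
#' importance, and returns the `top` largest resulting heights. Ties are
#' broken towards the lower position index.
#'
#' @param iota Numeric importance vector (one class column of
#'   [position_importance()]).
#' @param window Odd window length (default 11).
#' @param top Number of peaks to return (default 10).
#' @return A data.frame with columns `position` and `height`, sorted by
#'   decreasing height.
#' @export
detect_peaks <- function(iota, window = 11L, top = 10L) {
  if (window %% 2L != 1L) stop("window must be odd")
  L <- length(iota)
  half <- (window - 1L) %/% 2L
  height <- vapply(seq_len(L), function(p) {
    lo <- max(1L, p - half); hi <- min(L, p + half)
    iota[p] - mean(iota[lo:hi])
  }, numeric(1))
  ord <- order(-height, seq_len(L))
  sel <- ord[seq_len(min(top, L))]
  data.frame(position = sel, height = height[sel])
}

#' Weighted mean motif of a class at a position
#'
#' Identifies the anchors at the given window position whose importance for
#' the class is positive, normalises those importances to sum to one, and
#' averages the anchor nPFMs under these weights; columns of the mean are
#' rescaled back to unit l2 norm. The per-column residue ranking (descending
#' column entries) gives the most important residues of the motif.
#'
#' @param model A trained `pam_model`.
#' @param position 1-based window position.
#' @param class_index 0-based class.
#' @return A `class_motif`: list with `position`, `class_index`, `npfm`,
#'   `contributing_weights` (per contributing anchor, summing to 1) and
#'   `anchor_index`; or `NULL` (with a message) when no anchor at the
#'   position carries positive weight for the class.
#' @export
class_mean_motif <- function(model, position, class_index) {
  if (position < 1 || position > model$L_out) stop("position out of range")
  n <- model$anchors$n
  iota <- neuron_importance(model, class_index)
  w <- iota[(position - 1L) * n + seq_len(n)]
  keep <- which(w > 0)
  if (length(keep) == 0L) {
    message(sprintf("no class-%d-associated motif at position %d",
                    class_index, position))
    return(NULL)
  }
  wn <- w[keep] / sum(w[keep])
  d <- model$alphabet_size; k <- model$anchors$k
  mean_flat <- drop(wn %*% model$anchors$motifs[keep, , drop = FALSE])
  npfm <- matrix(mean_flat, nrow = d, ncol = k)
  if (!is.null(model$kind)) {
    rownames(npfm) <- make_alphabet(model$kind)$symbols
  }
  nrm <- sqrt(colSums(npfm^2))
  nrm[nrm < 1e-12] <- 1
  npfm <- sweep(npfm, 2, nrm, "/")
  structure(list(position = position, class_index = class_index,
                 npfm = npfm, contributing_weights = wn,
                 anchor_index = keep),
            class = "class_motif")
}

#' @export
print.class_motif <- function(x, ...) {
  cat(sprintf("<class_motif> class %d at position %d (%d anchors)\n",
              x$class_index, x$position, length(x$anchor_index)))
  print(round(x$npfm, 3))
  invisible(x)
}

#' Top residues of a motif, column by column
#'
#' @param npfm An nPFM matrix with residue rownames.
#' @param top How many residues per column.
#' @return A character matrix, `top` rows by `k` columns.
#' @export
motif_top_residues <- function(npfm, top = 2L) {
  out <- vapply(seq_len(ncol(npfm)), function(j) {
    rownames(npfm)[order(npfm[, j], decreasing = TRUE)][seq_len(top)]
  }, character(top))
  matrix(out, nrow = top, ncol = ncol(npfm))
}

#' l2-norm of a motif function on a sequence
#'
#' The motif function of a motif-position pair evaluated on the integer
#' position grid of a sequence is
#' \deqn{f(t) = \sum_p K_{nPFM}(\omega, \omega_p(x)) \, K_{pos}(t, p),}
#' summing over all window starts `p`: a position-smoothed occurrence
#' profile generalising the oligo function from exact k-mers to degenerate
#' motifs. Its euclidean norm over `t = 1..|x|` measures how strongly the
#' motif occurs in the sequence (larger for better matches near any
#' position).
#'
#' @param npfm The motif's nPFM matrix.
#' @param x An `encoded_seq`.
#' @param params A [pam_params()] object.
#' @return A positive scalar.
#' @export
motif_function_norm <- function(npfm, x, params) {
  check_npfm(npfm)
  k <- params$k
  W <- sequence_windows(x, k)
  match_score <- exp(params$alpha * (drop(W %*% as.vector(npfm)) - k))
  Pwin <- map_position(seq_len(nrow(W)), x$length)
  if (nrow(W) == 1L) Pwin <- matrix(Pwin, nrow = 1)
  Pt <- map_position(seq_len(x$length), x$length)
  cpos <- params$beta / (2 * params$sigma^2)
  f <- drop(exp(cpos * (Pt %*% t(Pwin) - 1)) %*% match_score)
  sqrt(sum(f^2))
}

#' Local explanation of a single input
#'
#' For each selected window position, retrieves the per-class mean motifs
#' ([class_mean_motif()]), evaluates each motif function's l2-norm on the
#' input, rescales the norms at each position to [0, 1] by their maximum,
#' and assigns the position to the class with the largest norm (ties go to
#' the lower class index and are flagged).
#'
#' @param model A trained `pam_model`.
#' @param x An `encoded_seq` of the training length.
#' @param positions 1-based window positions to explain.
#' @param params Kernel parameters for the motif functions; defaults to the
#'   model's.
#' @return A `local_explanation`: data.frame with one row per position:
#'   `position`, `residue` (the input residue at that position),
#'   `assigned_class`, `tie`, and one `norm_class<c>` column per class.
#' @export
explain_input <- function(model, x, positions, params = NULL) {
  if (is.null(params)) params <- model$config$pam
  n_classes <- model$config$n_classes
  alphabet <- make_alphabet(x$kind)
  rows <- lapply(positions, function(p) {
    norms <- vapply(seq_len(n_classes) - 1L, function(cl) {
      cm <- suppressMessages(class_mean_motif(model, p, cl))
      if (is.null(cm)) 0 else motif_function_norm(cm$npfm, x, params)
    }, numeric(1))
    mx <- max(norms)
    scaled <- if (mx > 0) norms / mx else norms
    best <- which(scaled == max(scaled))
    res <- data.frame(position = p,
                      residue = alphabet$symbols[which.max(x$matrix[, p])],
                      assigned_class = best[1] - 1L,
                      tie = length(best) > 1L)
    for (cl in seq_len(n_classes)) res[[paste0("norm_class", cl - 1L)]] <-
      scaled[cl]
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "sequence_id") <- x$id
  class(out) <- c("local_explanation", "data.frame")
  out
}

#' Global interpretation summary of a trained model
#'
#' Convenience wrapper: per-class importance profiles, their top peaks, and
#' the class mean motifs at each peak with the top residues.
#'
#' @param model A trained `pam_model`.
#' @param window Sliding-window length for peak detection.
#' @param top Number of peaks per class.
#' @param top_residues Residues to report per motif column.
#' @return A list with `importance` (matrix), and per class a data.frame of
#'   peaks plus the list of peak motifs.
#' @export
interpret_model <- function(model, window = 11L, top = 10L,
                            top_residues = 2L) {
  imp <- position_importance(model)
  classes <- seq_len(model$config$n_classes) - 1L
  per_class <- lapply(classes, function(cl) {
    peaks <- detect_peaks(imp[, cl + 1L], window = window, top = top)
    motifs <- lapply(peaks$position, function(p)
      suppressMessages(class_mean_motif(model, p, cl)))
    peaks$top_residues <- vapply(motifs, function(m) {
      if (is.null(m)) return(NA_character_)
      paste(apply(motif_top_residues(m$npfm, top_residues), 2, paste,
                  collapse = "/"), collapse = " ")
    }, character(1))
    list(peaks = peaks, motifs = motifs)
  })
  names(per_class) <- paste0("class", classes)
  list(importance = imp, classes = per_class)
}
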
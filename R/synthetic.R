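#' Specification of a planted motif
#'
#' Describes a degenerate motif planted into one class of synthetic
#' sequences: one residue distribution per motif column, a 1-based planting
#' start position, and a maximum absolute positional jitter. Each generated
#' sequence of the class receives exactly one motif instance, sampled
#' column-wise from the distributions and written at
#' `center + U{-jitter, ..., +jitter}`.
#'
#' @param columns List of named numeric vectors, one per motif column; each
#'   must sum to 1 (e.g. `c(G = 2/3, T = 1/3)` for a column that is guanine
#'   two-thirds of the time and thymine otherwise).
#' @param center 1-based planting start position.
#' @param jitter Maximum absolute positional offset (non-negative integer).
#' @param class_index 0-based class the motif belongs to.
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(columns, center, jitter, class_index) {
  stopifnot(length(columns) >= 1, jitter >= 0, center - jitter >= 1)
  for (col in columns) {
    stopifnot(!is.null(names(col)), all(col > 0),
              abs(sum(col) - 1) < 1e-9)
  }
  structure(list(columns = columns, center = as.integer(center),
                 jitter = as.integer(jitter),
                 class_index = as.integer(class_index),
                 k = length(columns)),
            class = "plant_spec")
}

#' Default two-class planting scheme
#'
#' The shipped default emulates a two-class setup on length-100 DNA: a
#' 5-mer planted at position 20 (+/- 5) in class 0 ("negative") and a
#' distinct 5-mer planted at position 80 (+/- 5) in class 1 ("positive").
#' The negative motif's second column is guanine with probability 2/3 and
#' thymine with probability 1/3; the positive motif carries an analogous
#' degenerate column at its fourth position. The remaining columns are
#' deterministic consensus residues chosen here as a synthetic stand-in
#' (the full published motif matrices are not reproduced).
#'
#' @return List of two [plant_spec()] objects.
#' @export
default_plant_specs <- function() {
  list(
    plant_spec(list(c(A = 1), c(G = 2 / 3, T = 1 / 3), c(C = 1), c(G = 1),
                    c(T = 1)),
               center = 20, jitter = 5, class_index = 0L),
    plant_spec(list(c(C = 1), c(G = 1), c(A = 1), c(A = 2 / 3, C = 1 / 3),
                    c(G = 1)),
               center = 80, jitter = 5, class_index = 1L)
  )
}

#' Generate a two-class synthetic DNA dataset
#'
#' Background residues are i.i.d. uniform over `ACGT`; the dataset is split
#' exactly evenly between the classes; every sequence carries one planted
#' motif instance per its class's [plant_spec()], overwriting the
#' background at a jittered start position. Deterministic given `seed`.
#'
#' @param n_seqs Total number of sequences (must be divisible by the number
#'   of classes).
#' @param length Sequence length.
#' @param specs List of [plant_spec()], one per class, 0-based class
#'   indices covering `0..n_classes-1`.
#' @param seed RNG seed.
#' @return A list with `sequences` (named character vector), `labels`
#'   (integer vector), and `plant_starts` (the realised planting start of
#'   each sequence; useful for diagnostics).
#' @export
generate_dataset <- function(n_seqs = 1000L, length = 100L,
                             specs = default_plant_specs(), seed = 1L) {
  classes <- sort(vapply(specs, `[[`, integer(1), "class_index"))
  n_classes <- length(specs)
  if (!identical(classes, seq_len(n_classes) - 1L)) {
    stop("specs must cover classes 0 .. n_classes-1 exactly once")
  }
  if (n_seqs %% n_classes != 0L) {
    stop("n_seqs must be divisible by the number of classes")
  }
  for (sp in specs) {
    if (sp$center + sp$jitter + sp$k - 1L > length) {
      stop("planted motif overflows the sequence for class ", sp$class_index)
    }
  }
  set.seed(seed)
  per_class <- n_seqs %/% n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = per_class)
  nt <- c("A", "C", "G", "T")
  seqs <- character(n_seqs)
  starts <- integer(n_seqs)
  spec_of <- stats::setNames(specs[order(vapply(specs, `[[`, integer(1),
                                               "class_index"))],
                             as.character(seq_len(n_classes) - 1L))
  for (i in seq_len(n_seqs)) {
    chars <- sample(nt, length, replace = TRUE)
    sp <- spec_of[[as.character(labels[i])]]
    offset <- sample.int(2L * sp$jitter + 1L, 1L) - sp$jitter - 1L
    start <- sp$center + offset
    motif <- vapply(sp$columns, function(col)
      names(col)[sample.int(length(col), 1L, prob = col)], character(1))
    chars[start:(start + sp$k - 1L)] <- motif
    seqs[i] <- paste(chars, collapse = "")
    starts[i] <- start
  }
  names(seqs) <- sprintf("synth%04d", seq_len(n_seqs))
  list(sequences = seqs, labels = labels, plant_starts = starts)
}

#' Ground-truth nPFM of a planting specification
#'
#' Converts the per-column probability distributions of a [plant_spec()]
#' into a valid nPFM by rescaling each probability column to unit l2 norm.
#' Used as the recovery target when comparing learned class mean motifs to
#' the planted truth.
#'
#' @param spec A [plant_spec()].
#' @param alphabet A [make_alphabet()] object (default DNA).
#' @return An \eqn{|A| \times k} nPFM with residue rownames.
#' @export
spec_to_npfm <- function(spec, alphabet = make_alphabet("dna")) {
  d <- length(alphabet$symbols)
  m <- matrix(0, d, spec$k, dimnames = list(alphabet$symbols, NULL))
  for (j in seq_len(spec$k)) {
    col <- spec$columns[[j]]
    m[match(names(col), alphabet$symbols), j] <- col
    m[, j] <- m[, j] / sqrt(sum(m[, j]^2))
  }
  m
}

#' Consensus residues of a planting spec
#' @param spec A [plant_spec()].
#' @return Character vector: per motif column, the residue with the highest
#'   planting probability.
#' @export
spec_consensus <- function(spec) {
  vapply(spec$columns, function(col) names(col)[which.max(col)], character(1))
}

#' Degenerate columns of a planting spec
#' @param spec A [plant_spec()].
#' @return Logical vector over motif columns, `TRUE` where more than one
#'   residue has positive planting probability.
#' @export
spec_degenerate <- function(spec) {
  vapply(spec$columns, function(col) length(col) > 1L, logical(1))
}
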
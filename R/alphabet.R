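#' Residue alphabets
#'
#' An alphabet holds the ordered residue symbols over which sequences and
#' motifs are defined, together with a map from ambiguity codes to the subset
#' of symbols they stand for. DNA uses the four nucleotides in `ACGT` order
#' with the full IUPAC ambiguity set; the protein alphabet uses the 20
#' standard amino acids with `B`, `Z`, `J` and `X` as ambiguity codes.
#'
#' @param kind `"dna"` or `"protein"`.
#' @return An object of class `pam_alphabet` with fields `symbols`, `kind`
#'   and `ambiguity_map`.
#' @examples
#' ab <- make_alphabet("dna")
#' ab$symbols
#' @export
make_alphabet <- function(kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  if (kind == "dna") {
    symbols <- c("A", "C", "G", "T")
    amb <- list(
      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
      K = c("G", "T"), M = c("A", "C"),
      B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
      V = c("A", "C", "G"), N = c("A", "C", "G", "T")
    )
  } else {
    symbols <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    amb <- list(
      B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"), X = symbols
    )
  }
  structure(list(symbols = symbols, kind = kind, ambiguity_map = amb),
            class = "pam_alphabet")
}

#' @export
print.pam_alphabet <- function(x, ...) {
  cat(sprintf("<pam_alphabet> %s: %s (+%d ambiguity codes)\n",
              x$kind, paste(x$symbols, collapse = ""),
              length(x$ambiguity_map)))
  invisible(x)
}

#' One-hot encode a residue string
#'
#' Encodes a sequence as an \eqn{|A| \times L} matrix whose columns have unit
#' l2 norm. Unambiguous residues become one-hot columns; an ambiguity code
#' becomes the uniform column over its symbol subset, rescaled to unit l2
#' norm, so that every input column is a valid motif (nPFM) column. Parsing
#' is case-insensitive and, for DNA, `U` is read as `T`.
#'
#' @param seq A single residue string.
#' @param alphabet A [make_alphabet()] object.
#' @param id Sequence identifier stored with the encoding.
#' @param label Optional integer class label.
#' @return An `encoded_seq`: list with `id`, `matrix` (\eqn{|A| \times L}),
#'   `length`, `label` and `kind`.
#' @examples
#' x <- encode_sequence("ACGT", make_alphabet("dna"))
#' x$matrix
#' @export
encode_sequence <- function(seq, alphabet, id = "seq", label = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (alphabet$kind == "dna") chars[chars == "U"] <- "T"
  L <- length(chars)
  if (L == 0L) stop("cannot encode an empty sequence (id: ", id, ")")
  d <- length(alphabet$symbols)
  m <- matrix(0, nrow = d, ncol = L, dimnames = list(alphabet$symbols, NULL))
  base_idx <- match(chars, alphabet$symbols)
  for (p in seq_len(L)) {
    if (!is.na(base_idx[p])) {
      m[base_idx[p], p] <- 1
    } else {
      subset <- alphabet$ambiguity_map[[chars[p]]]
      if (is.null(subset)) {
        stop(sprintf("unknown character '%s' at position %d in sequence '%s'",
                     chars[p], p, id))
      }
      m[match(subset, alphabet$symbols), p] <- 1 / sqrt(length(subset))
    }
  }
  structure(list(id = id, matrix = m, length = L, label = label,
                 kind = alphabet$kind),
            class = "encoded_seq")
}

#' Decode an encoded sequence back to a residue string
#'
#' Inverse of [encode_sequence()] for unambiguous sequences: each one-hot
#' column maps back to its residue. Columns that are not one-hot (ambiguity
#' codes, motif columns) decode to the residue with the largest entry.
#'
#' @param x An `encoded_seq`.
#' @param alphabet The alphabet used for encoding.
#' @return A residue string.
#' @export
decode_sequence <- function(x, alphabet) {
  paste(alphabet$symbols[apply(x$matrix, 2, which.max)], collapse = "")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq> %s: %s, length %d%s\n", x$id, x$kind, x$length,
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Map a sequence position onto the upper unit half-circle
#'
#' Position \eqn{p} of a length-\eqn{L} sequence is represented as the unit
#' vector \eqn{(\cos(p\pi/L), \sin(p\pi/L))}. The dot product of two mapped
#' positions is then \eqn{\cos(\pi(p-q)/L)}, which turns positional distance
#' into a linear operation used by the position kernel.
#'
#' @param p 1-based position (vectorised).
#' @param L Sequence length.
#' @return A matrix with `length(p)` rows and columns `cos`, `sin`; for a
#'   single position, a plain 2-vector.
#' @examples
#' map_position(50, 100)  # (0, 1)
#' @export
map_position <- function(p, L) {
  stopifnot(L >= 1)
  if (any(p < 1 | p > L)) {
    stop(sprintf("position out of range: p must lie in [1, %d]", L))
  }
  theta <- p * pi / L
  out <- cbind(cos = cos(theta), sin = sin(theta))
  if (length(p) == 1L) out[1, ] else out
}

# internal validators -------------------------------------------------------

is_circle_position <- function(v, tol = 1e-9) {
  length(v) == 2L && is.finite(sum(v)) &&
    abs(sqrt(sum(v^2)) - 1) <= tol && v[2] >= -tol
}

check_circle_position <- function(v, what = "position") {
  if (!is_circle_position(v)) {
    stop(what, " is not a unit vector on the upper half-circle")
  }
  invisible(v)
}
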
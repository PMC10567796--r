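# shared fixtures: random valid objects built in code, no files

dna <- make_alphabet("dna")

random_dna_string <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

random_encoded <- function(L, id = "x", label = NULL) {
  encode_sequence(random_dna_string(L), dna, id = id, label = label)
}

# random valid nPFM: non-negative entries, unit l2-norm columns
random_npfm <- function(d = 4, k = 5) {
  m <- matrix(stats::rexp(d * k), d, k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

random_circle_position <- function() {
  theta <- stats::runif(1, 0, pi)
  c(cos(theta), sin(theta))
}

random_pair <- function(d = 4, k = 5) {
  list(npfm = random_npfm(d, k), position = random_circle_position())
}

# anchor_set from explicit matrices (bypasses k-means)
make_anchors <- function(motifs, positions, d, k) {
  structure(list(n = nrow(motifs), motifs = motifs, positions = positions,
                 alphabet_size = as.integer(d), k = as.integer(k),
                 trainable = FALSE),
            class = "anchor_set")
}

random_anchors <- function(n, d = 4, k = 5) {
  motifs <- t(vapply(seq_len(n), function(i) as.vector(random_npfm(d, k)),
                     numeric(d * k)))
  positions <- t(vapply(seq_len(n), function(i) random_circle_position(),
                        numeric(2)))
  make_anchors(motifs, positions, d, k)
}

# n one-hot single-column anchors, all sitting at the circle apex
hand_anchors <- function(n, d = 4) {
  motifs <- diag(d)[rep_len(seq_len(d), n), , drop = FALSE]
  make_anchors(motifs, matrix(rep(c(0, 1), n), n, 2, byrow = TRUE), d, 1)
}

# minimal model-shaped list for interpretation unit tests: a kernel layer of
# L_out positions x n anchors feeding W1 (hidden x L_out*n) and W2
fake_model <- function(W1, W2, anchors, L_out, kind = "dna") {
  structure(list(W1 = W1, b1 = numeric(nrow(W1)),
                 W2 = W2, b2 = numeric(nrow(W2)),
                 anchors = anchors, L_out = L_out,
                 alphabet_size = anchors$alphabet_size, kind = kind,
                 config = list(n_classes = nrow(W2),
                               pam = pam_params(k = anchors$k))),
            class = "pam_model")
}

# tiny labelled dataset with a deterministic single-position class signal
toy_separable <- function(n_per_class = 5, L = 20) {
  seqs <- character(2 * n_per_class)
  labels <- rep(0:1, each = n_per_class)
  for (i in seq_along(seqs)) {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    chars[8:12] <- if (labels[i] == 0) c("A", "A", "C", "C", "A")
                   else c("G", "T", "G", "G", "T")
    seqs[i] <- paste(chars, collapse = "")
  }
  list(data = Map(function(s, i, l) encode_sequence(s, dna, paste0("t", i), l),
                  seqs, seq_along(seqs), labels),
       labels = labels)
}
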
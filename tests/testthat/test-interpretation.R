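# exhaustive positive-path oracle for the importance recursion: enumerate all
# positive-weight paths from a kernel-layer neuron through the hidden layers;
# a path contributes the product of its weights up to (excluding) the final
# neuron, which must be positively connected to exactly the class output
path_importance <- function(weights, class_index, neuron) {
  n_layers <- length(weights)
  out_sets <- function(layer, j) which(weights[[layer]][, j] > 0)
  recurse <- function(layer, j) {
    succ <- out_sets(layer, j)
    if (layer == n_layers) {
      # successors are output neurons
      if (length(succ) == 1L && succ == class_index + 1L) return(1)
      return(0)
    }
    total <- 0
    for (m in succ) {
      total <- total + weights[[layer]][m, j] * recurse(layer + 1L, m)
    }
    total
  }
  recurse(1L, neuron)
}

test_that("neuron importance reproduces the worked 2-2-2 network", {
  W1 <- matrix(c(0.5, 0.25, -1, 0.75), 2, 2, byrow = TRUE)
  W2 <- diag(2)
  m <- fake_model(W1, W2, hand_anchors(2), L_out = 1L)
  expect_equal(neuron_importance(m, 0), c(0.5, 0.25))
  expect_equal(neuron_importance(m, 1), c(0, 0.75))
  expect_error(neuron_importance(m, 2), "out of range")
  # both kernel neurons sit at the single window position
  expect_equal(position_importance(m, 0), 0.375)
})

test_that("importance is zero without positive paths and for shared outputs", {
  W1 <- matrix(-abs(rnorm(8)), 2, 4)
  W2 <- diag(2)
  m <- fake_model(W1, W2, hand_anchors(4), L_out = 2L)
  expect_equal(neuron_importance(m, 0), rep(0, 4))

  # a hidden neuron positively connected to both outputs contributes nothing
  W1b <- matrix(c(1, 1), 1, 2)
  W2b <- matrix(c(1, 1), 2, 1)   # hidden neuron feeds both classes
  mb <- fake_model(W1b, W2b, hand_anchors(2), L_out = 1L)
  expect_equal(neuron_importance(mb, 0), c(0, 0))
  expect_equal(neuron_importance(mb, 1), c(0, 0))
})

test_that("importance recursion equals exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:50) {
    d0 <- sample(2:12, 1); d1 <- sample(2:12, 1)
    W1 <- matrix(rnorm(d1 * d0), d1, d0)
    W2 <- matrix(rnorm(2 * d1), 2, d1)
    m <- fake_model(W1, W2, hand_anchors(d0), L_out = 1L)
    cl <- sample(0:1, 1)
    got <- neuron_importance(m, cl)
    ref <- vapply(seq_len(d0), function(j)
      path_importance(list(W1, W2), cl, j), numeric(1))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("symmetric weights give symmetric position importances", {
  # two positions, one anchor each, identical weight patterns
  W1 <- matrix(c(0.4, 0.4), 1, 2)
  W2 <- matrix(c(1, -1), 2, 1)
  m <- fake_model(W1, W2, hand_anchors(1), L_out = 2L)
  imp <- position_importance(m, 0)
  expect_equal(imp[1], imp[2])
  expect_true(all(position_importance(m) >= 0))
})

test_that("peak heights subtract the truncated sliding-window mean", {
  expect_equal(detect_peaks(rep(3, 50))$height, rep(0, 10))
  iota <- rep(0, 100); iota[50] <- 1
  pk <- detect_peaks(iota, window = 11, top = 1)
  expect_equal(pk$position, 50)
  expect_equal(pk$height, 1 - 1 / 11)
  iota2 <- rep(0, 100); iota2[1] <- 1
  pk2 <- detect_peaks(iota2, window = 11, top = 1)
  expect_equal(pk2$position, 1)
  expect_equal(pk2$height, 1 - 1 / 6)  # boundary truncates to positions 1..6
  expect_error(detect_peaks(iota, window = 10), "odd")
  # ties break towards the lower position index
  tie <- detect_peaks(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1), window = 3,
                      top = 2)
  expect_equal(tie$position[1], min(tie$position))
})

test_that("class mean motifs average anchors by positive importance", {
  # anchors: one-hot A motif and one-hot C motif at a single position
  A <- as.vector(diag(4)[, 1, drop = FALSE]); C <- as.vector(diag(4)[, 2])
  anchors <- make_anchors(rbind(A, C), matrix(c(0, 1, 0, 1), 2, 2,
                                              byrow = TRUE), 4, 1)
  # hidden layer: one neuron per class; anchor weights chosen per case
  W2 <- diag(2)
  m_eq <- fake_model(matrix(c(0.3, 0.3, -1, -1), 2, 2, byrow = TRUE), W2,
                     anchors, L_out = 1L)
  cm <- class_mean_motif(m_eq, 1, 0)
  expect_equal(unname(cm$npfm[, 1]), c(1, 1, 0, 0) / sqrt(2))
  expect_setequal(motif_top_residues(cm$npfm, 2)[, 1], c("A", "C"))
  expect_equal(sum(cm$contributing_weights), 1)

  m_75 <- fake_model(matrix(c(0.75, 0.25, -1, -1), 2, 2, byrow = TRUE), W2,
                     anchors, L_out = 1L)
  cm75 <- class_mean_motif(m_75, 1, 0)
  expect_equal(motif_top_residues(cm75$npfm, 1)[1, 1], "A")
  expect_equal(unname(cm75$contributing_weights), c(0.75, 0.25))

  # single positive anchor: its nPFM is returned unchanged
  m_one <- fake_model(matrix(c(0.4, -0.2, -1, -1), 2, 2, byrow = TRUE), W2,
                      anchors, L_out = 1L)
  cm1 <- class_mean_motif(m_one, 1, 0)
  expect_equal(unname(cm1$npfm[, 1]), A)

  # no positive weights at all: flagged, not an error
  m_none <- fake_model(matrix(c(-1, -1, -1, -1), 2, 2, byrow = TRUE), W2,
                       anchors, L_out = 1L)
  expect_message(res <- class_mean_motif(m_none, 1, 0), "no class")
  expect_null(res)
  expect_error(class_mean_motif(m_eq, 5, 0), "out of range")
})

test_that("motif function norms behave like smoothed occurrence profiles", {
  params <- pam_params(k = 3, alpha = 2, beta = 40, sigma = 2)
  x <- encode_sequence("AAACGTAAA", dna)
  hit <- encode_sequence("CGT", dna)$matrix
  miss <- encode_sequence("TTT", dna)$matrix  # orthogonal to every window?
  expect_gt(motif_function_norm(hit, x, params),
            motif_function_norm(miss, x, params))

  # single-window sequence: closed scalar form
  y <- encode_sequence("CGT", dna)
  nrm <- motif_function_norm(hit, y, params)
  f <- vapply(1:3, function(t)
    k_npfm(hit, y$matrix, params) *
      k_position(map_position(t, 3), map_position(1, 3), params), numeric(1))
  expect_equal(nrm, sqrt(sum(f^2)), tolerance = 1e-12)
  expect_gt(nrm, 0)

  # joint relabeling of alphabet rows leaves the norm unchanged
  perm <- c(3, 1, 4, 2)
  xp <- x; xp$matrix <- x$matrix[perm, ]
  expect_equal(motif_function_norm(hit[perm, ], xp, params),
               motif_function_norm(hit, x, params), tolerance = 1e-12)

  # continuity in sigma: finite differences stay bounded
  sigmas <- seq(1, 6, by = 0.25)
  vals <- vapply(sigmas, function(sg)
    motif_function_norm(hit, x, pam_params(k = 3, alpha = 2, beta = 40,
                                           sigma = sg)), numeric(1))
  expect_true(all(is.finite(diff(vals) / 0.25)))
  expect_lt(max(abs(diff(vals) / 0.25)), 50)
})

test_that("explain_input assigns classes by motif-function dominance", {
  params <- pam_params(k = 1, alpha = 4, beta = 40, sigma = 2)
  A <- as.vector(diag(4)[, 1]); C <- as.vector(diag(4)[, 2])
  anchors <- make_anchors(rbind(A, C), matrix(c(0, 1, 0, 1), 2, 2,
                                              byrow = TRUE), 4, 1)
  # class 0 wired to the A anchor, class 1 to the C anchor, at all 4 positions
  W1 <- rbind(rep(c(1, -1), 4), rep(c(-1, 1), 4))
  m <- fake_model(W1, diag(2), anchors, L_out = 4L)
  m$config$pam <- params
  m$L <- 4L
  x <- encode_sequence("AAAA", dna, id = "allA")
  ex <- explain_input(m, x, positions = c(1, 3), params = params)
  expect_equal(ex$assigned_class, c(0L, 0L))
  expect_equal(ex$residue, c("A", "A"))
  expect_equal(ex$norm_class0, c(1, 1))
  expect_true(all(ex$norm_class1 < 1))
  expect_equal(attr(ex, "sequence_id"), "allA")

  # identical class motifs: tie flagged, lower class index wins
  W1t <- rbind(rep(c(1, -1), 4), rep(c(1, -1), 4))
  mt <- fake_model(W1t, diag(2), anchors, L_out = 4L)
  mt$config$pam <- params
  ext <- explain_input(mt, x, positions = 2, params = params)
  expect_equal(ext$assigned_class, 0L)
  expect_true(ext$tie)
})
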
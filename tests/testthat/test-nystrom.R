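params5 <- pam_params(k = 5, alpha = 1, beta = 100, sigma = 4)

test_that("sample_pairs is seeded-deterministic and returns real windows", {
  set.seed(1)
  data <- lapply(1:2, function(i) random_encoded(20, id = paste0("s", i)))
  a <- sample_pairs(data, 10, k = 5, seed = 99)
  b <- sample_pairs(data, 10, k = 5, seed = 99)
  expect_identical(a, b)
  for (i in 1:10) {
    s <- data[[a$seq_idx[i]]]; p <- a$win_idx[i]
    expect_equal(a$motifs[i, ], as.vector(s$matrix[, p:(p + 4)]))
    expect_equal(a$positions[i, ], unname(map_position(p, s$length)))
  }
  expect_error(sample_pairs(list(), 5, k = 5), "empty")
})

test_that("sampled window starts are uniform over valid windows", {
  set.seed(2)
  data <- lapply(1:4, function(i) random_encoded(20, id = paste0("s", i)))
  m <- 40000
  prs <- sample_pairs(data, m, k = 3, seed = 5)
  # 4 sequences x 18 windows, each cell expected m/72 with binomial 3-sigma
  counts <- table(factor(prs$win_idx, levels = 1:18))
  p0 <- 1 / 18
  bound <- 3 * sqrt(m * p0 * (1 - p0))
  expect_true(all(abs(counts - m * p0) <= bound))
})

test_that("constraint_project clamps, rescales, backfills and is idempotent", {
  motifs <- rbind(c(3, 0, 0, 0), c(-1, -2, -3, -4))
  anchors <- make_anchors(motifs, rbind(c(2, 2), c(1, -1)), d = 4, k = 1)
  proj <- constraint_project(anchors)
  expect_equal(proj$motifs[1, ], c(1, 0, 0, 0))
  expect_equal(proj$motifs[2, ], rep(0.5, 4))
  expect_equal(proj$positions[1, ], c(1, 1) / sqrt(2))
  expect_equal(proj$positions[2, ], c(1, 0))  # negative sin clamped first
  again <- constraint_project(proj)
  expect_equal(again$motifs, proj$motifs, tolerance = 1e-12)
  expect_equal(again$positions, proj$positions, tolerance = 1e-12)

  set.seed(3)
  valid <- random_anchors(5)
  reproj <- constraint_project(valid)
  expect_equal(reproj$motifs, valid$motifs, tolerance = 1e-12)
  expect_equal(reproj$positions, valid$positions, tolerance = 1e-12)
})

test_that("init_anchors recovers duplicated points and separated clusters", {
  set.seed(4)
  base <- random_anchors(3)
  reps <- rep(1:3, each = 40)
  pairs <- list(motifs = base$motifs[reps, ], positions = base$positions[reps, ])
  fit <- init_anchors(pairs, 3, alphabet_size = 4, k = 5, seed = 11)
  # recovered centres are the three points, in some order
  dmat <- as.matrix(stats::dist(rbind(fit$motifs, base$motifs)))[1:3, 4:6]
  expect_equal(unname(sort(apply(dmat, 1, min))), rep(0, 3), tolerance = 1e-9)
  expect_error(init_anchors(pairs, 200, 4, 5), "cannot place")

  # jittered clusters around three separated nPFM/position centres
  jit <- list(
    motifs = base$motifs[reps, ] + matrix(stats::rnorm(120 * 20, 0, 0.01), 120),
    positions = base$positions[reps, ] +
      matrix(stats::rnorm(240, 0, 0.01), 120))
  fit2 <- init_anchors(jit, 3, alphabet_size = 4, k = 5, seed = 12)
  for (i in 1:3) {
    errs <- sqrt(rowSums(sweep(cbind(fit2$motifs, fit2$positions), 2,
                               cbind(base$motifs, base$positions)[i, ])^2))
    expect_lt(min(errs), 0.1)
  }
  # projected outputs satisfy the anchor invariants
  for (i in 1:3) expect_true(is_npfm(anchor_npfm(fit2, i)))
  expect_true(all(abs(rowSums(fit2$positions^2) - 1) < 1e-9))
  expect_true(all(fit2$positions[, 2] >= 0))
})

test_that("gram_inverse_sqrt inverts full-rank Grams and survives rank loss", {
  one <- make_anchors(t(as.vector(random_npfm())), t(c(0, 1)), 4, 5)
  st1 <- gram_inverse_sqrt(one, params5)
  expect_equal(st1$K_ZZ, matrix(1, 1, 1))
  expect_equal(st1$K_ZZ_inv_sqrt, matrix(1, 1, 1), tolerance = 1e-9)

  set.seed(5)
  anchors <- random_anchors(12)
  st <- gram_inverse_sqrt(anchors, params5, epsilon = 1e-6)
  expect_equal(diag(st$K_ZZ), rep(1, 12), tolerance = 1e-12)
  err <- st$K_ZZ_inv_sqrt %*% st$K_ZZ %*% st$K_ZZ_inv_sqrt - diag(12)
  expect_lt(max(abs(err)), 1e-5)

  dup <- make_anchors(anchors$motifs[c(1, 1, 2), ],
                      anchors$positions[c(1, 1, 2), ], 4, 5)
  stdup <- gram_inverse_sqrt(dup, params5)
  expect_true(all(is.finite(stdup$K_ZZ_inv_sqrt)))
})

test_that("project_window matches its closed forms and a dense oracle", {
  set.seed(6)
  one <- make_anchors(t(as.vector(random_npfm())), t(random_circle_position()),
                      4, 5)
  st1 <- gram_inverse_sqrt(one, params5)
  w <- random_pair()
  expect_equal(project_window(w, st1, one, params5),
               k0(list(npfm = anchor_npfm(one, 1),
                       position = one$positions[1, ]), w, params5),
               tolerance = 1e-12)

  anchors <- random_anchors(5)
  st <- gram_inverse_sqrt(anchors, params5)
  for (i in 1:10) {
    w <- random_pair()
    kz <- vapply(1:5, function(j)
      k0(list(npfm = anchor_npfm(anchors, j),
              position = anchors$positions[j, ]), w, params5), numeric(1))
    expect_equal(project_window(w, st, anchors, params5),
                 drop(st$K_ZZ_inv_sqrt %*% kz), tolerance = 1e-9)
  }
})

test_that("Nystroem projection reproduces the anchor Gram at full rank", {
  set.seed(7)
  anchors <- random_anchors(20)
  st <- gram_inverse_sqrt(anchors, params5, epsilon = 1e-6)
  Psi <- t(vapply(1:20, function(i)
    project_window(list(npfm = anchor_npfm(anchors, i),
                        position = anchors$positions[i, ]),
                   st, anchors, params5), numeric(20)))
  expect_lt(max(abs(Psi %*% t(Psi) - st$K_ZZ)), 1e-6)
})

test_that("forward_sequence equals the per-window reference path", {
  set.seed(8)
  anchors <- random_anchors(10)
  st <- gram_inverse_sqrt(anchors, params5)
  x <- random_encoded(30)
  Fmap <- forward_sequence(x, st, anchors, params5)
  expect_equal(dim(Fmap), c(26L, 10L))
  expect_true(all(is.finite(Fmap)))
  for (p in c(1, 7, 26)) {
    w <- list(npfm = x$matrix[, p:(p + 4)], position = map_position(p, 30))
    expect_equal(Fmap[p, ], drop(project_window(w, st, anchors, params5)),
                 tolerance = 1e-9)
  }
  y <- random_encoded(41)
  expect_equal(dim(forward_sequence(y, st, anchors, params5)), c(37L, 10L))
  expect_error(forward_sequence(random_encoded(4), st, anchors, params5),
               "shorter")
})

test_that("stale states are rejected after anchors change", {
  set.seed(9)
  anchors <- random_anchors(4)
  st <- gram_inverse_sqrt(anchors, params5)
  moved <- anchors
  moved$motifs[1, 1] <- moved$motifs[1, 1] + 0.05
  moved <- constraint_project(moved)
  expect_error(project_window(random_pair(), st, moved, params5), "stale")
  expect_error(forward_sequence(random_encoded(12), st, moved, params5),
               "stale")
})

test_that("pre-projection kernel responses lie in (0, 1]", {
  set.seed(10)
  anchors <- random_anchors(6)
  x <- random_encoded(20)
  W <- pamnet:::sequence_windows(x, 5)
  P <- map_position(1:16, 20)
  K0 <- exp(1 * (W %*% t(anchors$motifs) - 5) +
            100 / 32 * (P %*% t(anchors$positions) - 1))
  expect_true(all(K0 > 0 & K0 <= 1 + 1e-12))
})
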
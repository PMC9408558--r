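# Kabsch superposition, TM-score, structural alignment, matched RMSD.

test_that("kabsch recovers exact superpositions and rigid transforms", {
  P <- fixture_xyz(4, seed = 3)
  expect_equal(kabsch(P, P)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch(P, P)$rotation, diag(3), tolerance = 1e-9)
  Q <- P %*% t(rot_z(pi / 2)) + matrix(c(5, 0, 0), 4, 3, byrow = TRUE)
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, rot_z(pi / 2), tolerance = 1e-9)
  expect_equal(fit$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "3 paired points")
})

test_that("kabsch rmsd matches a brute-force rotation-grid minimizer", {
  # unit square with one corner lifted 1 A out of plane
  P <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  Q <- P
  Q[3, 3] <- 1
  expect_equal(kabsch(P, Q)$rmsd, brute_force_rmsd(P, Q), tolerance = 1e-3)
})

test_that("kabsch rmsd is invariant under rigid motion of either input", {
  P <- fixture_xyz(15, seed = 5)
  Q <- P + matrix(rnorm(45, 0, 0.5), 15, 3)
  base <- kabsch(P, Q)$rmsd
  for (i in 1:5) {
    set.seed(i)
    th <- runif(3, 0, 2 * pi)
    R <- rot_z(th[1]) %*%
      matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
               sin(th[2]), 0, cos(th[2])), 3, 3) %*% rot_z(th[3])
    t1 <- runif(3, -50, 50)
    expect_equal(kabsch(P %*% t(R) + matrix(t1, 15, 3, byrow = TRUE),
                        Q)$rmsd, base, tolerance = 1e-9)
    expect_equal(kabsch(P, Q %*% t(R) +
                          matrix(t1, 15, 3, byrow = TRUE))$rmsd, base,
                 tolerance = 1e-9)
  }
})

test_that("collinear point sets are flagged degenerate", {
  P <- cbind(1:5, 0, 0)
  expect_warning(fit <- kabsch(P, P), "degenerate")
  expect_true(fit$degenerate)
})

test_that("tm_score follows its closed form", {
  expect_equal(tm_score(rep(0, 37), 37), 1.0)
  # a single pair at d = d0 with L_target = 1 scores exactly one half
  expect_equal(tm_score(tm_d0(1), 1), 0.5)
  # closed-form d0: 1.24 (L-15)^(1/3) - 1.8, floored at 0.5 A
  expect_equal(tm_d0(40), 1.24 * 25^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(20), max(0.5, 1.24 * 5^(1 / 3) - 1.8),
               tolerance = 1e-12)
  d <- c(0, 1, 2.5, 4, 8)
  d0 <- tm_d0(40)
  expect_equal(tm_score(d, 40), sum(1 / (1 + (d / d0)^2)) / 40,
               tolerance = 1e-12)
  # short-chain clamp
  expect_equal(tm_d0(5), 0.5)
})

test_that("tm_score decreases monotonically as any distance grows", {
  set.seed(11)
  d <- runif(30, 0, 12)
  base <- tm_score(d, 30)
  for (i in c(1, 15, 30)) {
    d2 <- d
    d2[i] <- d2[i] + 2
    expect_lt(tm_score(d2, 30), base)
  }
})

test_that("self-alignment returns TM = 1 with the identity pairing", {
  for (seed in 1:3) {
    xyz <- mock_tmd_fold(mock_class_names()[seed])
    cs <- coordset(data.frame(chain = "A", resno = seq_len(nrow(xyz))), xyz)
    aln <- structural_align(cs, cs)
    expect_equal(aln$tm_score, 1, tolerance = 1e-6)
    expect_equal(aln$paired[, 1], aln$paired[, 2])
    expect_equal(nrow(aln$paired), nrow(xyz))
  }
})

test_that("noisy copies realign with high TM and correct pairing", {
  nbd <- mock_nbd_fold()$ca
  set.seed(21)
  noisy <- nbd$xyz + matrix(rnorm(length(nbd$xyz), 0, 0.3),
                            nrow(nbd$xyz), 3)
  noisy <- noisy %*% t(rot_z(1.1)) +
    matrix(c(12, -7, 30), nrow(noisy), 3, byrow = TRUE)
  aln <- structural_align(coordset(nbd$labels, noisy), nbd)
  expect_gt(aln$tm_score, 0.9)
  correct <- sum(aln$paired[, 1] == aln$paired[, 2])
  expect_gte(correct / nrow(nbd$xyz), 0.95)
})

test_that("a truncated noisy copy scores at least its planted pairing", {
  # the aligner maximises TM, so it can never fall below the TM of the
  # known planted correspondence
  nbd <- mock_nbd_fold()$ca
  set.seed(41)
  n_keep <- nrow(nbd$xyz) - 25L
  B <- nbd$xyz[1:n_keep, ] + matrix(rnorm(n_keep * 3, 0, 0.5), n_keep, 3)
  B <- B %*% t(rot_z(0.8)) + matrix(c(15, 5, -10), n_keep, 3, byrow = TRUE)
  planted_fit <- kabsch(B, nbd$xyz[1:n_keep, ])
  planted_tm <- tm_score(sqrt(rowSums((
    B %*% t(planted_fit$rotation) +
      matrix(planted_fit$translation, n_keep, 3, byrow = TRUE) -
      nbd$xyz[1:n_keep, ])^2)), nrow(nbd$xyz))
  aln <- structural_align(coordset(nbd$labels[1:n_keep, ], B), nbd)
  expect_gte(aln$tm_score, planted_tm - 1e-6)
  expect_gt(aln$tm_score, 0.6)
})

test_that("an ideal helix does not reach the fold-similarity threshold", {
  helix <- make_ideal_helix(100)
  nbd <- mock_nbd_fold()$ca
  aln <- structural_align(helix, nbd)
  expect_lt(aln$tm_score, 0.4)
})

test_that("matched_rmsd equals kabsch exactly and rejects outliers", {
  set.seed(31)
  P <- fixture_xyz(50, seed = 31)
  noise <- matrix(rnorm(150, 0, 0.2), 50, 3)
  Q <- P + noise
  csP <- coordset(data.frame(chain = "A", resno = 1:50), P)
  csQ <- coordset(data.frame(chain = "A", resno = 1:50), Q)
  # identical structures
  same <- matched_rmsd(csP, csP)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$n_retained, 50L)
  # rejection off: exactly the kabsch value
  plain <- matched_rmsd(csP, csQ, outlier_rejection = FALSE)
  expect_equal(plain$rmsd, kabsch(P, Q)$rmsd, tolerance = 1e-12)
  # one of 50 pairs displaced 20 A: dropped, rmsd back near noise level
  Q2 <- Q
  Q2[25, ] <- Q2[25, ] + c(20, 0, 0)
  csQ2 <- coordset(data.frame(chain = "A", resno = 1:50), Q2)
  rej <- matched_rmsd(csP, csQ2, outlier_rejection = TRUE)
  expect_equal(rej$n_retained, 49L)
  expect_false(25L %in% rej$pairing[, 1])
  expect_equal(rej$rmsd,
               kabsch(P[-25, ], Q2[-25, ])$rmsd, tolerance = 1e-9)
  expect_lt(rej$rmsd, 0.5)
})

test_that("label pairing drives matched_rmsd when no pairing is given", {
  nbd <- mock_nbd_fold()$ca
  sub <- coordset(nbd$labels[11:60, ], nbd$xyz[11:60, ])
  r <- matched_rmsd(sub, nbd)
  expect_equal(r$n_retained, 50L)
  expect_equal(r$rmsd, 0, tolerance = 1e-12)
})
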
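test_that("reads single-residue and multi-model PDB files", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_s3_class(s, "structure_model")
  expect_equal(nrow(s$atoms), 5)
  expect_setequal(s$atoms$atom, c("N", "CA", "C", "O", "H"))

  pm <- write_multimodel_pdb(tempfile(fileext = ".pdb"))
  e <- read_structure(pm)
  expect_s3_class(e, "conformer_ensemble")
  expect_length(e, 3)
  m2 <- read_structure(pm, model_index = 2)
  expect_s3_class(m2, "structure_model")
  expect_equal(m2$atoms$x[m2$atoms$atom == "N"], 2) # model 2 shifted by +2

  expect_error(read_structure(tempfile()), "not found")
  expect_error(read_structure(pm, model_index = 9), "out of range")
})

test_that("altloc resolution keeps highest occupancy, tie goes to A", {
  p <- write_altloc_pdb(tempfile(fileext = ".pdb"))
  expect_message(s <- read_structure(p), "altloc")
  expect_equal(nrow(s$atoms), 3)
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_equal(as.numeric(ca[, c("x", "y", "z")]), c(2, 2, 2)) # occ 0.70 B
  n <- s$atoms[s$atoms$atom == "N", ]
  expect_equal(as.numeric(n[, c("x", "y", "z")]), c(0, 0, 0)) # tie -> A
})

test_that("NH vectors are unit norm, prolines skipped, built H matches", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  v <- extract_nh_vectors(s)
  expect_equal(nrow(v), 1)
  expect_equal(c(v$x, v$y, v$z), c(0, 0, 1)) # H at (0,0,1.02) above N

  # proline never contributes an amide vector
  helix <- build_backbone(rep(-57, 8), rep(-47, 8),
                          resnames = c(rep("ALA", 4), "PRO", rep("ALA", 3)))
  vh <- extract_nh_vectors(helix)
  expect_false(5 %in% vh$resno)
  expect_equal(nrow(vh), 6) # residues 2:8 minus the proline
  expect_true(all(abs(sqrt(vh$x^2 + vh$y^2 + vh$z^2) - 1) < 1e-9))

  # rebuilding H from ideal geometry reproduces the explicit H direction
  noh <- helix
  noh$atoms <- noh$atoms[noh$atoms$atom != "H", ]
  vb <- extract_nh_vectors(noh, build_missing_h = TRUE)
  shared <- intersect(vh$resno, vb$resno)
  dots <- vapply(shared, function(r) {
    sum(vh[vh$resno == r, c("x", "y", "z")] *
          vb[vb$resno == r, c("x", "y", "z")])
  }, numeric(1))
  expect_true(all(acos(pmin(dots, 1)) * 180 / pi < 5))

  # missing H without the builder: skipped with warnings, not an error
  w <- capture_warnings(vs <- extract_nh_vectors(noh))
  expect_true(all(grepl("no amide H", w)))
  expect_equal(nrow(vs), 0)
})

test_that("superposition recovers exact rigid motions", {
  s <- build_backbone(rep(-57, 10), rep(-47, 10))
  fit <- superpose(s, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3) # 90 deg about z
  moved <- transform_model(s, rot90, c(3, -2, 7))
  fit <- superpose(moved, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation %*% rot90, diag(3), tolerance = 1e-9)

  expect_error(superpose(s, s, selection = "CB"), "paired atoms")
})

test_that("superposed rmsd under noise matches the Monte-Carlo expectation", {
  set.seed(101)
  sigma <- 0.1
  rmsds <- replicate(60, {
    cloud <- matrix(rnorm(30, sd = 5), ncol = 3)
    moved <- cloud %*% t(random_rotation()) +
      matrix(rnorm(30, sd = sigma), ncol = 3)
    kabsch(moved, cloud)$rmsd
  })
  expect_lt(abs(mean(rmsds) - sqrt(3) * sigma), 0.2 * sqrt(3) * sigma)
})

test_that("superposed rmsd is symmetric and rigid-motion invariant", {
  set.seed(7)
  a <- make_toy_ensemble(n_residues = 12, n_members = 2, loop = 5:8,
                         loop_disp = 3, jitter_sigma = 0.2, seed = 5)
  m1 <- a$members[[1]]; m2 <- a$members[[2]]
  r12 <- superpose(m1, m2)$rmsd
  r21 <- superpose(m2, m1)$rmsd
  expect_equal(r12, r21, tolerance = 1e-9)
  for (i in 1:3) {
    g1 <- transform_model(m1, random_rotation(), rnorm(3, sd = 10))
    g2 <- transform_model(m2, random_rotation(), rnorm(3, sd = 10))
    expect_equal(superpose(g1, g2)$rmsd, r12, tolerance = 1e-7)
  }
})

test_that("pairwise rmsd matrix matches one-by-one superposition", {
  e <- make_toy_ensemble(n_residues = 12, n_members = 4, loop = 5:8,
                         loop_disp = 4, jitter_sigma = 0.1, seed = 2)
  M <- pairwise_rmsd_matrix(e)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(M[i, j],
                 superpose(e$members[[i]], e$members[[j]], "CA")$rmsd,
                 tolerance = 1e-9)
  }

  dup <- conformer_ensemble(list(e$members[[1]], e$members[[1]]))
  expect_equal(pairwise_rmsd_matrix(dup), matrix(0, 2, 2), tolerance = 1e-9)
})

test_that("K-medoids clustering separates planted groups", {
  pool <- make_conformer_pool(n_planted = 2, decoys_per = 3, loop_disp = 8,
                              decoy_jitter = 0.2, seed = 9)
  D <- pairwise_rmsd_matrix(pool$pool)
  cl <- cluster_frames(D, 2)
  truth <- rep(1:2, each = 4)
  expect_equal(length(unique(cl$assignments)), 2)
  # partition matches ground truth up to label permutation
  tab <- table(cl$assignments, truth)
  expect_equal(sum(apply(tab, 1, max)), 8)

  n <- nrow(D)
  expect_equal(cluster_frames(D, n)$medoids, seq_len(n))
  zero <- matrix(0, 4, 4)
  expect_equal(cluster_frames(zero, 2)$objective, 0)
  expect_error(cluster_frames(D, 0), "positive")
  expect_error(cluster_frames(D, n + 1), "exceeds")
})

test_that("clustering objective is non-increasing in K", {
  pool <- make_conformer_pool(n_planted = 3, decoys_per = 3, seed = 4)
  D <- pairwise_rmsd_matrix(pool$pool)
  obj <- vapply(1:6, function(k) cluster_frames(D, k)$objective, numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
})

test_that("representative member is the one closest to the ensemble mean", {
  single <- conformer_ensemble(list(build_backbone(rep(-57, 8), rep(-47, 8))))
  expect_equal(representative_member(single), 1L)

  # member 2 constructed as the exact coordinate mean of members 1 and 3
  e <- make_toy_ensemble(n_residues = 12, n_members = 2, loop = 5:8,
                         loop_disp = 4, seed = 6)
  m1 <- e$members[[1]]; m3 <- e$members[[2]]
  m2 <- m1
  for (col in c("x", "y", "z")) {
    m2$atoms[[col]] <- (m1$atoms[[col]] + m3$atoms[[col]]) / 2
  }
  expect_equal(representative_member(conformer_ensemble(list(m1, m2, m3))), 2L)

  # duplicated pair + outlier: first duplicate wins the tie
  out <- conformer_ensemble(list(m1, m1, m3))
  expect_equal(representative_member(out), 1L)
})
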
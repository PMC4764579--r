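test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(13)
  ref <- matrix(rnorm(12, sd = 4), ncol = 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  # 90 degrees about z plus a translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mob <- ref %*% t(Rz) + matrix(rep(c(3, -2, 7), each = 4), ncol = 3)
  fit <- kabsch_superpose(mob, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(ref[1:3, ], ref), "mismatch")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line * 2), "degenerate")
})

test_that("Kabsch RMSD matches an independent numerical minimisation", {
  # fixed 4-point sets; oracle = quaternion-parameterised optimisation
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2),
              ncol = 3, byrow = TRUE)
  B <- matrix(c(0.1, -0.2, 0, 1.2, 0.1, 0.1, -0.1, 1.1, -0.2,
                0.4, 0.5, 1.0), ncol = 3, byrow = TRUE)
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2)); w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- quat_rot(q)
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
  }
  best <- Inf
  set.seed(2)
  for (k in 1:40) {
    r <- optim(rnorm(4), obj, method = "BFGS")
    best <- min(best, r$value)
  }
  expect_equal(kabsch_superpose(A, B)$rmsd, best, tolerance = 1e-5)
  # cross-check against an established superposition implementation
  if (requireNamespace("bio3d", quietly = TRUE)) {
    xyz_a <- as.vector(t(A)); xyz_b <- as.vector(t(B))
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_b,
                                              mobile = xyz_a))
    rmsd_bio3d <- sqrt(mean(colSums(matrix((fitted - xyz_b)^2, nrow = 3))))
    expect_equal(kabsch_superpose(A, B)$rmsd, rmsd_bio3d,
                 tolerance = 1e-5)
  }
})

test_that("ensemble RMSD to the iterated mean behaves as constructed", {
  tc <- std_toy()
  base <- get_model(tc$structure, 1)
  same <- perturb_ensemble(base, 4, 0, seed = 1)
  expect_equal(rmsd_to_mean(same, list(elety = "CA")), 0,
               tolerance = 1e-9)
  # symmetric 3-atom case: triangles of radius 5 +/- 0.5 about the
  # origin; the converged mean is the radius-5 triangle and every atom
  # deviates exactly 0.5
  ang <- c(90, 210, 330) * pi / 180
  tri <- function(r, model) do.call(rbind, lapply(1:3, function(i)
    atom_at(r * cos(ang[i]), r * sin(ang[i]), 0, serial = as.integer(i),
            resno = i, model_id = model)))
  s <- structure3d(rbind(tri(5.5, 1L), tri(4.5, 2L)))
  expect_equal(rmsd_to_mean(s), 0.5, tolerance = 1e-6)
  # rigid motion of the whole ensemble leaves the statistic unchanged
  ens <- perturb_ensemble(base, 6, 0.4, seed = 9)
  moved <- rigid_move(ens)
  expect_equal(rmsd_to_mean(moved, list(elety = c("N", "CA", "C"))),
               rmsd_to_mean(ens, list(elety = c("N", "CA", "C"))),
               tolerance = 1e-6)
  expect_error(rmsd_to_mean(base), ">= 2 models")
})

test_that("Daura clustering follows the greedy neighbour-count trace", {
  # hand-traced fixture: 1-D 'positions' 0, .5, .9, 3.0, 3.4 under
  # cutoff 1.0 give neighbour counts (2,2,2,1,1); lowest-index tie-break
  # picks model 1 -> cluster {1,2,3}; then model 4 -> cluster {4,5}
  p <- c(0, 0.5, 0.9, 3.0, 3.4)
  d <- abs(outer(p, p, "-"))
  res <- toxinterface:::.daura_from_matrix(d, 1.0)
  expect_equal(res$membership, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(res$centers, c(1L, 4L))
  # every member within cutoff of its center
  for (cl in seq_along(res$centers))
    expect_true(all(d[res$centers[cl],
                      res$membership == cl] <= 1.0))
  # all-identical ensemble -> one cluster centred on model 1
  tc <- std_toy()
  same <- perturb_ensemble(get_model(tc$structure, 1), 5, 0, seed = 1)
  cl1 <- daura_cluster(same, list(elety = "CA"), cutoff = 1)
  expect_equal(length(cl1$centers), 1L)
  expect_equal(cl1$representative, 1L)
  # cutoff below the minimum pairwise RMSD -> singleton clusters
  ens <- perturb_ensemble(get_model(tc$structure, 1), 5, 0.5, seed = 2)
  cl2 <- daura_cluster(ens, list(elety = "CA"), cutoff = 1e-6)
  expect_equal(length(cl2$centers), 5L)
})

test_that("Daura partitions are stable under model relabelling", {
  # two tight groups of models; shuffling the model order must give the
  # same partition after relabelling
  tc <- std_toy()
  base <- get_model(tc$structure, 1)
  g1 <- perturb_ensemble(base, 3, 0.05, seed = 3)
  far <- base; far$atoms$x <- far$atoms$x + 3
  g2 <- perturb_ensemble(far, 3, 0.05, seed = 4)
  a2 <- g2$atoms; a2$model_id <- a2$model_id + 3L
  ens <- structure3d(rbind(g1$atoms, a2))
  cl <- daura_cluster(ens, list(elety = "CA"), cutoff = 1)
  perm <- c(4L, 1L, 5L, 2L, 6L, 3L)   # interleave the groups
  a_shuf <- ens$atoms
  a_shuf$model_id <- match(a_shuf$model_id, perm)
  cl_shuf <- daura_cluster(structure3d(a_shuf), list(elety = "CA"),
                           cutoff = 1)
  # same partition up to cluster labels
  expect_equal(length(cl$centers), length(cl_shuf$centers))
  part1 <- unname(split(seq_len(6), cl$membership))
  part2 <- unname(split(perm[seq_len(6)], cl_shuf$membership))
  expect_setequal(lapply(part1, sort), lapply(part2, sort))
})

test_that("SASA matches analytic sphere and cap closed forms", {
  lone <- structure3d(atom_at(0, 0, 0))
  r1 <- sasa(lone)
  expect_equal(r1$atom$area, 4 * pi * 3.1^2, tolerance = 0.01)
  # quadrature convergence: doubling points changes the area < 0.5 %
  r2 <- sasa(lone, n_points = 1920L)
  expect_lt(abs(r2$atom$area - r1$atom$area) / r1$atom$area, 0.005)
  # two carbons 1 A apart: exposed area is the spherical-cap closed form
  two <- structure3d(rbind(atom_at(0, 0, 0),
                           atom_at(1, 0, 0, serial = 2L, resno = 2L)))
  rt <- sasa(two)
  R <- 1.7 + 1.4; h <- R - 0.5
  cap_exposed <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(rt$atom$area, rep(cap_exposed, 2), tolerance = 0.02)
  # an atom fully enclosed by a tight shell scores 0
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  shell <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(i) {
    u <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    atom_at(2 * u[1], 2 * u[2], 2 * u[3], serial = i + 1L, resno = 2L)
  }))
  enc <- structure3d(rbind(atom_at(0, 0, 0), shell))
  expect_equal(sasa(enc)$atom$area[1], 0)
  # hydrogens are ignored; unknown radii are an error
  with_h <- structure3d(rbind(atom_at(0, 0, 0),
                              atom_at(0.5, 0, 0, element = "H",
                                      serial = 2L, name = "H")))
  expect_equal(sasa(with_h)$atom$area, r1$atom$area, tolerance = 1e-9)
  # rigid-motion invariance (up to the fixed-lattice quadrature error)
  tc <- std_toy()
  frame <- get_model(tc$structure, 1)
  moved <- rigid_move(frame)
  expect_equal(sasa(moved)$atom$area, sasa(frame)$atom$area,
               tolerance = 0.02)
})

test_that("buried interface area is symmetric and vanishes when apart", {
  tc <- std_toy()
  frame <- get_model(tc$structure, 1)
  ab <- buried_interface_area(frame, list(chain = "A"), list(chain = "B"))
  ba <- buried_interface_area(frame, list(chain = "B"), list(chain = "A"))
  expect_equal(ab, ba)
  expect_gt(ab, 0)
  # parts 50 A apart bury nothing
  far <- frame$atoms
  far$x[far$chain_id == "B"] <- far$x[far$chain_id == "B"] + 200
  f2 <- structure3d(far)
  expect_equal(buried_interface_area(f2, list(chain = "A"),
                                     list(chain = "B")), 0,
               tolerance = 0.5)
  expect_error(buried_interface_area(frame, list(chain = "A"),
                                     list(chain = c("A", "B"))),
               "overlap")
  # two-atom touching fixture matches the cap closed form
  two <- structure3d(rbind(atom_at(0, 0, 0),
                           atom_at(1, 0, 0, serial = 2L, resno = 2L)))
  R <- 3.1; h <- R - 0.5
  buried_cap <- 2 * pi * R * h   # per complex: (2*4piR2 - 2*exposed)/2
  expect_equal(buried_interface_area(two, list(resno = 1),
                                     list(resno = 2)),
               buried_cap, tolerance = 0.02 * buried_cap)
})

test_that("delta-SASA is consistent with the buried interface identity", {
  tc <- std_toy()
  frame <- get_model(tc$structure, 1)
  free_a <- structure3d(frame$atoms[frame$atoms$chain_id == "A", ])
  free_b <- structure3d(frame$atoms[frame$atoms$chain_id == "B", ])
  da <- delta_sasa(frame, free_a, list(chain = "A"))
  db <- delta_sasa(frame, free_b, list(chain = "B"))
  buried <- buried_interface_area(frame, list(chain = "A"),
                                  list(chain = "B"))
  expect_equal(sum(da$delta) + sum(db$delta), 2 * buried,
               tolerance = 0.03 * max(2 * buried, 1))
  # bound == free gives all zeros
  d0 <- delta_sasa(free_a, free_a, list(chain = "A"))
  expect_true(all(d0$delta == 0))
  expect_error(delta_sasa(frame, free_b, list(chain = "A")),
               "no residues|mismatch")
})

test_that("residue classification follows the surface-colouring scheme", {
  mk <- function(resn, i) atom_at(i * 10, 0, 0, serial = as.integer(i),
                                  resno = i) |>
    transform(res_name = resn)
  s <- structure3d(rbind(mk("TRP", 1), mk("LYS", 2), mk("ASP", 3),
                         mk("SER", 4), mk("HIS", 5)))
  cls <- classify_residues(s)
  got <- setNames(cls$class, cls$res_name)
  expect_equal(unname(got[c("TRP", "LYS", "ASP", "SER", "HIS")]),
               c("hydrophobic", "basic", "acidic", "other", "basic"))
  odd <- structure3d(transform(atom_at(0, 0, 0), res_name = "XYZ"))
  expect_warning(co <- classify_residues(odd), "nonstandard")
  expect_equal(co$class, "other")
})
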
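test_that("np_pairs counts heavy-atom pairs with an inclusive cutoff", {
  a <- atom_at(0, 0, 0)
  expect_equal(np_pairs(a, atom_at(0, 0, 5.9, serial = 2L)), 1L)
  expect_equal(np_pairs(a, atom_at(0, 0, 6.1, serial = 2L)), 0L)
  expect_equal(np_pairs(a, atom_at(0, 0, 6.0, serial = 2L)), 1L)
  # hydrogens never change the count
  b <- atom_at(0, 0, 5, serial = 2L)
  with_h_a <- rbind(a, atom_at(0.5, 0, 0, element = "H", serial = 3L,
                               name = "H"))
  with_h_b <- rbind(b, atom_at(0, 0.5, 5, element = "H", serial = 4L,
                               name = "H"))
  expect_equal(np_pairs(with_h_a, with_h_b), np_pairs(a, b))
  # overlapping groups are refused
  expect_error(np_pairs(a, a), "disjoint")
  expect_warning(np0 <- np_pairs(a, atom_at(1, 1, 1, element = "H",
                                            serial = 2L, name = "H")),
                 "empty")
  expect_equal(np0, 0L)
})

test_that("cell-list counts equal the brute-force oracle on random clouds", {
  set.seed(11)
  for (rep in 1:5) {
    a <- rand_cloud(50, box = 20, chain = "A")
    b <- rand_cloud(50, box = 20, chain = "B", serial0 = 100L)
    for (cutoff in c(3, 6, 9)) {
      expect_identical(np_pairs(a, b, cutoff), bf_np(a, b, cutoff))
    }
  }
})

test_that("np_pairs is symmetric, cutoff-monotone, and rigid-motion invariant", {
  set.seed(23)
  a <- rand_cloud(30, chain = "A")
  b <- rand_cloud(30, chain = "B", serial0 = 50L)
  expect_equal(np_pairs(a, b, 6), np_pairs(b, a, 6))
  counts <- vapply(c(2, 4, 6, 8, 10), function(cf) np_pairs(a, b, cf),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  s <- structure3d(rbind(a, b))
  moved <- rigid_move(s)
  expect_equal(
    np_pairs(moved$atoms[moved$atoms$chain_id == "A", ],
             moved$atoms[moved$atoms$chain_id == "B", ]),
    np_pairs(a, b))
})

test_that("contact matrices average frames and conserve marginals", {
  # two frames where one pair has counts 2 and 4 -> mean 3
  f1 <- rbind(atom_at(0, 0, 0, chain = "A", resno = 1L),
              atom_at(1.5, 0, 0, chain = "A", resno = 1L, serial = 2L,
                      name = "CB"),
              atom_at(0, 5, 0, chain = "B", resno = 1L, serial = 3L))
  f2 <- f1
  f2$y[3] <- 3                       # closer: both A atoms now pair twice?
  f2 <- rbind(f2, atom_at(1.5, 3, 0, chain = "B", resno = 1L,
                          serial = 4L, name = "CB"))
  # build comparable rosters: use two frames with the same atoms
  f1 <- rbind(f1, atom_at(30, 30, 30, chain = "B", resno = 1L,
                          serial = 4L, name = "CB"))
  f1$model_id <- 1L; f2$model_id <- 2L
  s <- structure3d(rbind(f1, f2))
  cm <- residue_contact_matrix(s, list(chain = "A"), list(chain = "B"))
  expect_equal(unname(cm$matrix[1, 1]), (2 + 4) / 2)
  # single frame: matrix total equals Np of the union selections
  tc <- std_toy()
  frame <- get_model(tc$structure, 1)
  cm2 <- residue_contact_matrix(frame, list(chain = "A"),
                                list(chain = "B"))
  expect_equal(sum(cm2$matrix),
               np_pairs(atom_select(frame, chain = "A"),
                        atom_select(frame, chain = "B")))
  expect_equal(unname(rowSums(cm2$matrix)), unname(cm2$row_totals))
  # planted contacts are exactly the nonzero entries
  nz <- which(cm2$matrix > 0, arr.ind = TRUE)
  got <- data.frame(
    res_a = as.integer(sub("^A:(\\d+):.*$", "\\1",
                           rownames(cm2$matrix)[nz[, 1]])),
    res_b = as.integer(sub("^B:(\\d+):.*$", "\\1",
                           colnames(cm2$matrix)[nz[, 2]])))
  expect_setequal(paste(got$res_a, got$res_b),
                  paste(tc$contacts$res_a, tc$contacts$res_b))
})

test_that("sidechain_only drops backbone atoms from both sides", {
  tc <- std_toy()
  frame <- get_model(tc$structure, 1)
  full <- residue_contact_matrix(frame, list(chain = "A"),
                                 list(chain = "B"))
  sc <- residue_contact_matrix(frame, list(chain = "A"),
                               list(chain = "B"), sidechain_only = TRUE)
  expect_true(all(sc$matrix <= full$matrix))
  # brute-force recomputation on CB-only atoms
  a_cb <- atom_select(frame, chain = "A", elety = "CB")
  b_cb <- atom_select(frame, chain = "B", elety = "CB")
  expect_equal(sum(sc$matrix), bf_np(a_cb, b_cb, 6))
})

test_that("lipid contact profiles split head and tail counts correctly", {
  # a protein residue 5 A from one head atom and far from all tails
  prot <- atom_at(0, 0, 23, chain = "P", resno = 1L, serial = 500L)
  slab <- build_membrane_slab(4, seed = 3)
  a <- slab$atoms
  head1 <- a[a$res_name == "HEA", ][1, ]
  prot$x <- head1$x; prot$y <- head1$y; prot$z <- head1$z + 5
  s <- structure3d(rbind(a, prot))
  prof <- lipid_contact_profile(s, list(chain = "P"))
  expect_equal(nrow(prof), 1L)
  expect_gte(prof$np_head, 1)
  expect_equal(prof$np_tail, 0)
  # brute-force consistency on a protein placed inside the slab
  tc <- std_toy()
  prot2 <- get_model(tc$structure, 1)$atoms
  prot2$serial <- prot2$serial + 1000L
  s2 <- structure3d(rbind(slab$atoms, prot2))
  prof2 <- lipid_contact_profile(s2, list(chain = "A"))
  heads <- s2$atoms[s2$atoms$res_name == "HEA", ]
  tails <- s2$atoms[s2$atoms$res_name == "TAI", ]
  for (k in seq_len(nrow(prof2))) {
    resno <- as.integer(sub("^A:(\\d+):.*$", "\\1", prof2$residue[k]))
    ra <- s2$atoms[s2$atoms$chain_id == "A" & s2$atoms$res_seq == resno, ]
    expect_equal(prof2$np_head[k], bf_np(ra, heads, 6))
    expect_equal(prof2$np_tail[k], bf_np(ra, tails, 6))
  }
  expect_error(lipid_contact_profile(s, list(chain = "P"),
                                     head_res = "HEA",
                                     tail_res = c("HEA", "TAI")),
               "disjoint")
})

test_that("cluster compactness matches per-frame brute force", {
  tc <- std_toy()
  ens <- perturb_ensemble(get_model(tc$structure, 1), 3, 0.2, seed = 4)
  members <- lapply(c(2, 5, 9, 10), function(r)
    list(chain = "A", resno = r))
  prof <- cluster_compactness(ens, members, cutoff = 12)
  # brute-force recomputation (side-chain = CB in the toy residues)
  for (i in seq_along(members)) {
    tot <- 0
    for (m in 1:3) {
      a <- ens$atoms[ens$atoms$model_id == m, ]
      mine <- a[a$chain_id == "A" & a$res_seq == c(2, 5, 9, 10)[i] &
                  a$name == "CB", ]
      others <- a[a$chain_id == "A" &
                    a$res_seq %in% setdiff(c(2, 5, 9, 10),
                                           c(2, 5, 9, 10)[i]) &
                    a$name == "CB", ]
      tot <- tot + bf_np(mine, others, 12)
    }
    expect_equal(prof$np_mean[i], tot / 3)
  }
  # members pairwise beyond the cutoff give all zeros
  prof0 <- cluster_compactness(ens, members, cutoff = 2)
  expect_true(all(prof0$np_mean == 0))
  # symmetric two-member case: both values equal
  two <- structure3d(rbind(atom_at(0, 0, 0, name = "CB", resno = 1L),
                           atom_at(5, 0, 0, name = "CB", resno = 2L,
                                   serial = 2L)))
  p2 <- cluster_compactness(two, list(list(resno = 1), list(resno = 2)),
                            cutoff = 6)
  expect_equal(p2$np_mean, c(1, 1))
})

test_that("neighbour-residue counts average over frames", {
  tc <- std_toy()
  frames <- tc$structure
  n <- neighbor_residue_count(frames, list(chain = "A", resno = 2),
                              list(chain = "B"))
  expect_equal(n, 1)  # planted partner B:3 only
  # two-frame mean: query touches 2 then 4 partner residues
  mk_frame <- function(partners, model) {
    q <- atom_at(0, 0, 0, chain = "Q", resno = 1L, model_id = model)
    ps <- do.call(rbind, lapply(seq_len(4), function(i)
      atom_at(if (i <= partners) 3 else 50, i * 2, 0, chain = "P",
              resno = i, serial = i + 1L, model_id = model)))
    rbind(q, ps)
  }
  s <- structure3d(rbind(mk_frame(2, 1L), mk_frame(4, 2L)))
  expect_equal(neighbor_residue_count(s, list(chain = "Q"),
                                      list(chain = "P"), cutoff = 15),
               3)
  expect_equal(neighbor_residue_count(s, list(chain = "Q"),
                                      list(chain = "P"), cutoff = 0.1),
               0)
})
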
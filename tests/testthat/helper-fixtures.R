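# Shared fixture builders and independent brute-force oracles.

# O(n^2) double-loop heavy-atom pair count: the oracle the cell-list
# production path is checked against.
bf_np <- function(atoms_a, atoms_b, cutoff = 6) {
  ha <- atoms_a[atoms_a$element != "H", , drop = FALSE]
  hb <- atoms_b[atoms_b$element != "H", , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(ha))) for (j in seq_len(nrow(hb))) {
    d <- sqrt((ha$x[i] - hb$x[j])^2 + (ha$y[i] - hb$y[j])^2 +
                (ha$z[i] - hb$z[j])^2)
    if (d <= cutoff) n <- n + 1L
  }
  n
}

# Random atom cloud as an atom table (single model, one chain).
rand_cloud <- function(n, box = 20, chain = "A", serial0 = 0L,
                       element = "C") {
  data.frame(serial = serial0 + seq_len(n), name = "CA",
             element = element, mass = element_mass(rep(element, n)),
             res_name = "ALA", res_seq = seq_len(n), chain_id = chain,
             x = runif(n, 0, box), y = runif(n, 0, box),
             z = runif(n, 0, box), model_id = 1L)
}

# Single atom structure at a point.
atom_at <- function(x, y, z, element = "C", serial = 1L, chain = "A",
                    resno = serial, name = "CA", model_id = 1L) {
  data.frame(serial = serial, name = name, element = element,
             mass = element_mass(element), res_name = "ALA",
             res_seq = resno, chain_id = chain, x = x, y = y, z = z,
             model_id = model_id)
}

# Two-chain toy complex with 3 planted contacts (deterministic).
std_toy <- function(seed = 7) {
  build_toy_complex(10, c("A", "B"),
                    data.frame(chain_a = "A", res_a = c(2, 5, 9),
                               chain_b = "B", res_b = c(3, 6, 1)),
                    seed = seed)
}

# Apply a rigid rotation (about z by `angle`) plus translation to all
# atoms of a structure.
rigid_move <- function(structure, angle = pi / 3, shift = c(10, -5, 3)) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  a <- structure$atoms
  xyz <- cbind(a$x, a$y, a$z) %*% R
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  structure3d(a, title = structure$title)
}
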
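#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` in the least-squares sense (SVD-based, with the
#' determinant correction so reflections are never returned).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3, det +1), `translation` (applied
#'   as `coords %*% t(R) + t`), `rmsd` (after transform) and `transform`,
#'   a function applying the fit to an m x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point-count mismatch")
  if (nrow(mobile) < 3L) stop("need >= 3 points")
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else weights
  if (any(w < 0) || sum(w) == 0) stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2L)
    stop("degenerate (collinear) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(R %*% cm)
  transform <- function(x) sweep(as.matrix(x) %*% t(R), 2, trans, "+")
  fitted <- transform(mobile)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = trans, rmsd = rmsd,
       transform = transform)
}

# Selected coordinates of every model as a list of n x 3 matrices.
.model_coords <- function(ensemble, selection = NULL) {
  a <- .apply_selection(ensemble$atoms, selection)
  if (nrow(a) == 0L) stop("selection resolves to no atoms")
  frames <- split(a, a$model_id)
  .check_roster(frames, "selection")
  lapply(frames, .coords)
}

#' Ensemble RMSD to the iterated mean structure
#'
#' Superposes all models on the current mean over the selection,
#' recomputes the mean, and iterates until the mean moves by less than
#' `tol` Angstrom; returns the average over models of each model's RMSD
#' to the converged mean. The `pairwise` method instead reports the mean
#' of all pairwise superposed RMSDs (an alternative convention some
#' ensemble statistics use).
#'
#' @param ensemble multi-model [structure3d()] (>= 2 models).
#' @param selection selection list (e.g.
#'   `list(elety = c("N","CA","C"), resno = 2:31)`).
#' @param method `"to_mean"` (default) or `"pairwise"`.
#' @param tol convergence threshold on the mean shift (Angstrom).
#' @param max_iter iteration cap; exceeding it is an error.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_mean <- function(ensemble, selection = NULL,
                         method = c("to_mean", "pairwise"),
                         tol = 1e-6, max_iter = 100L) {
  method <- match.arg(method)
  xs <- .model_coords(ensemble, selection)
  if (length(xs) < 2L) stop("need >= 2 models")
  if (method == "pairwise") {
    n <- length(xs); tot <- 0; np <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tot <- tot + kabsch_superpose(xs[[i]], xs[[j]])$rmsd
      np <- np + 1L
    }
    return(tot / np)
  }
  mean_c <- Reduce(`+`, xs) / length(xs)
  for (it in seq_len(max_iter)) {
    xs <- lapply(xs, function(x) kabsch_superpose(x, mean_c)$transform(x))
    new_mean <- Reduce(`+`, xs) / length(xs)
    shift <- sqrt(mean(rowSums((new_mean - mean_c)^2)))
    mean_c <- new_mean
    if (shift < tol) {
      rmsds <- vapply(xs, function(x)
        sqrt(mean(rowSums((x - mean_c)^2))), numeric(1))
      return(mean(rmsds))
    }
  }
  stop("mean-structure iteration did not converge in ", max_iter,
       " iterations")
}

# Greedy neighbour-count clustering on a precomputed distance matrix.
# Repeatedly pick the member with the most neighbours within cutoff
# (lowest index on ties), form a cluster from it plus its neighbours,
# remove them, repeat.
.daura_from_matrix <- function(d, cutoff) {
  n <- nrow(d)
  membership <- integer(n)
  centers <- integer(0)
  remaining <- seq_len(n)
  cl <- 0L
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(d[i, remaining] <= cutoff) - 1L, integer(1))
    center <- remaining[which.max(counts)]   # which.max: lowest index tie
    neigh <- remaining[d[center, remaining] <= cutoff]
    cl <- cl + 1L
    membership[neigh] <- cl
    centers <- c(centers, center)
    remaining <- setdiff(remaining, neigh)
  }
  list(membership = membership, centers = centers)
}

#' Daura neighbour-count clustering of an ensemble
#'
#' Clusters models by pairwise superposed RMSD using the greedy
#' neighbour-count algorithm: the model with the most neighbours within
#' the cutoff seeds a cluster (it becomes the cluster's central,
#' representative structure), the cluster is removed, and the procedure
#' repeats. The most representative model of the ensemble is the center
#' of the largest cluster.
#'
#' @param ensemble multi-model [structure3d()].
#' @param selection selection list used for the RMSD.
#' @param cutoff similarity cutoff in Angstrom.
#' @return object of class `cluster_result`: list with `membership`
#'   (cluster id per model), `centers` (model index per cluster, in
#'   cluster order), `representative` (center of the largest cluster),
#'   `cutoff`, and the `rmsd_matrix`.
#' @export
daura_cluster <- function(ensemble, selection = NULL, cutoff) {
  xs <- .model_coords(ensemble, selection)
  n <- length(xs)
  d <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- kabsch_superpose(xs[[i]], xs[[j]])$rmsd
  res <- .daura_from_matrix(d, cutoff)
  sizes <- tabulate(res$membership)
  out <- list(membership = res$membership, centers = res$centers,
              representative = res$centers[which.max(sizes)],
              cutoff = cutoff, rmsd_matrix = d)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d model(s) in %d cluster(s), cutoff %g A; representative model %d\n",
              length(x$membership), length(x$centers), x$cutoff,
              x$representative))
  invisible(x)
}

# Deterministic Fibonacci-lattice points on the unit sphere.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA of the heavy atoms of a single model: each atom's
#' sphere of radius `r_vdw + probe` is sampled on a deterministic
#' Fibonacci lattice, and its area is `4 pi (r + probe)^2` times the
#' fraction of points outside every neighbour's probe-expanded sphere.
#' Hydrogens are ignored. Van der Waals radii: C 1.70, N 1.55, O 1.52,
#' S 1.80, P 1.80 Angstrom; other elements are an error.
#'
#' @param structure a [structure3d()]; `model_id` selects the model.
#' @param probe probe radius (Angstrom), default 1.4.
#' @param n_points lattice points per atom, default 960.
#' @param model_id model to analyse.
#' @return object of class `sasa_report`: list with `atom` (data.frame
#'   `serial`, `name`, `res_seq`, `chain_id`, `res_name`, `area`),
#'   `residue` (data.frame `residue`, `area`), `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L, model_id = 1L) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms[structure$atoms$model_id == model_id &
                         structure$atoms$element != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy atoms in model ", model_id)
  r <- .VDW_RADIUS[a$element]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$element[is.na(r)]), collapse = ", "))
  r <- unname(r) + probe
  pts <- .fibonacci_sphere(n_points)
  xyz <- .coords(a)
  n <- nrow(a)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    neigh <- which(d < r[i] + r & seq_len(n) != i)
    sp <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(neigh)) {
      acc <- rep(TRUE, n_points)
      for (j in neigh) {
        if (!any(acc)) break
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > r[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    area[i] <- 4 * pi * r[i]^2 * frac
  }
  atom_tab <- data.frame(serial = a$serial, name = a$name,
                         res_seq = a$res_seq, chain_id = a$chain_id,
                         res_name = a$res_name, area = area)
  res_lab <- .residue_label(a)
  res_tab <- stats::aggregate(area ~ residue,
                              data = data.frame(residue = res_lab,
                                                area = area),
                              FUN = sum)
  out <- list(atom = atom_tab, residue = res_tab, probe = probe,
              n_points = n_points)
  class(out) <- "sasa_report"
  out
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(sprintf("<sasa_report> %d atoms, total %.1f A^2 (probe %.2f A)\n",
              nrow(x$atom), sum(x$atom$area), x$probe))
  invisible(x)
}

# Build a structure3d from a subset of atom rows (single model).
.substructure <- function(atoms) {
  atoms$model_id <- 1L
  structure3d(atoms)
}

#' Buried interface area between two parts of a complex
#'
#' The buried surface per complex: `(SASA_A + SASA_B - SASA_AB) / 2`,
#' where the parts are scored in isolation and together. Symmetric in
#' its arguments by construction.
#'
#' @param complex single-model [structure3d()].
#' @param part_a,part_b disjoint selection lists.
#' @param probe probe radius (Angstrom).
#' @param n_points lattice points per atom.
#' @return buried area in Angstrom^2.
#' @export
buried_interface_area <- function(complex, part_a, part_b, probe = 1.4,
                                  n_points = 960L) {
  aa <- .apply_selection(complex$atoms, part_a)
  bb <- .apply_selection(complex$atoms, part_b)
  if (length(intersect(aa$serial, bb$serial)))
    stop("part_a and part_b overlap")
  if (nrow(aa) == 0L || nrow(bb) == 0L) stop("empty part selection")
  s_a <- sum(sasa(.substructure(aa), probe, n_points)$atom$area)
  s_b <- sum(sasa(.substructure(bb), probe, n_points)$atom$area)
  s_ab <- sum(sasa(.substructure(rbind(aa, bb)), probe,
                   n_points)$atom$area)
  (s_a + s_b - s_ab) / 2
}

#' Per-residue change in solvent accessibility between two states
#'
#' `dSASA(res) = SASA_free(res) - SASA_bound(res)` for each residue of
#' the selection: positive values mark surface buried on binding.
#'
#' @param bound,free single-model [structure3d()] objects; the selection
#'   must resolve to the same residues in both.
#' @param selection selection list (default: all residues present in
#'   both).
#' @param probe probe radius (Angstrom).
#' @param n_points lattice points per atom.
#' @return data.frame with columns `residue`, `sasa_free`, `sasa_bound`,
#'   `delta`.
#' @export
delta_sasa <- function(bound, free, selection = NULL, probe = 1.4,
                       n_points = 960L) {
  sb <- sasa(bound, probe, n_points)$residue
  sf <- sasa(free, probe, n_points)$residue
  sel_res <- unique(.residue_label(.apply_selection(free$atoms, selection)))
  sel_res <- sel_res[sel_res %in% sb$residue]
  if (!length(sel_res))
    stop("selection resolves to no residues shared by both states")
  if (!all(sel_res %in% sf$residue))
    stop("residue roster mismatch between bound and free states")
  fb <- sb$area[match(sel_res, sb$residue)]
  ff <- sf$area[match(sel_res, sf$residue)]
  data.frame(residue = sel_res, sasa_free = ff, sasa_bound = fb,
             delta = ff - fb)
}

#' Classify residues by physico-chemical character
#'
#' Surface-colouring classes: hydrophobic (ALA, VAL, LEU, ILE, MET, PHE,
#' TRP, PRO), basic (LYS, ARG, HIS), acidic (ASP, GLU), everything else
#' `other` (nonstandard names get `other` with a warning). Histidine
#' counts as basic.
#'
#' @param structure a [structure3d()].
#' @return data.frame with columns `residue`, `res_name`, `class`.
#' @export
classify_residues <- function(structure) {
  std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  hydrophobic <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
  basic <- c("LYS", "ARG", "HIS")
  acidic <- c("ASP", "GLU")
  a <- structure$atoms[structure$atoms$model_id ==
                         min(structure$atoms$model_id), , drop = FALSE]
  res <- unique(data.frame(residue = .residue_label(a),
                           res_name = a$res_name))
  if (any(!res$res_name %in% std))
    warning("nonstandard residue name(s) classified as 'other': ",
            paste(unique(res$res_name[!res$res_name %in% std]),
                  collapse = ", "))
  cls <- ifelse(res$res_name %in% hydrophobic, "hydrophobic",
                ifelse(res$res_name %in% basic, "basic",
                       ifelse(res$res_name %in% acidic, "acidic", "other")))
  data.frame(residue = res$residue, res_name = res$res_name, class = cls,
             row.names = NULL)
}
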
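#' Pearson correlation between two density maps
#'
#' Voxel-wise Pearson correlation of two maps on an identical grid
#' (same dimensions, voxel spacing and origin; resampling is the
#' caller's job). Optionally restricted to voxels where either map
#' exceeds a threshold. Invariant under affine rescaling of either map.
#'
#' @param map_a,map_b [density_map()] objects on the same grid.
#' @param mask_threshold optional; keep voxels where either map exceeds
#'   this value.
#' @return correlation in `[-1, 1]`.
#' @export
map_model_correlation <- function(map_a, map_b, mask_threshold = NULL) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  if (!identical(dim(map_a$grid), dim(map_b$grid)))
    stop("grid dimension mismatch")
  if (max(abs(map_a$voxel - map_b$voxel)) > 1e-6 ||
      max(abs(map_a$origin - map_b$origin)) > 1e-6)
    stop("voxel/origin mismatch: resample before correlating")
  va <- as.vector(map_a$grid); vb <- as.vector(map_b$grid)
  if (!is.null(mask_threshold)) {
    keep <- va > mask_threshold | vb > mask_threshold
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 2L || stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero-variance map: correlation undefined")
  stats::cor(va, vb)
}

# Trilinear interpolation of map values at Cartesian points (n x 3).
# Points outside the grid bounding box evaluate to 0.
.trilinear <- function(map, pts) {
  dims <- dim(map$grid)
  f <- sweep(sweep(pts, 2, map$origin), 2, map$voxel, "/")  # 0-based frac idx
  out <- numeric(nrow(pts))
  inside <- f[, 1] >= 0 & f[, 1] <= dims[1] - 1 &
    f[, 2] >= 0 & f[, 2] <= dims[2] - 1 &
    f[, 3] >= 0 & f[, 3] <= dims[3] - 1
  if (!any(inside)) return(out)
  ff <- f[inside, , drop = FALSE]
  i0 <- pmin(floor(ff), matrix(rep(dims - 2, each = nrow(ff)), ncol = 3))
  t <- ff - i0
  g <- map$grid
  idx <- function(dx, dy, dz)
    g[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  val <-
    idx(0, 0, 0) * (1 - t[, 1]) * (1 - t[, 2]) * (1 - t[, 3]) +
    idx(1, 0, 0) * t[, 1] * (1 - t[, 2]) * (1 - t[, 3]) +
    idx(0, 1, 0) * (1 - t[, 1]) * t[, 2] * (1 - t[, 3]) +
    idx(0, 0, 1) * (1 - t[, 1]) * (1 - t[, 2]) * t[, 3] +
    idx(1, 1, 0) * t[, 1] * t[, 2] * (1 - t[, 3]) +
    idx(1, 0, 1) * t[, 1] * (1 - t[, 2]) * t[, 3] +
    idx(0, 1, 1) * (1 - t[, 1]) * t[, 2] * t[, 3] +
    idx(1, 1, 1) * t[, 1] * t[, 2] * t[, 3]
  out[inside] <- val
  out
}

#' Per-atom density confidence scores
#'
#' Ranks the confidence in each atom's position by the score
#' `s_a = -m_a * rho(x_a, y_a, z_a)`, where `m_a` is the atomic mass and
#' `rho` the density (normalised to unit maximum) interpolated
#' trilinearly at the atom position. The best (most negative) scores sit
#' in the densest map regions; the best `round(fraction * N)` atoms are
#' flagged as well resolved ("top" = most negative under this sign
#' convention). Atoms outside the map get `rho = 0` with a warning,
#' never an error. Ties are broken by lower serial.
#'
#' @param structure single-model [structure3d()].
#' @param map a [density_map()].
#' @param fraction selection fraction in (0, 1]; default 0.20.
#' @param normalize `"unit-max"` (default) rescales the map to a peak of
#'   1 before scoring; `"none"` uses raw values.
#' @return data.frame with columns `serial`, `name`, `res_seq`,
#'   `chain_id`, `mass`, `rho`, `score`, `selected`, ordered by rank.
#' @export
atom_confidence <- function(structure, map, fraction = 0.20,
                            normalize = c("unit-max", "none")) {
  stopifnot(inherits(structure, "structure3d"), inherits(map, "density_map"))
  normalize <- match.arg(normalize)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (structure$models != 1L) stop("expected a single-model structure")
  a <- structure$atoms
  g <- map
  if (normalize == "unit-max") {
    peak <- max(g$grid)
    if (peak <= 0) stop("map has no positive peak to normalise to")
    g$grid <- g$grid / peak
  }
  pts <- .coords(a)
  dims <- dim(g$grid)
  hi <- g$origin + (dims - 1) * g$voxel
  outside <- pts[, 1] < g$origin[1] | pts[, 1] > hi[1] |
    pts[, 2] < g$origin[2] | pts[, 2] > hi[2] |
    pts[, 3] < g$origin[3] | pts[, 3] > hi[3]
  if (any(outside))
    warning(sum(outside), " atom(s) outside the map box: rho = 0")
  rho <- .trilinear(g, pts)
  score <- -a$mass * rho
  ord <- order(score, a$serial)
  n_sel <- round(fraction * nrow(a))
  selected <- logical(nrow(a))
  selected[ord[seq_len(n_sel)]] <- TRUE
  out <- data.frame(serial = a$serial, name = a$name, res_seq = a$res_seq,
                    chain_id = a$chain_id, mass = a$mass, rho = rho,
                    score = score, selected = selected)
  out[ord, , drop = FALSE]
}

#' NOE restraint-violation report
#'
#' Evaluates each upper-bound distance restraint in one model: a
#' restraint is violated iff the inter-atom distance exceeds its bound.
#' The violation RMSD is the root-mean-square of `(d - upper)` over the
#' violated restraints only (0 when none are violated). Selectors that
#' do not resolve to exactly one atom are excluded and counted
#' separately.
#'
#' @param structure a [structure3d()].
#' @param restraints a [parse_restraints()] table.
#' @param model_id model to evaluate (default 1).
#' @return object of class `violation_report`: list with `n_restraints`,
#'   `n_violated`, `violation_rmsd`, `n_unresolved` and the per-restraint
#'   `excess` vector (NA when satisfied or unresolved).
#' @export
noe_violations <- function(structure, restraints, model_id = 1L) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms[structure$atoms$model_id == model_id, , drop = FALSE]
  if (nrow(a) == 0L) stop("no model with id ", model_id)
  n <- nrow(restraints)
  excess <- rep(NA_real_, n)
  unresolved <- logical(n)
  violated <- logical(n)
  find1 <- function(ch, rs, nm) {
    which(a$chain_id == ch & a$res_seq == rs & a$name == nm)
  }
  for (k in seq_len(n)) {
    ia <- find1(restraints$chain_a[k], restraints$res_a[k],
                restraints$atom_a[k])
    ib <- find1(restraints$chain_b[k], restraints$res_b[k],
                restraints$atom_b[k])
    if (length(ia) != 1L || length(ib) != 1L) {
      unresolved[k] <- TRUE
      next
    }
    d <- sqrt((a$x[ia] - a$x[ib])^2 + (a$y[ia] - a$y[ib])^2 +
                (a$z[ia] - a$z[ib])^2)
    if (d > restraints$upper[k]) {
      violated[k] <- TRUE
      excess[k] <- d - restraints$upper[k]
    }
  }
  vr <- if (any(violated)) sqrt(mean(excess[violated]^2)) else 0
  out <- list(n_restraints = n - sum(unresolved),
              n_violated = sum(violated),
              violation_rmsd = vr,
              n_unresolved = sum(unresolved),
              excess = excess)
  class(out) <- "violation_report"
  out
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("<violation_report> %d/%d violated, violation RMSD %.3f A",
              x$n_violated, x$n_restraints, x$violation_rmsd))
  if (x$n_unresolved) cat(sprintf(" (%d unresolved)", x$n_unresolved))
  cat("\n")
  invisible(x)
}

#' Rank candidate poses against an experimental map and restraints
#'
#' For each pose a model map is synthesised on the experimental grid
#' ([synthesize_map()] with `grid_like`), its correlation with the
#' experimental map computed, and the NOE violations evaluated. Poses
#' are ranked by higher correlation, then fewer violations, then lower
#' violation RMSD, then input order — the discrimination logic used to
#' choose between mirror-image lobe assignments.
#'
#' @param poses list of single-model [structure3d()] objects on a common
#'   atom roster.
#' @param map experimental [density_map()].
#' @param restraints a [parse_restraints()] table.
#' @param sigma Gaussian width used for the model maps (Angstrom).
#' @return data.frame ordered by rank with columns `pose`, `correlation`,
#'   `n_violated`, `violation_rmsd`, `rank`.
#' @export
rank_poses <- function(poses, map, restraints, sigma = 2) {
  if (length(poses) < 2L) stop("need >= 2 poses")
  roster <- lapply(poses, function(p)
    p$atoms[, c("serial", "name", "res_seq", "chain_id")])
  for (k in seq_along(roster)[-1])
    if (!identical(roster[[1]], roster[[k]]))
      stop("pose ", k, " does not share the atom roster of pose 1")
  stats_ <- lapply(seq_along(poses), function(k) {
    mm <- synthesize_map(poses[[k]], sigma = sigma, grid_like = map)
    v <- noe_violations(poses[[k]], restraints)
    data.frame(pose = k,
               correlation = map_model_correlation(map, mm),
               n_violated = v$n_violated,
               violation_rmsd = v$violation_rmsd)
  })
  df <- do.call(rbind, stats_)
  ord <- order(-df$correlation, df$n_violated, df$violation_rmsd, df$pose)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Backbone phi restraint from a 3J(HN-Halpha) coupling
#'
#' Standard NMR structure-calculation rule: couplings below 5.5 Hz
#' constrain phi to -65 +/- 25 degrees (helical); couplings above 8.0 Hz
#' constrain phi to -120 +/- 40 degrees (extended); intermediate values
#' give no restraint.
#'
#' @param j scalar coupling in Hz (>= 0).
#' @return list with `center` and `half_width` in degrees, or `NULL`
#'   when `j` is between the thresholds.
#' @export
coupling_to_phi <- function(j) {
  if (j < 0) stop("coupling constant must be >= 0")
  if (j < 5.5) return(list(center = -65, half_width = 25))
  if (j > 8.0) return(list(center = -120, half_width = 40))
  NULL
}

#' Combined proton chemical-shift difference
#'
#' The per-residue chemical-shift difference combining the Halpha and
#' amide-proton deviations: `sqrt(d_ha^2 + d_hn^2)` (ppm).
#'
#' @param d_ha Halpha shift difference (ppm).
#' @param d_hn HN shift difference (ppm).
#' @return list with `d_ha`, `d_hn`, `dcs`.
#' @export
chemical_shift_difference <- function(d_ha, d_hn) {
  if (!all(is.finite(d_ha)) || !all(is.finite(d_hn)))
    stop("shift differences must be finite")
  list(d_ha = d_ha, d_hn = d_hn, dcs = sqrt(d_ha^2 + d_hn^2))
}
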
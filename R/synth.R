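#' Noise model for simulated measurements
#'
#' @param kind `"multiplicative-gaussian"` (fluorescence-style: the
#'   signal is scaled by `1 + N(0, sd)`) or `"additive-gaussian"`
#'   (current-style: `N(0, sd)` is added in response units).
#' @param sd standard deviation; `sd = 0` reproduces the deterministic
#'   model exactly.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-gaussian",
                                 "additive-gaussian"), sd = 0) {
  kind <- match.arg(kind)
  if (sd < 0) stop("noise sd must be >= 0")
  structure(list(kind = kind, sd = sd), class = "noise_model")
}

.apply_noise <- function(values, noise) {
  if (noise$sd == 0) return(values)
  eps <- stats::rnorm(length(values), 0, noise$sd)
  switch(noise$kind,
         "multiplicative-gaussian" = values * (1 + eps),
         "additive-gaussian"       = values + eps)
}

# One pseudo-residue: 4 heavy atoms (N, CA, C, CB) + 1 amide hydrogen,
# all within 0.8 A (1.4 A for H) of the residue centre.
.pseudo_residue <- function(center, chain, resno, serial0, model_id = 1L) {
  off <- rbind(N  = c( 0.8, 0.0, 0.0),
               CA = c( 0.0, 0.0, 0.0),
               C  = c(-0.8, 0.0, 0.0),
               CB = c( 0.0, 0.8, 0.0),
               H  = c( 1.4, 0.0, 0.0))
  el <- c("N", "C", "C", "C", "H")
  data.frame(serial = serial0 + seq_len(5L), name = rownames(off),
             element = el, mass = element_mass(el), res_name = "GLY",
             res_seq = resno, chain_id = chain,
             x = center[1] + off[, 1], y = center[2] + off[, 2],
             z = center[3] + off[, 3], model_id = model_id)
}

#' Build a toy multi-chain complex with planted contacts
#'
#' Chains are laid out as straight strands of compact 4-heavy-atom
#' pseudo-residues (N, CA, C, CB plus one hydrogen), far apart from each
#' other. Each planted contact pair is realised by relocating the second
#' chain's residue next to its partner so that at least one heavy-atom
#' pair falls within 4.5 Angstrom, while every non-planted inter-chain
#' residue pair keeps all heavy-atom pairs beyond 8 Angstrom. The layout
#' is a deterministic function of the spec and seed.
#'
#' @param n_res_per_chain residues per chain.
#' @param chains character vector of chain ids (at least 2).
#' @param planted_contacts data.frame with columns `chain_a`, `res_a`,
#'   `chain_b`, `res_b`; may have zero rows.
#' @param seed integer seed.
#' @return list with elements `structure` (a [structure3d()]) and
#'   `contacts` (the planted ground-truth pairs).
#' @export
build_toy_complex <- function(n_res_per_chain, chains,
                              planted_contacts = NULL, seed = 1L) {
  if (length(chains) < 2L) stop("need at least 2 chains")
  if (is.null(planted_contacts))
    planted_contacts <- data.frame(chain_a = character(), res_a = integer(),
                                   chain_b = character(), res_b = integer())
  pc <- planted_contacts
  if (nrow(pc)) {
    ok <- pc$chain_a %in% chains & pc$chain_b %in% chains &
      pc$res_a >= 1 & pc$res_a <= n_res_per_chain &
      pc$res_b >= 1 & pc$res_b <= n_res_per_chain
    if (!all(ok)) stop("planted contact references a non-existent residue")
    key_a <- paste(pc$chain_a, pc$res_a)
    key_b <- paste(pc$chain_b, pc$res_b)
    if (anyDuplicated(key_a) || anyDuplicated(key_b))
      stop("geometric placement infeasible: a residue is planted in more ",
           "than one contact; request fewer planted contacts")
  }
  spacing <- 12      # intra-chain residue spacing: non-planted pairs stay > 8 A
  chain_gap <- 40    # baseline separation between chains
  centers <- list()
  for (ci in seq_along(chains)) {
    for (r in seq_len(n_res_per_chain)) {
      centers[[paste(chains[ci], r)]] <-
        c(r * spacing, (ci - 1) * chain_gap, 0)
    }
  }
  # relocate each planted chain-B residue 4 A from its chain-A partner
  if (nrow(pc)) {
    for (k in seq_len(nrow(pc))) {
      a <- centers[[paste(pc$chain_a[k], pc$res_a[k])]]
      centers[[paste(pc$chain_b[k], pc$res_b[k])]] <- a + c(0, 4, 0)
    }
  }
  jitter <- .with_seed(seed, matrix(stats::runif(3 * length(centers),
                                                 -0.05, 0.05), ncol = 3))
  rows <- vector("list", length(centers))
  serial <- 0L
  i <- 0L
  for (ci in seq_along(chains)) {
    for (r in seq_len(n_res_per_chain)) {
      i <- i + 1L
      ctr <- centers[[paste(chains[ci], r)]] + jitter[i, ]
      rows[[i]] <- .pseudo_residue(ctr, chains[ci], r, serial)
      serial <- serial + 5L
    }
  }
  s <- structure3d(do.call(rbind, rows), title = "toy complex")
  list(structure = s, contacts = pc)
}

#' Build a labelled lipid-slab structure
#'
#' A stylised planar bilayer: each lipid contributes one head-group
#' residue (`HEA`, P/O/N atoms) and one tail residue (`TAI`, C atoms),
#' with head atoms at larger `|z|` than tail atoms within each leaflet.
#' Lipids alternate between the two leaflets on an x-y grid with a small
#' seeded jitter.
#'
#' @param n_lipids number of lipids (>= 1).
#' @param seed integer seed.
#' @return a [structure3d()] with chain `L`.
#' @export
build_membrane_slab <- function(n_lipids, seed = 1L) {
  if (n_lipids < 1L) stop("n_lipids must be >= 1")
  ncol_grid <- ceiling(sqrt(n_lipids))
  jit <- .with_seed(seed, matrix(stats::runif(2 * n_lipids, -0.5, 0.5),
                                 ncol = 2))
  rows <- vector("list", 2L * n_lipids)
  serial <- 0L
  for (i in seq_len(n_lipids)) {
    gx <- ((i - 1) %% ncol_grid) * 8
    gy <- ((i - 1) %/% ncol_grid) * 8
    leaf <- if (i %% 2L == 1L) 1 else -1   # alternate leaflets
    hx <- gx + jit[i, 1]; hy <- gy + jit[i, 2]
    head_z <- leaf * 18
    head <- data.frame(
      serial = serial + 1:3, name = c("P", "O1", "N1"),
      element = c("P", "O", "N"),
      mass = element_mass(c("P", "O", "N")), res_name = "HEA",
      res_seq = 2L * i - 1L, chain_id = "L",
      x = hx + c(0, 1.2, -1.2), y = hy + c(0, 0.5, -0.5),
      z = head_z + leaf * c(0, 0.8, 0.4), model_id = 1L)
    tail <- data.frame(
      serial = serial + 4:7, name = paste0("C", 1:4), element = "C",
      mass = element_mass(rep("C", 4)), res_name = "TAI",
      res_seq = 2L * i, chain_id = "L",
      x = hx, y = hy, z = leaf * c(14, 11, 8, 5), model_id = 1L)
    rows[[2L * i - 1L]] <- head
    rows[[2L * i]] <- tail
    serial <- serial + 7L
  }
  structure3d(do.call(rbind, rows), title = "lipid slab")
}

#' Synthesize a Gaussian-atom density map
#'
#' The density at a grid point is the sum over heavy atoms of
#' mass-weighted isotropic Gaussians, `m_a * exp(-r^2 / (2 sigma^2))`
#' (peak amplitude `m_a`), so the analytic grid sum of a well-padded map
#' is `sum(m_a) * (2 pi sigma^2)^{3/2} / voxel^3`.
#'
#' @param structure a single-model [structure3d()] (hydrogens ignored);
#'   may have zero heavy atoms only via `grid_like`.
#' @param sigma Gaussian width (Angstrom), > 0.
#' @param voxel grid spacing (Angstrom), > 0.
#' @param padding extra space around the structure's bounding box.
#' @param grid_like optional [density_map()] whose grid geometry
#'   (dimensions, voxel, origin) is reused; then `voxel`/`padding` are
#'   ignored. Used when scoring poses against an experimental grid.
#' @return a [density_map()].
#' @export
synthesize_map <- function(structure, sigma, voxel = 1, padding = 5,
                           grid_like = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(grid_like) && voxel <= 0) stop("voxel must be > 0")
  a <- structure$atoms
  a <- a[a$element != "H" & a$model_id == min(a$model_id), , drop = FALSE]
  if (is.null(grid_like)) {
    if (voxel > 2 * sigma)
      warning("voxel spacing exceeds 2*sigma: map is undersampled")
    lo <- c(min(a$x), min(a$y), min(a$z)) - padding
    hi <- c(max(a$x), max(a$y), max(a$z)) + padding
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    origin <- lo
    vox <- rep(voxel, 3)
  } else {
    dims <- dim(grid_like$grid)
    origin <- grid_like$origin
    vox <- grid_like$voxel
  }
  grid <- array(0, dim = dims)
  ax <- origin[1] + (seq_len(dims[1]) - 1) * vox[1]
  ay <- origin[2] + (seq_len(dims[2]) - 1) * vox[2]
  az <- origin[3] + (seq_len(dims[3]) - 1) * vox[3]
  reach <- 5 * sigma
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(ax - a$x[i]) <= reach)
    iy <- which(abs(ay - a$y[i]) <= reach)
    iz <- which(abs(az - a$z[i]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax[ix] - a$x[i])^2 / (2 * sigma^2))
    gy <- exp(-(ay[iy] - a$y[i])^2 / (2 * sigma^2))
    gz <- exp(-(az[iz] - a$z[i])^2 / (2 * sigma^2))
    grid[ix, iy, iz] <- grid[ix, iy, iz] +
      a$mass[i] * (gx %o% gy %o% gz)
  }
  density_map(grid, voxel = vox, origin = origin)
}

#' Simulate a fluorescence titration
#'
#' Draws replicate F/F0 values at each total-lipid concentration from
#' the membrane partition model ([partition_model()]) perturbed by the
#' noise model. Deterministic under the seed.
#'
#' @param k_x mole-fraction partition coefficient (> 0).
#' @param f_max saturating relative fluorescence F/F0max (>= 1).
#' @param lipid_totals total lipid concentrations (molar, >= 0).
#' @param accessible_fraction fraction of lipid accessible to the toxin
#'   (outer leaflet); default 0.6.
#' @param noise a [noise_model()]; default 2 % multiplicative.
#' @param replicates number of replicates per concentration.
#' @param seed integer seed.
#' @return object of class `titration_data`: a data.frame with columns
#'   `lipid_total`, `replicate`, `f_over_f0`, carrying
#'   `accessible_fraction` and `water_molarity` as attributes.
#' @export
simulate_titration <- function(k_x, f_max,
                               lipid_totals = seq(0, 1.6e-3, length.out = 9),
                               accessible_fraction = 0.6,
                               noise = noise_model("multiplicative-gaussian", 0.02),
                               replicates = 3L, seed = 1L) {
  if (k_x <= 0) stop("k_x must be > 0")
  if (f_max < 1) stop("f_max must be >= 1")
  if (any(lipid_totals < 0)) stop("negative lipid concentration")
  if (accessible_fraction <= 0 || accessible_fraction > 1)
    stop("accessible_fraction must be in (0, 1]")
  model <- partition_model(lipid_totals, k_x, f_max, accessible_fraction)
  vals <- .with_seed(seed, {
    unlist(lapply(seq_len(replicates), function(r) .apply_noise(model, noise)))
  })
  out <- data.frame(
    lipid_total = rep(lipid_totals, times = replicates),
    replicate = rep(seq_len(replicates), each = length(lipid_totals)),
    f_over_f0 = vals)
  attr(out, "accessible_fraction") <- accessible_fraction
  attr(out, "water_molarity") <- 55.3
  class(out) <- c("titration_data", "data.frame")
  out
}

#' Simulate an electrophysiology dose-response
#'
#' Draws normalised currents from the Hill model ([hill_model()]) plus
#' additive noise. Deterministic under the seed.
#'
#' @param k_d apparent dissociation constant (molar, > 0).
#' @param s Hill coefficient (> 0).
#' @param i_min,i_max minimal and maximal normalised current.
#' @param concentrations toxin concentrations (molar).
#' @param noise a [noise_model()]; `sd` is in response units (use
#'   `0.02 * (i_max - i_min)` for 2 % of range).
#' @param replicates independent measurements per concentration
#'   (electrophysiology dose-response points are typically means over
#'   several cells).
#' @param seed integer seed.
#' @return object of class `dose_response_data`: a data.frame with
#'   columns `concentration`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(k_d, s, i_min = 0, i_max = 1,
                                   concentrations,
                                   noise = noise_model("additive-gaussian", 0.02),
                                   replicates = 1L, seed = 1L) {
  if (k_d <= 0 || s <= 0) stop("k_d and s must be > 0")
  if (any(concentrations < 0)) stop("negative concentration")
  model <- hill_model(concentrations, k_d, s, i_min, i_max)
  vals <- .with_seed(seed, {
    unlist(lapply(seq_len(replicates), function(r)
      .apply_noise(model, noise)))
  })
  out <- data.frame(
    concentration = rep(concentrations, times = replicates),
    replicate = rep(seq_len(replicates), each = length(concentrations)),
    response = vals)
  class(out) <- c("dose_response_data", "data.frame")
  out
}

#' Perturb a structure into a synthetic ensemble
#'
#' Produces `n_models` copies of a single-model structure with
#' independent isotropic Gaussian displacements (per-component sd =
#' `amplitude`) applied to each heavy atom; hydrogens follow their
#' nearest same-residue heavy atom rigidly.
#'
#' @param structure single-model [structure3d()].
#' @param n_models number of models to generate.
#' @param amplitude displacement sd per coordinate (Angstrom), >= 0.
#' @param seed integer seed.
#' @return multi-model [structure3d()].
#' @export
perturb_ensemble <- function(structure, n_models, amplitude, seed = 1L) {
  stopifnot(inherits(structure, "structure3d"))
  if (structure$models != 1L) stop("input must be single-model")
  if (n_models < 1L) stop("n_models must be >= 1")
  if (amplitude < 0) stop("amplitude must be >= 0")
  a <- structure$atoms
  heavy <- which(a$element != "H")
  # map each hydrogen to its nearest heavy atom within the same residue
  parent <- integer(nrow(a))
  parent[heavy] <- heavy
  for (i in which(a$element == "H")) {
    cand <- heavy[a$res_seq[heavy] == a$res_seq[i] &
                    a$chain_id[heavy] == a$chain_id[i]]
    if (!length(cand)) cand <- heavy
    d2 <- (a$x[cand] - a$x[i])^2 + (a$y[cand] - a$y[i])^2 +
      (a$z[cand] - a$z[i])^2
    parent[i] <- cand[which.min(d2)]
  }
  disp <- .with_seed(seed,
                     array(stats::rnorm(length(heavy) * 3 * n_models,
                                        0, amplitude),
                           dim = c(length(heavy), 3, n_models)))
  models <- vector("list", n_models)
  heavy_index <- match(seq_len(nrow(a)), heavy)  # NA for hydrogens
  for (m in seq_len(n_models)) {
    b <- a
    src <- heavy_index[parent]                   # per-atom row into disp
    b$x <- a$x + disp[src, 1, m]
    b$y <- a$y + disp[src, 2, m]
    b$z <- a$z + disp[src, 3, m]
    b$model_id <- m
    models[[m]] <- b
  }
  structure3d(do.call(rbind, models), title = structure$title)
}
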
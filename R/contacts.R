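# Backbone heavy-atom names excluded by sidechain-only analyses
# (CB is counted as side chain).
.BACKBONE_NAMES <- c("N", "CA", "C", "O")

# Cell-list neighbour counting. Returns the index pairs (i into A, j
# into B) whose Euclidean distance is <= cutoff (inclusive). Atoms are
# binned into cubic cells of edge `cutoff`; only the 27 neighbouring
# cells of each occupied A-cell are examined.
.pairs_within <- function(ax, bx, cutoff) {
  na <- nrow(ax); nb <- nrow(bx)
  if (na == 0L || nb == 0L)
    return(list(i = integer(0), j = integer(0)))
  orig <- pmin(apply(ax, 2, min), apply(bx, 2, min))
  cell_of <- function(m) floor(sweep(m, 2, orig) / cutoff)
  ca <- cell_of(ax); cb <- cell_of(bx)
  key <- function(cm) paste(cm[, 1], cm[, 2], cm[, 3], sep = ",")
  b_bins <- split(seq_len(nb), key(cb))
  ka <- key(ca)
  out_i <- vector("list", na); out_j <- vector("list", na)
  cut2 <- cutoff^2
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(na)) {
    neigh_keys <- paste(ca[i, 1] + offsets[, 1], ca[i, 2] + offsets[, 2],
                        ca[i, 3] + offsets[, 3], sep = ",")
    js <- unlist(b_bins[neigh_keys], use.names = FALSE)
    if (is.null(js) || !length(js)) next
    d2 <- (bx[js, 1] - ax[i, 1])^2 + (bx[js, 2] - ax[i, 2])^2 +
      (bx[js, 3] - ax[i, 3])^2
    hit <- js[d2 <= cut2]
    if (length(hit)) {
      out_i[[i]] <- rep.int(i, length(hit))
      out_j[[i]] <- hit
    }
  }
  list(i = unlist(out_i, use.names = FALSE),
       j = unlist(out_j, use.names = FALSE))
}

.coords <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

#' Count contacting atom pairs between two groups
#'
#' The contact statistic Np: the number of unordered heavy-atom pairs
#' (one atom from each group) within `cutoff` Angstrom, the pair-count
#' form of the pair-distance distribution integrated over the first
#' interaction shell. Hydrogens are excluded; the cutoff is inclusive
#' (a pair at exactly the cutoff counts). The production path uses a
#' cell-list neighbour search.
#'
#' @param atoms_a,atoms_b atom data.frames (rows of a structure's atom
#'   table); the groups must be disjoint.
#' @param cutoff contact distance in Angstrom (default 6).
#' @return integer pair count.
#' @export
np_pairs <- function(atoms_a, atoms_b, cutoff = 6) {
  key_a <- paste(atoms_a$model_id, atoms_a$serial)
  key_b <- paste(atoms_b$model_id, atoms_b$serial)
  if (length(intersect(key_a, key_b)))
    stop("atom groups overlap: Np is defined for disjoint groups")
  ha <- atoms_a[atoms_a$element != "H", , drop = FALSE]
  hb <- atoms_b[atoms_b$element != "H", , drop = FALSE]
  if (nrow(ha) == 0L || nrow(hb) == 0L) {
    warning("empty heavy-atom group: Np = 0")
    return(0L)
  }
  p <- .pairs_within(.coords(ha), .coords(hb), cutoff)
  length(p$i)
}

# Per-frame atom tables of a multi-model structure after selection.
.frames_of <- function(structure, sel) {
  a <- .apply_selection(structure$atoms, sel)
  if (nrow(a) == 0L) stop("selection resolves to no atoms")
  split(a, a$model_id)
}

# Consistent residue roster across frames or error.
.check_roster <- function(frames, what) {
  ref <- paste(frames[[1]]$serial, collapse = ",")
  for (f in frames)
    if (!identical(paste(f$serial, collapse = ","), ref))
      stop(what, " resolves to different atom sets across frames")
}

#' Residue-residue contact matrix averaged over frames
#'
#' Entry (i, j) is the mean over models/frames of [np_pairs()] between
#' residue i of selection A and residue j of selection B. With
#' `sidechain_only`, backbone atoms N, CA, C and O are excluded from
#' both sides. Row and column totals (per-residue Np against the whole
#' partner selection) are returned alongside.
#'
#' @param frames multi-model [structure3d()] (one model = one frame).
#' @param sel_a,sel_b selection lists (see [atom_select()] fields:
#'   `chain`, `resno`, `resname`, `elety`, `element`).
#' @param cutoff contact cutoff (Angstrom).
#' @param sidechain_only drop backbone atoms N, CA, C, O.
#' @return object of class `contact_matrix`: list with `matrix` (rows =
#'   residues of A, cols = residues of B), `row_totals`, `col_totals`,
#'   `n_frames`.
#' @export
residue_contact_matrix <- function(frames, sel_a, sel_b, cutoff = 6,
                                   sidechain_only = FALSE) {
  stopifnot(inherits(frames, "structure3d"))
  fa <- .frames_of(frames, sel_a)
  fb <- .frames_of(frames, sel_b)
  .check_roster(fa, "sel_a"); .check_roster(fb, "sel_b")
  strip <- function(at) {
    at <- at[at$element != "H", , drop = FALSE]
    if (sidechain_only)
      at <- at[!at$name %in% .BACKBONE_NAMES, , drop = FALSE]
    at
  }
  labs_a <- unique(.residue_label(strip(fa[[1]])))
  labs_b <- unique(.residue_label(strip(fb[[1]])))
  acc <- matrix(0, length(labs_a), length(labs_b),
                dimnames = list(labs_a, labs_b))
  nf <- length(fa)
  for (k in seq_len(nf)) {
    aa <- strip(fa[[k]]); bb <- strip(fb[[k]])
    if (nrow(aa) == 0L || nrow(bb) == 0L) next
    p <- .pairs_within(.coords(aa), .coords(bb), cutoff)
    if (!length(p$i)) next
    la <- .residue_label(aa)[p$i]
    lb <- .residue_label(bb)[p$j]
    tab <- table(factor(la, levels = labs_a), factor(lb, levels = labs_b))
    acc <- acc + unclass(tab)
  }
  m <- acc / nf
  out <- list(matrix = m, row_totals = rowSums(m), col_totals = colSums(m),
              n_frames = nf, cutoff = cutoff,
              sidechain_only = sidechain_only)
  class(out) <- "contact_matrix"
  out
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d residues, %d frame(s), cutoff %g A\n",
              nrow(x$matrix), ncol(x$matrix), x$n_frames, x$cutoff))
  invisible(x)
}

#' Per-residue lipid head/tail contact profile
#'
#' For each protein residue, the mean Np against all lipid head-group
#' atoms and all tail atoms, separately — the per-residue membrane
#' contact fingerprint of a protein sitting on a bilayer.
#'
#' @param frames multi-model [structure3d()] containing both protein and
#'   lipids.
#' @param protein_sel selection list for the protein residues.
#' @param head_res,tail_res residue-name sets labelling head-group and
#'   tail atoms; must be disjoint.
#' @param cutoff contact cutoff (Angstrom).
#' @return data.frame with columns `residue`, `np_head`, `np_tail`.
#' @export
lipid_contact_profile <- function(frames, protein_sel,
                                  head_res = "HEA", tail_res = "TAI",
                                  cutoff = 6) {
  if (length(intersect(head_res, tail_res)))
    stop("head_res and tail_res must be disjoint")
  m_head <- residue_contact_matrix(frames, protein_sel,
                                   list(resname = head_res), cutoff)
  m_tail <- residue_contact_matrix(frames, protein_sel,
                                   list(resname = tail_res), cutoff)
  stopifnot(identical(names(m_head$row_totals), names(m_tail$row_totals)))
  data.frame(residue = names(m_head$row_totals),
             np_head = unname(m_head$row_totals),
             np_tail = unname(m_tail$row_totals))
}

#' Side-chain compactness of a residue cluster
#'
#' For each member residue, the mean over frames of Np between its
#' side-chain heavy atoms and the union of all other members' side-chain
#' heavy atoms. Fewer contacts imply a less compact cluster with greater
#' solvent exposure.
#'
#' @param frames multi-model [structure3d()].
#' @param members list of selection lists, one per member residue (each
#'   must resolve to a single residue).
#' @param cutoff contact cutoff (Angstrom).
#' @return data.frame with columns `residue`, `np_mean`.
#' @export
cluster_compactness <- function(frames, members, cutoff = 6) {
  if (length(members) < 2L) stop("need >= 2 member residues")
  sidechain <- function(at)
    at[at$element != "H" & !at$name %in% .BACKBONE_NAMES, , drop = FALSE]
  per_member <- lapply(members, function(sel) {
    f <- .frames_of(frames, sel)
    .check_roster(f, "member selection")
    lapply(f, sidechain)
  })
  labels <- vapply(per_member, function(f) {
    at <- f[[1]]
    if (nrow(at) == 0L) return(NA_character_)
    unique(.residue_label(at))[1]
  }, character(1))
  nf <- length(per_member[[1]])
  vals <- numeric(length(members))
  for (i in seq_along(members)) {
    if (nrow(per_member[[i]][[1]]) == 0L) {
      message("member ", i, " has no side-chain heavy atoms; Np = 0")
      vals[i] <- 0
      next
    }
    tot <- 0
    for (k in seq_len(nf)) {
      others <- do.call(rbind, lapply(per_member[-i], `[[`, k))
      if (nrow(others) == 0L) next
      p <- .pairs_within(.coords(per_member[[i]][[k]]),
                         .coords(others), cutoff)
      tot <- tot + length(p$i)
    }
    vals[i] <- tot / nf
  }
  data.frame(residue = labels, np_mean = vals)
}

#' Mean number of partner residues in contact with a query residue
#'
#' The mean over frames of the count of partner residues having at
#' least one heavy atom within `cutoff` of at least one heavy atom of
#' the query residue.
#'
#' @param frames multi-model [structure3d()].
#' @param query_res selection list resolving to one residue per frame.
#' @param partner_sel selection list for the partner residues.
#' @param cutoff contact cutoff (Angstrom).
#' @return mean residue-neighbour count (real).
#' @export
neighbor_residue_count <- function(frames, query_res, partner_sel,
                                   cutoff = 6) {
  fq <- .frames_of(frames, query_res)
  .check_roster(fq, "query_res")
  if (length(unique(.residue_label(fq[[1]]))) != 1L)
    stop("query_res must resolve to exactly one residue")
  fp <- tryCatch(.frames_of(frames, partner_sel), error = function(e) NULL)
  if (is.null(fp)) {
    warning("empty partner selection: count = 0")
    return(0)
  }
  .check_roster(fp, "partner_sel")
  nf <- length(fq)
  tot <- 0
  for (k in seq_len(nf)) {
    q <- fq[[k]][fq[[k]]$element != "H", , drop = FALSE]
    p <- fp[[k]][fp[[k]]$element != "H", , drop = FALSE]
    if (nrow(q) == 0L || nrow(p) == 0L) next
    hits <- .pairs_within(.coords(q), .coords(p), cutoff)
    tot <- tot + length(unique(.residue_label(p)[hits$j]))
  }
  tot / nf
}
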
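#' @keywords internal
"_PACKAGE"

# Atomic masses (amu) for the elements the pipeline handles.  Lookup is
# total: any other symbol is an error, never a silent default.
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)

# Bondi-like van der Waals radii (Angstrom) used by the SASA routines.
.VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Atomic mass lookup
#'
#' Resolve one or more element symbols to atomic masses (amu). The table
#' covers H, C, N, O, S and P; any other symbol raises an error so that a
#' mistyped element can never silently acquire a default mass.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
#' @examples
#' element_mass(c("C", "N"))
element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .ATOMIC_MASS[el]
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Construct a coordinate structure
#'
#' A `structure3d` is the shared coordinate container of the package: an
#' atom table (one row per atom per model) plus a model count and a title.
#' Multi-model objects (NMR ensembles, trajectory frames) carry the same
#' atom roster in every model, ordered by `(model_id, serial)`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `mass`, `res_name`, `res_seq`, `chain_id`, `x`, `y`, `z`, `model_id`.
#' @param title free-text title.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, title = "") {
  req <- c("serial", "name", "element", "mass", "res_name", "res_seq",
           "chain_id", "x", "y", "z", "model_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty atom table")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (any(atoms$mass <= 0)) stop("non-positive atomic mass")
  atoms <- atoms[order(atoms$model_id, atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  models <- sort(unique(atoms$model_id))
  if (length(models) > 1L) {
    ref <- atoms[atoms$model_id == models[1L],
                 c("serial", "name", "res_name", "res_seq", "chain_id")]
    for (m in models[-1L]) {
      cur <- atoms[atoms$model_id == m,
                   c("serial", "name", "res_name", "res_seq", "chain_id")]
      if (!identical(unname(as.list(ref)), unname(as.list(cur))))
        stop("model ", m, " does not share the atom roster of model ",
             models[1L])
    }
  }
  out <- list(atoms = atoms, models = length(models), title = title)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  natom <- nrow(x$atoms) / x$models
  cat(sprintf("<structure3d> %d atoms x %d model(s)", natom, x$models))
  if (nzchar(x$title)) cat(" : ", x$title, sep = "")
  cat("\n")
  invisible(x)
}

#' Extract one model from a multi-model structure
#'
#' @param structure a [structure3d()].
#' @param model_id model index (1-based).
#' @return single-model `structure3d`.
#' @export
get_model <- function(structure, model_id) {
  stopifnot(inherits(structure, "structure3d"))
  sub <- structure$atoms[structure$atoms$model_id == model_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no model with id ", model_id)
  sub$model_id <- 1L
  structure3d(sub, title = structure$title)
}

#' Select atoms from a structure
#'
#' Lightweight attribute-based selection. All supplied criteria are
#' combined with AND; `NULL` criteria are ignored. Returns the matching
#' rows of the atom table (all models).
#'
#' @param structure a [structure3d()].
#' @param chain chain id(s).
#' @param resno residue number(s).
#' @param resname residue name(s), e.g. `"HEA"`.
#' @param elety atom name(s), e.g. `"CA"`.
#' @param element element symbol(s).
#' @param heavy if `TRUE`, drop hydrogens.
#' @return data.frame of matching atom rows.
#' @export
atom_select <- function(structure, chain = NULL, resno = NULL,
                        resname = NULL, elety = NULL, element = NULL,
                        heavy = FALSE) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain_id %in% chain
  if (!is.null(resno))   keep <- keep & a$res_seq %in% resno
  if (!is.null(resname)) keep <- keep & a$res_name %in% resname
  if (!is.null(elety))   keep <- keep & a$name %in% elety
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (heavy)             keep <- keep & a$element != "H"
  a[keep, , drop = FALSE]
}

# Apply a named selection list (chain/resno/resname/elety/element) to an
# atom data.frame; used by the contact and ensemble modules.
.apply_selection <- function(atoms, sel) {
  if (is.null(sel)) return(atoms)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain))   keep <- keep & atoms$chain_id %in% sel$chain
  if (!is.null(sel$resno))   keep <- keep & atoms$res_seq %in% sel$resno
  if (!is.null(sel$resname)) keep <- keep & atoms$res_name %in% sel$resname
  if (!is.null(sel$elety))   keep <- keep & atoms$name %in% sel$elety
  if (!is.null(sel$element)) keep <- keep & atoms$element %in% sel$element
  atoms[keep, , drop = FALSE]
}

# Residue label "chain:resseq:resname" used in contact-matrix outputs.
.residue_label <- function(atoms) {
  paste0(atoms$chain_id, ":", atoms$res_seq, ":", atoms$res_name)
}

# Evaluate code under a temporary RNG seed, restoring any prior
# .Random.seed afterwards so generators behave as pure functions.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
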
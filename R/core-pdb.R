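#' Parse PDB-format text into a structure
#'
#' Reads fixed-width ATOM/HETATM records, honouring MODEL/ENDMDL blocks.
#' The element is taken from columns 77-78 when present, otherwise
#' inferred from the atom name (first alphabetic character of the trimmed
#' name; leading digits of four-character hydrogen names are skipped).
#' Single-model files get `model_id = 1`. Insertion codes are not
#' supported and raise an error.
#'
#' @param text character scalar (whole file) or vector of lines, or a
#'   file path to read.
#' @return a [structure3d()].
#' @export
#' @examples
#' s <- parse_pdb("ATOM      1  CA  ALA A   1       0.000   0.000   0.000")
#' s$atoms$element
parse_pdb <- function(text) {
  lines <- .as_lines(text)
  model <- 0L
  in_model <- FALSE
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      model <- model + 1L
      in_model <- TRUE
    } else if (startsWith(rec, "ENDMDL")) {
      in_model <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (nchar(ln) < 54)
        stop("malformed ATOM/HETATM record (too short) at line ", i)
      serial  <- suppressWarnings(as.integer(substr(ln, 7, 11)))
      name    <- trimws(substr(ln, 13, 16))
      icode   <- substr(ln, 27, 27)
      res_name <- trimws(substr(ln, 18, 20))
      chain_id <- substr(ln, 22, 22)
      res_seq <- suppressWarnings(as.integer(substr(ln, 23, 26)))
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (is.na(serial) || is.na(res_seq) || is.na(x) || is.na(y) || is.na(z))
        stop("malformed fixed-width field in ATOM/HETATM record at line ", i)
      if (!icode %in% c(" ", ""))
        stop("insertion codes are not supported (line ", i, ")")
      element <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
      if (!nzchar(element)) element <- .element_from_name(name)
      mass <- element_mass(element)  # errors on unknown symbols
      n <- n + 1L
      rows[[n]] <- list(serial = serial, name = name,
                        element = toupper(element), mass = mass,
                        res_name = res_name, res_seq = res_seq,
                        chain_id = chain_id, x = x, y = y, z = z,
                        model_id = if (model > 0L && in_model) model else
                          max(model, 1L))
    }
  }
  if (n == 0L) stop("no ATOM/HETATM records found")
  atoms <- do.call(rbind, lapply(rows[seq_len(n)], as.data.frame))
  structure3d(atoms)
}

# Infer element from a PDB atom name: skip leading digits (e.g. "1HB"),
# then take the first alphabetic character. Two-letter element symbols
# are not needed for the residue chemistry handled here.
.element_from_name <- function(name) {
  chars <- strsplit(name, "")[[1]]
  alpha <- chars[grepl("[A-Za-z]", chars)]
  if (!length(alpha)) stop("cannot infer element from atom name '", name, "'")
  toupper(alpha[1])
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

#' Write a structure as PDB-format text
#'
#' Fixed-width records with coordinates printed to 3 decimals;
#' multi-model structures are wrapped in MODEL/ENDMDL blocks. Hybrid-36
#' numbering is not supported: residue numbers above 9999 or serials
#' above 99999 are an error.
#'
#' @param structure a [structure3d()].
#' @param file optional path; when given the text is also written there.
#' @return character scalar of PDB text (invisibly when `file` is set).
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms
  if (any(a$serial > 99999L)) stop("atom serial > 99999: no hybrid-36 support")
  if (any(a$res_seq > 9999L)) stop("residue number > 9999: no hybrid-36 support")
  fmt_atom <- function(r) {
    # names shorter than 4 characters start in column 14 (PDB convention)
    nm <- if (nchar(r$name) >= 4L) substr(r$name, 1, 4) else
      sprintf(" %-3s", r$name)
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            r$serial, nm, r$res_name, r$chain_id, r$res_seq,
            r$x, r$y, r$z, r$element)
  }
  out <- character(0)
  models <- sort(unique(a$model_id))
  multi <- length(models) > 1L
  for (m in models) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    sub <- a[a$model_id == m, , drop = FALSE]
    out <- c(out, vapply(seq_len(nrow(sub)),
                         function(i) fmt_atom(sub[i, ]), character(1)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(txt))
  }
  txt
}
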
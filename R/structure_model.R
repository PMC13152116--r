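#' @importFrom stats rexp rnorm runif optim setNames
#' @importFrom utils read.delim write.table head tail
NULL

# wwPDB v3.3 fixed columns for ATOM/HETATM records
.pdb_cols <- list(
  record  = c(1L, 6L),  serial = c(7L, 11L), name  = c(13L, 16L),
  altloc  = c(17L, 17L), resname = c(18L, 20L), chain = c(22L, 22L),
  resno   = c(23L, 26L), icode  = c(27L, 27L),
  x = c(31L, 38L), y = c(39L, 46L), z = c(47L, 54L),
  occ = c(55L, 60L), bfac = c(61L, 66L), element = c(77L, 78L)
)

.substr_trim <- function(lines, span) {
  trimws(substr(lines, span[1], span[2]))
}

.infer_element <- function(name) {
  # strip digits/primes, first alphabetic character(s); two-letter elements
  # (FE, ZN, ...) are rare in our inputs so first letter is the default
  el <- sub("^[0-9' ]*", "", name)
  toupper(substr(el, 1, 1))
}

.atom_lines_to_df <- function(lines, water_names) {
  rec <- .substr_trim(lines, .pdb_cols$record)
  keep <- rec %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  rec <- rec[keep]
  if (length(lines) == 0L) return(NULL)
  name <- .substr_trim(lines, .pdb_cols$name)
  resname <- .substr_trim(lines, .pdb_cols$resname)
  element <- .substr_trim(lines, .pdb_cols$element)
  blank <- element == ""
  element[blank] <- .infer_element(name[blank])
  is_water <- resname %in% water_names
  record_class <- ifelse(is_water, "water",
                         ifelse(rec == "HETATM", "ligand", "polymer"))
  df <- data.frame(
    id = as.integer(.substr_trim(lines, .pdb_cols$serial)),
    name = name,
    element = element,
    chain = substr(lines, .pdb_cols$chain[1], .pdb_cols$chain[2]),
    resno = as.integer(.substr_trim(lines, .pdb_cols$resno)),
    icode = .substr_trim(lines, .pdb_cols$icode),
    resname = resname,
    record_class = record_class,
    x = as.numeric(.substr_trim(lines, .pdb_cols$x)),
    y = as.numeric(.substr_trim(lines, .pdb_cols$y)),
    z = as.numeric(.substr_trim(lines, .pdb_cols$z)),
    generic = NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) ||
      any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z)))
    stop("non-finite or unparsable coordinates in input")
  df
}

#' Parse a single-model PDB file into a numbered structure
#'
#' Reads ATOM/HETATM records (wwPDB v3.3 columns) and partitions atoms into
#' polymer, ligand and water record classes.  Water residues are recognised
#' by residue name (default `HOH`, `WAT`; configurable).  Multi-model files
#' are rejected here: use [read_trajectory()] for those.
#'
#' @param path Path to a PDB file.
#' @param dialect PDB dialect tag; only `"pdb"` (wwPDB v3.3 columns) is
#'   currently understood.
#' @param water_names Character vector of residue names treated as water.
#' @return An object of class `hydronet_structure`: a list with elements
#'   `atoms` (a data frame with one row per atom: id, name, element, chain,
#'   resno, icode, resname, record_class, x, y, z, generic) and `metadata`.
#' @export
#' @examples
#' p <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
#'   "END"), p)
#' s <- parse_structure(p)
#' nrow(s$atoms)
parse_structure <- function(path, dialect = "pdb",
                            water_names = c("HOH", "WAT")) {
  if (!identical(dialect, "pdb"))
    stop("unknown PDB dialect: ", dialect)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  n_models <- sum(startsWith(lines, "MODEL"))
  if (n_models > 1L)
    stop("multi-model input: this is a trajectory; use read_trajectory()")
  atoms <- .atom_lines_to_df(lines, water_names)
  if (is.null(atoms))
    stop("empty structure: no ATOM/HETATM records in ", path)
  structure(
    list(atoms = atoms,
         metadata = list(source = path, dialect = dialect,
                         water_names = water_names)),
    class = "hydronet_structure")
}

#' @export
print.hydronet_structure <- function(x, ...) {
  a <- x$atoms
  cat("hydronet_structure:", nrow(a), "atoms,",
      nrow(unique(a[a$record_class == "polymer", c("chain", "resno", "icode")])),
      "polymer residues,", sum(a$record_class == "water"), "water atoms,",
      sum(a$record_class == "ligand"), "ligand atoms\n")
  ng <- sum(!is.na(unique(a[, c("chain", "resno", "icode", "generic")])$generic))
  cat("  generic numbers assigned:", ng, "\n")
  invisible(x)
}

#' Water oxygen positions of a structure
#'
#' @param structure A `hydronet_structure`.
#' @return Data frame of water oxygen atoms (one per water molecule).
#' @export
structure_waters <- function(structure) {
  a <- structure$atoms
  a[a$record_class == "water" & a$element == "O", , drop = FALSE]
}

#' Ligand (non-water HETATM) atoms of a structure
#' @param structure A `hydronet_structure`.
#' @export
ligand_atoms <- function(structure) {
  a <- structure$atoms
  a[a$record_class == "ligand", , drop = FALSE]
}

#' One-row-per-residue summary of a structure
#'
#' @param structure A `hydronet_structure`.
#' @return Data frame with chain, resno, icode, resname, record_class and
#'   generic number per residue, in file order.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  out <- a[first, c("chain", "resno", "icode", "resname",
                    "record_class", "generic")]
  rownames(out) <- NULL
  out
}

#' Attach Ballesteros-Weinstein generic numbers from a mapping table
#'
#' The mapping is the single source of truth for generic numbering; no
#' renumbering heuristics are applied.  Mapping rows whose (chain, author
#' number) key is absent from the structure are skipped with a warning.
#'
#' @param structure A `hydronet_structure`.
#' @param mapping Data frame with columns `chain`, `author_number`,
#'   `generic_number` (strings of the form `"x.yy"`), or a path to a TSV
#'   file with those columns.
#' @return The structure with `generic` filled in on every atom of each
#'   mapped residue.  The number of labels applied is stored in
#'   `metadata$n_generic_assigned`.
#' @export
assign_generic_numbers <- function(structure, mapping) {
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_mapping(mapping)
  stopifnot(all(c("chain", "author_number", "generic_number") %in%
                  names(mapping)))
  if (nrow(mapping) == 0L) {
    structure$metadata$n_generic_assigned <- 0L
    return(structure)
  }
  bad <- !grepl("^[0-9]+\\.[0-9]{2}$", mapping$generic_number)
  if (any(bad))
    stop("malformed generic number(s): ",
         paste(unique(mapping$generic_number[bad]), collapse = ", "))
  dup <- duplicated(mapping[, c("chain", "generic_number")])
  if (any(dup))
    stop("conflict: generic number assigned to two residues of one chain: ",
         paste(unique(mapping$generic_number[dup]), collapse = ", "))
  a <- structure$atoms
  akey <- paste(a$chain, a$resno)
  mkey <- paste(mapping$chain, mapping$author_number)
  missing <- !(mkey %in% akey)
  if (any(missing))
    warning("mapping keys absent from structure, skipped: ",
            paste(mkey[missing], collapse = ", "))
  idx <- match(akey, mkey)
  hit <- !is.na(idx)
  a$generic[hit] <- mapping$generic_number[idx[hit]]
  structure$atoms <- a
  structure$metadata$n_generic_assigned <- sum(!missing)
  structure
}

#' Read a residue-to-generic-number mapping TSV
#'
#' Expected header: `chain  author_number  generic_number`.
#' @param path TSV path.
#' @export
read_mapping <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chain = "character",
                                 generic_number = "character"))
  stopifnot(all(c("chain", "author_number", "generic_number") %in% names(m)))
  m
}

#' Write the one-row-per-residue structure summary as TSV
#' @param structure A `hydronet_structure`.
#' @param path Output TSV path.
#' @export
write_structure_summary <- function(structure, path) {
  write.table(residue_table(structure), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fmt_pdb_atom <- function(a, serial) {
  rec <- ifelse(a$record_class == "polymer", "ATOM  ", "HETATM")
  name <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                 sprintf(" %-3s", a$name))
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, "", a$resname, a$chain, a$resno,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, 1, 0, a$element)
}

#' Write a structure back to single-model PDB
#'
#' Round-trips atom count, residue keys and coordinates at the format's
#' 3-decimal precision.
#' @param structure A `hydronet_structure`.
#' @param path Output path.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  lines <- .fmt_pdb_atom(a, seq_len(nrow(a)))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a structure object from an atom data frame
#'
#' Convenience constructor for programmatic structures.  Required columns:
#' name, element, chain, resno, x, y, z; `icode`, `resname`,
#' `record_class`, `id` and `generic` are filled with defaults when
#' absent.
#' @param atoms Data frame of atoms.
#' @param water_names Residue names treated as water.
#' @export
as_hydronet_structure <- function(atoms, water_names = c("HOH", "WAT")) {
  req <- c("name", "element", "chain", "resno", "x", "y", "z")
  stopifnot(all(req %in% names(atoms)))
  if (is.null(atoms$icode)) atoms$icode <- rep("", nrow(atoms))
  if (is.null(atoms$resname)) atoms$resname <- rep("ALA", nrow(atoms))
  if (is.null(atoms$record_class))
    atoms$record_class <- ifelse(atoms$resname %in% water_names,
                                 "water", "polymer")
  if (is.null(atoms$id)) atoms$id <- seq_len(nrow(atoms))
  if (is.null(atoms$generic)) atoms$generic <- rep(NA_character_, nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 metadata = list(source = "in-memory", dialect = "pdb",
                                 water_names = water_names)),
            class = "hydronet_structure")
}

# ---- superposition ---------------------------------------------------------

.as_points <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("point set must be an n x 3 matrix")
  x
}

#' Weighted least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the weighted RMSD between
#' two equally sized point sets.  The degenerate reflection case is resolved
#' by sign-correction of the smallest singular direction, so the returned
#' rotation is always proper (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), n >= 3.
#' @param weights Optional non-negative per-point weights.
#' @return `hydronet_superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3) and `rmsd` (Angstrom, after transformation).
#'   The fitted transform maps `mobile` onto `reference` as
#'   `mobile %*% t(rotation) + translation`.
#' @export
superpose_kabsch <- function(mobile, reference, weights = NULL) {
  m <- .as_points(mobile); r <- .as_points(reference)
  if (nrow(m) != nrow(r)) stop("point-set size mismatch")
  n <- nrow(m)
  if (n < 3L) stop("at least 3 points required for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(m * w); cr <- colSums(r * w)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  h <- t(mc * w) %*% rc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- m %*% t(rot) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "hydronet_superposition")
}

#' Apply a fitted superposition to a coordinate matrix
#' @param points n x 3 matrix.
#' @param sp A `hydronet_superposition`.
#' @export
apply_superposition <- function(points, sp) {
  p <- .as_points(points)
  p %*% t(sp$rotation) + matrix(sp$translation, nrow(p), 3, byrow = TRUE)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a selection against a reference structure
#'
#' Computes one RMSD value per trajectory frame over a residue/atom
#' selection, with optional per-frame least-squares superposition on a
#' (possibly different) alignment selection before measuring.
#'
#' @param trajectory A `hydronet_trajectory` (see [read_trajectory()]).
#' @param reference A `hydronet_structure` with the same atom order as the
#'   trajectory topology.
#' @param selection Logical or integer vector over the topology atoms, or a
#'   predicate `function(atoms_df)` returning one.  Defaults to Calpha atoms.
#' @param superpose Superpose each frame on the alignment selection first.
#' @param align_selection Selection used for superposition (defaults to
#'   `selection`).
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
residue_rmsd_series <- function(trajectory, reference, selection = NULL,
                                superpose = TRUE, align_selection = NULL) {
  atoms <- trajectory$atoms
  sel <- .resolve_selection(selection, atoms)
  if (length(sel) == 0L) stop("empty selection")
  if (nrow(reference$atoms) != nrow(atoms))
    stop("atom-count mismatch between trajectory topology and reference")
  ref <- as.matrix(reference$atoms[, c("x", "y", "z")])
  asel <- if (is.null(align_selection)) sel
          else .resolve_selection(align_selection, atoms)
  nf <- trajectory$n_frames
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- trajectory$coords[, , f]
    if (superpose) {
      sp <- superpose_kabsch(fr[asel, , drop = FALSE],
                             ref[asel, , drop = FALSE])
      fr <- apply_superposition(fr, sp)
    }
    out[f] <- .rmsd(fr[sel, , drop = FALSE], ref[sel, , drop = FALSE])
  }
  out
}

.resolve_selection <- function(selection, atoms) {
  if (is.null(selection)) {
    sel <- which(atoms$name == "CA" & atoms$record_class == "polymer")
  } else if (is.function(selection)) {
    sel <- which(selection(atoms))
  } else if (is.logical(selection)) {
    sel <- which(selection)
  } else {
    sel <- as.integer(selection)
  }
  sel
}
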
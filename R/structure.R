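## Core containers: Structure (atoms + coordinates), Trajectory (frames
## over one topology), Alignment (gapped sequences). Plain S3 built on a
## data.frame of atoms plus an n x 3 coordinate matrix, in Angstrom.

#' Construct a Structure
#'
#' The topology object used throughout the package: an ordered atom table
#' plus an `n x 3` coordinate matrix in Angstrom. Residues are identified
#' by `(chain, res_id)` with PDB-style 1-based numbering; no renumbering
#' is ever performed.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `chain`, and optionally `charge`, `radius`,
#'   `hydrophobicity`. Missing optional columns are added as `NA`
#'   (radius is defaulted from the element's van der Waals radius).
#' @param xyz numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @return object of class `Structure`.
#' @export
Structure <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(atoms) == nrow(xyz))
  req <- c("serial", "name", "element", "res_name", "res_id", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  if (any(atoms$res_id < 1))
    stop("res_id must be >= 1 (PDB-style numbering)")
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  bad_r <- !is.na(atoms$radius) & atoms$radius <= 0
  if (any(bad_r)) stop("atom radius must be > 0 when present")
  atoms$radius <- ifelse(is.na(atoms$radius),
                         vdw_radius(atoms$element), atoms$radius)
  if (!"hydrophobicity" %in% names(atoms)) atoms$hydrophobicity <- NA_real_
  atoms$element <- toupper(atoms$element)
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$res_id))
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), length(res), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory topology
#' @param x Structure or Trajectory.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Coordinates of a Structure (or one Trajectory frame)
#'
#' @param x Structure or Trajectory.
#' @param frame frame index when `x` is a Trajectory.
#' @return `n x 3` numeric matrix (Angstrom).
#' @export
coords <- function(x, frame = NULL) {
  if (inherits(x, "Trajectory")) {
    if (is.null(frame)) stop("frame index required for a Trajectory")
    return(x$frames[[frame]])
  }
  x$xyz
}

#' Replace the coordinates of a Structure
#' @param structure Structure.
#' @param xyz replacement `n x 3` matrix.
#' @return Structure with new coordinates.
#' @export
with_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms))
  structure$xyz <- as.matrix(xyz)
  dimnames(structure$xyz) <- list(NULL, c("x", "y", "z"))
  structure
}

#' Select atoms by attribute
#'
#' All given filters are combined with AND; each may be a vector
#' (membership test). Returns integer atom indices in file order, so a
#' selection is stable under write/read round-trips.
#'
#' @param structure Structure.
#' @param chain,res_id,res_name,name,element optional filters.
#' @param heavy if TRUE, drop hydrogens (element H or D).
#' @param water one of `NA` (ignore), `TRUE` (waters only), `FALSE`
#'   (exclude waters); water residues are those in [water_resnames()].
#' @return integer vector of atom indices (possibly empty).
#' @export
atom_select <- function(structure, chain = NULL, res_id = NULL,
                        res_name = NULL, name = NULL, element = NULL,
                        heavy = FALSE, water = NA) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))    keep <- keep & a$chain %in% chain
  if (!is.null(res_id))   keep <- keep & a$res_id %in% res_id
  if (!is.null(res_name)) keep <- keep & toupper(a$res_name) %in% toupper(res_name)
  if (!is.null(name))     keep <- keep & a$name %in% name
  if (!is.null(element))  keep <- keep & a$element %in% toupper(element)
  if (isTRUE(heavy))      keep <- keep & !(a$element %in% c("H", "D"))
  if (!is.na(water)) {
    is_w <- toupper(a$res_name) %in% water_resnames()
    keep <- keep & (if (isTRUE(water)) is_w else !is_w)
  }
  which(keep)
}

#' Residue table of a Structure
#'
#' @param structure Structure.
#' @param indices optional atom indices to restrict to.
#' @return data.frame with one row per residue: `chain`, `res_id`,
#'   `res_name`, in first-occurrence order.
#' @export
residue_table <- function(structure, indices = NULL) {
  a <- structure$atoms
  if (!is.null(indices)) a <- a[indices, , drop = FALSE]
  key <- paste(a$chain, a$res_id, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], res_id = a$res_id[first],
             res_name = a$res_name[first], stringsAsFactors = FALSE)
}

# integer residue id per atom (first-occurrence order); internal
.residue_of_atom <- function(structure) {
  key <- paste(structure$atoms$chain, structure$atoms$res_id, sep = "|")
  match(key, unique(key))
}

#' Construct a Trajectory
#'
#' @param topology Structure shared by all frames.
#' @param frames list of `n x 3` coordinate matrices, one per frame.
#' @param frame_interval nanoseconds between stored frames (metadata
#'   only; no analysis depends on it).
#' @return object of class `Trajectory`.
#' @export
Trajectory <- function(topology, frames, frame_interval = NA_real_) {
  stopifnot(inherits(topology, "Structure"), length(frames) >= 1)
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("frame ", i, " has ", NROW(f), " atoms; topology has ", n)
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param trajectory Trajectory.
#' @return integer.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Construct an Alignment
#'
#' @param sequences named character vector of equal-length gapped
#'   sequences (1-letter codes, `-` for gap, `X` allowed).
#' @return object of class `Alignment` with fields `sequences`, `length`.
#' @export
Alignment <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop("all sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("unequal gapped lengths for ids: ",
         paste(ids[lens != lens[1]], collapse = ", "))
  sequences <- toupper(sequences)
  ok <- c(.aa1, "-", "X")
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop("alignment contains symbols outside the amino-acid alphabet: ",
         paste(bad, collapse = " "))
  structure(list(sequences = sequences, length = unname(lens[1])),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x$sequences), x$length))
  invisible(x)
}
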
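## Structure / trajectory / alignment I/O.
##
## PDB and PQR are parsed natively (fixed columns for PDB, whitespace
## tokens for PQR) so the test suite has no binary-format dependence;
## DCD is delegated to bio3d when available. Coordinates are written at
## the PDB-standard 3 decimals, which defines the round-trip precision.

.two_letter_elements <- c("CL", "BR", "FE", "ZN", "MG", "MN", "CU", "SE",
                          "NA", "CA")

# Infer element from the raw 4-character PDB atom-name field.
# A name starting in column 13 (no leading blank) whose first two letters
# form a known two-letter element is taken as that element; otherwise the
# first alphabetic character wins (so " CA " is carbon, "CA  " calcium).
.element_from_name <- function(raw_name) {
  vapply(raw_name, function(nm) {
    lead2 <- toupper(substr(nm, 1, 2))
    if (substr(nm, 1, 1) != " " && grepl("^[A-Za-z]{2}", nm) &&
        lead2 %in% .two_letter_elements)
      return(lead2)
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(ch) == 0) return("C")
    toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}

.parse_pdb_atom_lines <- function(lines, line_numbers) {
  n <- length(lines)
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  res_id <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(res_id))
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", line_numbers[bad[1]],
         ": ", lines[bad[1]])
  raw_name <- substr(lines, 13, 16)
  elem_col <- trimws(substr(lines, 77, 78))
  element <- ifelse(elem_col == "" | is.na(elem_col),
                    .element_from_name(raw_name), toupper(elem_col))
  data.frame(
    serial = serial,
    name = trimws(raw_name),
    element = element,
    res_name = trimws(substr(lines, 18, 20)),
    res_id = res_id,
    chain = ifelse(substr(lines, 22, 22) == " ", "A", substr(lines, 22, 22)),
    x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )
}

.check_duplicate_atoms <- function(atoms) {
  key <- paste(atoms$chain, atoms$res_id, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate atom (chain, res_id, name): ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  invisible(NULL)
}

.parse_pqr_lines <- function(lines, line_numbers) {
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # recordName serial name resName [chain] resSeq x y z charge radius
    if (length(tok) == 11) {
      chain <- tok[5]; rest <- tok[6:11]
    } else if (length(tok) == 10) {
      chain <- "A"; rest <- tok[5:10]
    } else {
      stop("malformed PQR record at line ", line_numbers[i], ": ", lines[i])
    }
    vals <- suppressWarnings(as.numeric(rest))
    if (anyNA(vals))
      stop("malformed PQR record at line ", line_numbers[i], ": ", lines[i])
    list(serial = as.integer(tok[2]), name = tok[3], res_name = tok[4],
         chain = chain, res_id = as.integer(rest[1]),
         x = vals[2], y = vals[3], z = vals[4],
         charge = vals[5], radius = vals[6])
  })
  nm <- vapply(rows, `[[`, character(1), "name")
  data.frame(
    serial = vapply(rows, `[[`, integer(1), "serial"),
    name = nm,
    element = .element_from_name(nm),
    res_name = vapply(rows, `[[`, character(1), "res_name"),
    chain = vapply(rows, `[[`, character(1), "chain"),
    res_id = vapply(rows, `[[`, integer(1), "res_id"),
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    z = vapply(rows, `[[`, numeric(1), "z"),
    charge = vapply(rows, `[[`, numeric(1), "charge"),
    radius = vapply(rows, `[[`, numeric(1), "radius"),
    stringsAsFactors = FALSE
  )
}

#' Read a structure from PDB or PQR
#'
#' Reads the first model of a PDB file (records `ATOM`/`HETATM`, stopping
#' at the first `ENDMDL`) or a PQR file (whitespace-separated, charge and
#' radius in the last two columns). Atoms keep file order; residue
#' numbering is taken verbatim. A blank PDB element column is inferred
#' from the atom name; a radius of 0/absent defaults to the element's
#' van der Waals radius.
#'
#' @param path file path.
#' @param format `"pdb"` or `"pqr"`.
#' @return a [Structure].
#' @export
read_structure <- function(path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  end <- which(grepl("^ENDMDL", lines))[1]
  if (!is.na(end)) is_atom[seq_along(lines) > end] <- FALSE
  idx <- which(is_atom)
  if (length(idx) == 0) stop("no ATOM/HETATM records in ", path)
  tab <- if (format == "pdb") .parse_pdb_atom_lines(lines[idx], idx)
         else .parse_pqr_lines(lines[idx], idx)
  .check_duplicate_atoms(tab)
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  atoms <- tab[, setdiff(names(tab), c("x", "y", "z")), drop = FALSE]
  Structure(atoms, xyz)
}

.format_pdb_lines <- function(structure) {
  a <- structure$atoms
  xyz <- structure$xyz
  name4 <- vapply(a$name, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else sprintf(" %-3s", nm)  # standard padding: cols 14-16 for short names
  }, character(1), USE.NAMES = FALSE)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000, name4, substr(a$res_name, 1, 3),
          substr(a$chain, 1, 1), a$res_id %% 10000,
          xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, a$element)
}

#' Write a structure as PDB or PQR
#'
#' PDB coordinates are written with 3 decimals (the format's precision);
#' PQR appends charge and radius columns (charge 0 when absent).
#'
#' @param structure [Structure].
#' @param path output file.
#' @param format `"pdb"` or `"pqr"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "pdb") {
    writeLines(c(.format_pdb_lines(structure), "END"), path)
  } else {
    a <- structure$atoms
    xyz <- structure$xyz
    q <- ifelse(is.na(a$charge), 0, a$charge)
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s %4d %11.4f %11.4f %11.4f %8.4f %8.4f",
                     a$serial %% 100000, a$name, substr(a$res_name, 1, 3),
                     substr(a$chain, 1, 1), a$res_id,
                     xyz[, 1], xyz[, 2], xyz[, 3], q, a$radius)
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Multi-model PDB is parsed natively: each `MODEL`/`ENDMDL` block (or
#' the whole file when no `MODEL` records exist) becomes one frame, and
#' every frame must match the topology atom count. DCD reading is
#' delegated to `bio3d::read.dcd` (suggested dependency). The first
#' `skip_frames` frames are dropped, e.g. to discard equilibration.
#'
#' @param path file path.
#' @param topology [Structure] giving the atom order of every frame.
#' @param format `"multi_model_pdb"` or `"dcd"`.
#' @param skip_frames number of leading frames to drop (default 0).
#' @param frame_interval ns between frames (metadata).
#' @return a [Trajectory].
#' @export
read_trajectory <- function(path, topology,
                            format = c("multi_model_pdb", "dcd"),
                            skip_frames = 0, frame_interval = NA_real_) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "Structure"))
  n <- nrow(topology$atoms)
  if (format == "dcd") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("DCD reading requires the bio3d package")
    m <- bio3d::read.dcd(path, verbose = FALSE)
    frames <- lapply(seq_len(nrow(m)), function(i)
      matrix(m[i, ], ncol = 3, byrow = TRUE,
             dimnames = list(NULL, c("x", "y", "z"))))
  } else {
    lines <- readLines(path, warn = FALSE)
    model_starts <- grep("^MODEL", lines)
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    if (length(model_starts) == 0) {
      blocks <- list(which(is_atom))
    } else {
      model_ends <- grep("^ENDMDL", lines)
      if (length(model_ends) != length(model_starts))
        stop("unbalanced MODEL/ENDMDL records in ", path)
      blocks <- mapply(function(s, e) {
        idx <- s:e
        idx[is_atom[idx]]
      }, model_starts, model_ends, SIMPLIFY = FALSE)
    }
    frames <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      idx <- blocks[[i]]
      if (length(idx) != n)
        stop("frame ", i, " has ", length(idx),
             " atoms; topology has ", n)
      xs <- lines[idx]
      frames[[i]] <- cbind(
        x = as.numeric(substr(xs, 31, 38)),
        y = as.numeric(substr(xs, 39, 46)),
        z = as.numeric(substr(xs, 47, 54)))
    }
  }
  for (i in seq_along(frames))
    if (nrow(frames[[i]]) != n)
      stop("frame ", i, " has ", nrow(frames[[i]]),
           " atoms; topology has ", n)
  if (skip_frames >= length(frames))
    stop("skip_frames (", skip_frames, ") leaves no frames")
  if (skip_frames > 0) frames <- frames[-seq_len(skip_frames)]
  Trajectory(topology, frames, frame_interval = frame_interval)
}

#' Write a trajectory as multi-model PDB
#'
#' @param trajectory [Trajectory].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- trajectory$topology
  for (i in seq_along(trajectory$frames)) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(.format_pdb_lines(with_coords(s, trajectory$frames[[i]])), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' FASTA and Clustal parsing is delegated to `seqinr::read.alignment`;
#' the result is validated (unique ids, equal gapped lengths, protein
#' alphabet) into an [Alignment].
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return an [Alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  if (aln$nb < 1) stop("no sequences in ", path)
  ids <- aln$nam
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(unlist(aln$seq))
  names(seqs) <- ids
  Alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param alignment [Alignment].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(alignment$sequences)) {
    writeLines(paste0(">", id), con)
    s <- alignment$sequences[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
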
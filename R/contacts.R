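## Ligand-residue contact detection and frequency statistics. The contact
## criterion is a single heavy-atom distance cutoff (default 4.0 A,
## inclusive): transparent and testable where interaction-type-specific
## geometric rules would be opaque. Hydrogens are excluded on both sides.

#' Residues in contact with the ligand in one frame
#'
#' @param structure [Structure] holding the frame coordinates.
#' @param ligand_selection atom indices of the ligand.
#' @param receptor_selection atom indices of the receptor.
#' @param cutoff heavy-atom distance cutoff (Angstrom, inclusive).
#' @return data.frame of contacted residues: `chain`, `res_id`,
#'   `res_name` (zero rows when none).
#' @export
frame_contacts <- function(structure, ligand_selection, receptor_selection,
                           cutoff = 4.0) {
  stopifnot(cutoff > 0)
  hv <- function(sel) sel[!(structure$atoms$element[sel] %in% c("H", "D"))]
  lig <- hv(ligand_selection); rec <- hv(receptor_selection)
  if (length(lig) == 0 || length(rec) == 0)
    return(data.frame(chain = character(), res_id = integer(),
                      res_name = character()))
  pairs <- neighbor_pairs(structure$xyz[rec, , drop = FALSE],
                          structure$xyz[lig, , drop = FALSE], cutoff)
  if (nrow(pairs) == 0)
    return(data.frame(chain = character(), res_id = integer(),
                      res_name = character()))
  residue_table(structure, unique(rec[pairs$i]))
}

#' Per-residue contact frequencies over a trajectory
#'
#' Fraction of window frames in which each receptor residue has a heavy
#' atom within `cutoff` of a ligand heavy atom. By default the window
#' starts at the first frame with any contact (ingress convention: bulk
#' diffusion before first touch would dilute frequencies arbitrarily
#' with trajectory length); pass `window` explicitly for the
#' whole-trajectory convention.
#'
#' @param trajectory [Trajectory].
#' @param ligand_selection,receptor_selection atom index vectors.
#' @param cutoff contact cutoff (Angstrom).
#' @param window frame indices to average over, or `NULL` (default) for
#'   first-contact-to-end. An explicitly empty window is an error.
#' @return object of class `ContactTable`: `residues` (data.frame),
#'   `matrix` (residue x frame logical over the window), `frequencies`
#'   (named numeric), `window`.
#' @export
contact_frequencies <- function(trajectory, ligand_selection,
                                receptor_selection, cutoff = 4.0,
                                window = NULL) {
  if (!is.null(window) && length(window) == 0) stop("empty window")
  topo <- trajectory$topology
  res <- residue_table(topo, receptor_selection)
  res_key <- paste(res$chain, res$res_id)
  all_frames <- if (is.null(window)) seq_along(trajectory$frames) else window
  mat <- matrix(FALSE, nrow(res), length(all_frames),
                dimnames = list(res_key, NULL))
  for (k in seq_along(all_frames)) {
    fr <- with_coords(topo, trajectory$frames[[all_frames[k]]])
    hits <- frame_contacts(fr, ligand_selection, receptor_selection, cutoff)
    mat[res_key %in% paste(hits$chain, hits$res_id), k] <- TRUE
  }
  if (is.null(window)) {
    touched <- which(colSums(mat) > 0)
    if (length(touched) == 0) {
      window <- integer(0)  # never in contact: all frequencies 0
      freqs <- stats::setNames(rep(0, nrow(res)), res_key)
      mat <- mat[, 0, drop = FALSE]
    } else {
      window <- all_frames[touched[1]:length(all_frames)]
      mat <- mat[, touched[1]:ncol(mat), drop = FALSE]
      freqs <- rowMeans(mat)
    }
  } else {
    freqs <- rowMeans(mat)
  }
  structure(list(residues = res, matrix = mat, frequencies = freqs,
                 window = window),
            class = "ContactTable")
}

#' @export
print.ContactTable <- function(x, ...) {
  top <- sort(x$frequencies[x$frequencies > 0], decreasing = TRUE)
  cat(sprintf("ContactTable: %d residues over %d frames; top contacts: %s\n",
              nrow(x$residues), length(x$window),
              paste(sprintf("%s=%.2f", names(utils::head(top, 5)),
                            utils::head(top, 5)), collapse = ", ")))
  invisible(x)
}

#' Average contact frequencies over entry trajectories
#'
#' Unweighted mean of per-trajectory frequencies over the trajectories
#' flagged in `entry_mask`, outer-joining the residue universes with 0
#' fill, mirroring the convention of averaging over entry trajectories
#' only.
#'
#' @param tables list of [ContactTable]s.
#' @param entry_mask logical vector, one per table.
#' @return named numeric vector of mean frequencies over the union of
#'   residues.
#' @export
cohort_frequencies <- function(tables, entry_mask) {
  stopifnot(length(tables) == length(entry_mask))
  keep <- which(entry_mask)
  if (length(keep) == 0) stop("no entry trajectories in mask")
  universe <- unique(unlist(lapply(tables[keep], function(t)
    names(t$frequencies))))
  acc <- stats::setNames(rep(0, length(universe)), universe)
  for (k in keep) {
    f <- tables[[k]]$frequencies
    acc[names(f)] <- acc[names(f)] + f
    # residues absent from this table contribute 0 (outer join fill)
  }
  acc / length(keep)
}

#' Write a contact table as TSV
#'
#' @param table [ContactTable].
#' @param path output file.
#' @param helix_map optional named character vector mapping
#'   `"chain res_id"` keys to helix annotations (e.g. `"S6"`).
#' @param header_lines optional comment lines.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(table, path, helix_map = NULL,
                              header_lines = NULL) {
  res <- table$residues
  key <- paste(res$chain, res$res_id)
  df <- data.frame(chain = res$chain, res_id = res$res_id,
                   res_name = res$res_name,
                   helix = if (is.null(helix_map)) ""
                           else ifelse(key %in% names(helix_map),
                                       helix_map[key], ""),
                   frequency = sprintf("%.4f", table$frequencies[key]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
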
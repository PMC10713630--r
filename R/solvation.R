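## First-solvation-shell water counting and bulk normalisation. A water
## residue is in the shell when any of its atoms lies within `cutoff`
## (default 3.0 Angstrom, inclusive) of any ligand heavy atom; per-frame
## counts divided by a bulk-reference mean give the solvation fraction,
## which may exceed 1 under fluctuation and is never clipped.

#' Count first-shell waters in one frame
#'
#' @param structure [Structure] holding the frame (use [with_coords()]
#'   to realise a trajectory frame).
#' @param ligand_selection atom indices of the ligand (hydrogens are
#'   dropped internally).
#' @param water_selection atom indices of the water atoms.
#' @param cutoff shell cutoff in Angstrom (default 3.0, inclusive).
#' @return integer: number of distinct water residues with at least one
#'   atom within `cutoff` of any ligand heavy atom. Empty water
#'   selection returns 0 with a warning.
#' @export
shell_count <- function(structure, ligand_selection, water_selection,
                        cutoff = 3.0) {
  stopifnot(cutoff > 0)
  if (length(water_selection) == 0) {
    warning("empty water selection; shell count is 0")
    return(0L)
  }
  lig <- ligand_selection[
    !(structure$atoms$element[ligand_selection] %in% c("H", "D"))]
  if (length(lig) == 0) stop("ligand selection has no heavy atoms")
  pairs <- neighbor_pairs(structure$xyz[water_selection, , drop = FALSE],
                          structure$xyz[lig, , drop = FALSE], cutoff)
  if (nrow(pairs) == 0) return(0L)
  wat_atoms <- water_selection[pairs$i]
  key <- paste(structure$atoms$chain[wat_atoms],
               structure$atoms$res_id[wat_atoms])
  length(unique(key))
}

#' Mean bulk shell count
#'
#' The normalisation constant for [solvation_fraction()]: the mean
#' first-shell count over the frames of a bulk source — either a
#' dedicated ligand-in-water trajectory or the pre-contact frames of the
#' main trajectory.
#'
#' @param trajectory [Trajectory] of the bulk source.
#' @param ligand_selection,water_selection atom index vectors.
#' @param frames frames to average over (default all); >= 5 required.
#' @param cutoff shell cutoff (Angstrom).
#' @return mean shell count (> 0 expected for a real bulk system).
#' @export
bulk_reference <- function(trajectory, ligand_selection, water_selection,
                           frames = seq_along(trajectory$frames),
                           cutoff = 3.0) {
  if (length(frames) < 5)
    stop("bulk reference needs >= 5 frames, got ", length(frames))
  counts <- vapply(frames, function(f)
    shell_count(with_coords(trajectory$topology, trajectory$frames[[f]]),
                ligand_selection, water_selection, cutoff),
    integer(1))
  mean(counts)
}

#' Per-frame solvation fraction
#'
#' Shell counts over a trajectory, normalised by a bulk mean.
#'
#' @param trajectory [Trajectory].
#' @param ligand_selection,water_selection atom index vectors.
#' @param bulk_mean positive normalisation constant from
#'   [bulk_reference()].
#' @param cutoff shell cutoff (Angstrom).
#' @return object of class `SolvationSeries`: `shell_counts` (integer per
#'   frame), `fraction` (counts / bulk_mean), `bulk_mean`, `cutoff`.
#' @export
solvation_fraction <- function(trajectory, ligand_selection,
                               water_selection, bulk_mean, cutoff = 3.0) {
  if (bulk_mean <= 0) stop("bulk_mean must be > 0")
  counts <- vapply(seq_along(trajectory$frames), function(f)
    shell_count(with_coords(trajectory$topology, trajectory$frames[[f]]),
                ligand_selection, water_selection, cutoff),
    integer(1))
  structure(list(shell_counts = counts, fraction = counts / bulk_mean,
                 bulk_mean = bulk_mean, cutoff = cutoff),
            class = "SolvationSeries")
}

#' @export
print.SolvationSeries <- function(x, ...) {
  cat(sprintf("SolvationSeries: %d frames, mean fraction %.2f (bulk %.2f waters, cutoff %.1f A)\n",
              length(x$shell_counts), mean(x$fraction), x$bulk_mean,
              x$cutoff))
  invisible(x)
}

#' Combined ingress plot: distance curve with solvation overlay
#'
#' Draws the ligand-to-site distance per frame with state-segment
#' shading and, when given, the solvation fraction on a secondary axis —
#' the classic single-panel summary of a binding event.
#'
#' @param series [DistanceSeries].
#' @param solvation optional [SolvationSeries] over the same frames.
#' @param segmentation optional [StateSegmentation] for segment shading.
#' @param ... passed to the underlying line plot.
#' @return invisibly, NULL; draws on the active device.
#' @export
plot_ingress <- function(series, solvation = NULL, segmentation = NULL,
                         ...) {
  d <- series$distances
  graphics::plot(series$frame_indices, d, type = "l",
                 xlab = "frame", ylab = "distance to site (A)", ...)
  if (!is.null(segmentation)) {
    r <- rle(segmentation$labels)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    shade <- c(bulk = NA, contact = "#fdd9b4", entry = "#c7e9c0",
               vestibule = "#9ecae1", binding = "#bcbddc")
    for (k in seq_along(r$values)) {
      col <- shade[[r$values[k]]]
      if (!is.na(col))
        graphics::rect(starts[k] - 0.5, graphics::par("usr")[3],
                       ends[k] + 0.5, graphics::par("usr")[4],
                       col = grDevices::adjustcolor(col, 0.4),
                       border = NA)
    }
    graphics::lines(series$frame_indices, d)
  }
  if (!is.null(solvation)) {
    usr <- graphics::par("usr")
    frac <- solvation$fraction
    scaled <- usr[3] + frac / max(frac, 1) * (usr[4] - usr[3])
    graphics::lines(seq_along(frac), scaled, col = "steelblue")
    graphics::axis(4, at = usr[3] + c(0, 0.5, 1) * (usr[4] - usr[3]),
                   labels = c("0", "0.5", "1"), col.axis = "steelblue")
    graphics::mtext("solvation fraction", side = 4, line = 2,
                    col = "steelblue")
  }
  invisible(NULL)
}

#' Write a solvation series (optionally merged with distances) as TSV
#'
#' @param solvation [SolvationSeries].
#' @param path output file.
#' @param series optional [DistanceSeries] over the same frames.
#' @param header_lines optional comment lines.
#' @return `path`, invisibly.
#' @export
write_solvation_tsv <- function(solvation, path, series = NULL,
                                header_lines = NULL) {
  df <- data.frame(frame = seq_along(solvation$shell_counts),
                   count = solvation$shell_counts,
                   fraction = sprintf("%.4f", solvation$fraction))
  if (!is.null(series))
    df$distance_A <- sprintf("%.4f", series$distances)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
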
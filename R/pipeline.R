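## Orchestration: end-to-end runs composing the analysis stages, with
## every output file carrying a header recording package version, seed
## and a hash of the configuration, so reruns are verifiably identical.

.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

.run_header <- function(config, seed) {
  c(sprintf("cavitrack %s",
            as.character(utils::packageVersion("cavitrack"))),
    sprintf("seed=%d", seed),
    sprintf("config_hash=%s", .config_hash(config)))
}

#' Generate a synthetic dataset on disk
#'
#' Emits a toy receptor (PDB), a planted translocation trajectory
#' (multi-model PDB), a planted alignment (FASTA) and the ground truth
#' (JSON sidecar), all via the package's public writers, so the full
#' pipeline can be exercised through its file readers.
#'
#' @param out_dir output directory (created).
#' @param seed RNG seed for every generator.
#' @param n_waters waters in the trajectory.
#' @param dwell_frames per-state frame counts for the trajectory.
#' @return `out_dir`, invisibly; files: `receptor.pdb`,
#'   `trajectory.pdb`, `alignment.fasta`, `truth.json`, `config.json`.
#' @export
run_synth <- function(out_dir, seed = 1, n_waters = 0,
                      dwell_frames = c(bulk = 40, contact = 40, entry = 40,
                                       vestibule = 40, binding = 40)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(seed = seed, n_waters = n_waters,
                 dwell_frames = dwell_frames)
  receptor <- make_toy_receptor(seed = seed)
  tr <- make_translocation_trajectory(receptor, dwell_frames = dwell_frames,
                                      n_waters = n_waters, seed = seed)
  aln <- make_alignment(n_seqs = 6, length = 100, identity = 0.73,
                        similarity = 0.82, seed = seed)
  write_structure(receptor, file.path(out_dir, "receptor.pdb"))
  write_trajectory(tr$trajectory, file.path(out_dir, "trajectory.pdb"))
  write_alignment(aln, file.path(out_dir, "alignment.fasta"))
  truth <- tr$truth
  truth$cavity_center <- attr(receptor, "cavity_center")
  truth$cavity_radius <- attr(receptor, "cavity_radius")
  jsonlite::write_json(
    list(header = .run_header(config, seed), truth = unclass(truth)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Run the full ingress analysis on one trajectory
#'
#' Composes the pipeline: distance series to the binding-site point,
#' state segmentation, entry events, contact frequencies, solvation
#' fraction (skipped with a warning when the system has no waters or no
#' bulk mean is available), and representative frames — all written
#' under `out_dir` with reproducible headers.
#'
#' @param trajectory [Trajectory].
#' @param site [site_point()] or [map_reference_site()] result.
#' @param ligand_selection,receptor_selection,water_selection atom index
#'   vectors into the topology (water selection may be empty).
#' @param out_dir output directory.
#' @param thresholds [state_thresholds()].
#' @param bulk_mean bulk shell mean for solvation normalisation; when
#'   NULL it is estimated from the frames labelled `bulk` (if any).
#' @param seed seed for representative-frame clustering.
#' @param contact_cutoff,shell_cutoff stage cutoffs (Angstrom).
#' @return list with `series`, `segmentation`, `events`, `contacts`,
#'   `solvation` (or NULL), `representatives`; files under `out_dir`.
#' @export
run_ingress <- function(trajectory, site, ligand_selection,
                        receptor_selection, water_selection = integer(0),
                        out_dir, thresholds = state_thresholds(),
                        bulk_mean = NULL, seed = 1, contact_cutoff = 4.0,
                        shell_cutoff = 3.0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(thresholds = unclass(thresholds), seed = seed,
                 contact_cutoff = contact_cutoff,
                 shell_cutoff = shell_cutoff)
  hdr <- .run_header(config, seed)
  series <- distance_series(trajectory, ligand_selection,
                            receptor_selection, site)
  seg <- segment_states(series, method = "threshold",
                        thresholds = thresholds)
  events <- detect_entry_events(series, thresholds)
  write_distance_tsv(series, file.path(out_dir, "distances.tsv"),
                     segmentation = seg, header_lines = hdr)
  contacts <- contact_frequencies(trajectory, ligand_selection,
                                  receptor_selection,
                                  cutoff = contact_cutoff)
  write_contact_tsv(contacts, file.path(out_dir, "contacts.tsv"),
                    header_lines = hdr)
  solvation <- NULL
  if (length(water_selection) == 0) {
    warning("no water selection; solvation stage skipped")
  } else {
    if (is.null(bulk_mean)) {
      bulk_frames <- which(seg$labels == "bulk")
      if (length(bulk_frames) >= 5) {
        bulk_mean <- bulk_reference(trajectory, ligand_selection,
                                    water_selection, frames = bulk_frames,
                                    cutoff = shell_cutoff)
      } else {
        warning("no bulk mean available (fewer than 5 bulk frames); ",
                "solvation stage skipped")
      }
    }
    if (!is.null(bulk_mean) && bulk_mean > 0) {
      solvation <- solvation_fraction(trajectory, ligand_selection,
                                      water_selection, bulk_mean,
                                      cutoff = shell_cutoff)
      write_solvation_tsv(solvation,
                          file.path(out_dir, "solvation.tsv"),
                          series = series, header_lines = hdr)
    }
  }
  reps <- select_representative_frames(trajectory, seg, ligand_selection,
                                       receptor_selection =
                                         receptor_selection, seed = seed)
  for (st in names(reps)) {
    fr <- with_coords(trajectory$topology, trajectory$frames[[reps[st]]])
    write_structure(fr, file.path(out_dir,
                                  sprintf("representative_%s.pdb", st)))
  }
  jsonlite::write_json(
    list(header = hdr,
         events = unclass(events),
         representatives = as.list(reps)),
    file.path(out_dir, "events.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(series = series, segmentation = seg, events = events,
                 contacts = contacts, solvation = solvation,
                 representatives = reps))
}

#' Run the ingress tally over a cohort of trajectories
#'
#' @param trajectories list of [Trajectory]s sharing ligand/receptor
#'   selections.
#' @param site [site_point()].
#' @param ligand_selection atom indices of the ligand.
#' @param thresholds [state_thresholds()].
#' @param out_file optional JSON path for the summary.
#' @return named integer vector from [summarize_cohort()], with the
#'   per-trajectory events as attribute `events`.
#' @export
run_cohort <- function(trajectories, site, ligand_selection,
                       thresholds = state_thresholds(), out_file = NULL) {
  events <- lapply(trajectories, function(tr)
    detect_entry_events(distance_series(tr, ligand_selection, site = site),
                        thresholds))
  counts <- summarize_cohort(events)
  if (!is.null(out_file)) {
    jsonlite::write_json(
      list(header = .run_header(list(thresholds = unclass(thresholds)), 0),
           counts = as.list(counts)),
      out_file, auto_unbox = TRUE, digits = NA)
  }
  attr(counts, "events") <- events
  counts
}

#' Run the comparative pocket analysis and write the table
#'
#' @param models named list of [Structure]s.
#' @param out_file TSV path.
#' @param ... passed to [compare_homolog_pockets()].
#' @return the comparison data.frame, invisibly.
#' @export
run_pockets <- function(models, out_file, ...) {
  tab <- compare_homolog_pockets(models, ...)
  con <- file(out_file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .run_header(list(models = names(models)), 0)),
             con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
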
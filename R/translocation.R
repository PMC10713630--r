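## Core ingress analysis: per-frame ligand-to-site distance, segmentation
## of the distance curve into metastable states (contact, entry,
## vestibule, binding), entry-event detection, cohort tallies, and
## representative-frame selection by k-means.

#' State thresholds for segmentation and event detection
#'
#' Distance bands (Angstrom) separating the ingress states, with a
#' minimum dwell in frames. Bands are open below: a frame is in the
#' binding band when `distance < d_binding`, in the vestibule band when
#' `d_binding <= distance < d_vestibule`, and so on; `distance >=
#' d_contact` is bulk. The defaults are calibrated on the synthetic
#' receptor family — the analysis they mirror divided the distance curve
#' visually, so no literature values exist.
#'
#' @param d_contact,d_entry,d_vestibule,d_binding band boundaries
#'   (strictly decreasing, all > 0).
#' @param min_dwell frames a crossing must persist to count (>= 1).
#' @return object of class `StateThresholds`.
#' @export
state_thresholds <- function(d_contact = 25, d_entry = 15,
                             d_vestibule = 9, d_binding = 4,
                             min_dwell = 5) {
  if (!(d_contact > d_entry && d_entry > d_vestibule &&
        d_vestibule > d_binding && d_binding > 0))
    stop("require d_contact > d_entry > d_vestibule > d_binding > 0")
  if (min_dwell < 1) stop("min_dwell must be >= 1")
  structure(list(d_contact = d_contact, d_entry = d_entry,
                 d_vestibule = d_vestibule, d_binding = d_binding,
                 min_dwell = as.integer(min_dwell)),
            class = "StateThresholds")
}

# band label of each distance under thresholds (no dwell smoothing)
.band_label <- function(d, th) {
  lab <- rep("bulk", length(d))
  lab[d < th$d_contact] <- "contact"
  lab[d < th$d_entry] <- "entry"
  lab[d < th$d_vestibule] <- "vestibule"
  lab[d < th$d_binding] <- "binding"
  lab
}

#' Per-frame ligand-to-site distance
#'
#' Distance between the ligand center of mass and a fixed site point for
#' every frame. With `align_each_frame = TRUE` each frame's receptor
#' selection is Kabsch-superposed onto the topology's reference
#' coordinates before measuring, so a site expressed in the receptor
#' reference frame stays valid when the receptor drifts or rotates.
#'
#' @param trajectory [Trajectory].
#' @param ligand_selection,receptor_selection atom index vectors into the
#'   topology (receptor selection only used when aligning).
#' @param site [site_point()] / [map_reference_site()] result, in the
#'   receptor reference frame (= the topology coordinates).
#' @param align_each_frame superpose receptor per frame (default FALSE:
#'   synthetic receptors are static).
#' @param weighting COM weighting (default mass).
#' @return object of class `DistanceSeries`: list with `distances`
#'   (Angstrom), `frame_indices`, `site`, `ligand_selection`.
#' @export
distance_series <- function(trajectory, ligand_selection,
                            receptor_selection = NULL, site,
                            align_each_frame = FALSE,
                            weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(trajectory, "Trajectory"), inherits(site, "SitePoint"))
  if (length(ligand_selection) == 0) stop("empty ligand selection")
  if (align_each_frame && length(receptor_selection) < 3)
    stop("align_each_frame requires a receptor selection of >= 3 atoms")
  topo <- trajectory$topology
  masses <- if (weighting == "mass")
    atomic_mass(topo$atoms$element[ligand_selection])
  else rep(1, length(ligand_selection))
  ref_rec <- if (align_each_frame)
    topo$xyz[receptor_selection, , drop = FALSE]
  n_fr <- length(trajectory$frames)
  d <- numeric(n_fr)
  for (f in seq_len(n_fr)) {
    fr <- trajectory$frames[[f]]
    lig <- fr[ligand_selection, , drop = FALSE]
    if (align_each_frame) {
      sup <- kabsch_superpose(fr[receptor_selection, , drop = FALSE], ref_rec)
      lig <- apply_superposition(lig, sup)
    }
    com <- colSums(lig * masses) / sum(masses)
    d[f] <- sqrt(sum((com - site$coord)^2))
  }
  structure(list(distances = d, frame_indices = seq_len(n_fr),
                 site = site, ligand_selection = ligand_selection),
            class = "DistanceSeries")
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("DistanceSeries: %d frames, %.1f-%.1f A\n",
              length(x$distances), min(x$distances), max(x$distances)))
  invisible(x)
}

#' @export
plot.DistanceSeries <- function(x, ...) {
  graphics::plot(x$frame_indices, x$distances, type = "l",
                 xlab = "frame", ylab = "distance to site (A)", ...)
  invisible(x)
}

# best single least-squares changepoint of y (piecewise-constant mean);
# returns split index b (segment = 1..b, b+1..n) and SSE gain, honouring
# a minimum segment length
.best_split <- function(y, min_len) {
  n <- length(y)
  if (n < 2 * min_len) return(NULL)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  b <- seq(min_len, n - min_len)
  n1 <- b; n2 <- n - b
  s1 <- cs[b]; s2 <- cs[n] - s1
  sse_split <- (cs2[b] - s1^2 / n1) + ((cs2[n] - cs2[b]) - s2^2 / n2)
  sse_all <- cs2[n] - cs[n]^2 / n
  i <- which.min(sse_split)
  list(b = b[i], gain = sse_all - sse_split[i])
}

#' Segment a distance series into metastable states
#'
#' Two methods. `"changepoint"` (default) fits a piecewise-constant mean
#' with `n_states - 1` breakpoints by least-squares binary segmentation
#' and labels the segments by their mean distance rank along the ingress
#' ladder (highest mean = outermost state). `"threshold"` assigns each
#' frame its distance band under `thresholds` and smooths with a
#' hysteresis of `min_dwell` frames: the label switches only at the start
#' of a run of `min_dwell` identical band labels.
#'
#' @param series [DistanceSeries].
#' @param method `"changepoint"` or `"threshold"`.
#' @param n_states segments for the changepoint method; the labels used
#'   are the last `n_states` of bulk, contact, entry, vestibule, binding
#'   (so 4 states span contact..binding, the classic ingress split).
#' @param thresholds [state_thresholds()].
#' @return object of class `StateSegmentation`: `labels` (per frame),
#'   `boundaries` (first frame of each segment after the first),
#'   `method`.
#' @export
segment_states <- function(series, method = c("changepoint", "threshold"),
                           n_states = 4, thresholds = state_thresholds()) {
  method <- match.arg(method)
  d <- series$distances
  n <- length(d)
  if (method == "changepoint") {
    min_len <- thresholds$min_dwell
    if (n < n_states * min_len)
      stop("series too short: ", n, " frames for ", n_states,
           " states with min_dwell ", min_len)
    # binary segmentation: repeatedly split the segment with best gain
    segs <- list(c(1, n))
    while (length(segs) < n_states) {
      best <- NULL; best_k <- NA
      for (k in seq_along(segs)) {
        sp <- .best_split(d[segs[[k]][1]:segs[[k]][2]], min_len)
        if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
          best <- sp; best_k <- k
        }
      }
      if (is.null(best)) stop("series too short to place ", n_states - 1,
                              " breakpoints with min_dwell ", min_len)
      seg <- segs[[best_k]]
      segs[[best_k]] <- c(seg[1], seg[1] + best$b - 1)
      segs <- append(segs, list(c(seg[1] + best$b, seg[2])), after = best_k)
    }
    starts <- vapply(segs, `[`, numeric(1), 1)
    ends <- vapply(segs, `[`, numeric(1), 2)
    means <- mapply(function(s, e) mean(d[s:e]), starts, ends)
    ladder <- utils::tail(.state_ladder, n_states)
    lab_of_seg <- ladder[rank(-means, ties.method = "first")]
    labels <- rep(lab_of_seg, times = ends - starts + 1)
    boundaries <- starts[-1]
  } else {
    raw <- .band_label(d, thresholds)
    md <- thresholds$min_dwell
    labels <- character(n)
    cur <- raw[1]
    run_val <- raw[1]; run_len <- 1
    labels[1] <- cur
    for (t in 2:n) {
      if (raw[t] == run_val) run_len <- run_len + 1
      else { run_val <- raw[t]; run_len <- 1 }
      if (run_val != cur && run_len >= md) {
        cur <- run_val
        labels[(t - md + 1):t] <- cur  # switch dates from the run start
      } else labels[t] <- cur
    }
    boundaries <- which(labels[-1] != labels[-n]) + 1
  }
  structure(list(labels = labels, boundaries = boundaries, method = method),
            class = "StateSegmentation")
}

#' @export
print.StateSegmentation <- function(x, ...) {
  rl <- rle(x$labels)
  cat(sprintf("StateSegmentation (%s): %s\n", x$method,
              paste(sprintf("%s[%d]", rl$values, rl$lengths),
                    collapse = " > ")))
  invisible(x)
}

#' Detect vestibule-entry and full-binding events
#'
#' A trajectory entered the vestibule when its distance stays below
#' `d_vestibule` for at least `min_dwell` consecutive frames, and is
#' fully bound when it stays below `d_binding` that long; single-frame
#' spikes never count.
#'
#' @param series [DistanceSeries].
#' @param thresholds [state_thresholds()].
#' @return object of class `EntryEvents`: `entered_vestibule`,
#'   `fully_bound`, `first_vestibule_frame`, `first_binding_frame`
#'   (NA when the event never happens).
#' @export
detect_entry_events <- function(series, thresholds = state_thresholds()) {
  d <- series$distances
  md <- thresholds$min_dwell
  first_run <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= md)
    if (length(ok) == 0) NA_integer_
    else ends[ok[1]] - r$lengths[ok[1]] + 1L
  }
  fv <- first_run(d < thresholds$d_vestibule)
  fb <- first_run(d < thresholds$d_binding)
  structure(list(entered_vestibule = !is.na(fv),
                 fully_bound = !is.na(fb),
                 first_vestibule_frame = fv,
                 first_binding_frame = fb),
            class = "EntryEvents")
}

#' @export
print.EntryEvents <- function(x, ...) {
  cat(sprintf("EntryEvents: vestibule=%s (frame %s), bound=%s (frame %s)\n",
              x$entered_vestibule, x$first_vestibule_frame,
              x$fully_bound, x$first_binding_frame))
  invisible(x)
}

#' Tally entry events over a trajectory cohort
#'
#' @param events list of [detect_entry_events()] results.
#' @return named integer vector `c(n_traj, n_vestibule, n_full)`.
#' @export
summarize_cohort <- function(events) {
  c(n_traj = length(events),
    n_vestibule = sum(vapply(events, `[[`, logical(1),
                             "entered_vestibule")),
    n_full = sum(vapply(events, `[[`, logical(1), "fully_bound")))
}

#' Representative frame per state by k-means
#'
#' Within each state of a segmentation, clusters the frames (k-means,
#' `nstart` random restarts under the given seed) on either the ligand
#' coordinates or a residue-contact fingerprint, and returns the frame
#' nearest the centroid of the most populated cluster (medoid rule).
#' Ties — equally populated clusters or equally near frames — go to the
#' lowest frame index. States with fewer than `k` frames use `k` reduced
#' to the frame count (with a message); empty states are skipped with a
#' warning.
#'
#' @param trajectory [Trajectory].
#' @param segmentation [StateSegmentation] over the same frames.
#' @param ligand_selection atom indices of the ligand.
#' @param feature `"ligand_coords"` (flattened ligand coordinates) or
#'   `"contact_fingerprint"` (per-residue contact booleans at `cutoff`).
#' @param receptor_selection receptor atom indices (needed for the
#'   fingerprint feature).
#' @param k clusters per state (default 4).
#' @param seed RNG seed for k-means initialisation.
#' @param cutoff contact cutoff for the fingerprint feature (Angstrom).
#' @param nstart k-means restarts (default 10).
#' @return named integer vector, state -> representative frame index.
#' @export
select_representative_frames <- function(trajectory, segmentation,
                                         ligand_selection,
                                         feature = c("ligand_coords",
                                                     "contact_fingerprint"),
                                         receptor_selection = NULL,
                                         k = 4, seed = 1, cutoff = 4.0,
                                         nstart = 10) {
  feature <- match.arg(feature)
  labels <- segmentation$labels
  states <- unique(labels)
  topo <- trajectory$topology
  feat_row <- function(f) {
    fr <- trajectory$frames[[f]]
    if (feature == "ligand_coords") {
      as.vector(t(fr[ligand_selection, , drop = FALSE]))
    } else {
      if (is.null(receptor_selection))
        stop("contact_fingerprint needs a receptor_selection")
      rec <- with_coords(topo, fr)
      hits <- frame_contacts(rec, ligand_selection, receptor_selection,
                             cutoff = cutoff)
      res <- residue_table(topo, receptor_selection)
      as.numeric(paste(res$chain, res$res_id) %in%
                   paste(hits$chain, hits$res_id))
    }
  }
  out <- stats::setNames(integer(0), character(0))
  set.seed(seed)
  for (st in states) {
    frames_st <- which(labels == st)
    if (length(frames_st) == 0) { warning("state ", st, " empty; skipped")
                                  next }
    X <- t(vapply(frames_st, feat_row,
                  numeric(length(feat_row(frames_st[1])))))
    k_st <- k
    if (length(frames_st) < k) {
      k_st <- length(frames_st)
      message("state ", st, ": only ", k_st, " frames; k reduced")
    }
    if (k_st == 1 || nrow(unique(X)) < k_st) {
      # degenerate: all (or too few distinct) points; medoid of the lot
      cen <- colMeans(X)
      d2 <- rowSums(sweep(X, 2, cen)^2)
      out[st] <- frames_st[which.min(d2)]
      next
    }
    km <- stats::kmeans(X, centers = k_st, nstart = nstart)
    big <- which(km$size == max(km$size))[1]
    members <- which(km$cluster == big)
    d2 <- rowSums(sweep(X[members, , drop = FALSE], 2,
                        km$centers[big, ])^2)
    out[st] <- frames_st[members[which.min(d2)]]
  }
  out
}

#' Write a distance series and segmentation as TSV
#'
#' @param series [DistanceSeries].
#' @param path output file.
#' @param segmentation optional [StateSegmentation] adding a state column.
#' @param header_lines optional comment lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(series, path, segmentation = NULL,
                               header_lines = NULL) {
  df <- data.frame(frame = series$frame_indices,
                   distance_A = sprintf("%.4f", series$distances))
  if (!is.null(segmentation)) df$state <- segmentation$labels
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
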
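## Synthetic-data generators: toy receptors with a buried cavity, planted
## translocation trajectories with exact ground truth, bulk hydration
## boxes, alignments with planted identity/similarity, and complementarity
## test complexes. All deterministic under a fixed seed. Ground truth is
## recomputed from the EMITTED coordinates by independent brute-force
## passes, never taken from sampling intent.

# quasi-uniform unit vectors (Fibonacci sphere lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

.unit <- function(v) v / sqrt(sum(v^2))

# canonical ingress order of states
.state_ladder <- c("bulk", "contact", "entry", "vestibule", "binding")

#' Toy receptor with a buried spherical cavity and an access channel
#'
#' Builds a pseudo-atom shell (one carbon "CA" pseudo-atom per residue)
#' enclosing an empty sphere of radius `cavity_radius` at `cavity_center`,
#' bored through by a cylindrical channel along `channel_axis` so the
#' cavity is reachable from outside. The innermost atom layer sits at
#' `cavity_radius + probe + vdW` so a grid cavity detector recovers the
#' planted sphere. Deterministic for a fixed seed.
#'
#' @param n_residues number of pseudo-residues (atoms) in the shell.
#' @param cavity_center length-3 vector (Angstrom).
#' @param cavity_radius planted cavity radius (Angstrom), > 0.
#' @param channel_axis direction of the access channel (normalised
#'   internally).
#' @param seed RNG seed for the small positional jitter.
#' @param shell_thickness radial extent of the atom shell beyond its
#'   innermost layer (Angstrom); must be > 0.
#' @param channel_radius bore radius of the access channel: atoms closer
#'   than this to the outbound channel axis are removed.
#' @param res_names residue names recycled over the shell residues.
#' @return [Structure] with attributes `cavity_center`, `cavity_radius`,
#'   `channel_axis` for downstream generators.
#' @export
make_toy_receptor <- function(n_residues = 1500, cavity_center = c(0, 0, 0),
                              cavity_radius = 5, channel_axis = c(0, 0, 1),
                              seed = 1, shell_thickness = 4,
                              channel_radius = 3.6, res_names = "ALA") {
  if (cavity_radius <= 0) stop("cavity_radius must be > 0")
  if (shell_thickness <= 0)
    stop("cavity larger than the shell allows: shell_thickness must be > 0")
  set.seed(seed)
  u <- .unit(channel_axis)
  r_inner <- cavity_radius + 1.4 + 1.7  # probe + carbon vdW: cavity stays empty
  layer_r <- seq(r_inner, r_inner + shell_thickness, by = 2)
  # distribute residues over layers proportional to surface area
  w <- layer_r^2 / sum(layer_r^2)
  n_layer <- round(n_residues * w)
  n_layer[length(n_layer)] <- n_residues - sum(n_layer[-length(n_layer)])
  pts <- do.call(rbind, lapply(seq_along(layer_r), function(k) {
    .fibonacci_sphere(n_layer[k]) * layer_r[k]
  }))
  pts <- pts + matrix(stats::rnorm(length(pts), 0, 0.08), ncol = 3)
  # bore the channel: drop atoms near the outbound half-axis
  t_axis <- as.vector(pts %*% u)
  perp <- sqrt(pmax(rowSums(pts^2) - t_axis^2, 0))
  keep <- !(t_axis > 0 & perp < channel_radius)
  pts <- pts[keep, , drop = FALSE]
  pts <- sweep(pts, 2, cavity_center, `+`)
  n <- nrow(pts)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    res_name = rep_len(toupper(res_names), n),
    res_id = seq_len(n), chain = "A", stringsAsFactors = FALSE)
  s <- Structure(atoms, pts)
  attr(s, "cavity_center") <- as.numeric(cavity_center)
  attr(s, "cavity_radius") <- cavity_radius
  attr(s, "channel_axis") <- u
  s
}

#' Toy ligand (rigid pseudo-molecule)
#'
#' An elongated carbon blob standing in for a drug-like agonist
#' (default 33 heavy atoms, roughly 14 x 6 x 5 Angstrom), centred so its
#' mass-weighted center of mass is exactly at the origin.
#'
#' @param n_atoms heavy-atom count.
#' @param seed RNG seed.
#' @param semi_axes ellipsoid semi-axes (Angstrom) the atoms fill.
#' @return [Structure] (res_name `LIG`, chain `L`).
#' @export
make_toy_ligand <- function(n_atoms = 33, seed = 1,
                            semi_axes = c(7, 3, 2.5)) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n_atoms) {
    cand <- matrix(stats::runif(3 * n_atoms * 2, -1, 1), ncol = 3)
    cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- sweep(pts[seq_len(n_atoms), , drop = FALSE], 2, semi_axes, `*`)
  pts <- sweep(pts, 2, colMeans(pts))  # equal masses: COM = centroid
  atoms <- data.frame(
    serial = seq_len(n_atoms), name = paste0("C", seq_len(n_atoms)),
    element = "C", res_name = "LIG", res_id = 1L, chain = "L",
    stringsAsFactors = FALSE)
  Structure(atoms, pts)
}

# min distance from each of m points to any ligand atom (vectorized)
.min_dist_to <- function(points, atom_xyz) {
  if (nrow(points) == 0) return(numeric(0))
  d2 <- matrix(Inf, nrow(points), nrow(atom_xyz))
  for (j in seq_len(nrow(atom_xyz)))
    d2[, j] <- (points[, 1] - atom_xyz[j, 1])^2 +
               (points[, 2] - atom_xyz[j, 2])^2 +
               (points[, 3] - atom_xyz[j, 3])^2
  sqrt(do.call(pmin, as.data.frame(d2)))
}

# rejection-sample n points in an axis-aligned box (center, edge) whose
# min distance to atom_xyz satisfies `accept(mindist)`
.sample_points <- function(n, center, edge, atom_xyz, accept) {
  out <- matrix(NA_real_, 0, 3)
  guard <- 0
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 64)
    cand <- matrix(stats::runif(3 * m, -edge / 2, edge / 2), ncol = 3)
    cand <- sweep(cand, 2, center, `+`)
    ok <- accept(.min_dist_to(cand, atom_xyz))
    out <- rbind(out, cand[ok, , drop = FALSE])
    guard <- guard + 1
    if (guard > 200) stop("water placement failed: acceptance region too small")
  }
  out[seq_len(n), , drop = FALSE]
}

# Monte-Carlo estimate of the expected first-shell water count for a
# ligand in a uniform box: n_waters * V_shell / V_free
.expected_shell_count <- function(lig_xyz, n_waters, box_edge,
                                  cutoff, excl, n_mc = 40000) {
  cand <- matrix(stats::runif(3 * n_mc, -box_edge / 2, box_edge / 2), ncol = 3)
  md <- .min_dist_to(cand, sweep(lig_xyz, 2, colMeans(lig_xyz)))
  n_excl <- sum(md <= excl)
  n_shell <- sum(md > excl & md <= cutoff)
  n_waters * n_shell / (n_mc - n_excl)
}

# brute-force per-residue contact frames from emitted coordinates
.contact_truth <- function(rec_xyz, residue_of, lig_frames, cutoff) {
  n_res <- max(residue_of)
  out <- vector("list", n_res)
  for (f in seq_along(lig_frames)) {
    lig <- lig_frames[[f]]
    mind <- .min_dist_to(rec_xyz, lig)
    hit <- unique(residue_of[mind <= cutoff])
    for (r in hit) out[[r]] <- c(out[[r]], f)
  }
  names(out) <- as.character(seq_len(n_res))
  out[!vapply(out, is.null, logical(1))]
}

#' Planted ligand-translocation trajectory with exact ground truth
#'
#' Emits a trajectory in which the ligand center of mass sits at
#' `planted_distances[state] + N(0, noise_sd)` Angstrom from the
#' receptor's cavity center along its channel axis, dwelling
#' `dwell_frames[state]` frames per state in ingress order. Optional
#' explicit water pseudo-atoms are placed at bulk density in a moving
#' box around the ligand; in states with a planted shell-retention
#' fraction the first-solvation-shell occupancy is constructed to be
#' that fraction of the expected bulk count. Ground truth (distances,
#' per-residue contact frames, per-frame shell counts) is recomputed
#' from the emitted coordinates.
#'
#' @param receptor a [make_toy_receptor()] structure.
#' @param ligand ligand [Structure]; default [make_toy_ligand()].
#' @param planted_distances named vector, state -> mean distance
#'   (Angstrom); names form a prefix-to-suffix run of
#'   bulk, contact, entry, vestibule, binding in that order.
#' @param dwell_frames named integer vector, state -> frame count (> 0),
#'   same names as `planted_distances`.
#' @param noise_sd Gaussian jitter of the planted distance (Angstrom).
#' @param n_waters water pseudo-atoms in the moving hydration box
#'   (0 disables solvation content).
#' @param seed RNG seed.
#' @param shell_retention named vector, state -> fraction of the expected
#'   bulk shell count planted in that state; states not listed get
#'   natural uniform placement.
#' @param water_box edge of the moving hydration box (Angstrom).
#' @param shell_cutoff first-shell cutoff used for planting and truth.
#' @param excl minimum water-to-ligand-atom distance (excluded volume).
#' @param contact_cutoff cutoff for the brute-force contact truth.
#' @param contact_truth compute the per-residue contact schedule (can be
#'   switched off for large cohorts where only distances matter).
#' @return list with elements `trajectory` ([Trajectory]) and `truth`
#'   (class `TranslocationTruth`: `state_schedule`, `planted_distances`,
#'   `distances`, `contact_schedule`, `shell_counts`,
#'   `expected_bulk_shell`, `entered_vestibule`, `fully_bound`, `seed`).
#' @export
make_translocation_trajectory <- function(
    receptor, ligand = NULL,
    planted_distances = c(bulk = 40, contact = 20, entry = 12,
                          vestibule = 6.5, binding = 2),
    dwell_frames = c(bulk = 40, contact = 40, entry = 40,
                     vestibule = 40, binding = 40),
    noise_sd = 0.5, n_waters = 0, seed = 1,
    shell_retention = c(contact = 0.7, entry = 0.5,
                        vestibule = 0.2, binding = 0.2),
    water_box = 20, shell_cutoff = 3.0, excl = 2.4,
    contact_cutoff = 4.0, contact_truth = TRUE) {
  states <- names(planted_distances)
  if (is.null(states) || !all(states %in% .state_ladder))
    stop("planted_distances must be named with states from: ",
         paste(.state_ladder, collapse = ", "))
  if (!identical(states, .state_ladder[.state_ladder %in% states]))
    stop("inconsistent state order: states must follow ",
         paste(.state_ladder, collapse = " -> "))
  if (!identical(sort(names(dwell_frames)), sort(states)))
    stop("dwell_frames must name the same states as planted_distances")
  if (any(dwell_frames <= 0)) stop("dwell_frames must be positive")
  dwell_frames <- dwell_frames[states]
  set.seed(seed)
  if (is.null(ligand)) ligand <- make_toy_ligand(seed = seed)
  center <- attr(receptor, "cavity_center")
  u <- attr(receptor, "channel_axis")
  if (is.null(center) || is.null(u))
    stop("receptor lacks cavity_center/channel_axis attributes; ",
         "use make_toy_receptor()")
  schedule <- rep(states, times = dwell_frames)
  n_fr <- length(schedule)
  d <- planted_distances[schedule] + stats::rnorm(n_fr, 0, noise_sd)
  d <- pmax(d, 0)
  lig0 <- sweep(ligand$xyz, 2, center_of_mass(ligand))  # COM at origin
  n_lig <- nrow(lig0)

  exp_shell <- if (n_waters > 0)
    .expected_shell_count(lig0, n_waters, water_box, shell_cutoff, excl)
  else NA_real_

  rec_heavy <- atom_select(receptor, heavy = TRUE)
  residue_of <- .residue_of_atom(receptor)

  frames <- vector("list", n_fr)
  lig_frames <- vector("list", n_fr)
  shell_counts <- integer(n_fr)
  for (f in seq_len(n_fr)) {
    com <- center + u * d[f]
    lig <- sweep(lig0, 2, com, `+`)
    lig_frames[[f]] <- lig
    wat <- NULL
    if (n_waters > 0) {
      st <- schedule[f]
      if (st %in% names(shell_retention)) {
        k <- round(shell_retention[[st]] * exp_shell)
        k <- min(k, n_waters)
        in_shell <- if (k > 0)
          .sample_points(k, com, water_box, lig,
                         function(md) md > excl & md <= shell_cutoff - 0.05)
        else matrix(NA_real_, 0, 3)
        out_shell <- .sample_points(n_waters - k, com, water_box, lig,
                                    function(md) md > shell_cutoff + 0.2)
        wat <- rbind(in_shell, out_shell)
      } else {
        wat <- .sample_points(n_waters, com, water_box, lig,
                              function(md) md > excl)
      }
      shell_counts[f] <- sum(.min_dist_to(wat, lig) <= shell_cutoff)
    }
    frames[[f]] <- rbind(receptor$xyz, lig, wat)
  }

  topo_atoms <- rbind(
    receptor$atoms[, c("serial", "name", "element", "res_name",
                       "res_id", "chain")],
    ligand$atoms[, c("serial", "name", "element", "res_name",
                     "res_id", "chain")])
  if (n_waters > 0) {
    topo_atoms <- rbind(topo_atoms, data.frame(
      serial = seq_len(n_waters), name = "O", element = "O",
      res_name = "HOH", res_id = seq_len(n_waters), chain = "W",
      stringsAsFactors = FALSE))
  }
  topo_atoms$serial <- seq_len(nrow(topo_atoms))
  topology <- Structure(topo_atoms, frames[[1]])
  traj <- Trajectory(topology, frames)

  contact_schedule <- if (contact_truth)
    .contact_truth(receptor$xyz[rec_heavy, , drop = FALSE],
                   residue_of[rec_heavy], lig_frames, contact_cutoff)
  else NULL

  truth <- structure(list(
    state_schedule = schedule,
    planted_distances = planted_distances,
    distances = {
      coms <- t(vapply(lig_frames, colMeans, numeric(3)))
      sqrt(rowSums(sweep(coms, 2, center)^2))
    },
    contact_schedule = contact_schedule,
    shell_counts = if (n_waters > 0) shell_counts else NULL,
    expected_bulk_shell = exp_shell,
    entered_vestibule = any(c("vestibule", "binding") %in% states),
    fully_bound = "binding" %in% states,
    seed = seed), class = "TranslocationTruth")
  list(trajectory = traj, truth = truth)
}

#' @export
print.TranslocationTruth <- function(x, ...) {
  cat(sprintf("TranslocationTruth: %d frames, states %s; vestibule=%s, bound=%s\n",
              length(x$state_schedule),
              paste(unique(x$state_schedule), collapse = ">"),
              x$entered_vestibule, x$fully_bound))
  invisible(x)
}

#' Cohort of planted trajectories with known entry counts
#'
#' Generates `n_traj` trajectories of which exactly `n_entering` reach
#' the vestibule and exactly `n_binding` (a subset) reach the binding
#' site; the rest stay in bulk/contact. Frame budgets are chosen so each
#' trajectory has the same length regardless of how far it gets.
#'
#' @param receptor [make_toy_receptor()] structure.
#' @param n_traj,n_entering,n_binding cohort design
#'   (`n_binding <= n_entering <= n_traj`).
#' @param seed RNG seed; trajectory i uses `seed + i`.
#' @param frames_per_traj total frames per trajectory (split evenly over
#'   that trajectory's states).
#' @param noise_sd distance jitter (Angstrom).
#' @param n_waters waters per trajectory (default 0: cohorts are about
#'   distances).
#' @param contact_truth compute contact schedules (default FALSE).
#' @param ... passed to [make_translocation_trajectory()].
#' @return list with `trajectories` (list of [Trajectory]) and `truth`
#'   (class `CohortTruth`: counts plus per-trajectory truths).
#' @export
make_cohort <- function(receptor, n_traj = 88, n_entering = 19,
                        n_binding = 7, seed = 1, frames_per_traj = 200,
                        noise_sd = 0.5, n_waters = 0,
                        contact_truth = FALSE, ...) {
  if (!(n_binding <= n_entering && n_entering <= n_traj))
    stop("require n_binding <= n_entering <= n_traj")
  full <- c(bulk = 40, contact = 20, entry = 12, vestibule = 6.5, binding = 2)
  kinds <- c(rep("binding", n_binding),
             rep("vestibule", n_entering - n_binding),
             rep("none", n_traj - n_entering))
  trajectories <- vector("list", n_traj)
  per_truth <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    dist_i <- switch(kinds[i],
                     binding = full,
                     vestibule = full[1:4],
                     none = full[1:2])
    n_states <- length(dist_i)
    dwell <- rep(frames_per_traj %/% n_states, n_states)
    dwell[n_states] <- frames_per_traj - sum(dwell[-n_states])
    names(dwell) <- names(dist_i)
    r <- make_translocation_trajectory(
      receptor, planted_distances = dist_i, dwell_frames = dwell,
      noise_sd = noise_sd, n_waters = n_waters, seed = seed + i,
      contact_truth = contact_truth, ...)
    trajectories[[i]] <- r$trajectory
    per_truth[[i]] <- r$truth
  }
  truth <- structure(list(
    n_trajectories = n_traj,
    n_vestibule_entries = n_entering,
    n_full_bindings = n_binding,
    per_trajectory = per_truth,
    seed = seed), class = "CohortTruth")
  list(trajectories = trajectories, truth = truth)
}

#' @export
print.CohortTruth <- function(x, ...) {
  cat(sprintf("CohortTruth: %d trajectories, %d vestibule entries, %d full bindings\n",
              x$n_trajectories, x$n_vestibule_entries, x$n_full_bindings))
  invisible(x)
}

#' Ligand in a bulk water box
#'
#' The bulk-reference system: the ligand fixed at the box center, water
#' pseudo-atoms (single oxygens) placed uniformly outside the ligand
#' excluded volume at the given number density, re-drawn every frame.
#'
#' @param ligand ligand [Structure]; default [make_toy_ligand()].
#' @param box_edge cubic box edge (Angstrom).
#' @param density waters per cubic Angstrom (default 0.0334, liquid
#'   water).
#' @param n_frames independent frames to emit.
#' @param seed RNG seed.
#' @param excl minimum water-to-ligand-atom distance (Angstrom).
#' @return [Trajectory] whose topology is ligand + waters.
#' @export
make_bulk_water_system <- function(ligand = NULL, box_edge = 20,
                                   density = 0.0334, n_frames = 50,
                                   seed = 1, excl = 2.4) {
  if (density <= 0) stop("density must be > 0")
  set.seed(seed)
  if (is.null(ligand)) ligand <- make_toy_ligand(seed = seed)
  lig0 <- sweep(ligand$xyz, 2, center_of_mass(ligand))
  max_ext <- max(sqrt(rowSums(lig0^2)))
  if (box_edge / 2 <= max_ext + excl)
    stop("box too small for ligand: need edge > ",
         round(2 * (max_ext + excl), 1), " A")
  n_w <- round(density * box_edge^3)
  n_lig <- nrow(lig0)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    wat <- if (n_w > 0)
      .sample_points(n_w, c(0, 0, 0), box_edge, lig0,
                     function(md) md > excl)
    else matrix(NA_real_, 0, 3)
    frames[[f]] <- rbind(lig0, wat)
  }
  atoms <- ligand$atoms[, c("serial", "name", "element", "res_name",
                            "res_id", "chain")]
  if (n_w > 0) {
    atoms <- rbind(atoms, data.frame(
      serial = seq_len(n_w), name = "O", element = "O",
      res_name = "HOH", res_id = seq_len(n_w), chain = "W",
      stringsAsFactors = FALSE))
  }
  atoms$serial <- seq_len(nrow(atoms))
  Trajectory(Structure(atoms, frames[[1]]), frames)
}

#' Alignment with planted pairwise identity and similarity
#'
#' Constructs (never samples) an alignment in which the designated
#' sequence pair realises the requested identity and similarity
#' percentages EXACTLY over the designated positions: matched columns get
#' equal residues, similar-only columns get distinct residues from the
#' same similarity group, and the rest get residues from different
#' groups.
#'
#' @param n_seqs number of sequences (>= 2).
#' @param length alignment columns.
#' @param positions columns over which the plan is planted
#'   (default `1:length`).
#' @param identity planned fraction of identical positions, in `[0, 1]`;
#'   `identity * length(positions)` must be an integer.
#' @param similarity planned fraction of identical-or-similar positions
#'   (>= identity; same integrality requirement). Default: equal to
#'   `identity` (no similar-only columns).
#' @param pair indices of the two planned sequences (default first two).
#' @param seed RNG seed for the unconstrained content.
#' @param groups similarity groups (default
#'   [default_similarity_groups()]).
#' @return [Alignment]; attribute `truth` records the planted positions
#'   and percentages.
#' @export
make_alignment <- function(n_seqs, length, positions = seq_len(length),
                           identity = 1, similarity = identity,
                           pair = c(1, 2), seed = 1,
                           groups = default_similarity_groups()) {
  stopifnot(n_seqs >= 2, length >= 1)
  if (identity < 0 || identity > 1 || similarity < identity ||
      similarity > 1)
    stop("require 0 <= identity <= similarity <= 1")
  npos <- base::length(positions)
  n_id <- identity * npos
  n_sim <- (similarity - identity) * npos
  if (abs(n_id - round(n_id)) > 1e-9 || abs(n_sim - round(n_sim)) > 1e-9)
    stop("infeasible plan: identity/similarity must be multiples of 1/",
         npos, " over ", npos, " positions")
  n_id <- round(n_id); n_sim <- round(n_sim)
  set.seed(seed)
  multi <- names(groups)[lengths(groups) >= 2]
  group_of <- unlist(lapply(names(groups), function(g)
    stats::setNames(rep(g, base::length(groups[[g]])), groups[[g]])))
  alphabet <- unlist(groups, use.names = FALSE)
  seqs <- matrix(sample(alphabet, n_seqs * length, replace = TRUE),
                 nrow = n_seqs)
  a <- pair[1]; b <- pair[2]
  # similar-only columns need a multi-member group on sequence A
  sim_cols <- positions[seq_len(n_sim)]
  id_cols <- positions[n_sim + seq_len(n_id)]
  diff_cols <- setdiff(positions, c(sim_cols, id_cols))
  for (p in sim_cols) {
    g <- sample(multi, 1)
    two <- sample(groups[[g]], 2)
    seqs[a, p] <- two[1]; seqs[b, p] <- two[2]
  }
  seqs[b, id_cols] <- seqs[a, id_cols]
  for (p in diff_cols) {
    g_a <- group_of[[seqs[a, p]]]
    other <- setdiff(names(groups), g_a)
    seqs[b, p] <- sample(groups[[sample(other, 1)]], 1)
  }
  out <- stats::setNames(apply(seqs, 1, paste, collapse = ""),
                         sprintf("seq%03d", seq_len(n_seqs)))
  aln <- Alignment(out)
  attr(aln, "truth") <- list(
    pair = names(out)[pair], positions = positions,
    identity_pct = 100 * identity, similarity_pct = 100 * similarity)
  aln
}

#' Constructed complementarity test complexes
#'
#' Emits a two-atom dipole ligand inside a spherical cage environment
#' whose per-atom charges or hydrophobicity constants are arranged to
#' make the complementarity outcome known by construction:
#' `perfect_electrostatic` anticorrelates the two surface potentials
#' (+q ligand pole faces -q cage side), `anti_electrostatic` is its
#' charge conjugate, and the hydrophobic variants align or oppose the
#' atomic hydrophobicity pattern.
#'
#' @param kind one of `"perfect_electrostatic"`, `"anti_electrostatic"`,
#'   `"hydrophobic_match"`, `"hydrophobic_clash"`.
#' @param seed RNG seed (small cage jitter).
#' @param cage_radius sphere radius of the environment cage (Angstrom).
#' @param n_cage cage atoms.
#' @return list with `ligand` and `environment` [Structure]s.
#' @export
make_complementarity_case <- function(kind = c("perfect_electrostatic",
                                               "anti_electrostatic",
                                               "hydrophobic_match",
                                               "hydrophobic_clash"),
                                      seed = 1, cage_radius = 7,
                                      n_cage = 80) {
  kind <- match.arg(kind)
  set.seed(seed)
  lig_xyz <- rbind(c(2, 0, 0), c(-2, 0, 0))
  lig <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                    res_name = "LIG", res_id = 1L, chain = "L",
                    stringsAsFactors = FALSE)
  cage_xyz <- .fibonacci_sphere(n_cage) * cage_radius
  cage_xyz <- cage_xyz + matrix(stats::rnorm(length(cage_xyz), 0, 0.05),
                                ncol = 3)
  env <- data.frame(serial = seq_len(n_cage), name = "C", element = "C",
                    res_name = "CGE", res_id = seq_len(n_cage), chain = "E",
                    stringsAsFactors = FALSE)
  xside <- cage_xyz[, 1] / cage_radius  # -1 .. 1 along the dipole axis
  if (kind %in% c("perfect_electrostatic", "anti_electrostatic")) {
    lig$charge <- c(1, -1)
    env$charge <- if (kind == "perfect_electrostatic") -0.5 * xside
                  else 0.5 * xside
  } else {
    lig$hydrophobicity <- c(1, -1)
    env$hydrophobicity <- if (kind == "hydrophobic_match") xside else -xside
  }
  list(ligand = Structure(lig, lig_xyz),
       environment = Structure(env, cage_xyz))
}

#' Trajectory with an exact per-residue contact schedule
#'
#' Builds a minimal system (single-atom pseudo-residues around a fixed
#' single-atom ligand) in which residue `r` is within the contact cutoff
#' exactly on the frames listed in `schedule[[r]]`, so planted contact
#' frequencies are recovered exactly.
#'
#' @param schedule named list, residue label -> integer frame vector.
#' @param n_frames total frames (>= max scheduled frame).
#' @param cutoff contact cutoff (Angstrom); residues sit at
#'   `cutoff - 0.5` when in contact and `cutoff + 4` when not.
#' @param res_names optional residue names (recycled; default `"ALA"`).
#' @return list with `trajectory` and `truth` (the schedule, plus the
#'   residue table).
#' @export
make_contact_trajectory <- function(schedule, n_frames, cutoff = 4.0,
                                    res_names = "ALA") {
  stopifnot(is.list(schedule), length(schedule) >= 1)
  if (max(unlist(schedule), 0) > n_frames)
    stop("schedule references frames beyond n_frames")
  n_res <- length(schedule)
  dirs <- .fibonacci_sphere(max(n_res, 4))[seq_len(n_res), , drop = FALSE]
  atoms <- rbind(
    data.frame(serial = 1L, name = "C1", element = "C", res_name = "LIG",
               res_id = 1L, chain = "L", stringsAsFactors = FALSE),
    data.frame(serial = 1L + seq_len(n_res), name = "CA", element = "C",
               res_name = rep_len(toupper(res_names), n_res),
               res_id = seq_len(n_res), chain = "A",
               stringsAsFactors = FALSE))
  frames <- lapply(seq_len(n_frames), function(f) {
    r_dist <- ifelse(vapply(schedule, function(fr) f %in% fr, logical(1)),
                     cutoff - 0.5, cutoff + 4)
    rbind(c(0, 0, 0), dirs * r_dist)
  })
  topo <- Structure(atoms, frames[[1]])
  list(trajectory = Trajectory(topo, frames),
       truth = list(schedule = schedule,
                    residues = residue_table(topo)[-1, ]))
}
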
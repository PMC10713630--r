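## Simplified surface-complementarity scores for pose ranking. Both
## scores are evaluated on quasi-uniform points of the ligand's
## solvent-accessible surface: the hydrophobic score is the Pearson
## correlation between ligand-sourced and environment-sourced molecular
## hydrophobicity potentials (MHP, exponential distance decay), the
## electrostatic score the ANTI-correlation of the two Coulomb surface
## potentials (+1 = perfectly complementary). These are documented
## correlates of the proprietary tools used in the literature, not
## replicas; only sign and ordering behaviour is claimed.

#' Sample the solvent-accessible surface of a ligand
#'
#' Places a Fibonacci lattice on each heavy atom's probe-expanded sphere
#' and removes points buried inside another atom's expanded sphere
#' (boundary points on coincident spheres are kept once). Deterministic.
#'
#' @param ligand [Structure].
#' @param probe probe radius (Angstrom).
#' @param density target points per square Angstrom.
#' @return object of class `SurfacePointSet`: `points` (m x 3), `areas`
#'   (per point, Angstrom^2), `owner_atom` (heavy-atom index into the
#'   ligand).
#' @export
sample_surface <- function(ligand, probe = 1.4, density = 1) {
  heavy <- atom_select(ligand, heavy = TRUE)
  if (length(heavy) == 0) stop("ligand has no heavy atoms")
  centers <- ligand$xyz[heavy, , drop = FALSE]
  R <- ligand$atoms$radius[heavy] + probe
  pts <- list(); owner <- list(); areas <- list()
  for (i in seq_along(heavy)) {
    n_i <- max(ceiling(density * 4 * pi * R[i]^2), 12)
    p <- .fibonacci_sphere(n_i) * R[i]
    p <- sweep(p, 2, centers[i, ], `+`)
    keep <- rep(TRUE, n_i)
    for (j in seq_along(heavy)) {
      if (j == i) next
      d <- sqrt(rowSums(sweep(p, 2, centers[j, ])^2))
      # strictly inside removes; exact-boundary duplicates (coincident
      # spheres) are kept only on the lower-index atom
      keep <- keep & !(d < R[j] - 1e-9 | (abs(d - R[j]) <= 1e-9 & j < i))
    }
    pts[[i]] <- p[keep, , drop = FALSE]
    owner[[i]] <- rep(heavy[i], sum(keep))
    areas[[i]] <- rep(4 * pi * R[i]^2 / n_i, sum(keep))
  }
  structure(list(points = do.call(rbind, pts),
                 areas = unlist(areas),
                 owner_atom = unlist(owner)),
            class = "SurfacePointSet")
}

#' @export
print.SurfacePointSet <- function(x, ...) {
  cat(sprintf("SurfacePointSet: %d points, total area %.1f A^2\n",
              nrow(x$points), sum(x$areas)))
  invisible(x)
}

# per-atom hydrophobicity constants: explicit column wins, element table
# otherwise; error on atoms covered by neither
.hydro_constants <- function(structure, selection) {
  f <- structure$atoms$hydrophobicity[selection]
  el <- structure$atoms$element[selection]
  tab <- atomic_hydrophobicity_table()
  miss <- is.na(f)
  f[miss] <- tab[el[miss]]
  if (anyNA(f)) {
    bad <- selection[is.na(f)]
    stop("no hydrophobicity constant for atom(s) ",
         paste(structure$atoms$name[bad], collapse = ", "),
         " (element ", paste(unique(el[is.na(f)]), collapse = ", "), ")")
  }
  f
}

#' Molecular hydrophobicity potential at surface points
#'
#' `value(p) = sum_i f_i * exp(-d(p, atom_i) / decay_length)` over the
#' heavy atoms of `source`, where `f_i` is the atom's hydrophobicity
#' constant (explicit `hydrophobicity` column, else the bundled element
#' table). There is no self-distance special case: a source atom
#' contributes `f_i * exp(-d/L)` at its own surface points too.
#'
#' @param points `m x 3` matrix or a `SurfacePointSet`.
#' @param source [Structure] generating the field.
#' @param decay_length exponential decay length (Angstrom).
#' @return numeric vector of field values, one per point.
#' @export
mhp_field <- function(points, source, decay_length = 2.0) {
  if (inherits(points, "SurfacePointSet")) points <- points$points
  heavy <- atom_select(source, heavy = TRUE)
  f <- .hydro_constants(source, heavy)
  axyz <- source$xyz[heavy, , drop = FALSE]
  v <- numeric(nrow(points))
  for (j in seq_along(heavy)) {
    d <- sqrt((points[, 1] - axyz[j, 1])^2 + (points[, 2] - axyz[j, 2])^2 +
                (points[, 3] - axyz[j, 3])^2)
    v <- v + f[j] * exp(-d / decay_length)
  }
  v
}

# Coulomb potential sum(q_i / d_i) at points; dielectric folded out by
# the downstream correlation
.coulomb_potential <- function(points, structure, selection) {
  q <- structure$atoms$charge[selection]
  if (anyNA(q)) stop("charges missing on some atoms; provide PQR charges")
  axyz <- structure$xyz[selection, , drop = FALSE]
  v <- numeric(nrow(points))
  for (j in seq_along(selection)) {
    d <- sqrt((points[, 1] - axyz[j, 1])^2 + (points[, 2] - axyz[j, 2])^2 +
                (points[, 3] - axyz[j, 3])^2)
    v <- v + q[j] / pmax(d, 1e-6)
  }
  v
}

#' Hydrophobic surface complementarity
#'
#' Pearson correlation between the ligand-sourced and environment-sourced
#' MHP over the ligand surface points: positive when hydrophobic ligand
#' patches face a hydrophobic environment.
#'
#' @param ligand,environment [Structure]s.
#' @param probe probe radius for the surface (Angstrom).
#' @param decay_length MHP decay length (Angstrom).
#' @param density surface point density (points per Angstrom^2).
#' @return score in `[-1, 1]`.
#' @export
hydrophobic_match <- function(ligand, environment, probe = 1.4,
                              decay_length = 2.0, density = 1) {
  sp <- sample_surface(ligand, probe = probe, density = density)
  vl <- mhp_field(sp, ligand, decay_length)
  ve <- mhp_field(sp, environment, decay_length)
  if (stats::sd(vl) == 0 || stats::sd(ve) == 0)
    stop("zero-variance MHP field; score undefined")
  stats::cor(vl, ve)
}

#' Electrostatic surface complementarity
#'
#' `-Pearson(phi_ligand, phi_environment)` over the ligand surface
#' points, with `phi = sum q_i / d_i`: +1 when the two potentials
#' perfectly anticorrelate (ideal complementarity), -1 when they match
#' in sign everywhere. Antisymmetric under charge conjugation of either
#' side.
#'
#' @param ligand,environment [Structure]s carrying `charge` (e.g. PQR).
#' @param probe probe radius (Angstrom).
#' @param density surface point density.
#' @return score in `[-1, 1]`.
#' @export
electrostatic_complementarity <- function(ligand, environment, probe = 1.4,
                                          density = 1) {
  sp <- sample_surface(ligand, probe = probe, density = density)
  lig_heavy <- atom_select(ligand, heavy = TRUE)
  env_heavy <- atom_select(environment, heavy = TRUE)
  phil <- .coulomb_potential(sp$points, ligand, lig_heavy)
  phie <- .coulomb_potential(sp$points, environment, env_heavy)
  if (stats::sd(phil) == 0 || stats::sd(phie) == 0)
    stop("zero-variance potential; score undefined")
  -stats::cor(phil, phie)
}

#' Both complementarity scores for one pose
#'
#' @inheritParams hydrophobic_match
#' @param electrostatic compute the electrostatic score (needs charges
#'   on both sides; skipped with NA when FALSE or charges are absent).
#' @return object of class `ComplementarityScore`: `hydrophobic_match`,
#'   `electrostatic_complementarity`, `n_points`.
#' @export
complementarity_score <- function(ligand, environment, probe = 1.4,
                                  decay_length = 2.0, density = 1,
                                  electrostatic = TRUE) {
  sp <- sample_surface(ligand, probe = probe, density = density)
  hm <- hydrophobic_match(ligand, environment, probe, decay_length, density)
  ec <- NA_real_
  has_q <- !anyNA(ligand$atoms$charge[atom_select(ligand, heavy = TRUE)]) &&
    !anyNA(environment$atoms$charge[atom_select(environment, heavy = TRUE)])
  if (electrostatic && has_q)
    ec <- electrostatic_complementarity(ligand, environment, probe, density)
  structure(list(hydrophobic_match = hm,
                 electrostatic_complementarity = ec,
                 n_points = nrow(sp$points)),
            class = "ComplementarityScore")
}

#' @export
print.ComplementarityScore <- function(x, ...) {
  cat(sprintf("ComplementarityScore: hydrophobic %.3f, electrostatic %s (%d surface points)\n",
              x$hydrophobic_match,
              if (is.na(x$electrostatic_complementarity)) "NA"
              else sprintf("%.3f", x$electrostatic_complementarity),
              x$n_points))
  invisible(x)
}

#' Flip a ligand pose 180 degrees
#'
#' Rotates the ligand half a turn about an axis through its center of
#' mass — the "reverted pose" operation used to test whether a bound
#' orientation beats its flip.
#'
#' @param ligand [Structure].
#' @param axis rotation axis (length-3; normalised internally).
#' @param weighting COM weighting.
#' @return [Structure] with rotated coordinates.
#' @export
flip_pose <- function(ligand, axis = c(0, 0, 1),
                      weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  u <- .unit(axis)
  R <- 2 * (u %o% u) - diag(3)  # 180-degree rotation about u
  com <- center_of_mass(ligand, weighting = weighting)
  with_coords(ligand, sweep(sweep(ligand$xyz, 2, com) %*% t(R), 2, com, `+`))
}

#' Score and rank ligand poses against a shared environment
#'
#' @param poses named list of ligand [Structure]s (>= 2).
#' @param environment shared environment [Structure].
#' @param order_by `"electrostatic"`, `"hydrophobic"`, or `"mean"`
#'   (mean of the two; NA electrostatic falls back to hydrophobic).
#' @param ... passed to [complementarity_score()].
#' @return data.frame sorted by the chosen metric (descending):
#'   `pose`, `hydrophobic`, `electrostatic`, `rank`.
#' @export
rank_poses <- function(poses, environment,
                       order_by = c("electrostatic", "hydrophobic",
                                    "mean"), ...) {
  order_by <- match.arg(order_by)
  stopifnot(length(poses) >= 2)
  if (is.null(names(poses)))
    names(poses) <- sprintf("pose%02d", seq_along(poses))
  rows <- lapply(names(poses), function(nm) {
    sc <- complementarity_score(poses[[nm]], environment, ...)
    data.frame(pose = nm, hydrophobic = sc$hydrophobic_match,
               electrostatic = sc$electrostatic_complementarity)
  })
  df <- do.call(rbind, rows)
  key <- switch(order_by,
                electrostatic = df$electrostatic,
                hydrophobic = df$hydrophobic,
                mean = rowMeans(cbind(df$hydrophobic, df$electrostatic),
                                na.rm = TRUE))
  if (order_by == "electrostatic" && anyNA(key)) key <- df$hydrophobic
  df <- df[order(-key), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
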
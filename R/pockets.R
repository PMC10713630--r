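## Grid-based cavity detection with ray-casting buriedness, lining-residue
## extraction and polarity scoring. A deterministic re-implementation of
## the classic pocket-finding step: a regular grid is laid over the
## structure, grid points outside every (vdW + probe) sphere are "empty",
## empty points seeing protein in at least `buriedness_min` of 14 fixed
## ray directions (within `max_ray` Angstrom) are pocket points, and
## 26-connected components of at least `min_points` points become
## pockets. Volume = n_points * spacing^3; no randomness anywhere.

# 14 ray directions: 6 axial + 8 cube diagonals, unit length
.ray_directions <- function() {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  unname(rbind(ax, dg))
}

#' Detect buried pockets on a regular grid
#'
#' @param structure [Structure] with at least one heavy atom.
#' @param spacing grid spacing (Angstrom).
#' @param probe solvent probe radius added to atomic van der Waals radii.
#' @param buriedness_min minimum number of the 14 ray directions that
#'   must hit protein for an empty point to count as buried (default 9).
#' @param min_points minimum component size, in grid points.
#' @param max_ray how far a ray looks for protein (Angstrom).
#' @param lining_cutoff cutoff used to fill each pocket's lining-residue
#'   list (see [lining_residues()]).
#' @param scale hydrophobicity scale used to fill each pocket's polarity
#'   score (see [polarity_score()]).
#' @return list of `Pocket` objects sorted by volume (descending); each
#'   has `grid_points`, `spacing`, `volume` (Angstrom^3), `centroid`,
#'   `lining_residues`, `polarity_score`, `buriedness_threshold`.
#' @export
detect_pockets <- function(structure, spacing = 1.0, probe = 1.4,
                           buriedness_min = 9, min_points = 30,
                           max_ray = 12, lining_cutoff = 4.5,
                           scale = hydrophobicity_scale("kd")) {
  heavy <- atom_select(structure, heavy = TRUE)
  if (length(heavy) == 0) stop("structure has no heavy atoms")
  axyz <- structure$xyz[heavy, , drop = FALSE]
  radii <- structure$atoms$radius[heavy]
  pad <- max(radii) + probe + spacing
  lo <- apply(axyz, 2, min) - pad
  hi <- apply(axyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  dims <- c(length(gx), length(gy), length(gz))
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))

  # occupancy: grid point within (vdw + probe) of any atom
  occ <- array(FALSE, dims)
  pairs <- neighbor_pairs(grid, axyz, max(radii) + probe)
  if (nrow(pairs) > 0) {
    inside <- pairs$distance <= radii[pairs$j] + probe
    occ[unique(pairs$i[inside])] <- TRUE
  }

  cand <- which(!occ)
  if (length(cand) == 0) return(list())
  # integer grid coordinates of the empty points
  ci <- arrayInd(cand, dims)
  dirs <- .ray_directions()
  n_steps <- floor(max_ray / spacing)
  bur <- integer(length(cand))
  for (d in seq_len(nrow(dirs))) {
    hit <- rep(FALSE, length(cand))
    for (s in seq_len(n_steps)) {
      # sample the ray at arc length s * spacing, mapped to the nearest
      # grid index (offset in cells = direction * s)
      pos_i <- ci + matrix(round(dirs[d, ] * s),
                           nrow = length(cand), ncol = 3, byrow = TRUE)
      ok <- !hit &
        pos_i[, 1] >= 1 & pos_i[, 1] <= dims[1] &
        pos_i[, 2] >= 1 & pos_i[, 2] <= dims[2] &
        pos_i[, 3] >= 1 & pos_i[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- pos_i[ok, 1] + (pos_i[ok, 2] - 1) * dims[1] +
        (pos_i[ok, 3] - 1) * dims[1] * dims[2]
      hit[ok] <- occ[lin]
    }
    bur <- bur + hit
  }
  pocket_pts <- cand[bur >= buriedness_min]
  if (length(pocket_pts) == 0) return(list())

  # 26-connected components over the pocket points
  is_pocket <- array(FALSE, dims); is_pocket[pocket_pts] <- TRUE
  visited <- array(FALSE, dims)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  comps <- list()
  for (p in pocket_pts) {
    if (visited[p]) next
    comp <- integer(0)
    frontier <- p
    visited[p] <- TRUE
    while (length(frontier) > 0) {
      comp <- c(comp, frontier)
      fc <- arrayInd(frontier, dims)
      nb <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(o)
        sweep(fc, 2, offsets[o, ], `+`)))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1) * dims[1] +
                      (nb[, 3] - 1) * dims[1] * dims[2])
      lin <- lin[is_pocket[lin] & !visited[lin]]
      visited[lin] <- TRUE
      frontier <- lin
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps <- comps[lengths(comps) >= min_points]
  if (length(comps) == 0) return(list())
  comps <- comps[order(lengths(comps), decreasing = TRUE)]
  lapply(comps, function(comp) {
    pts <- grid[comp, , drop = FALSE]
    lin_res <- .lining_from_points(pts, structure, lining_cutoff)
    pol <- if (nrow(lin_res) > 0 &&
               all(toupper(lin_res$res_name) %in% names(scale)))
      polarity_score(lin_res, scale) else NA_real_
    structure(list(grid_points = pts, spacing = spacing,
                   volume = length(comp) * spacing^3,
                   centroid = colMeans(pts),
                   lining_residues = lin_res,
                   polarity_score = pol,
                   buriedness_threshold = buriedness_min),
              class = "Pocket")
  })
}

#' @export
print.Pocket <- function(x, ...) {
  cat(sprintf("Pocket: %d grid points (%.1f A spacing), volume %.1f A^3, %d lining residues%s\n",
              nrow(x$grid_points), x$spacing, x$volume,
              nrow(x$lining_residues),
              if (is.na(x$polarity_score)) ""
              else sprintf(", polarity %.2f", x$polarity_score)))
  invisible(x)
}

.lining_from_points <- function(points, structure, lining_cutoff) {
  heavy <- atom_select(structure, heavy = TRUE)
  if (lining_cutoff <= 0 || length(heavy) == 0)
    return(data.frame(chain = character(), res_id = integer(),
                      res_name = character()))
  pairs <- neighbor_pairs(structure$xyz[heavy, , drop = FALSE], points,
                          lining_cutoff)
  if (nrow(pairs) == 0)
    return(data.frame(chain = character(), res_id = integer(),
                      res_name = character()))
  residue_table(structure, unique(heavy[pairs$i]))
}

#' Residues lining a pocket
#'
#' @param pocket `Pocket` from [detect_pockets()] on the same structure.
#' @param structure [Structure].
#' @param lining_cutoff residues with a heavy atom within this distance
#'   of any pocket grid point are lining (Angstrom).
#' @return data.frame `chain`, `res_id`, `res_name`.
#' @export
lining_residues <- function(pocket, structure, lining_cutoff = 4.5) {
  .lining_from_points(pocket$grid_points, structure, lining_cutoff)
}

#' Polarity score of a residue set
#'
#' Mean hydrophilicity of the residues under the chosen scale. Both
#' bundled scales are oriented so that HIGHER = MORE POLAR.
#'
#' @param residues character vector of 3-letter codes, or a data.frame
#'   with a `res_name` column (e.g. a lining-residue table).
#' @param scale [hydrophobicity_scale()].
#' @return mean scale value.
#' @export
polarity_score <- function(residues, scale = hydrophobicity_scale("kd")) {
  if (is.data.frame(residues)) residues <- residues$res_name
  residues <- toupper(residues)
  if (length(residues) == 0) stop("empty residue list")
  unknown <- setdiff(residues, names(scale))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "))
  mean(scale[residues])
}

#' Select the pocket of interest
#'
#' Automates the manual "pocket of interest" choice: `"largest"` takes
#' the biggest pocket; `"nearest_to_point"` takes the pocket whose
#' centroid is closest to a guide coordinate (e.g. a mapped reference
#' site), falling back to largest when no guide is given.
#'
#' @param pockets list of `Pocket`s from [detect_pockets()].
#' @param selector `"largest"` or `"nearest_to_point"`.
#' @param guide_point length-3 coordinate for `"nearest_to_point"`.
#' @return one `Pocket`, or `NULL` for an empty list.
#' @export
select_pocket <- function(pockets, selector = c("largest",
                                                "nearest_to_point"),
                          guide_point = NULL) {
  selector <- match.arg(selector)
  if (length(pockets) == 0) return(NULL)
  if (selector == "nearest_to_point" && !is.null(guide_point)) {
    d <- vapply(pockets, function(p)
      sqrt(sum((p$centroid - guide_point)^2)), numeric(1))
    return(pockets[[which.min(d)]])
  }
  pockets[[1]]  # detect_pockets sorts by volume descending
}

#' Compare pockets across homolog models
#'
#' Runs [detect_pockets()] on every model with identical parameters,
#' selects one pocket per model with the same selector, and tabulates
#' volume, polarity and lining composition so models can be ranked by
#' cavity polarity.
#'
#' @param models named list of [Structure]s (>= 2).
#' @param selector,guide_point see [select_pocket()].
#' @param scale [hydrophobicity_scale()].
#' @param ... passed to [detect_pockets()].
#' @return data.frame with one row per model: `name`, `n_pockets`,
#'   `volume`, `polarity`, `n_lining`, `lining` (comma-separated
#'   residues). Models without a pocket get NA values (with a message).
#' @export
compare_homolog_pockets <- function(models,
                                    selector = c("largest",
                                                 "nearest_to_point"),
                                    guide_point = NULL,
                                    scale = hydrophobicity_scale("kd"),
                                    ...) {
  selector <- match.arg(selector)
  stopifnot(length(models) >= 2)
  if (is.null(names(models)))
    names(models) <- sprintf("model%02d", seq_along(models))
  rows <- lapply(names(models), function(nm) {
    pk <- select_pocket(detect_pockets(models[[nm]], scale = scale, ...),
                        selector, guide_point)
    if (is.null(pk)) {
      message("model ", nm, ": no pocket detected")
      return(data.frame(name = nm, n_pockets = 0L, volume = NA_real_,
                        polarity = NA_real_, n_lining = NA_integer_,
                        lining = NA_character_))
    }
    lin <- pk$lining_residues
    data.frame(name = nm, n_pockets = 1L, volume = pk$volume,
               polarity = polarity_score(lin, scale),
               n_lining = nrow(lin),
               lining = paste(sprintf("%s%d:%s", lin$chain, lin$res_id,
                                      lin$res_name), collapse = ","))
  })
  do.call(rbind, rows)
}

#' Write pocket grid points as PDB pseudo-atoms
#'
#' @param pocket `Pocket`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(pocket, path) {
  n <- nrow(pocket$grid_points)
  atoms <- data.frame(serial = seq_len(n), name = "DU", element = "C",
                      res_name = "PKT", res_id = 1L, chain = "P",
                      stringsAsFactors = FALSE)
  write_structure(Structure(atoms, pocket$grid_points), path)
}
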
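## Geometric primitives: centers of mass, Kabsch superposition, mapping a
## reference-ligand site into a target frame, and cutoff neighbor search
## (cell lists, inclusive <=). No periodic-boundary handling anywhere:
## input coordinates are assumed imaged/whole.

#' Center of mass of a selection
#'
#' @param x [Structure], or an `n x 3` coordinate matrix.
#' @param selection atom indices (required when `x` is a Structure with
#'   more atoms than wanted; defaults to all atoms). Ignored for plain
#'   matrices unless given.
#' @param weighting `"mass"` (standard atomic masses, the default) or
#'   `"geometric"` (unweighted mean).
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(x, selection = NULL,
                           weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (inherits(x, "Structure")) {
    if (is.null(selection)) selection <- seq_len(nrow(x$atoms))
    if (length(selection) == 0) stop("empty selection")
    xyz <- x$xyz[selection, , drop = FALSE]
    w <- if (weighting == "mass") atomic_mass(x$atoms$element[selection])
         else rep(1, length(selection))
  } else {
    xyz <- as.matrix(x)
    if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
    if (nrow(xyz) == 0) stop("empty selection")
    w <- rep(1, nrow(xyz))  # plain matrices carry no elements: geometric
  }
  colSums(xyz * w) / sum(w)
}

#' Kabsch superposition
#'
#' Finds the rotation (det = +1, reflections corrected) and translation
#' minimising the weighted RMSD between paired coordinate sets, mapping
#' `mobile` onto `reference`.
#'
#' @param mobile,reference `n x 3` matrices of paired coordinates, n >= 3
#'   and not collinear.
#' @param weights optional per-pair weights (default uniform).
#' @return object of class `SuperpositionResult`: list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (Angstrom, weighted), and
#'   `n_pairs`. The transform maps mobile points as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("coordinate sets must be paired")
  if (n < 3) stop("need >= 3 paired points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # collinearity check on the weighted covariance of the mobile set
  if (qr(A * sqrt(w))$rank < 2)
    stop("points are collinear; superposition is underdetermined")
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- cr - as.vector(R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_pairs = n),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition over %d pairs: RMSD %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param xyz `n x 3` matrix.
#' @param sup `SuperpositionResult`.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' RMSD between two structures after optional superposition
#'
#' Convenience wrapper for model-vs-model comparisons: superposes paired
#' selections (default all atoms, assumed in matching order) and reports
#' the post-fit RMSD.
#'
#' @param a,b [Structure]s with paired atom order over the selections.
#' @param selection_a,selection_b atom indices (default all).
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
structure_rmsd <- function(a, b, selection_a = NULL, selection_b = NULL,
                           fit = TRUE) {
  xa <- if (is.null(selection_a)) a$xyz else a$xyz[selection_a, , drop = FALSE]
  xb <- if (is.null(selection_b)) b$xyz else b$xyz[selection_b, , drop = FALSE]
  if (nrow(xa) != nrow(xb)) stop("selections must pair one-to-one")
  if (fit) {
    sup <- kabsch_superpose(xa, xb)
    xa <- apply_superposition(xa, sup)
  }
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Map a reference-ligand site into a target structure
#'
#' Superposes C-alpha anchors of a ligand-bound reference complex onto
#' paired anchors of the target (Kabsch), then returns the transformed
#' center of mass of the reference ligand. This defines the binding-site
#' point used by [distance_series()].
#'
#' @param reference_complex [Structure] holding both the reference
#'   receptor and its bound ligand.
#' @param reference_ligand_selection atom indices of the reference ligand.
#' @param target [Structure] (or Trajectory frame realised as Structure).
#' @param pairing data.frame with columns `ref_chain`, `ref_res_id`,
#'   `target_chain`, `target_res_id`: residue pairs whose C-alpha atoms
#'   anchor the superposition (>= 3 pairs).
#' @param anchor_name atom name used as anchor (default `"CA"`).
#' @param weighting COM weighting for the ligand (default `"mass"`).
#' @return object of class `SitePoint`: list with `coord` (length-3,
#'   target frame), `source` description, and the `superposition` used.
#' @export
map_reference_site <- function(reference_complex, reference_ligand_selection,
                               target, pairing, anchor_name = "CA",
                               weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(pairing), nrow(pairing) >= 3)
  pick_ca <- function(s, chain, res_id) {
    i <- atom_select(s, chain = chain, res_id = res_id, name = anchor_name)
    if (length(i) != 1) NA_integer_ else i
  }
  ref_idx <- mapply(pick_ca, list(reference_complex),
                    pairing$ref_chain, pairing$ref_res_id)
  tgt_idx <- mapply(pick_ca, list(target),
                    pairing$target_chain, pairing$target_res_id)
  bad <- is.na(ref_idx) | is.na(tgt_idx)
  if (any(bad))
    stop("unpaired anchor residues: ",
         paste(sprintf("%s%d->%s%d", pairing$ref_chain[bad],
                       pairing$ref_res_id[bad], pairing$target_chain[bad],
                       pairing$target_res_id[bad]), collapse = ", "))
  sup <- kabsch_superpose(reference_complex$xyz[ref_idx, , drop = FALSE],
                          target$xyz[tgt_idx, , drop = FALSE])
  lig_com <- center_of_mass(reference_complex, reference_ligand_selection,
                            weighting = weighting)
  coord <- as.vector(apply_superposition(matrix(lig_com, 1, 3), sup))
  structure(list(coord = coord,
                 source = sprintf("reference ligand COM mapped via %d CA anchors (anchor RMSD %.3f A)",
                                  sup$n_pairs, sup$rmsd),
                 superposition = sup),
            class = "SitePoint")
}

#' Construct a SitePoint from an explicit coordinate
#' @param coord length-3 numeric vector (Angstrom, target frame).
#' @param source free-text provenance.
#' @return `SitePoint`.
#' @export
site_point <- function(coord, source = "user-specified") {
  stopifnot(length(coord) == 3, all(is.finite(coord)))
  structure(list(coord = as.numeric(coord), source = source,
                 superposition = NULL), class = "SitePoint")
}

#' @export
print.SitePoint <- function(x, ...) {
  cat(sprintf("SitePoint (%.2f, %.2f, %.2f) A [%s]\n",
              x$coord[1], x$coord[2], x$coord[3], x$source))
  invisible(x)
}

#' All cross pairs within a distance cutoff
#'
#' Cell-list neighbor search between two coordinate sets; the comparison
#' is inclusive (`distance <= cutoff`). Output is set-identical to the
#' brute-force double loop.
#'
#' @param coords_a,coords_b `n x 3` matrices.
#' @param cutoff Angstrom, > 0.
#' @return data.frame with columns `i` (row in a), `j` (row in b),
#'   `distance`; zero rows when nothing is in range.
#' @export
neighbor_pairs <- function(coords_a, coords_b, cutoff) {
  stopifnot(cutoff > 0)
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  cell <- cutoff
  ga <- floor(sweep(a, 2, lo) / cell)
  gb <- floor(sweep(b, 2, lo) / cell)
  # bucket b atoms by integer cell; for each a atom scan its 27 cells
  kb <- paste(gb[, 1], gb[, 2], gb[, 3])
  buckets <- split(seq_len(nrow(b)), kb)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  cutoff2 <- cutoff^2
  for (o in seq_len(nrow(offsets))) {
    ka <- paste(ga[, 1] + offsets[o, 1], ga[, 2] + offsets[o, 2],
                ga[, 3] + offsets[o, 3])
    hit <- ka %in% names(buckets)
    if (!any(hit)) next
    ai <- which(hit)
    cand <- buckets[ka[ai]]
    lens <- lengths(cand)
    ii <- rep(ai, lens)
    jj <- unlist(cand, use.names = FALSE)
    d2 <- rowSums((a[ii, , drop = FALSE] - b[jj, , drop = FALSE])^2)
    keep <- d2 <= cutoff2
    res_i <- c(res_i, ii[keep]); res_j <- c(res_j, jj[keep])
    res_d <- c(res_d, sqrt(d2[keep]))
  }
  if (length(res_i) == 0) return(empty)
  ord <- order(res_i, res_j)
  data.frame(i = res_i[ord], j = res_j[ord], distance = res_d[ord])
}
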
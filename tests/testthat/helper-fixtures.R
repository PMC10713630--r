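# Shared fixtures, memoised so expensive generators run once per session.
.fx <- new.env(parent = emptyenv())

fx_receptor <- function() {
  if (is.null(.fx$receptor)) .fx$receptor <- make_toy_receptor(seed = 7)
  .fx$receptor
}

# smaller receptor for cohort work (cavity geometry identical, fewer atoms)
fx_small_receptor <- function() {
  if (is.null(.fx$small))
    .fx$small <- make_toy_receptor(n_residues = 300, seed = 5)
  .fx$small
}

fx_site <- function(receptor = fx_receptor()) {
  site_point(attr(receptor, "cavity_center"))
}

# O(n^2) brute-force oracle for neighbor_pairs
brute_pairs <- function(a, b, cutoff) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    d <- sqrt(rowSums(sweep(b, 2, a[i, ])^2))
    j <- which(d <= cutoff)
    if (length(j))
      out[[length(out) + 1]] <- data.frame(i = i, j = j, distance = d[j])
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  do.call(rbind, out)
}

# minimal single-residue ligand structure at given coordinates
tiny_structure <- function(xyz, element = "C", chain = "L",
                           res_name = "LIG", charge = NULL,
                           hydrophobicity = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                      element = element, res_name = res_name, res_id = 1L,
                      chain = chain, stringsAsFactors = FALSE)
  if (!is.null(charge)) atoms$charge <- charge
  if (!is.null(hydrophobicity)) atoms$hydrophobicity <- hydrophobicity
  Structure(atoms, xyz)
}

# random rigid motion (rotation + translation), seeded by caller
random_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, 0, 5))
}

apply_rigid <- function(xyz, rg) sweep(xyz %*% t(rg$R), 2, rg$t, `+`)
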
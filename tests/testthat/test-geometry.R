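# Geometric primitives: centers of mass, Kabsch superposition, reference
# site mapping, and the cell-list neighbor search against brute force.

test_that("center of mass handles symmetry, single atoms, and mass weighting", {
  s <- tiny_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(s), c(x = 1, y = 0, z = 0))
  s1 <- tiny_structure(c(3, -1, 2))
  expect_equal(unname(center_of_mass(s1)), c(3, -1, 2))
  # brute-force check with mixed elements
  set.seed(10)
  xyz <- matrix(rnorm(150), ncol = 3)
  el <- sample(c("C", "N", "O", "S"), 50, replace = TRUE)
  s50 <- tiny_structure(xyz, element = el)
  m <- atomic_mass(el)
  expect_equal(unname(center_of_mass(s50)),
               as.numeric(colSums(xyz * m) / sum(m)))
  expect_equal(unname(center_of_mass(s50, weighting = "geometric")),
               as.numeric(colMeans(xyz)))
  expect_error(center_of_mass(s50, integer(0)), "empty")
})

test_that("Kabsch recovers exact rotations and never reflects", {
  set.seed(3)
  x <- matrix(rnorm(60), ncol = 3)
  th <- pi / 2
  R90 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  sup <- kabsch_superpose(x, x %*% t(R90))
  expect_lt(sup$rmsd, 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
  expect_equal(sup$rotation, R90, tolerance = 1e-10)
  # identical sets: identity rotation, zero translation
  sup0 <- kabsch_superpose(x, x)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sup0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("jittered superposition RMSD matches direct post-fit computation", {
  set.seed(4)
  for (k in 1:5) {
    x <- matrix(rnorm(60, sd = 5), ncol = 3)
    rg <- random_rigid()
    y <- apply_rigid(x, rg) + matrix(rnorm(60, sd = 0.1), ncol = 3)
    sup <- kabsch_superpose(x, y)
    fitted <- apply_superposition(x, sup)
    expect_equal(sup$rmsd, sqrt(mean(rowSums((fitted - y)^2))),
                 tolerance = 1e-10)
    expect_true(sup$rmsd > 0.05 && sup$rmsd < 0.2)
    # superposed RMSD never exceeds the unsuperposed pairing
    expect_lte(sup$rmsd, sqrt(mean(rowSums((x - y)^2))))
  }
})

test_that("neighbor_pairs is inclusive at the cutoff and matches brute force", {
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(3.99, 0, 0), 1)
  expect_equal(nrow(neighbor_pairs(a, b, 4.0)), 1)
  expect_equal(nrow(neighbor_pairs(a, matrix(c(4.01, 0, 0), 1), 4.0)), 0)
  for (seed in 1:10) {
    set.seed(seed)
    pa <- matrix(runif(1500, 0, 25), ncol = 3)
    pb <- matrix(runif(1500, 0, 25), ncol = 3)
    np <- neighbor_pairs(pa, pb, 3.0)
    bf <- brute_pairs(pa, pb, 3.0)
    expect_setequal(paste(np$i, np$j), paste(bf$i, bf$j))
  }
})

test_that("neighbor_pairs is symmetric and rigid-motion invariant", {
  set.seed(20)
  pa <- matrix(runif(300, 0, 15), ncol = 3)
  pb <- matrix(runif(300, 0, 15), ncol = 3)
  np <- neighbor_pairs(pa, pb, 4.0)
  sw <- neighbor_pairs(pb, pa, 4.0)
  expect_setequal(paste(np$i, np$j), paste(sw$j, sw$i))
  rg <- random_rigid()
  nr <- neighbor_pairs(apply_rigid(pa, rg), apply_rigid(pb, rg), 4.0)
  expect_setequal(paste(np$i, np$j), paste(nr$i, nr$j))
})

test_that("reference-site mapping is exact for identity and rigid motion", {
  rec <- fx_small_receptor()
  lig_atoms <- data.frame(serial = 1:3, name = c("C1", "C2", "C3"),
                          element = "C", res_name = "EUG", res_id = 999L,
                          chain = "X")
  ref <- Structure(
    rbind(rec$atoms[, c("serial", "name", "element", "res_name", "res_id",
                        "chain")], lig_atoms),
    rbind(coords(rec), matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3,
                              byrow = TRUE)))
  pairing <- data.frame(ref_chain = "A", ref_res_id = 1:20,
                        target_chain = "A", target_res_id = 1:20)
  ligsel <- atom_select(ref, chain = "X")
  com <- center_of_mass(ref, ligsel)
  sp <- map_reference_site(ref, ligsel, rec, pairing)
  expect_equal(sp$coord, unname(com), tolerance = 1e-9)
  # rigid covariance: moving the target moves the mapped site with it
  set.seed(8)
  rg <- random_rigid()
  tgt2 <- with_coords(rec, apply_rigid(coords(rec), rg))
  sp2 <- map_reference_site(ref, ligsel, tgt2, pairing)
  expect_equal(sp2$coord, as.numeric(apply_rigid(matrix(sp$coord, 1), rg)),
               tolerance = 1e-8)
  # unpaired residues are named
  badpair <- data.frame(ref_chain = "A", ref_res_id = c(1, 2, 99999),
                        target_chain = "A", target_res_id = c(1, 2, 99999))
  expect_error(map_reference_site(ref, ligsel, rec, badpair), "unpaired")
})

test_that("mapped site lands on the planted cavity center", {
  rec <- fx_small_receptor()
  center <- attr(rec, "cavity_center")
  lig_atoms <- data.frame(serial = 1:3, name = c("C1", "C2", "C3"),
                          element = "C", res_name = "EUG", res_id = 999L,
                          chain = "X")
  tri <- matrix(c(0.5, 0, 0, -0.25, 0.4, 0, -0.25, -0.4, 0), 3,
                byrow = TRUE)
  ref <- Structure(
    rbind(rec$atoms[, c("serial", "name", "element", "res_name", "res_id",
                        "chain")], lig_atoms),
    rbind(coords(rec), sweep(tri, 2, center - colMeans(tri), `+`)))
  pairing <- data.frame(ref_chain = "A", ref_res_id = 1:30,
                        target_chain = "A", target_res_id = 1:30)
  sp <- map_reference_site(ref, atom_select(ref, chain = "X"), rec, pairing)
  expect_equal(sp$coord, center, tolerance = 1e-6)
})

test_that("structure_rmsd reports the post-superposition deviation", {
  rec <- fx_small_receptor()
  set.seed(5)
  rg <- random_rigid()
  moved <- with_coords(rec, apply_rigid(coords(rec), rg))
  expect_lt(structure_rmsd(rec, moved), 1e-8)
  expect_gt(structure_rmsd(rec, moved, fit = FALSE), 1)
})
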
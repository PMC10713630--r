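# Surface sampling, MHP and electrostatic complementarity, pose ranking.

test_that("single-atom surface is an analytic probe-expanded sphere", {
  lig <- tiny_structure(c(0, 0, 0))  # carbon, vdW 1.7; probe 1.4 -> R 3.1
  sp <- sample_surface(lig)
  r <- sqrt(rowSums(sp$points^2))
  expect_true(all(abs(r - 3.1) < 1e-9))
  expect_equal(sum(sp$areas), 4 * pi * 3.1^2, tolerance = 0.05)
})

test_that("fully overlapping atoms expose the surface of one", {
  two <- tiny_structure(rbind(c(0, 0, 0), c(0, 0, 0)))
  one <- tiny_structure(c(0, 0, 0))
  sp2 <- sample_surface(two)
  sp1 <- sample_surface(one)
  expect_equal(sum(sp2$areas), sum(sp1$areas), tolerance = 1e-6)
})

test_that("dumbbell surface area matches Monte-Carlo rejection sampling", {
  dumb <- tiny_structure(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  sp <- sample_surface(dumb, density = 4)
  # MC oracle: fraction of each expanded sphere outside the other
  set.seed(90)
  R <- 3.1
  sphere_pts <- {
    v <- matrix(rnorm(3 * 20000), ncol = 3)
    v / sqrt(rowSums(v^2))
  }
  frac_outside <- function(center, other) {
    pts <- sweep(sphere_pts * R, 2, center, `+`)
    mean(sqrt(rowSums(sweep(pts, 2, other)^2)) >= R)
  }
  area_mc <- 4 * pi * R^2 * (frac_outside(c(0, 0, 0), c(2.5, 0, 0)) +
                               frac_outside(c(2.5, 0, 0), c(0, 0, 0)))
  expect_equal(sum(sp$areas), area_mc, tolerance = 0.05)
})

test_that("the MHP field is the stated exponential sum", {
  set.seed(91)
  xyz <- matrix(rnorm(30, sd = 3), ncol = 3)
  f <- runif(10, -1, 1)
  src <- tiny_structure(xyz, hydrophobicity = f)
  pts <- matrix(rnorm(15, sd = 5), ncol = 3)
  got <- mhp_field(pts, src, decay_length = 2)
  direct <- sapply(seq_len(nrow(pts)), function(i)
    sum(f * exp(-sqrt(rowSums(sweep(xyz, 2, pts[i, ])^2)) / 2)))
  expect_equal(got, direct, tolerance = 1e-12)
  # all-zero constants give an identically zero field
  zero <- tiny_structure(xyz, hydrophobicity = rep(0, 10))
  expect_equal(mhp_field(pts, zero), rep(0, nrow(pts)))
  # missing constants are reported by atom
  nohydro <- tiny_structure(xyz, element = "ZZ")
  expect_error(mhp_field(pts, nohydro), "no hydrophobicity constant")
})

test_that("constructed electrostatic cases score at their designed sign", {
  perfect <- make_complementarity_case("perfect_electrostatic", seed = 1)
  ec <- electrostatic_complementarity(perfect$ligand, perfect$environment)
  expect_gte(ec, 0.9)
  anti <- make_complementarity_case("anti_electrostatic", seed = 1)
  expect_lte(electrostatic_complementarity(anti$ligand, anti$environment),
             -0.9)
  # charge conjugation of the environment negates the score exactly
  env_flip <- perfect$environment
  env_flip$atoms$charge <- -env_flip$atoms$charge
  expect_equal(electrostatic_complementarity(perfect$ligand, env_flip), -ec,
               tolerance = 1e-12)
  # uncorrelated random charges give a null centered at zero and well
  # inside the designed extremes. Coulomb potentials are long-range, so
  # both surface fields are smooth and low-rank: individual null
  # correlations have sd ~ 0.3 whatever the atom count, and only the
  # center of the null distribution can be bounded tightly.
  set.seed(92)
  cage_xyz <- matrix(rnorm(600), ncol = 3)
  cage_xyz <- 8 * cage_xyz / sqrt(rowSums(cage_xyz^2))
  null_scores <- vapply(1:10, function(k) {
    lig_r <- tiny_structure(matrix(rnorm(90, sd = 3), ncol = 3),
                            charge = rnorm(30))
    env_r <- tiny_structure(cage_xyz, chain = "E", res_name = "CGE",
                            charge = rnorm(200))
    electrostatic_complementarity(lig_r, env_r)
  }, numeric(1))
  expect_lt(abs(mean(null_scores)), 0.3)  # ~3 sigma of the mean
  expect_true(all(abs(null_scores) < 0.9))
})

test_that("hydrophobic match and clash have the designed sign and rigid invariance", {
  hm <- make_complementarity_case("hydrophobic_match", seed = 1)
  hc <- make_complementarity_case("hydrophobic_clash", seed = 1)
  s_match <- hydrophobic_match(hm$ligand, hm$environment)
  s_clash <- hydrophobic_match(hc$ligand, hc$environment)
  expect_gt(s_match, 0)
  expect_lt(s_clash, 0)
  expect_gt(s_match, s_clash)
  # rigid motion of the whole complex leaves both scores unchanged up to
  # the surface-sampling resolution (the lattice is laid in grid axes,
  # so rotation re-samples the smooth fields at slightly shifted points)
  set.seed(93)
  rg <- random_rigid()
  lig_m <- with_coords(hm$ligand, apply_rigid(coords(hm$ligand), rg))
  env_m <- with_coords(hm$environment,
                       apply_rigid(coords(hm$environment), rg))
  expect_equal(hydrophobic_match(lig_m, env_m), s_match, tolerance = 2e-3)
  pe <- make_complementarity_case("perfect_electrostatic", seed = 1)
  e0 <- electrostatic_complementarity(pe$ligand, pe$environment)
  lig_e <- with_coords(pe$ligand, apply_rigid(coords(pe$ligand), rg))
  env_e <- with_coords(pe$environment,
                       apply_rigid(coords(pe$environment), rg))
  expect_equal(electrostatic_complementarity(lig_e, env_e), e0,
               tolerance = 2e-3)
})

test_that("a planted pose beats its flip on both metrics and ranking is consistent", {
  pe <- make_complementarity_case("perfect_electrostatic", seed = 2)
  # decorate with a matched hydrophobicity pattern so both metrics apply
  pe$ligand$atoms$hydrophobicity <- c(1, -1)
  pe$environment$atoms$hydrophobicity <-
    coords(pe$environment)[, 1] / 7
  flipped <- flip_pose(pe$ligand, axis = c(0, 0, 1))
  s_orig <- complementarity_score(pe$ligand, pe$environment)
  s_flip <- complementarity_score(flipped, pe$environment)
  expect_gt(s_orig$electrostatic_complementarity,
            s_flip$electrostatic_complementarity)
  expect_gt(s_orig$hydrophobic_match, s_flip$hydrophobic_match)
  # a pose and its copy tie; rank order equals a brute-force sort
  tab <- rank_poses(list(md = pe$ligand, copy = pe$ligand,
                         reverted = flipped),
                    pe$environment)
  expect_equal(tab$electrostatic[tab$pose == "md"],
               tab$electrostatic[tab$pose == "copy"])
  expect_equal(tab$pose[tab$rank == 3], "reverted")
  expect_setequal(tab$pose[tab$rank <= 2], c("md", "copy"))
})
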
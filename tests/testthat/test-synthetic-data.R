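# The generators: determinism, planted-geometry guarantees, and the
# consistency of emitted ground truth with emitted coordinates.

test_that("toy receptor keeps the planted cavity empty and is deterministic", {
  rec <- make_toy_receptor(cavity_radius = 5, seed = 7)
  d <- sqrt(rowSums(sweep(coords(rec), 2, attr(rec, "cavity_center"))^2))
  expect_gt(min(d), 5)
  rec2 <- make_toy_receptor(cavity_radius = 5, seed = 7)
  expect_identical(coords(rec), coords(rec2))
  expect_error(make_toy_receptor(cavity_radius = -1), "cavity_radius")
  expect_error(make_toy_receptor(shell_thickness = 0), "shell")
})

test_that("zero-noise trajectories sit exactly on the planted plateaus", {
  rec <- fx_small_receptor()
  pd <- c(bulk = 40, contact = 25, entry = 15, vestibule = 8, binding = 2)
  tr <- make_translocation_trajectory(
    rec, planted_distances = pd,
    dwell_frames = c(bulk = 5, contact = 5, entry = 5, vestibule = 5,
                     binding = 5),
    noise_sd = 0, seed = 3)
  lig <- atom_select(tr$trajectory$topology, chain = "L")
  ds <- distance_series(tr$trajectory, lig, site = fx_site(rec))
  expect_equal(unique(round(ds$distances, 9)), unname(pd))
  # emitted truth distances agree with the measured series
  expect_equal(tr$truth$distances, ds$distances, tolerance = 1e-9)
})

test_that("truncated schedules yield partial-entry truth flags", {
  rec <- fx_small_receptor()
  pd <- c(bulk = 40, contact = 20, entry = 12, vestibule = 6.5)
  tr <- make_translocation_trajectory(
    rec, planted_distances = pd,
    dwell_frames = c(bulk = 5, contact = 5, entry = 5, vestibule = 5),
    noise_sd = 0.2, seed = 4)
  expect_true(tr$truth$entered_vestibule)
  expect_false(tr$truth$fully_bound)
  expect_error(make_translocation_trajectory(
    rec, planted_distances = c(binding = 2, bulk = 40),
    dwell_frames = c(binding = 5, bulk = 5)), "state order")
})

test_that("contact ground truth is recomputed from emitted coordinates", {
  rec <- make_toy_receptor(n_residues = 200, seed = 11)
  tr <- make_translocation_trajectory(
    rec, dwell_frames = c(bulk = 10, contact = 10, entry = 10,
                          vestibule = 10, binding = 10),
    noise_sd = 0.5, seed = 12)
  topo <- tr$trajectory$topology
  lig <- atom_select(topo, chain = "L")
  recsel <- atom_select(topo, chain = "A")
  # independent re-scan of a few frames against the truth schedule
  for (f in c(1, 25, 50)) {
    fr <- with_coords(topo, tr$trajectory$frames[[f]])
    hits <- frame_contacts(fr, lig, recsel, cutoff = 4.0)
    truth_res <- names(tr$truth$contact_schedule)[
      vapply(tr$truth$contact_schedule, function(v) f %in% v, logical(1))]
    expect_setequal(as.character(hits$res_id), truth_res)
  }
})

test_that("cohort truth counts are planted exactly and validated", {
  rec <- fx_small_receptor()
  co <- make_cohort(rec, n_traj = 6, n_entering = 3, n_binding = 1,
                    seed = 2, frames_per_traj = 60)
  expect_equal(co$truth$n_trajectories, 6)
  expect_equal(co$truth$n_vestibule_entries, 3)
  expect_equal(co$truth$n_full_bindings, 1)
  flags <- vapply(co$truth$per_trajectory, `[[`, logical(1),
                  "entered_vestibule")
  expect_equal(sum(flags), 3)
  # full <= vestibule <= total holds on the per-trajectory truth too
  bound <- vapply(co$truth$per_trajectory, `[[`, logical(1), "fully_bound")
  expect_true(all(!bound | flags))
  expect_error(make_cohort(rec, n_traj = 4, n_entering = 5, n_binding = 1),
               "n_binding <= n_entering <= n_traj")
  # saturated and empty designs
  co0 <- make_cohort(rec, n_traj = 3, n_entering = 0, n_binding = 0,
                     seed = 2, frames_per_traj = 40)
  expect_true(all(!vapply(co0$truth$per_trajectory, `[[`, logical(1),
                          "entered_vestibule")))
  co1 <- make_cohort(rec, n_traj = 3, n_entering = 3, n_binding = 3,
                     seed = 2, frames_per_traj = 40)
  expect_true(all(vapply(co1$truth$per_trajectory, `[[`, logical(1),
                         "fully_bound")))
})

test_that("bulk water boxes scale with density and respect exclusion", {
  lig <- make_toy_ligand(seed = 1)
  b1 <- make_bulk_water_system(lig, n_frames = 20, seed = 5)
  b2 <- make_bulk_water_system(lig, density = 2 * 0.0334, n_frames = 20,
                               seed = 5)
  sel_l <- atom_select(b1$topology, chain = "L")
  counts <- function(tr) {
    w <- atom_select(tr$topology, water = TRUE)
    l <- atom_select(tr$topology, chain = "L")
    vapply(seq_len(n_frames(tr)), function(f)
      shell_count(with_coords(tr$topology, tr$frames[[f]]), l, w),
      integer(1))
  }
  c1 <- counts(b1); c2 <- counts(b2)
  # doubling density doubles the mean shell count within sampling error
  expect_equal(mean(c2) / mean(c1), 2, tolerance = 0.25)
  # no water violates the excluded volume
  w <- atom_select(b1$topology, water = TRUE)
  md <- apply(b1$frames[[1]][w, ], 1, function(p)
    min(sqrt(rowSums(sweep(b1$frames[[1]][sel_l, ], 2, p)^2))))
  expect_gt(min(md), 2.4)
  expect_error(make_bulk_water_system(lig, box_edge = 10), "too small")
})

test_that("planted alignments are constructive, not sampled", {
  aln <- make_alignment(6, 100, identity = 0.73, similarity = 0.82,
                        seed = 1)
  pc <- pocket_identity(aln, "seq001", "seq002")
  expect_equal(pc$identity_pct, 73.0)
  expect_equal(pc$similarity_pct, 82.0)
  # identical sequences
  aln2 <- make_alignment(2, 40, identity = 1, seed = 2)
  pc2 <- pocket_identity(aln2, "seq001", "seq002")
  expect_equal(pc2$identity_pct, 100.0)
  expect_equal(pc2$similarity_pct, 100.0)
  # infeasible plan: 73% of 10 positions is not an integer count
  expect_error(make_alignment(2, 10, identity = 0.73, seed = 1),
               "infeasible")
  # determinism
  expect_identical(make_alignment(6, 50, identity = 0.5, seed = 9)$sequences,
                   make_alignment(6, 50, identity = 0.5, seed = 9)$sequences)
})

test_that("complementarity cases carry the designed charge/hydrophobicity pattern", {
  cs <- make_complementarity_case("perfect_electrostatic", seed = 1)
  expect_equal(cs$ligand$atoms$charge, c(1, -1))
  x <- coords(cs$environment)[, 1]
  expect_true(all(sign(cs$environment$atoms$charge[abs(x) > 1]) ==
                    -sign(x[abs(x) > 1])))
  anti <- make_complementarity_case("anti_electrostatic", seed = 1)
  expect_equal(anti$environment$atoms$charge, -cs$environment$atoms$charge)
  hm <- make_complementarity_case("hydrophobic_match", seed = 1)
  hc <- make_complementarity_case("hydrophobic_clash", seed = 1)
  expect_equal(hm$environment$atoms$hydrophobicity,
               -hc$environment$atoms$hydrophobicity)
})
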
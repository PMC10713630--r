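# Distance series, state segmentation, entry events, cohort tallies and
# representative-frame selection.

test_that("distance series: ligand at the site gives zero, alignment gives invariance", {
  rec <- fx_small_receptor()
  site <- fx_site(rec)
  lig <- make_toy_ligand(seed = 2)
  lig0 <- sweep(coords(lig), 2, unname(center_of_mass(lig)))
  topo <- Structure(
    rbind(rec$atoms[, c("serial", "name", "element", "res_name", "res_id",
                        "chain")],
          lig$atoms[, c("serial", "name", "element", "res_name", "res_id",
                        "chain")]),
    rbind(coords(rec), sweep(lig0, 2, site$coord, `+`)))
  tr <- Trajectory(topo, list(coords(topo), coords(topo)))
  ligsel <- atom_select(topo, chain = "L")
  recsel <- atom_select(topo, chain = "A")
  ds <- distance_series(tr, ligsel, site = site)
  expect_equal(ds$distances, c(0, 0), tolerance = 1e-9)
  # rigidly rotating the whole system per frame is erased by alignment
  set.seed(6)
  frames <- lapply(1:4, function(k) apply_rigid(coords(topo), random_rigid()))
  tr2 <- Trajectory(topo, frames)
  ds2 <- distance_series(tr2, ligsel, recsel, site, align_each_frame = TRUE)
  expect_equal(ds2$distances, rep(0, 4), tolerance = 1e-6)
  expect_error(distance_series(tr, integer(0), site = site), "empty")
})

test_that("zero-noise segmentation places boundaries exactly at planted switches", {
  rec <- fx_small_receptor()
  tr <- make_translocation_trajectory(
    rec, planted_distances = c(contact = 20, entry = 12, vestibule = 6.5,
                               binding = 2),
    dwell_frames = c(contact = 30, entry = 25, vestibule = 20,
                     binding = 25),
    noise_sd = 0, seed = 3)
  ds <- distance_series(tr$trajectory,
                        atom_select(tr$trajectory$topology, chain = "L"),
                        site = fx_site(rec))
  seg <- segment_states(ds, method = "changepoint", n_states = 4)
  expect_equal(seg$boundaries, c(31, 56, 76))
  expect_equal(unique(seg$labels), c("contact", "entry", "vestibule",
                                     "binding"))
})

test_that("a monotone ramp enters each threshold state once, in order", {
  d <- seq(40, 1, length.out = 200)
  ds <- structure(list(distances = d, frame_indices = 1:200,
                       site = site_point(c(0, 0, 0)),
                       ligand_selection = 1L), class = "DistanceSeries")
  seg <- segment_states(ds, method = "threshold")
  rl <- rle(seg$labels)
  expect_equal(rl$values, c("bulk", "contact", "entry", "vestibule",
                            "binding"))
})

test_that("noisy changepoint recovery stays within 3 frames over 10 seeds", {
  rec <- fx_small_receptor()
  for (seed in 1:10) {
    tr <- make_translocation_trajectory(
      rec, planted_distances = c(contact = 20, entry = 12,
                                 vestibule = 6.5, binding = 2),
      dwell_frames = c(contact = 100, entry = 100, vestibule = 100,
                       binding = 100),
      noise_sd = 0.5, seed = 100 + seed, contact_truth = FALSE)
    ds <- distance_series(tr$trajectory,
                          atom_select(tr$trajectory$topology, chain = "L"),
                          site = fx_site(rec))
    seg <- segment_states(ds, method = "changepoint", n_states = 4)
    expect_true(all(abs(seg$boundaries - c(101, 201, 301)) <= 3),
                info = paste("seed", seed, "boundaries",
                             paste(seg$boundaries, collapse = " ")))
  }
})

test_that("entry events honour the dwell filter and threshold semantics", {
  th <- state_thresholds()
  mk <- function(d) structure(list(distances = d,
                                   frame_indices = seq_along(d),
                                   site = site_point(c(0, 0, 0)),
                                   ligand_selection = 1L),
                              class = "DistanceSeries")
  # always far outside: nothing detected
  ev <- detect_entry_events(mk(rep(30, 50)), th)
  expect_false(ev$entered_vestibule); expect_false(ev$fully_bound)
  # a sustained dip below d_binding triggers both with correct first frames
  d <- c(rep(30, 10), rep(8, 6), rep(3, 7), rep(8, 5))
  ev2 <- detect_entry_events(mk(d), th)
  expect_true(ev2$entered_vestibule); expect_true(ev2$fully_bound)
  expect_equal(ev2$first_vestibule_frame, 11L)
  expect_equal(ev2$first_binding_frame, 17L)
  # a single-frame spike below d_vestibule does not count
  d3 <- c(rep(30, 20), 8, rep(30, 20))
  ev3 <- detect_entry_events(mk(d3), th)
  expect_false(ev3$entered_vestibule)
  # monotone in thresholds: raising d_vestibule never loses an entry
  th_hi <- state_thresholds(d_vestibule = 12, d_binding = 4)
  set.seed(30)
  for (k in 1:10) {
    d <- runif(80, 0, 40)
    e_lo <- detect_entry_events(mk(d), th)
    e_hi <- detect_entry_events(mk(d), th_hi)
    expect_true(!e_lo$entered_vestibule || e_hi$entered_vestibule)
  }
})

test_that("threshold segmentation and event detection agree on vestibule entry", {
  rec <- fx_small_receptor()
  th <- state_thresholds()
  for (seed in 1:5) {
    tr <- make_translocation_trajectory(
      rec, noise_sd = 0.5, seed = 200 + seed, contact_truth = FALSE,
      dwell_frames = c(bulk = 30, contact = 30, entry = 30, vestibule = 30,
                       binding = 30))
    ds <- distance_series(tr$trajectory,
                          atom_select(tr$trajectory$topology, chain = "L"),
                          site = fx_site(rec))
    seg <- segment_states(ds, method = "threshold", thresholds = th)
    ev <- detect_entry_events(ds, th)
    r <- rle(seg$labels)
    has_vest_segment <- any(r$values %in% c("vestibule", "binding") &
                              r$lengths >= th$min_dwell)
    if (has_vest_segment) expect_true(ev$entered_vestibule)
  }
})

test_that("cohort tallies equal the brute-force flag count", {
  mk_ev <- function(v, b) structure(list(entered_vestibule = v,
                                         fully_bound = b,
                                         first_vestibule_frame = NA,
                                         first_binding_frame = NA),
                                    class = "EntryEvents")
  expect_equal(unname(summarize_cohort(list())), c(0, 0, 0))
  set.seed(40)
  for (k in 1:5) {
    v <- runif(30) < 0.4
    b <- v & runif(30) < 0.5
    evs <- mapply(mk_ev, v, b, SIMPLIFY = FALSE)
    expect_equal(unname(summarize_cohort(evs)), c(30, sum(v), sum(b)))
  }
})

test_that("representative frames obey the majority-cluster medoid rule", {
  # 1-atom ligand; frames form planted blobs in ligand position
  blob <- function(center, n, sd = 0.05) {
    lapply(seq_len(n), function(i)
      matrix(center + rnorm(3, 0, sd), 1, 3))
  }
  set.seed(50)
  frames <- c(blob(c(0, 0, 0), 30), blob(c(20, 0, 0), 10))
  topo <- tiny_structure(c(0, 0, 0))
  tr <- Trajectory(topo, frames)
  seg <- structure(list(labels = rep("binding", 40),
                        boundaries = integer(0), method = "threshold"),
                   class = "StateSegmentation")
  rep1 <- select_representative_frames(tr, seg, 1L, k = 2, seed = 1)
  expect_lte(rep1[["binding"]], 30)  # from the majority blob
  # 4 planted blobs: medoid equals brute-force nearest-to-centroid
  frames4 <- c(blob(c(0, 0, 0), 25), blob(c(20, 0, 0), 10),
               blob(c(0, 20, 0), 8), blob(c(0, 0, 20), 7))
  tr4 <- Trajectory(topo, frames4)
  seg4 <- structure(list(labels = rep("binding", 50),
                         boundaries = integer(0), method = "threshold"),
                    class = "StateSegmentation")
  rep4 <- select_representative_frames(tr4, seg4, 1L, k = 4, seed = 1)
  big <- t(vapply(frames4[1:25], function(m) m[1, ], numeric(3)))
  medoid <- which.min(rowSums(sweep(big, 2, colMeans(big))^2))
  expect_equal(unname(rep4[["binding"]]), medoid)
  # degenerate state: identical frames -> any frame, deterministically 1st
  tr_id <- Trajectory(topo, rep(list(matrix(c(1, 1, 1), 1, 3)), 10))
  seg_id <- structure(list(labels = rep("bulk", 10),
                           boundaries = integer(0), method = "threshold"),
                      class = "StateSegmentation")
  rep_id <- select_representative_frames(tr_id, seg_id, 1L, k = 4, seed = 1)
  expect_equal(unname(rep_id[["bulk"]]), 1L)
})
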
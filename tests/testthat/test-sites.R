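test_that("dual-cutoff hysteresis follows the stated rule", {
  d <- c(0.50, 0.70, 0.95, 1.05, 0.60)
  expect_identical(dual_cutoff_states(d), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # 0.60 does not re-bind: binding requires dropping below 0.55
  expect_error(dual_cutoff_states(numeric(0)), "empty")
  expect_error(dual_cutoff_states(d, lower = 1.2, upper = 1.0), "lower")
})

test_that("dual-cutoff states equal the frame-by-frame automaton on random series", {
  set.seed(11)
  for (rep in 1:200) {
    d <- runif(200, 0.2, 1.4)
    expect_identical(dual_cutoff_states(d),
                     dual_cutoff_oracle(d, 0.55, 1.0))
  }
  # degenerate lower == upper reduces to single-cutoff thresholding
  for (rep in 1:20) {
    d <- runif(100, 0.2, 1.4)
    expect_identical(dual_cutoff_states(d, 0.55, 0.55), d < 0.55)
  }
})

test_that("raising the upper cutoff never shortens a bound run", {
  set.seed(13)
  for (rep in 1:50) {
    d <- runif(300, 0.3, 1.3)
    lo_states <- dual_cutoff_states(d, 0.55, 0.8)
    hi_states <- dual_cutoff_states(d, 0.55, 1.1)
    # hysteresis monotonicity: every frame bound under the tight upper
    # cutoff is also bound under the looser one
    expect_true(all(hi_states[lo_states]))
  }
})

test_that("co-binding graph edges reflect simultaneous binding", {
  # two residues always bound to the same lipid together -> edge weight 1
  m <- matrix(c(rep(TRUE, 10), rep(TRUE, 10)), 2, 10, byrow = TRUE,
              dimnames = list(c("1", "2"), NULL))
  g <- build_cobinding_graph(make_bound_series(list(`1` = m)))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)
  # residues only ever bound to different lipids -> no edge
  m1 <- matrix(c(rep(c(TRUE, FALSE), 5), rep(FALSE, 10)), 2, 10,
               byrow = TRUE, dimnames = list(c("1", "2"), NULL))
  m2 <- matrix(c(rep(FALSE, 10), rep(c(FALSE, TRUE), 5)), 2, 10,
               byrow = TRUE, dimnames = list(c("1", "2"), NULL))
  g2 <- build_cobinding_graph(make_bound_series(list(`1` = m1, `2` = m2)))
  expect_equal(igraph::ecount(g2), 0)
  # no bound frames at all -> empty graph, flagged
  m0 <- matrix(FALSE, 2, 10, dimnames = list(c("1", "2"), NULL))
  expect_warning(g0 <- build_cobinding_graph(make_bound_series(list(`1` = m0))),
                 "no bound frames")
  expect_true(attr(g0, "empty"))
  expect_identical(detect_sites(g0), list())
})

test_that("community detection separates disjoint triplets and keeps cliques whole", {
  # residues 1-3 co-bind lipid A, residues 4-6 co-bind lipid B
  mk <- function(rows, frames_on) {
    m <- matrix(FALSE, 6, 40, dimnames = list(as.character(1:6), NULL))
    m[rows, frames_on] <- TRUE
    m
  }
  bs <- make_bound_series(list(`1` = mk(1:3, 1:20), `2` = mk(4:6, 21:40)))
  g <- build_cobinding_graph(bs)
  sites <- detect_sites(g, seed = 1)
  expect_length(sites, 2)
  expect_identical(sites[[1]], 1:3)
  expect_identical(sites[[2]], 4:6)
  # oracle: connected components of the thresholded graph
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  # a fully co-binding clique is one site
  bs2 <- make_bound_series(list(`1` = mk(1:6, 1:40)))
  sites2 <- detect_sites(build_cobinding_graph(bs2), seed = 1)
  expect_length(sites2, 1)
  expect_identical(sites2[[1]], 1:6)
  # detection is reproducible run-to-run with a fixed seed
  expect_identical(detect_sites(g, seed = 3), detect_sites(g, seed = 3))
})

test_that("site metrics compute occupancy, events and residence time", {
  # 100 frames; lipid bound to residue 1 in frames 11-12 and 51-54
  m <- matrix(FALSE, 2, 100, dimnames = list(c("1", "2"), NULL))
  m[1, c(11:12, 51:54)] <- TRUE
  bs <- make_bound_series(list(`1` = m))
  met <- site_metrics(c(1L, 2L), bs)
  expect_equal(met$occupancy, 0.06)
  expect_equal(met$n_events, 2)
  expect_equal(met$residence_ns, 3)      # mean of 2 and 4 frames at 1 ns
  expect_equal(met$events$start, c(10L, 50L))  # 0-based
  expect_equal(met$events$end, c(11L, 53L))
  expect_error(site_metrics(integer(0), bs), "empty site")
  # occupancy of a residue-set union dominates either subset
  m2 <- matrix(FALSE, 2, 100, dimnames = list(c("1", "2"), NULL))
  m2[1, 1:30] <- TRUE; m2[2, 60:70] <- TRUE
  bs2 <- make_bound_series(list(`1` = m2))
  expect_gte(site_metrics(c(1L, 2L), bs2)$occupancy,
             max(site_metrics(1L, bs2)$occupancy,
                 site_metrics(2L, bs2)$occupancy))
})

test_that("occupancy: 30 bound frames out of 100 gives 0.30", {
  m <- matrix(FALSE, 1, 100, dimnames = list("7", NULL))
  m[1, 21:50] <- TRUE
  bs <- make_bound_series(list(`1` = m))
  expect_equal(site_metrics(7L, bs)$occupancy, 0.30)
})

test_that("survival-fit residence estimator recovers a geometric dwell", {
  set.seed(17)
  dur <- rgeom(500, 0.1) + 1    # mean 10 frames
  est <- residence_time(dur, estimator = "survival")
  expect_lt(abs(est - 10) / 10, 0.25)
  # falls back to the mean with few events
  expect_equal(residence_time(c(2, 4), estimator = "survival"), 3)
})

test_that("filters drop short-residence sites and prune low-occupancy residues", {
  # site A: residence 8 ns -> removed; site B: long events -> kept
  mA <- matrix(FALSE, 3, 1000, dimnames = list(c("1", "2", "3"), NULL))
  for (s in seq(1, 900, by = 100)) mA[1, s:(s + 7)] <- TRUE  # 8-frame events
  mB <- matrix(FALSE, 3, 1000, dimnames = list(c("1", "2", "3"), NULL))
  for (s in seq(1, 900, by = 100)) mB[2, s:(s + 49)] <- TRUE # 50-frame events
  mB[3, 2] <- TRUE  # residue 3: occupancy 0.001 << 10% of site occupancy
  bs <- make_bound_series(list(`1` = mA, `2` = mB))
  sites <- list(c(list(site_id = 1, residue_ids = 1L),
                  site_metrics(1L, bs)),
                c(list(site_id = 2, residue_ids = c(2L, 3L)),
                  site_metrics(c(2L, 3L), bs)))
  expect_equal(sites[[1]]$residence_ns, 8)
  kept <- filter_sites(sites, bs, min_residence_ns = 10)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$residue_ids, 2L)  # residue 3 pruned
  # metrics recomputed after pruning
  expect_equal(kept[[1]]$occupancy, site_metrics(2L, bs)$occupancy)
  # all sites above threshold -> unchanged
  kept2 <- filter_sites(sites[2], bs, min_residence_ns = 1,
                        residue_occupancy_floor = 0)
  expect_identical(kept2[[1]]$residue_ids, c(2L, 3L))
})

test_that("the residue-occupancy floor is 10% of the site occupancy", {
  # site occupancy 0.50; residue 2 occupancy 0.03 < 0.05 -> pruned
  m <- matrix(FALSE, 2, 100, dimnames = list(c("1", "2"), NULL))
  m[1, 1:50] <- TRUE
  m[2, 10:12] <- TRUE
  bs <- make_bound_series(list(`1` = m))
  sites <- list(c(list(site_id = 1, residue_ids = c(1L, 2L)),
                  site_metrics(c(1L, 2L), bs)))
  kept <- filter_sites(sites, bs, min_residence_ns = 1)
  expect_identical(kept[[1]]$residue_ids, 1L)
})

test_that("representative pose picks the longest event with deterministic ties", {
  p <- generator_params(
    n_lipids_per_leaflet = 6, n_protein_residues = 10, n_frames = 600,
    seed = 23, min_background_distance = 0.7,
    planted_sites = list(planted_site(c(3, 4), p_on = 0.2, p_off = 0.1)))
  sys <- generate_system(p)
  bs <- find_binding_sites(sys$trajectory, sys$topology,
                           min_residence_ns = NULL)
  s <- bs$sites[[1]]
  expect_identical(s$pose$lipid_id, sys$ground_truth[[1]]$lipid_id)
  # pose frame lies inside the longest event
  dur <- s$events$end - s$events$start
  ev <- s$events[which.max(dur), ]
  expect_gte(s$pose$frame, ev$start)
  expect_lte(s$pose$frame, ev$end)
  # single one-frame event -> that frame and lipid
  m <- matrix(FALSE, 1, 10, dimnames = list("3", NULL))
  m[1, 4] <- TRUE
  bs1 <- make_bound_series(list(`1` = m))
  bs1$lipid_ids <- sys$ground_truth[[1]]$lipid_id
  names(bs1$states) <- as.character(bs1$lipid_ids)
  pose <- representative_pose(3L, sys$trajectory, sys$topology, bs1)
  expect_equal(pose$frame, 3L)
  # ties: two equal events -> the earlier one
  m2 <- matrix(FALSE, 1, 20, dimnames = list("3", NULL))
  m2[1, c(3:4, 11:12)] <- TRUE
  bs2 <- bs1; bs2$states <- list(m2); names(bs2$states) <- names(bs1$states)
  bs2$n_frames <- 20
  ev2 <- site_metrics(3L, bs2)$events
  pose2 <- representative_pose(3L, sys$trajectory, sys$topology, bs2, ev2)
  expect_lte(pose2$frame, 3L)
})

test_that("serialized events reproduce the stored occupancy exactly", {
  p <- generator_params(
    n_lipids_per_leaflet = 6, n_protein_residues = 10, n_frames = 500,
    seed = 29, min_background_distance = 0.7,
    planted_sites = list(planted_site(c(3, 4), p_on = 0.3, p_off = 0.2)))
  sys <- generate_system(p)
  bs <- find_binding_sites(sys$trajectory, sys$topology,
                           min_residence_ns = NULL)
  tf <- tempfile(fileext = ".json")
  sites_to_json(bs, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  for (i in seq_along(bs$sites)) {
    ev <- as.data.frame(back$sites$events[[i]])
    expect_equal(occupancy_from_events(ev, back$n_frames),
                 bs$sites[[i]]$occupancy)
  }
})
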
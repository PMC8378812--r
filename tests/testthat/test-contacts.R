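test_that("min_distance applies the minimum-image convention", {
  topo <- toy_topology(res_names = "ARG",
                       lipid_spec = data.frame(type = "POPE",
                                               leaflet = "inner"))
  # residue BB at x = 0.2, lipid PO4 at x = 9.9 in a 10 nm box -> 0.3 nm
  pos <- rbind(c(0.2, 5, 5), c(9.9, 5, 5), c(9.9, 5, 5))
  traj <- static_trajectory(pos)
  expect_equal(min_distance(traj, topo, 1, 1), 0.3, tolerance = 1e-12)
  # identical coordinates -> 0
  pos2 <- rbind(c(1, 1, 1), c(1, 1, 1), c(4, 4, 4))
  expect_equal(min_distance(static_trajectory(pos2), topo, 1, 1), 0)
  expect_error(min_distance(traj, topo, 5, 1), "unknown residue_id")
  expect_error(min_distance(traj, topo, 1, 1, lipid_roles = "GL9"),
               "no beads")
})

test_that("min distance is symmetric and translation invariant, matching brute force", {
  set.seed(101)
  box <- c(5, 5, 5)
  for (rep in 1:20) {
    a <- matrix(runif(9, 0, 5), 3)
    b <- matrix(runif(12, 0, 5), 4)
    coords <- array(rbind(a, b), c(1, 7, 3))
    traj <- trajectory(coords, times = 0, box = box)
    d1 <- min_dist_series(traj, 1:3, 4:7)
    d2 <- min_dist_series(traj, 4:7, 1:3)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_equal(d1, brute_min_dist(a, b, box), tolerance = 1e-10)
    # shift one molecule by a full box vector
    shifted <- sweep(b, 2, c(5, 0, -5), `+`)
    traj2 <- trajectory(array(rbind(a, shifted), c(1, 7, 3)), 0, box)
    expect_equal(min_dist_series(traj2, 1:3, 4:7), d1, tolerance = 1e-10)
  }
})

test_that("cell-list contact pairs equal the brute-force scan", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 60
    box <- c(4, 5, 6)
    coords <- cbind(runif(n, 0, 4), runif(n, 0, 5), runif(n, -3, 9))
    for (cutoff in c(0.4, 0.9)) {
      expect_identical(contact_pairs(coords, box, cutoff, "cell"),
                       contact_pairs(coords, box, cutoff, "brute"))
    }
  }
})

test_that("propensity reproduces the 20%-bound / 10%-total worked example", {
  # 100 lipids, 10% CDL, composition mirrored exactly across leaflets
  # (5 CDL + 33 POPE + 12 POPG each); per frame exactly 2 CDL + 8 POPE sit
  # at the protein, the rest far away -> CDL is 20% of bound, 10% of total
  spec <- data.frame(
    type = rep(c("CDL", "POPE", "POPG"), c(10, 66, 24)),
    leaflet = "inner")
  spec$leaflet[c(1:5, 11:43, 77:88)] <- "outer"
  topo <- toy_topology(res_names = "ARG", lipid_spec = spec)
  nb <- nrow(topo$beads)
  pos <- matrix(0, nb, 3)
  pos[1, ] <- c(10, 10, 0)  # the protein residue
  # park all lipids far away, then move the bound ones close
  for (i in seq_len(nrow(spec))) {
    ids <- beads_of_lipid(topo, i)
    pos[ids, 1] <- 2 + (i %% 10) * 0.1
    pos[ids, 2] <- 2 + (i %/% 10) * 0.3
    pos[ids, 3] <- if (spec$leaflet[i] == "inner") -2 else 2
  }
  bound <- c(6, 7,                 # 2 inner CDL
             45:52)                # 8 inner POPE
  for (k in seq_along(bound)) {
    ids <- beads_of_lipid(topo, bound[k])
    pos[ids, ] <- matrix(c(10 + 0.3 * cos(k), 10 + 0.3 * sin(k), 0),
                         length(ids), 3, byrow = TRUE)
  }
  traj <- static_trajectory(pos, n_frames = 10, box = c(20, 20, 20))
  pt <- lipid_binding_propensity(traj, topo, cutoff = 0.6,
                                 skip_fraction = 0)
  inner <- as.data.frame(pt)[pt$leaflet == "inner", ]
  cdl <- inner[inner$lipid_type == "CDL", ]
  expect_equal(cdl$bound_fraction, 0.2)
  expect_equal(cdl$total_fraction, 0.1)
  expect_equal(cdl$propensity, 2)
  # whole-membrane scope gives the same ratio here (2/10 bound, 10/100 total)
  pm <- lipid_binding_propensity(traj, topo, cutoff = 0.6,
                                 skip_fraction = 0, scope = "membrane")
  expect_equal(pm$propensity[pm$lipid_type == "CDL"], 2)
  # bound fractions within a leaflet sum to 1
  expect_equal(sum(inner$bound_fraction), 1)
  expect_equal(sum(inner$total_fraction), 1)
})

test_that("single-type membranes and proportional binding give propensity 1", {
  spec <- data.frame(type = "POPE", leaflet = rep(c("inner", "outer"), 3))
  topo <- toy_topology(res_names = "ARG", lipid_spec = spec)
  pos <- matrix(c(5, 5, 0), nrow(topo$beads), 3, byrow = TRUE)
  pos[1, ] <- c(5, 5.4, 0)
  traj <- static_trajectory(pos, n_frames = 5)
  pt <- lipid_binding_propensity(traj, topo, skip_fraction = 0)
  expect_true(all(pt$propensity == 1))
})

test_that("propensity errors on empty leaflets and empty frame windows", {
  topo <- toy_topology(lipid_spec = data.frame(type = "CDL",
                                               leaflet = "inner"))
  pos <- matrix(0, nrow(topo$beads), 3)
  traj <- static_trajectory(pos, n_frames = 4)
  expect_error(lipid_binding_propensity(traj, topo), "outer")
})

test_that("z-profile keeps only residues above the contact-probability floor", {
  topo <- toy_topology(res_names = c("ARG", "LYS", "LEU"),
                       lipid_spec = data.frame(type = "POPE",
                                               leaflet = "inner"))
  nb <- nrow(topo$beads)
  nf <- 20
  coords <- array(0, c(nf, nb, 3))
  # residue 1 (ARG): in contact every frame, BB z = -2.0
  coords[, 1, ] <- matrix(c(5, 5, -2), nf, 3, byrow = TRUE)
  # residue 2 (LYS): in contact in exactly 1 of 20 frames (prob 0.05 < 0.10)
  coords[, 2, ] <- matrix(c(8, 8, -2), nf, 3, byrow = TRUE)
  coords[1, 2, ] <- c(5.3, 5, -2)
  # residue 3: never in contact
  coords[, 3, ] <- matrix(c(2, 2, 2), nf, 3, byrow = TRUE)
  # lipid beads near (5, 5, -2)
  lb <- beads_of_lipid(topo, 1)
  for (b in lb) coords[, b, ] <- matrix(c(5, 5.4, -2), nf, 3, byrow = TRUE)
  traj <- trajectory(coords, times = 0:(nf - 1), box = c(10, 10, 10))
  zp <- contacting_residue_z_profile(traj, topo)
  expect_identical(zp$residues$residue_id, 1L)
  expect_equal(zp$residues$z, -2)
  expect_equal(sum(zp$histogram$count), 1)
  expect_lt(zp$histogram$z_mid[zp$histogram$count == 1], 0)
  # residue filter that matches nothing errors
  expect_error(contacting_residue_z_profile(traj, topo,
                                            residue_filter = "TRP"),
               "matches no residues")
})

test_that("a planted inner-leaflet Arg site concentrates the z-profile below zero", {
  p <- generator_params(
    n_lipids_per_leaflet = 10, n_protein_residues = 12, n_frames = 800,
    seed = 21, min_background_distance = 0.7,
    planted_sites = list(planted_site(c(5, 6), p_on = 0.5, p_off = 0.05,
                                      residue_names = c("ARG", "ARG"))))
  sys <- generate_system(p)
  zp <- contacting_residue_z_profile(sys$trajectory, sys$topology,
                                     residue_filter = c("ARG", "LYS"))
  expect_gt(nrow(zp$residues), 0)
  expect_true(all(zp$residues$z < 0))
})

test_that("bead-residue profile matches a brute-force count and flags unknown types", {
  topo <- toy_topology(res_names = "ARG",
                       lipid_spec = data.frame(type = "CDL",
                                               leaflet = "inner"))
  pos <- matrix(0, nrow(topo$beads), 3)
  pos[1, ] <- c(5, 5, 0)
  lb <- beads_of_lipid(topo, 1)
  pos[lb, ] <- matrix(c(5, 5.3, 0), length(lb), 3, byrow = TRUE)
  traj <- static_trajectory(pos, n_frames = 7)
  prof <- bead_residue_profile(traj, topo, "CDL")
  # the lipid sits 0.3 nm from the lone Arg: every bead role contacts ARG in
  # all 7 frames
  expect_true(all(prof$counts$contacts[prof$counts$residue_name == "ARG"] == 7))
  expect_true(all(vapply(prof$top, identical, TRUE, "ARG")))
  expect_error(bead_residue_profile(traj, topo, "DOPC"), "no lipids of type")

  # randomized frame equals an exhaustive per-pair recount
  set.seed(31)
  topo2 <- toy_topology(res_names = c("ARG", "SER", "LEU"),
                        lipid_spec = data.frame(type = c("CDL", "CDL"),
                                                leaflet = c("inner", "outer")))
  nb <- nrow(topo2$beads)
  nf <- 6
  coords <- array(runif(nf * nb * 3, 0, 4), c(nf, nb, 3))
  traj2 <- trajectory(coords, times = 0:(nf - 1), box = c(4, 4, 4))
  prof2 <- bead_residue_profile(traj2, topo2, "CDL", cutoff = 0.8)
  # oracle: loop over every (lipid bead, residue, frame)
  for (row in sample(nrow(prof2$counts), 5)) {
    ro <- prof2$counts$bead_role[row]
    rn <- prof2$counts$residue_name[row]
    want <- 0
    for (l in lipid_ids(topo2, "CDL")) {
      lb <- beads_of_lipid(topo2, l)
      lb <- lb[topo2$beads$role[lb] == ro]
      if (!length(lb)) next
      for (r in topo2$residues$residue_id[topo2$residues$name == rn]) {
        rb <- beads_of_residue(topo2, r)
        for (f in seq_len(nf)) {
          dmin <- brute_min_dist(matrix(coords[f, lb, ], ncol = 3),
                                 matrix(coords[f, rb, ], ncol = 3),
                                 c(4, 4, 4))
          if (dmin < 0.8) want <- want + 1
        }
      }
    }
    expect_equal(prof2$counts$contacts[row], want)
  }
})
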
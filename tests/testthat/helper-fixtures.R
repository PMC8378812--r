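# Small hand-built fixtures used across test files. Everything is built in
# code; no data files.

# a minimal topology: `n_res` one-bead residues and `lipid_spec` a data.frame
# (type, leaflet, one row per lipid); every lipid gets its full bead template
toy_topology <- function(res_names = c("ARG", "LEU"),
                         lipid_spec = data.frame(type = "CDL",
                                                 leaflet = "inner")) {
  n_res <- length(res_names)
  residues <- data.frame(residue_id = seq_len(n_res), name = res_names,
                         chain = "A", resno = seq_len(n_res))
  lipids <- data.frame(lipid_id = seq_len(nrow(lipid_spec)),
                       type = lipid_spec$type, leaflet = lipid_spec$leaflet)
  rows <- lapply(seq_len(n_res), function(i)
    data.frame(owner = "residue", owner_id = i, role = "BB"))
  for (i in seq_len(nrow(lipids))) {
    roles <- if (toupper(lipids$type[i]) == "CDL")
      c("GL0", "PO1", "PO2", "C1A", "C2A", "C1B", "C2B") else c("PO4", "C1A")
    rows[[length(rows) + 1L]] <- data.frame(owner = "lipid",
                                            owner_id = i, role = roles)
  }
  beads <- do.call(rbind, rows)
  beads <- data.frame(bead_id = seq_len(nrow(beads)), beads)
  system_topology(residues, lipids, beads)
}

# trajectory where every bead sits at a fixed position in every frame
static_trajectory <- function(positions, n_frames = 1, box = c(10, 10, 10),
                              dt = 1) {
  coords <- array(NA_real_, c(n_frames, nrow(positions), 3))
  for (k in 1:3) coords[, , k] <- matrix(positions[, k], n_frames,
                                         nrow(positions), byrow = TRUE)
  trajectory(coords, times = (seq_len(n_frames) - 1) * dt, box = box)
}

# independent frame-by-frame oracle for the dual-cutoff rule, written as the
# literal two-state automaton
dual_cutoff_oracle <- function(d, lower, upper) {
  state <- FALSE
  out <- logical(length(d))
  for (i in seq_along(d)) {
    if (!state && d[i] < lower) state <- TRUE
    else if (state && d[i] > upper) state <- FALSE
    out[i] <- state
  }
  out
}

# brute-force minimum-image distance between two coordinate sets (oracle)
brute_min_dist <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- a[i, ] - b[j, ]
    d <- d - box * round(d / box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# a synthetic bound_series built directly from per-lipid logical matrices
# (rows named by residue id)
make_bound_series <- function(states, dt = 1, lipid_type = "CDL") {
  structure(list(states = states,
                 residue_ids = as.integer(rownames(states[[1]])),
                 lipid_ids = as.integer(seq_along(states)),
                 lower = 0.55, upper = 1.0, dt = dt,
                 n_frames = ncol(states[[1]]), lipid_type = lipid_type),
            class = "bound_series")
}
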
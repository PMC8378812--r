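# Fixed geometry of the toy membrane (nm). All lipid types carry beads at
# the same two z levels, and all beads of a lipid are laterally co-located
# (roles are distinguished by identity, not geometry), so that absent a
# planted site the contact cross-section -- and hence the per-lipid binding
# probability -- is identical for every lipid type and binding is
# composition-proportional.
HEAD_Z <- 2.0          # |z| of headgroup beads
TAIL_Z <- 1.2          # |z| of tail beads
RESIDUE_Z_SPAN <- 2.2  # protein residues span z in [-2.2, 2.2]
SC_RADIAL <- 0.25      # side-chain bead radial offset from BB
SITE_EXCLUSION <- 1.3  # non-site residues kept this far from a planted site

GOLDEN_ANGLE <- pi * (3 - sqrt(5))

#' Describe a planted binding site
#'
#' A planted site is a set of protein residues plus one dedicated lipid that
#' follows a two-state (bound/unbound) Markov chain with per-frame switching
#' probabilities. When bound, the lipid headgroup is placed `bound_distance`
#' from the site so the dual-cutoff rule (0.55/1.0 nm) recovers the planted
#' state exactly; when unbound it diffuses outside the upper cutoff.
#'
#' @param residue_ids Integer ids of the site residues (must exist in the
#'   generated protein).
#' @param lipid_type Type of the planted lipid (default `"CDL"`).
#' @param p_on,p_off Per-frame binding/unbinding probabilities; the
#'   stationary occupancy is `p_on / (p_on + p_off)`.
#' @param bound_distance Headgroup--site distance when bound (nm), must be
#'   < 0.55.
#' @param unbound_distance Minimum distance to any protein residue when
#'   unbound (nm), must be > 1.0.
#' @param leaflet Leaflet the site faces (`"inner"` or `"outer"`).
#' @param residue_names Optional names for the site residues; default cycles
#'   ARG, LYS, SER so planted sites are basic-rich like their real
#'   counterparts.
#' @return An object of class `planted_site`.
#' @export
planted_site <- function(residue_ids, lipid_type = "CDL", p_on, p_off,
                         bound_distance = 0.35, unbound_distance = 1.5,
                         leaflet = "inner", residue_names = NULL) {
  residue_ids <- as.integer(residue_ids)
  if (!length(residue_ids)) stop("a planted site needs at least one residue")
  if (p_on <= 0 || p_off <= 0 || p_on > 1 || p_off > 1)
    stop("p_on and p_off must lie in (0, 1]")
  pi_occ <- p_on / (p_on + p_off)
  if (pi_occ <= 0 || pi_occ >= 1)
    stop("stationary occupancy must lie strictly between 0 and 1")
  if (bound_distance >= 0.55)
    stop("bound_distance must be < 0.55 nm (the lower dual cutoff)")
  if (unbound_distance <= 1.0)
    stop("unbound_distance must be > 1.0 nm (the upper dual cutoff)")
  if (!leaflet %in% c("inner", "outer"))
    stop("leaflet must be 'inner' or 'outer'")
  structure(list(residue_ids = residue_ids, lipid_type = lipid_type,
                 p_on = p_on, p_off = p_off,
                 bound_distance = bound_distance,
                 unbound_distance = unbound_distance,
                 leaflet = leaflet, residue_names = residue_names),
            class = "planted_site")
}

#' Parameters for the synthetic system generator
#'
#' Defaults emulate the study membrane: POPE/POPG/CDL at 67/23/10 mol%,
#' two symmetric leaflets, coarse-grained bead granularity, lipid lateral
#' diffusion, and a frame spacing of 1 ns.
#'
#' @param n_lipids_per_leaflet Number of lipids in each leaflet.
#' @param composition Named fractions per lipid type; must sum to 1.
#' @param n_protein_residues Number of protein residues, placed on a
#'   cylinder spanning the membrane.
#' @param protein_radius Cylinder radius (nm).
#' @param box Box edge lengths (x, y, z) in nm; z must span both leaflets.
#' @param n_frames Number of trajectory frames.
#' @param dt Frame spacing (ns).
#' @param planted_sites List of [planted_site()] objects.
#' @param seed Integer RNG seed; the full output is reproducible from it.
#' @param diffusion Lateral diffusion coefficient (nm^2/ns) of background
#'   lipids.
#' @param min_background_distance If > 0, background lipids are kept at
#'   least this far (nm) outside the protein cylinder, mimicking the
#'   protein's excluded volume; use a value above 0.55 when exact planted-set
#'   recovery is required.
#' @param residue_names Optional character vector (length
#'   `n_protein_residues`) of residue names; defaults to a mixed sequence.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_lipids_per_leaflet = 100,
                             composition = c(POPE = 0.67, POPG = 0.23,
                                             CDL = 0.10),
                             n_protein_residues = 24,
                             protein_radius = 1.5,
                             box = c(8, 8, 10),
                             n_frames = 1000,
                             dt = 1,
                             planted_sites = list(),
                             seed = 1,
                             diffusion = 0.05,
                             min_background_distance = 0,
                             residue_names = NULL) {
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must be >= 0 and sum to 1")
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be named by lipid type")
  if (box[3] < 2 * HEAD_Z + 0.5)
    stop("box z must span both leaflets (>= ", 2 * HEAD_Z + 0.5, " nm)")
  if (n_frames < 1 || dt <= 0) stop("need n_frames >= 1 and dt > 0")
  for (s in planted_sites) {
    if (!inherits(s, "planted_site")) stop("planted_sites must be planted_site objects")
    if (any(!s$residue_ids %in% seq_len(n_protein_residues)))
      stop("planted residue_ids must index protein residues")
    r_orbit <- protein_radius + s$unbound_distance + 0.4
    if (r_orbit >= min(box[1], box[2]) / 2)
      stop("box too small for the unbound orbit of a planted lipid")
  }
  if (!is.null(residue_names) && length(residue_names) != n_protein_residues)
    stop("residue_names must have one entry per protein residue")
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 composition = composition,
                 n_protein_residues = as.integer(n_protein_residues),
                 protein_radius = protein_radius, box = as.numeric(box),
                 n_frames = as.integer(n_frames), dt = dt,
                 planted_sites = planted_sites, seed = as.integer(seed),
                 diffusion = diffusion,
                 min_background_distance = min_background_distance,
                 residue_names = residue_names),
            class = "generator_params")
}

#' Largest-remainder rounding of composition fractions to integer counts
#'
#' @param n Total count to distribute.
#' @param fractions Named non-negative fractions summing to 1.
#' @return Named integer vector summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  base <- floor(n * fractions)
  rem <- n * fractions - base
  short <- n - sum(base)
  if (short > 0) {
    # ties broken by position, keeping the result deterministic
    gets <- order(-rem, seq_along(rem))[seq_len(short)]
    base[gets] <- base[gets] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# bead templates: local (dx, dy) offsets and z level sign multipliers
lipid_bead_template <- function(type) {
  if (toupper(type) == "CDL") {
    data.frame(role = c("GL0", "PO1", "PO2", "C1A", "C2A", "C1B", "C2B"),
               zlev = c(HEAD_Z, HEAD_Z, HEAD_Z, TAIL_Z, TAIL_Z, TAIL_Z,
                        TAIL_Z))
  } else {
    data.frame(role = c("PO4", "C1A"), zlev = c(HEAD_Z, TAIL_Z))
  }
}

DEFAULT_RESIDUE_CYCLE <- c("LEU", "ALA", "VAL", "SER", "PHE", "ILE",
                           "THR", "GLY")
SITE_RESIDUE_CYCLE <- c("ARG", "LYS", "SER")

#' Generate a synthetic membrane-protein system with known ground truth
#'
#' Builds a static protein (residues on a cylinder spanning the membrane), a
#' two-leaflet membrane at the requested composition (largest-remainder
#' rounding), background lipids performing a 2-D random walk in their
#' leaflet with periodic wrapping, and one dedicated lipid per planted site
#' following its two-state Markov chain. The realized bound/unbound series
#' of every planted site is returned as ground truth.
#'
#' @param params A [generator_params()] object.
#' @return An object of class `lipid_system`: a list with elements
#'   `topology` ([system_topology()]), `trajectory` ([trajectory()]),
#'   `ground_truth` (one record per planted site, with the realized `state`
#'   series and the id of the planted lipid) and `params`.
#' @export
generate_system <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  p <- params
  nf <- p$n_frames
  cx <- p$box[1] / 2
  cy <- p$box[2] / 2
  cats <- residue_categories()

  ## ---- protein residues -------------------------------------------------
  n_res <- p$n_protein_residues
  res_names <- if (!is.null(p$residue_names)) toupper(p$residue_names) else
    rep_len(DEFAULT_RESIDUE_CYCLE, n_res)
  ang <- GOLDEN_ANGLE * seq_len(n_res)
  zres <- seq(-RESIDUE_Z_SPAN, RESIDUE_Z_SPAN, length.out = n_res)

  n_sites <- length(p$planted_sites)
  site_centers <- vector("list", n_sites)
  for (si in seq_len(n_sites)) {
    s <- p$planted_sites[[si]]
    th <- 2 * pi * (si - 1) / max(1, n_sites) + 0.3
    zc <- if (s$leaflet == "inner") -1.8 else 1.8
    m <- length(s$residue_ids)
    nm <- if (!is.null(s$residue_names)) toupper(s$residue_names) else
      rep_len(SITE_RESIDUE_CYCLE, m)
    for (k in seq_len(m)) {
      i <- s$residue_ids[k]
      ang[i] <- th + (k - (m + 1) / 2) * 0.15 / p$protein_radius
      zres[i] <- zc + 0.07 * (-1)^k
      res_names[i] <- nm[k]
    }
    site_centers[[si]] <- c(th, zc)
  }
  site_res_ids <- unlist(lapply(p$planted_sites, `[[`, "residue_ids"))
  # keep non-site residues out of the planted neighbourhoods so background
  # residues never enter a planted lipid's contact shell
  if (n_sites) {
    bx <- p$protein_radius * cos(ang) ; by <- p$protein_radius * sin(ang)
    for (i in setdiff(seq_len(n_res), site_res_ids)) {
      for (sc in site_centers) {
        sx <- p$protein_radius * cos(sc[1]); sy <- p$protein_radius * sin(sc[1])
        d <- sqrt((bx[i] - sx)^2 + (by[i] - sy)^2 + (zres[i] - sc[2])^2)
        if (d < SITE_EXCLUSION) zres[i] <- -sc[2] + (zres[i] - sc[2]) * 0.1
      }
    }
  }
  has_sc <- res_names %in% unlist(cats)
  residues <- data.frame(residue_id = seq_len(n_res), name = res_names,
                         chain = "A", resno = seq_len(n_res))

  ## ---- lipid bookkeeping ------------------------------------------------
  counts <- largest_remainder(p$n_lipids_per_leaflet, p$composition)
  bg_types <- rep(rep(names(counts), counts), 2)
  bg_leaf <- rep(c("inner", "outer"), each = p$n_lipids_per_leaflet)
  pl_types <- vapply(p$planted_sites, `[[`, "", "lipid_type")
  pl_leaf <- vapply(p$planted_sites, `[[`, "", "leaflet")
  lipids <- data.frame(lipid_id = seq_len(length(bg_types) + n_sites),
                       type = c(bg_types, pl_types),
                       leaflet = c(bg_leaf, pl_leaf))
  n_bg <- length(bg_types)

  ## ---- bead table -------------------------------------------------------
  bead_rows <- list()
  for (i in seq_len(n_res)) {
    roles <- if (has_sc[i]) c("BB", "SC1") else "BB"
    bead_rows[[length(bead_rows) + 1L]] <-
      data.frame(owner = "residue", owner_id = i, role = roles)
  }
  templates <- lapply(stats::setNames(nm = unique(lipids$type)),
                      lipid_bead_template)
  for (i in seq_len(nrow(lipids))) {
    tpl <- templates[[lipids$type[i]]]
    bead_rows[[length(bead_rows) + 1L]] <-
      data.frame(owner = "lipid", owner_id = lipids$lipid_id[i],
                 role = tpl$role)
  }
  beads <- do.call(rbind, bead_rows)
  beads <- data.frame(bead_id = seq_len(nrow(beads)), beads)
  topo <- system_topology(residues, lipids, beads, cats)

  ## ---- coordinates ------------------------------------------------------
  coords <- array(NA_real_, c(nf, nrow(beads), 3))
  # protein: static
  for (i in seq_len(n_res)) {
    bx <- cx + p$protein_radius * cos(ang[i])
    by <- cy + p$protein_radius * sin(ang[i])
    ids <- beads$bead_id[beads$owner == "residue" & beads$owner_id == i]
    coords[, ids[1], 1] <- bx; coords[, ids[1], 2] <- by
    coords[, ids[1], 3] <- zres[i]
    if (length(ids) > 1) {  # side chain radially outward
      coords[, ids[2], 1] <- cx + (p$protein_radius + SC_RADIAL) * cos(ang[i])
      coords[, ids[2], 2] <- cy + (p$protein_radius + SC_RADIAL) * sin(ang[i])
      coords[, ids[2], 3] <- zres[i]
    }
  }
  step_sd <- sqrt(2 * p$diffusion * p$dt)
  # the excluded radius covers the side-chain beads
  r_excl <- if (p$min_background_distance > 0)
    p$protein_radius + SC_RADIAL + p$min_background_distance else 0
  if (r_excl > 0 && r_excl >= min(p$box[1:2]) / 2 - 0.1)
    stop("box too small for the requested background exclusion distance")
  wrap <- function(x, L) x - L * floor(x / L)
  for (i in seq_len(n_bg)) {
    sgn <- if (bg_leaf[i] == "inner") -1 else 1
    x <- cumsum(c(stats::runif(1, 0, p$box[1]), stats::rnorm(nf - 1, 0, step_sd)))
    y <- cumsum(c(stats::runif(1, 0, p$box[2]), stats::rnorm(nf - 1, 0, step_sd)))
    if (r_excl > 0) {
      # reflect the walk off the protein's excluded cylinder, in
      # minimum-image coordinates; the reflected radius is scaled to stay
      # inside the half box so no periodic image re-enters the exclusion
      rx <- min_image(x - cx, p$box[1]); ry <- min_image(y - cy, p$box[2])
      r <- sqrt(rx^2 + ry^2)
      r_max <- min(p$box[1], p$box[2]) / 2 - 0.02
      scale <- (r_max - r_excl) / r_excl
      inside <- r < r_excl & r > 0
      if (any(inside)) {
        rr <- r_excl + (r_excl - r[inside]) * scale
        f <- rr / r[inside]
        x[inside] <- cx + rx[inside] * f
        y[inside] <- cy + ry[inside] * f
        x[!inside] <- cx + rx[!inside]
        y[!inside] <- cy + ry[!inside]
      } else {
        x <- cx + rx; y <- cy + ry
      }
    }
    tpl <- templates[[bg_types[i]]]
    ids <- beads$bead_id[beads$owner == "lipid" & beads$owner_id == i]
    for (k in seq_along(ids)) {
      coords[, ids[k], 1] <- wrap(x, p$box[1])
      coords[, ids[k], 2] <- wrap(y, p$box[2])
      coords[, ids[k], 3] <- sgn * tpl$zlev[k]
    }
  }

  ## ---- planted lipids ---------------------------------------------------
  ground_truth <- vector("list", n_sites)
  for (si in seq_len(n_sites)) {
    s <- p$planted_sites[[si]]
    lip_id <- n_bg + si
    pi_occ <- s$p_on / (s$p_on + s$p_off)
    state <- logical(nf)
    state[1] <- stats::runif(1) < pi_occ
    u <- stats::runif(nf)
    for (t in seq_len(nf - 1L))
      state[t + 1L] <- if (state[t]) u[t] >= s$p_off else u[t] < s$p_on
    # bound anchor: centroid of site backbone beads, headgroup pushed
    # radially outward by bound_distance
    bb_ids <- vapply(s$residue_ids, function(r)
      beads_of_residue(topo, r, roles = "BB")[1], integer(1))
    cpos <- if (length(bb_ids) > 1L) colMeans(coords[1, bb_ids, ]) else
      coords[1, bb_ids, ]
    th <- atan2(cpos[2] - cy, cpos[1] - cx)
    ur <- c(cos(th), sin(th))
    ut <- c(-sin(th), cos(th))
    gl0_b <- c(cpos[1], cpos[2]) + ur * s$bound_distance
    sgn <- if (s$leaflet == "inner") -1 else 1
    # unbound orbit outside the upper cutoff
    r_orb <- p$protein_radius + s$unbound_distance + 0.4
    phi <- stats::runif(1, 0, 2 * pi) + cumsum(c(0, stats::rnorm(nf - 1, 0, 0.15)))
    ox <- cx + r_orb * cos(phi)
    oy <- cy + r_orb * sin(phi)
    tpl <- templates[[s$lipid_type]]
    ids <- beads$bead_id[beads$owner == "lipid" & beads$owner_id == lip_id]
    for (k in seq_along(ids)) {
      zoff <- if (tpl$zlev[k] == HEAD_Z) 0 else 0.6
      bx <- gl0_b[1]
      by <- gl0_b[2]
      bz <- cpos[3] - sgn * zoff  # tails sit 0.6 nm toward z = 0
      ux <- ox
      uy <- oy
      uz <- sgn * tpl$zlev[k]
      coords[, ids[k], 1] <- wrap(ifelse(state, bx, ux), p$box[1])
      coords[, ids[k], 2] <- wrap(ifelse(state, by, uy), p$box[2])
      coords[, ids[k], 3] <- ifelse(state, bz, uz)
    }
    ground_truth[[si]] <- list(site = s, lipid_id = lip_id,
                               residue_ids = s$residue_ids, state = state)
  }

  traj <- trajectory(coords, times = (seq_len(nf) - 1) * p$dt, box = p$box)
  structure(list(topology = topo, trajectory = traj,
                 ground_truth = ground_truth, params = p),
            class = "lipid_system")
}

#' @export
print.lipid_system <- function(x, ...) {
  cat("Synthetic CG system (seed", x$params$seed, ")\n")
  print(x$topology)
  print(x$trajectory)
  cat(length(x$ground_truth), "planted site(s)\n")
  invisible(x)
}

#' Generate a membrane-oriented structure with a planted rule-conforming site
#'
#' Builds a flat residue layout (backbone-bead coordinates in the membrane
#' frame, z = 0 at the bilayer center) containing one site satisfying all
#' three cardiolipin-site rules -- two or three adjacent basic residues in
#' the same membrane plane at ~1.8 nm depth, a polar residue, and a deeper
#' aromatic residue -- plus isolated decoy basic residues (pairwise farther
#' than the adjacency cutoff) and indifferent background residues.
#'
#' @param seed RNG seed.
#' @param n_planted_basics 2 or 3 basic residues in the planted site.
#' @param n_decoys Number of isolated decoy basics.
#' @param n_background Number of non-basic background residues.
#' @param box_xy Lateral extent (nm) over which residues are scattered.
#' @return A structure data.frame (`residue_id`, `name`, `chain`, `resno`,
#'   `x`, `y`, `z`) with attribute `planted_ids` giving the residue ids of
#'   the planted site.
#' @export
generate_rule_structure <- function(seed = 1, n_planted_basics = 2,
                                    n_decoys = 5, n_background = 10,
                                    box_xy = 12) {
  stopifnot(n_planted_basics %in% 2:3)
  set.seed(seed)
  side <- sample(c(-1, 1), 1)         # which leaflet face hosts the site
  ctr <- stats::runif(2, 2, box_xy - 2)
  rows <- list()
  add <- function(name, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, x = x, y = y, z = z)
  # planted basics: pairwise < 0.8 nm, |dz| <= 0.15, depth ~1.8 nm
  zb <- side * stats::runif(1, 1.7, 1.9)
  add("ARG", ctr[1], ctr[2], zb)
  add("LYS", ctr[1] + 0.55, ctr[2], zb + side * stats::runif(1, -0.12, 0.12))
  if (n_planted_basics == 3)
    add("ARG", ctr[1] + 0.25, ctr[2] + 0.45, zb + stats::runif(1, -0.1, 0.1))
  # polar companion within the expansion radius
  add("SER", ctr[1] + 0.3, ctr[2] - 0.6, zb - side * 0.1)
  # aromatic, deeper toward the membrane center
  add("TRP", ctr[1] - 0.4, ctr[2] + 0.4, zb - side * stats::runif(1, 0.4, 0.6))
  planted_ids <- seq_len(length(rows))
  # decoys: isolated basics (no qualifying partner within 0.8 nm)
  placed <- do.call(rbind, rows)[, c("x", "y", "z")]
  k <- 0
  while (k < n_decoys) {
    cand <- c(stats::runif(1, 0.5, box_xy - 0.5),
              stats::runif(1, 0.5, box_xy - 0.5),
              sample(c(-1, 1), 1) * stats::runif(1, 1.3, 2.2))
    basics <- do.call(rbind, rows)
    basics <- basics[basics$name %in% c("ARG", "LYS"), c("x", "y", "z")]
    dmin <- min(sqrt(colSums((t(as.matrix(basics)) - cand)^2)))
    if (dmin > 1.2) {
      add(sample(c("ARG", "LYS"), 1), cand[1], cand[2], cand[3])
      k <- k + 1
    }
  }
  for (i in seq_len(n_background)) {
    add(sample(c("LEU", "ALA", "VAL", "ILE", "GLY"), 1),
        stats::runif(1, 0, box_xy), stats::runif(1, 0, box_xy),
        sample(c(-1, 1), 1) * stats::runif(1, 0.2, 2.2))
  }
  out <- do.call(rbind, rows)
  out <- data.frame(residue_id = seq_len(nrow(out)), name = out$name,
                    chain = "A", resno = seq_len(nrow(out)),
                    x = out$x, y = out$y, z = out$z)
  attr(out, "planted_ids") <- planted_ids
  out
}
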
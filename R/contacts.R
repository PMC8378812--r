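#' Minimum residue--lipid distance in one frame
#'
#' Minimum over the selected bead pairs of the periodic (minimum-image,
#' orthorhombic) Euclidean distance.
#'
#' @param traj A `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @param residue_id,lipid_id Identifiers of the pair.
#' @param frame Frame index (1-based).
#' @param lipid_roles Optional bead-role filter on the lipid side (e.g.
#'   `c("GL0", "PO1", "PO2")`); `NULL` selects all beads.
#' @return Distance in nm.
#' @export
min_distance <- function(traj, topo, residue_id, lipid_id, frame = 1L,
                         lipid_roles = NULL) {
  if (frame < 1L || frame > n_frames(traj)) stop("frame out of range")
  rb <- beads_of_residue(topo, residue_id)
  lb <- beads_of_lipid(topo, lipid_id, roles = lipid_roles)
  box <- traj$box[frame, ]
  cc <- traj$coords[frame, , , drop = TRUE]
  best <- Inf
  for (a in rb) {
    d <- sweep(cc[lb, , drop = FALSE], 2, cc[a, ], `-`)
    d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
    best <- min(best, min(rowSums(d * d)))
  }
  sqrt(best)
}

frames_after_skip <- function(nf, skip_fraction) {
  start <- floor(nf * skip_fraction) + 1L
  if (start > nf) stop("no frames left after equilibration skip")
  start:nf
}

#' Leaflet-resolved lipid binding propensity
#'
#' For each lipid type and leaflet, the propensity is the type's share among
#' protein-bound lipids divided by its share of all lipids:
#' \deqn{propensity = \frac{\%\ of\ bound\ lipid}{\%\ of\ total\ lipid}}
#' A lipid counts as bound in a frame when any of its beads lies within
#' `cutoff` of any protein bead. Bound counts are aggregated over the frames
#' remaining after the equilibration skip. A propensity of 1 means no
#' enrichment; if a lipid type makes up 20% of the bound lipid but only 10%
#' of the membrane, its propensity is 2.
#'
#' @param traj A `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @param cutoff Contact cutoff in nm (default 0.6).
#' @param skip_fraction Fraction of initial frames discarded as
#'   equilibration (default 0.1).
#' @param scope `"leaflet"` computes bound/total fractions within each
#'   leaflet (default); `"membrane"` aggregates over both leaflets and
#'   reports one row per lipid type (leaflet column `"all"`).
#' @return A data.frame of class `propensity_table` with columns
#'   `lipid_type`, `leaflet`, `n_lipids`, `bound_frames`, `bound_fraction`,
#'   `total_fraction`, `propensity`.
#' @export
lipid_binding_propensity <- function(traj, topo, cutoff = 0.6,
                                     skip_fraction = 0.1,
                                     scope = c("leaflet", "membrane")) {
  scope <- match.arg(scope)
  for (lf in c("inner", "outer"))
    if (!any(topo$lipids$leaflet == lf))
      stop("leaflet '", lf, "' contains no lipids")
  keep <- frames_after_skip(n_frames(traj), skip_fraction)
  prot <- protein_bead_ids(topo)
  sub <- traj
  sub$coords <- traj$coords[keep, , , drop = FALSE]
  sub$box <- traj$box[keep, , drop = FALSE]
  sub$times <- traj$times[keep]
  lip <- topo$lipids
  bound_frames <- integer(nrow(lip))
  for (i in seq_len(nrow(lip))) {
    lb <- beads_of_lipid(topo, lip$lipid_id[i])
    bound_frames[i] <- sum(contact_series(sub, prot, lb, cutoff))
  }
  leaf <- if (scope == "leaflet") lip$leaflet else rep("all", nrow(lip))
  agg <- stats::aggregate(cbind(n_lipids = rep(1, nrow(lip)),
                                bound_frames = bound_frames),
                          by = list(lipid_type = lip$type, leaflet = leaf),
                          FUN = sum)
  tot_bound <- tapply(agg$bound_frames, agg$leaflet, sum)[agg$leaflet]
  tot_lip <- tapply(agg$n_lipids, agg$leaflet, sum)[agg$leaflet]
  agg$bound_fraction <- ifelse(tot_bound > 0, agg$bound_frames / tot_bound,
                               NA_real_)
  agg$total_fraction <- agg$n_lipids / tot_lip
  agg$propensity <- ifelse(agg$total_fraction > 0,
                           agg$bound_fraction / agg$total_fraction, NA_real_)
  agg <- agg[order(agg$leaflet, agg$lipid_type), ]
  rownames(agg) <- NULL
  class(agg) <- c("propensity_table", "data.frame")
  attr(agg, "cutoff") <- cutoff
  attr(agg, "scope") <- scope
  agg
}

#' z-profile of lipid-contacting residues
#'
#' Residues whose probability of contacting any lipid (over all frames)
#' exceeds `min_contact_probability` contribute the z position of their
#' backbone bead in the final frame; the positions are binned along z. The
#' trajectory must be in the membrane frame (bilayer center at z = 0).
#'
#' @param traj A centered `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @param cutoff Contact cutoff in nm (default 0.6).
#' @param min_contact_probability Minimum any-lipid contact probability for
#'   a residue to be counted (default 0.10).
#' @param residue_filter Optional character vector of residue names (e.g.
#'   `c("ARG", "LYS")`).
#' @param bin_width Histogram bin width along z in nm (default 0.1).
#' @return A list with `residues` (data.frame: residue_id, name,
#'   contact_probability, z) and `histogram` (data.frame: z_mid, count).
#' @export
contacting_residue_z_profile <- function(traj, topo, cutoff = 0.6,
                                         min_contact_probability = 0.10,
                                         residue_filter = NULL,
                                         bin_width = 0.1) {
  res <- topo$residues
  if (!is.null(residue_filter)) {
    res <- res[res$name %in% toupper(residue_filter), ]
    if (!nrow(res)) stop("residue_filter matches no residues")
  }
  all_lipid_beads <- topo$beads$bead_id[topo$beads$owner == "lipid"]
  nf <- n_frames(traj)
  out <- data.frame(residue_id = res$residue_id, name = res$name,
                    contact_probability = NA_real_, z = NA_real_)
  for (i in seq_len(nrow(res))) {
    rb <- beads_of_residue(topo, res$residue_id[i])
    out$contact_probability[i] <-
      mean(contact_series(traj, rb, all_lipid_beads, cutoff))
    bb <- beads_of_residue(topo, res$residue_id[i], roles = "BB")
    out$z[i] <- traj$coords[nf, bb[1], 3]
  }
  out <- out[out$contact_probability > min_contact_probability, ]
  rownames(out) <- NULL
  if (nrow(out)) {
    lo <- floor(min(out$z) / bin_width) * bin_width
    hi <- ceiling(max(out$z) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    h <- hist(out$z, breaks = breaks, plot = FALSE)
    histo <- data.frame(z_mid = h$mids, count = h$counts)
  } else {
    histo <- data.frame(z_mid = numeric(0), count = integer(0))
  }
  list(residues = out, histogram = histo)
}

#' Lipid-bead by residue-name contact profile
#'
#' Counts, for every bead role of a lipid type, the number of
#' (lipid, residue, frame) triples in which that bead lies within `cutoff`
#' of any bead of a residue with a given name (the per-bead-type interaction
#' profile of the CDL headgroup and tails).
#'
#' @param traj A `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @param lipid_type Lipid type to profile (e.g. `"CDL"`).
#' @param cutoff Contact cutoff in nm (default 0.6).
#' @param top_k How many top residue names to report per bead role.
#' @return A list with `counts` (data.frame: bead_role, residue_name,
#'   contacts) and `top` (named list of the top-k residue names per role).
#' @export
bead_residue_profile <- function(traj, topo, lipid_type, cutoff = 0.6,
                                 top_k = 5) {
  lips <- lipid_ids(topo, type = lipid_type)
  if (!length(lips)) stop("no lipids of type ", lipid_type)
  roles <- unique(topo$beads$role[topo$beads$owner == "lipid" &
                                    topo$beads$owner_id %in% lips])
  res <- topo$residues
  counts <- matrix(0L, length(roles), length(unique(res$name)),
                   dimnames = list(roles, sort(unique(res$name))))
  for (l in lips) {
    for (ro in roles) {
      lb <- tryCatch(beads_of_lipid(topo, l, roles = ro), error = function(e) NULL)
      if (is.null(lb)) next
      for (i in seq_len(nrow(res))) {
        rb <- beads_of_residue(topo, res$residue_id[i])
        counts[ro, res$name[i]] <- counts[ro, res$name[i]] +
          sum(contact_series(traj, lb, rb, cutoff))
      }
    }
  }
  long <- data.frame(bead_role = rep(rownames(counts), ncol(counts)),
                     residue_name = rep(colnames(counts),
                                        each = nrow(counts)),
                     contacts = as.vector(counts))
  long <- long[order(long$bead_role, -long$contacts, long$residue_name), ]
  rownames(long) <- NULL
  top <- lapply(stats::setNames(nm = rownames(counts)), function(ro) {
    v <- stats::setNames(as.vector(counts[ro, ]), colnames(counts))
    v <- sort(v, decreasing = TRUE)
    names(v)[seq_len(min(top_k, sum(v > 0)))]
  })
  list(counts = long, top = top)
}
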
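#' Dual-cutoff (hysteretic) binding states from a distance series
#'
#' A lipid--residue pair starts unbound, becomes bound when the distance
#' falls below `lower`, stays bound while the distance remains at or below
#' `upper`, and unbinds only once the distance exceeds `upper`. The
#' hysteresis suppresses flicker from thermal fluctuation around a single
#' cutoff. With `upper == lower` the rule reduces to plain thresholding.
#'
#' @param distances Numeric vector of per-frame distances (nm).
#' @param lower,upper Cutoffs in nm; defaults 0.55 and 1.0.
#' @return Logical vector of bound states, one per frame.
#' @export
dual_cutoff_states <- function(distances, lower = 0.55, upper = 1.0) {
  if (!length(distances)) stop("empty distance series")
  if (lower > upper) stop("lower cutoff must not exceed upper cutoff")
  s <- ifelse(distances < lower, TRUE,
              ifelse(distances > upper, FALSE, NA))
  known <- !is.na(s)
  # carry the last decided state forward; initial state is unbound
  c(FALSE, s[known])[cumsum(known) + 1L]
}

#' Per-pair bound time series for one lipid type
#'
#' Computes, for every (lipid of `lipid_type`, residue) pair, the per-frame
#' minimum distance restricted to the lipid's headgroup beads and converts
#' it into a bound series with [dual_cutoff_states()].
#'
#' @param traj A `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @param lipid_type Lipid type whose binding is analyzed (default `"CDL"`).
#' @param lower,upper Dual cutoffs in nm.
#' @param headgroup_only Restrict lipid beads to headgroup roles (GL0, PO1,
#'   PO2 for CDL; PO4 otherwise). Site identification follows the headgroup.
#' @param residue_ids Optional subset of residues to consider.
#' @return An object of class `bound_series`: a list with `states` (a list
#'   keyed by lipid id, each a logical `[n_residues, n_frames]` matrix),
#'   `residue_ids`, `lipid_ids`, `lower`, `upper`, `dt` (ns),
#'   `n_frames` and `lipid_type`.
#' @export
compute_bound_series <- function(traj, topo, lipid_type = "CDL",
                                 lower = 0.55, upper = 1.0,
                                 headgroup_only = TRUE,
                                 residue_ids = NULL) {
  lips <- lipid_ids(topo, type = lipid_type)
  if (!length(lips)) stop("no lipids of type ", lipid_type)
  if (is.null(residue_ids)) residue_ids <- topo$residues$residue_id
  roles <- if (headgroup_only) headgroup_roles(lipid_type) else NULL
  states <- vector("list", length(lips))
  names(states) <- as.character(lips)
  for (li in seq_along(lips)) {
    lb <- beads_of_lipid(topo, lips[li], roles = roles)
    m <- matrix(FALSE, length(residue_ids), n_frames(traj),
                dimnames = list(as.character(residue_ids), NULL))
    for (ri in seq_along(residue_ids)) {
      rb <- beads_of_residue(topo, residue_ids[ri])
      d <- min_dist_series(traj, rb, lb)
      m[ri, ] <- dual_cutoff_states(d, lower, upper)
    }
    states[[li]] <- m
  }
  structure(list(states = states, residue_ids = as.integer(residue_ids),
                 lipid_ids = as.integer(lips), lower = lower, upper = upper,
                 dt = frame_dt(traj), n_frames = n_frames(traj),
                 lipid_type = lipid_type),
            class = "bound_series")
}

#' Residue co-binding graph
#'
#' Nodes are residues with at least one bound frame. The edge weight between
#' residues i and j is the number of (lipid, frame) pairs in which the same
#' lipid is simultaneously bound to both, normalized by the smaller of the
#' two residues' total bound-frame counts; edges below `threshold` are
#' dropped. Clustering this graph groups residues that tend to bind the same
#' lipid headgroup at the same time.
#'
#' @param bound A `bound_series`.
#' @param threshold Minimum normalized co-binding weight for an edge to be
#'   retained (default 0.3).
#' @return An `igraph` weighted undirected graph whose vertex names are
#'   residue ids; carries attribute `empty = TRUE` when no pair is ever
#'   bound.
#' @export
build_cobinding_graph <- function(bound, threshold = 0.3) {
  stopifnot(inherits(bound, "bound_series"))
  co <- Reduce(`+`, lapply(bound$states, function(m) tcrossprod(m * 1)))
  tot <- diag(co)
  active <- tot > 0
  if (!any(active)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "empty") <- TRUE
    warning("no bound frames anywhere; co-binding graph is empty")
    return(g)
  }
  co <- co[active, active, drop = FALSE]
  tot <- tot[active]
  w <- co / outer(tot, tot, pmin)
  diag(w) <- 0
  w[w < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  attr(g, "empty") <- FALSE
  g
}

#' Partition the co-binding graph into candidate sites
#'
#' Modularity-maximizing (Louvain) community detection with a fixed RNG
#' seed; singleton communities with no retained edges are discarded. Two
#' disconnected cliques come out as exactly two sites; a uniform fully
#' connected clique is never split.
#'
#' @param graph Graph from [build_cobinding_graph()].
#' @param seed RNG seed making the community detection reproducible.
#' @return List of integer vectors of residue ids, ordered by smallest
#'   member id.
#' @export
detect_sites <- function(graph, seed = 1) {
  if (igraph::vcount(graph) == 0) return(list())
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
  memb <- igraph::membership(comm)
  deg <- igraph::degree(graph)
  groups <- split(names(memb), memb)
  sites <- list()
  for (gmem in groups) {
    ids <- sort(as.integer(gmem))
    if (length(ids) == 1L && deg[as.character(ids)] == 0) next
    sites[[length(sites) + 1L]] <- ids
  }
  if (!length(sites)) return(list())
  sites[order(vapply(sites, min, numeric(1)))]
}

# per-lipid bound-to-site series: TRUE when the lipid is bound to >= 1 site
# residue in that frame
site_lipid_series <- function(site, bound) {
  rows <- match(as.character(site), rownames(bound$states[[1]]))
  if (anyNA(rows)) stop("site residues missing from the bound series")
  lapply(bound$states, function(m) {
    if (length(rows) == 1L) m[rows, ] else colSums(m[rows, , drop = FALSE]) > 0
  })
}

#' Residence-time estimate from event durations
#'
#' Default is the arithmetic mean of the continuous-contact event durations.
#' `"survival"` fits a single exponential to the empirical survival curve of
#' event durations (least squares on the log-survival), falling back to the
#' mean when fewer than `min_events_for_fit` events are available.
#'
#' @param durations_ns Numeric event durations (ns).
#' @param estimator `"mean"` or `"survival"`.
#' @param min_events_for_fit Minimum events for the survival fit.
#' @return Residence time in ns (NA when there are no events).
#' @export
residence_time <- function(durations_ns, estimator = c("mean", "survival"),
                           min_events_for_fit = 20) {
  estimator <- match.arg(estimator)
  if (!length(durations_ns)) return(NA_real_)
  if (estimator == "mean" || length(durations_ns) < min_events_for_fit)
    return(mean(durations_ns))
  ts <- sort(unique(durations_ns))
  surv <- vapply(ts, function(t) mean(durations_ns >= t), numeric(1))
  keep <- surv > 0
  fit <- stats::lm(log(surv[keep]) ~ 0 + ts[keep])
  rate <- -stats::coef(fit)[[1]]
  if (rate <= 0) return(mean(durations_ns))
  1 / rate
}

#' Occupancy, residence time and binding events of a site
#'
#' A frame counts as bound when any lipid of the analyzed type is bound (by
#' the dual-cutoff rule) to at least one residue of the site. Occupancy is
#' bound frames over total frames. Events are the maximal runs, per lipid,
#' of continuous binding to any site residue; a lipid shared between two
#' sites contributes to both sites' occupancies but each event is counted
#' once per site. Event frames are reported 0-based.
#'
#' @param site Integer vector of residue ids.
#' @param bound A `bound_series`.
#' @param estimator Residence-time estimator, see [residence_time()].
#' @return A list with `occupancy`, `residence_ns`, `events` (data.frame:
#'   `lipid_id`, `start`, `end`, `duration_ns`), `n_events` and
#'   `residue_occupancy` (named per-residue any-lipid bound fractions).
#' @export
site_metrics <- function(site, bound, estimator = c("mean", "survival")) {
  estimator <- match.arg(estimator)
  if (!length(site)) stop("empty site")
  per_lipid <- site_lipid_series(site, bound)
  any_bound <- Reduce(`|`, per_lipid)
  occ <- mean(any_bound)
  ev <- list()
  for (li in seq_along(per_lipid)) {
    r <- rle(per_lipid[[li]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    if (any(sel))
      ev[[length(ev) + 1L]] <- data.frame(
        lipid_id = bound$lipid_ids[li],
        start = starts[sel] - 1L, end = ends[sel] - 1L)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(lipid_id = integer(0), start = integer(0), end = integer(0))
  events <- events[order(events$start, events$lipid_id), , drop = FALSE]
  rownames(events) <- NULL
  events$duration_ns <- (events$end - events$start + 1L) * bound$dt
  rows <- match(as.character(site), rownames(bound$states[[1]]))
  res_occ <- vapply(rows, function(r) {
    mean(Reduce(`|`, lapply(bound$states, function(m) m[r, ])))
  }, numeric(1))
  names(res_occ) <- as.character(site)
  list(occupancy = occ,
       residence_ns = residence_time(events$duration_ns, estimator),
       events = events, n_events = nrow(events),
       residue_occupancy = res_occ)
}

#' Identify binding sites from a trajectory
#'
#' Full site-identification pass: per-pair dual-cutoff bound series on the
#' lipid headgroup beads, residue co-binding graph, community detection,
#' per-site metrics, and (optionally) the residence-time and
#' residue-occupancy filters plus a representative pose per site.
#'
#' @inheritParams compute_bound_series
#' @param edge_threshold Minimum normalized co-binding for a graph edge.
#' @param seed Seed for the community detection.
#' @param estimator Residence-time estimator.
#' @param min_residence_ns Sites with residence time at or below this are
#'   dropped (default 10 ns); set to `NULL` to skip filtering.
#' @param residue_occupancy_floor Within retained sites, residues whose
#'   individual bound fraction is below this times the site occupancy are
#'   pruned (default 0.10).
#' @param poses Attach a representative (frame, lipid) pose per site.
#' @return An object of class `binding_sites`: list with `sites` (each a
#'   list: `site_id`, `residue_ids`, metrics, optional `pose`), the `bound`
#'   series and the parameters used.
#' @export
find_binding_sites <- function(traj, topo, lipid_type = "CDL",
                               lower = 0.55, upper = 1.0,
                               headgroup_only = TRUE,
                               edge_threshold = 0.3, seed = 1,
                               estimator = c("mean", "survival"),
                               min_residence_ns = 10,
                               residue_occupancy_floor = 0.10,
                               poses = TRUE) {
  estimator <- match.arg(estimator)
  bound <- compute_bound_series(traj, topo, lipid_type, lower, upper,
                                headgroup_only)
  graph <- suppressWarnings(build_cobinding_graph(bound, edge_threshold))
  memberships <- detect_sites(graph, seed = seed)
  sites <- lapply(seq_along(memberships), function(i) {
    m <- site_metrics(memberships[[i]], bound, estimator)
    c(list(site_id = i, residue_ids = memberships[[i]]), m)
  })
  if (!is.null(min_residence_ns))
    sites <- filter_sites(sites, bound, min_residence_ns,
                          residue_occupancy_floor, estimator)
  if (poses)
    sites <- lapply(sites, function(s) {
      s$pose <- if (s$n_events > 0)
        representative_pose(s$residue_ids, traj, topo, bound, s$events)
      else NULL
      s
    })
  structure(list(sites = sites, bound = bound,
                 params = list(lipid_type = lipid_type, lower = lower,
                               upper = upper, edge_threshold = edge_threshold,
                               seed = seed, estimator = estimator,
                               min_residence_ns = min_residence_ns,
                               residue_occupancy_floor = residue_occupancy_floor)),
            class = "binding_sites")
}

#' @export
print.binding_sites <- function(x, ...) {
  cat(length(x$sites), "binding site(s) [", x$params$lipid_type, "]\n")
  for (s in x$sites)
    cat(sprintf("  site %d: residues {%s}  occupancy %.3f  residence %.2f ns  %d events\n",
                s$site_id, paste(s$residue_ids, collapse = ","),
                s$occupancy, s$residence_ns, s$n_events))
  invisible(x)
}

#' Residence-time and residue-occupancy filters
#'
#' Drops sites whose residence time is at or below `min_residence_ns`
#' (binding shorter than that is indistinguishable from free lipid
#' diffusion), then prunes, within each retained site, residues whose
#' individual bound-frame occupancy is below `residue_occupancy_floor`
#' times the site occupancy, and recomputes the metrics of pruned sites.
#'
#' @param sites List of site records (as built by [find_binding_sites()]).
#' @param bound The `bound_series` the metrics were computed from.
#' @param min_residence_ns Residence-time threshold in ns.
#' @param residue_occupancy_floor Fraction of site occupancy below which a
#'   residue is pruned.
#' @param estimator Residence-time estimator for recomputed metrics.
#' @return Filtered list of site records (site_id renumbered).
#' @export
filter_sites <- function(sites, bound, min_residence_ns = 10,
                         residue_occupancy_floor = 0.10,
                         estimator = c("mean", "survival")) {
  estimator <- match.arg(estimator)
  kept <- list()
  for (s in sites) {
    if (is.na(s$residence_ns) || s$residence_ns <= min_residence_ns) next
    floor_occ <- residue_occupancy_floor * s$occupancy
    keep_res <- s$residue_ids[s$residue_occupancy >= floor_occ]
    if (!length(keep_res)) next
    if (length(keep_res) < length(s$residue_ids)) {
      m <- site_metrics(keep_res, bound, estimator)
      s <- c(list(site_id = s$site_id, residue_ids = keep_res), m)
    }
    kept[[length(kept) + 1L]] <- s
  }
  for (i in seq_along(kept)) kept[[i]]$site_id <- i
  kept
}

#' Representative bound pose of a site
#'
#' Picks the longest binding event (ties: earliest start, then lowest lipid
#' id) and, within it, the frame minimizing the mean headgroup-bead distance
#' to the site residues (ties: earliest frame).
#'
#' @param site Integer vector of residue ids.
#' @param traj A `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @param bound The `bound_series`.
#' @param events Optional precomputed events (from [site_metrics()]).
#' @return List with `frame` (0-based), `lipid_id` and `mean_distance_nm`.
#' @export
representative_pose <- function(site, traj, topo, bound, events = NULL) {
  if (is.null(events))
    events <- site_metrics(site, bound)$events
  if (!nrow(events)) stop("site has no binding events")
  ord <- order(-(events$end - events$start), events$start, events$lipid_id)
  best_ev <- events[ord[1], ]
  roles <- headgroup_roles(bound$lipid_type)
  hg <- beads_of_lipid(topo, best_ev$lipid_id, roles = roles)
  res_beads <- unlist(lapply(site, function(r) beads_of_residue(topo, r)))
  frames <- (best_ev$start:best_ev$end) + 1L
  score <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cc <- traj$coords[f, , , drop = TRUE]
    box <- traj$box[f, ]
    per_bead <- vapply(hg, function(b) {
      d <- sweep(cc[res_beads, , drop = FALSE], 2, cc[b, ], `-`)
      d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
      sqrt(min(rowSums(d * d)))
    }, numeric(1))
    score[fi] <- mean(per_bead)
  }
  pick <- which.min(score)  # which.min takes the first minimum: earliest frame
  list(frame = frames[pick] - 1L, lipid_id = best_ev$lipid_id,
       mean_distance_nm = score[pick])
}

#' Serialize identified sites to JSON
#'
#' Events carry 0-based frame indices; occupancy can be recomputed exactly
#' from the serialized events and frame count.
#'
#' @param bs A `binding_sites` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sites_to_json <- function(bs, path) {
  out <- list(
    lipid_type = bs$params$lipid_type,
    lower = bs$params$lower, upper = bs$params$upper,
    dt = bs$bound$dt, n_frames = bs$bound$n_frames,
    sites = lapply(bs$sites, function(s) {
      list(site_id = s$site_id, residue_ids = s$residue_ids,
           occupancy = s$occupancy, residence_ns = s$residence_ns,
           events = s$events[, c("lipid_id", "start", "end")],
           pose = s$pose)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Recompute site occupancy from serialized events
#'
#' @param events data.frame with 0-based `start`, `end` columns (any lipid).
#' @param n_frames Total frame count.
#' @return Occupancy fraction: bound frames (union over events) / total.
#' @export
occupancy_from_events <- function(events, n_frames) {
  if (!nrow(events)) return(0)
  covered <- logical(n_frames)
  for (i in seq_len(nrow(events)))
    covered[(events$start[i]:events$end[i]) + 1L] <- TRUE
  mean(covered)
}
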
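#' Construct a trajectory
#'
#' Coordinates are in nm, times in ns. The membrane frame convention places
#' the bilayer center (phosphate-bead center of mass) at z = 0; use
#' [center_membrane()] to establish it for imported data. Only orthorhombic
#' boxes are supported; the minimum-image convention is applied in all
#' distance computations.
#'
#' @param coords Numeric array `[n_frames, n_beads, 3]` of bead positions
#'   (nm), or a single `[n_beads, 3]` matrix for a one-frame trajectory.
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param box Either a length-3 vector (constant box) or an
#'   `[n_frames, 3]` matrix of box edge lengths (nm).
#' @return An object of class `lipid_trajectory`.
#' @export
trajectory <- function(coords, times, box) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_frames <- dim(coords)[1]
  if (length(times) != n_frames)
    stop("times must have one entry per frame")
  if (n_frames > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1L && n_frames > 1L)
    box <- box[rep(1L, n_frames), , drop = FALSE]
  if (ncol(box) != 3 || nrow(box) != n_frames)
    stop("box must be a length-3 vector or an [n_frames, 3] matrix")
  if (any(box <= 0)) stop("box lengths must be positive")
  structure(list(coords = coords, times = as.numeric(times), box = box),
            class = "lipid_trajectory")
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("CG trajectory:", d[1], "frames,", d[2], "beads,",
      sprintf("t = %.3g..%.3g ns", x$times[1], x$times[d[1]]), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `lipid_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame spacing in ns
#'
#' The median spacing of the frame times; trajectories are expected to be
#' uniformly sampled.
#' @param traj A `lipid_trajectory`.
#' @return Time step in ns (1 for a single-frame trajectory).
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2L) return(1)
  stats::median(diff(traj$times))
}

# minimum-image component differences for an orthorhombic box
min_image <- function(d, L) d - L * round(d / L)

#' Per-frame minimum distance between two bead sets
#'
#' Minimum over all bead pairs of the periodic (minimum-image, orthorhombic)
#' Euclidean distance, computed for every frame at once.
#'
#' @param traj A `lipid_trajectory`.
#' @param beads_a,beads_b Integer vectors of bead ids.
#' @return Numeric vector of length `n_frames(traj)` (nm).
#' @export
min_dist_series <- function(traj, beads_a, beads_b) {
  if (!length(beads_a) || !length(beads_b))
    stop("empty bead selection")
  cc <- traj$coords
  box <- traj$box
  nf <- dim(cc)[1]
  best <- rep(Inf, nf)
  for (a in beads_a) {
    xa <- cc[, a, 1]; ya <- cc[, a, 2]; za <- cc[, a, 3]
    for (b in beads_b) {
      dx <- min_image(xa - cc[, b, 1], box[, 1])
      dy <- min_image(ya - cc[, b, 2], box[, 2])
      dz <- min_image(za - cc[, b, 3], box[, 3])
      best <- pmin(best, dx * dx + dy * dy + dz * dz)
    }
  }
  sqrt(best)
}

#' Per-frame contact indicator between two bead sets
#' @inheritParams min_dist_series
#' @param cutoff Contact cutoff (nm).
#' @return Logical vector of length `n_frames(traj)`.
#' @keywords internal
contact_series <- function(traj, beads_a, beads_b, cutoff) {
  # same loop as min_dist_series but short-circuits on squared cutoff
  cc <- traj$coords
  box <- traj$box
  nf <- dim(cc)[1]
  cut2 <- cutoff * cutoff
  hit <- rep(FALSE, nf)
  for (a in beads_a) {
    xa <- cc[, a, 1]; ya <- cc[, a, 2]; za <- cc[, a, 3]
    for (b in beads_b) {
      dx <- min_image(xa - cc[, b, 1], box[, 1])
      dy <- min_image(ya - cc[, b, 2], box[, 2])
      dz <- min_image(za - cc[, b, 3], box[, 3])
      hit <- hit | (dx * dx + dy * dy + dz * dz < cut2)
      if (all(hit)) return(hit)
    }
  }
  hit
}

#' Contact pairs within a single frame
#'
#' Enumerates all bead pairs closer than `cutoff` under periodic boundaries.
#' The default method bins beads into a cell grid of spacing >= cutoff and
#' compares only neighbouring cells; `method = "brute"` performs the full
#' all-pairs scan and serves as a reference.
#'
#' @param coords `[n_beads, 3]` coordinate matrix (nm).
#' @param box Length-3 box vector (nm).
#' @param cutoff Contact cutoff (nm).
#' @param method `"cell"` (spatially indexed) or `"brute"`.
#' @return Two-column integer matrix of bead index pairs (i < j), ordered
#'   lexicographically.
#' @export
contact_pairs <- function(coords, box, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  if (method == "brute") {
    res <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      dx <- min_image(coords[i, 1] - coords[j, 1], box[1])
      dy <- min_image(coords[i, 2] - coords[j, 2], box[2])
      dz <- min_image(coords[i, 3] - coords[j, 3], box[3])
      hit <- j[dx * dx + dy * dy + dz * dz < cutoff * cutoff]
      if (length(hit)) res[[i]] <- cbind(i, hit)
    }
    out <- do.call(rbind, res)
    if (is.null(out)) out <- matrix(integer(0), 0, 2)
    return(order_pairs(out))
  }
  # cell list
  ncell <- pmax(1L, as.integer(floor(box / cutoff)))
  wrapped <- sweep(coords, 2, box, function(x, L) x - L * floor(x / L))
  ci <- pmin(ncell[1] - 1L, as.integer(floor(wrapped[, 1] / box[1] * ncell[1])))
  cj <- pmin(ncell[2] - 1L, as.integer(floor(wrapped[, 2] / box[2] * ncell[2])))
  ck <- pmin(ncell[3] - 1L, as.integer(floor(wrapped[, 3] / box[3] * ncell[3])))
  cell <- (ci * ncell[2] + cj) * ncell[3] + ck
  members <- split(seq_len(n), cell)
  # neighbour offsets; with <3 cells along an axis every cell neighbours
  # every other, so clamp the offset range
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  cut2 <- cutoff * cutoff
  acc <- list()
  cell_ids <- as.integer(names(members))
  decode <- function(id) {
    k <- id %% ncell[3]; r <- id %/% ncell[3]
    j <- r %% ncell[2]; i <- r %/% ncell[2]
    c(i, j, k)
  }
  pair_block <- function(ia, ib) {
    da <- coords[ia, , drop = FALSE]
    db <- coords[ib, , drop = FALSE]
    out <- list()
    for (u in seq_along(ia)) {
      dx <- min_image(da[u, 1] - db[, 1], box[1])
      dy <- min_image(da[u, 2] - db[, 2], box[2])
      dz <- min_image(da[u, 3] - db[, 3], box[3])
      hit <- ib[dx * dx + dy * dy + dz * dz < cut2]
      hit <- hit[hit != ia[u]]
      if (length(hit)) out[[length(out) + 1L]] <- cbind(ia[u], hit)
    }
    do.call(rbind, out)
  }
  for (mi in seq_along(members)) {
    id <- cell_ids[mi]
    ijk <- decode(id)
    neigh_ids <- unique(apply(offs, 1, function(o) {
      ni <- (ijk[1] + o[1]) %% ncell[1]
      nj <- (ijk[2] + o[2]) %% ncell[2]
      nk <- (ijk[3] + o[3]) %% ncell[3]
      (ni * ncell[2] + nj) * ncell[3] + nk
    }))
    ia <- members[[mi]]
    for (nid in neigh_ids) {
      mj <- match(as.character(nid), names(members))
      if (is.na(mj) || mj < mi) next
      ib <- members[[mj]]
      blk <- if (nid == id) pair_block(ia, ia) else pair_block(ia, ib)
      if (!is.null(blk)) acc[[length(acc) + 1L]] <- blk
    }
  }
  out <- do.call(rbind, acc)
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  # orient i < j and drop duplicates from symmetric enumeration
  out <- cbind(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
  out <- unique(out)
  order_pairs(out)
}

order_pairs <- function(m) {
  if (!nrow(m)) return(matrix(integer(0), 0, 2))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Shift a trajectory into the membrane frame
#'
#' Subtracts, per frame, the z center of mass of all phosphate-role beads
#' (`PO4`, `PO1`, `PO2`) so the bilayer midplane sits at z = 0.
#'
#' @param traj A `lipid_trajectory`.
#' @param topo The matching `lipid_topology`.
#' @return The re-centered `lipid_trajectory`.
#' @export
center_membrane <- function(traj, topo) {
  ph <- topo$beads$bead_id[topo$beads$role %in% PHOSPHATE_ROLES]
  if (!length(ph))
    stop("no phosphate-role beads: membrane frame undefined")
  zc <- rowMeans(traj$coords[, ph, 3, drop = FALSE])
  traj$coords[, , 3] <- traj$coords[, , 3] - zc
  traj
}

#' Assign leaflets from phosphate z sign
#'
#' Labels each lipid `inner` (negative z) or `outer` (positive z) from the
#' mean phosphate z of its first frame in the membrane frame, and warns if a
#' lipid's phosphate z changes sign in more than half of the frames.
#'
#' @param traj A centered `lipid_trajectory`.
#' @param topo A `lipid_topology`; the returned copy carries the labels.
#' @return `topo` with updated `leaflet` labels.
#' @export
assign_leaflets <- function(traj, topo) {
  for (i in seq_len(nrow(topo$lipids))) {
    id <- topo$lipids$lipid_id[i]
    ph <- beads_of_lipid(topo, id)
    ph <- intersect(ph, topo$beads$bead_id[topo$beads$role %in% PHOSPHATE_ROLES])
    if (!length(ph)) next
    z <- rowMeans(traj$coords[, ph, 3, drop = FALSE])
    topo$lipids$leaflet[i] <- if (z[1] < 0) "inner" else "outer"
    if (mean(sign(z) != sign(z[1])) > 0.5)
      warning("lipid ", id, " changes leaflet for >50% of frames; ",
              "leaflet label kept from frame 0")
  }
  topo
}
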
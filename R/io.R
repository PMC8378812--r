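# Known lipid residue names and the default atom-name -> bead-role map.
KNOWN_LIPID_NAMES <- c("CDL", "POPE", "POPG", "POPC", "POPS", "CL4P")

DEFAULT_ROLE_MAP <- c(BB = "BB", SC1 = "SC1", SC2 = "SC2", SC3 = "SC3",
                      SC4 = "SC4", PO4 = "PO4", PO1 = "PO1", PO2 = "PO2",
                      GL0 = "GL0", GL1 = "GL1", GL2 = "GL2",
                      NC3 = "NC3", NH3 = "NH3")

map_role <- function(atom, role_map) {
  atom <- toupper(atom)
  if (atom %in% names(role_map)) return(unname(role_map[atom]))
  if (grepl("^[CD][0-9][A-D]$", atom)) return(atom)  # tail beads
  NA_character_
}

# build a topology + one coordinate frame from a flat atom table
# (resno, resname, atom, x, y, z in nm)
build_system_from_atoms <- function(at, role_map = DEFAULT_ROLE_MAP,
                                    chain = "A") {
  mol <- cumsum(c(TRUE, at$resno[-1] != at$resno[-nrow(at)] |
                    at$resname[-1] != at$resname[-nrow(at)]))
  res_rows <- list(); lip_rows <- list(); bead_rows <- list()
  rid <- 0L; lid <- 0L
  for (m in split(seq_len(nrow(at)), mol)) {
    nm <- toupper(at$resname[m[1]])
    roles <- vapply(at$atom[m], map_role, "", role_map = role_map)
    if (anyNA(roles))
      stop("atom(s) ", paste(at$atom[m][is.na(roles)], collapse = ","),
           " in ", nm, " map to no bead role")
    if (nm %in% KNOWN_LIPID_NAMES) {
      lid <- lid + 1L
      lip_rows[[lid]] <- data.frame(lipid_id = lid, type = nm,
                                    leaflet = "inner")  # fixed later from z
      bead_rows[[length(bead_rows) + 1L]] <-
        data.frame(bead_id = m, owner = "lipid", owner_id = lid,
                   role = roles)
    } else {
      rid <- rid + 1L
      res_rows[[rid]] <- data.frame(residue_id = rid, name = nm,
                                    chain = chain, resno = at$resno[m[1]])
      bead_rows[[length(bead_rows) + 1L]] <-
        data.frame(bead_id = m, owner = "residue", owner_id = rid,
                   role = roles)
    }
  }
  topo <- system_topology(
    if (rid) do.call(rbind, res_rows) else
      data.frame(residue_id = integer(0), name = character(0),
                 chain = character(0), resno = integer(0)),
    if (lid) do.call(rbind, lip_rows) else
      data.frame(lipid_id = integer(0), type = character(0),
                 leaflet = character(0)),
    do.call(rbind, bead_rows))
  list(topology = topo, coords = as.matrix(at[, c("x", "y", "z")]))
}

# flat atom table from a topology + one frame (nm)
atoms_from_system <- function(topo, coords) {
  b <- topo$beads
  resno <- integer(nrow(b)); resname <- character(nrow(b))
  n_res <- nrow(topo$residues)
  for (i in seq_len(nrow(b))) {
    if (b$owner[i] == "residue") {
      resno[i] <- b$owner_id[i]
      resname[i] <- topo$residues$name[match(b$owner_id[i],
                                             topo$residues$residue_id)]
    } else {
      resno[i] <- n_res + b$owner_id[i]
      resname[i] <- topo$lipids$type[match(b$owner_id[i],
                                           topo$lipids$lipid_id)]
    }
  }
  data.frame(resno = resno, resname = resname, atom = b$role,
             atomnum = b$bead_id, x = coords[, 1], y = coords[, 2],
             z = coords[, 3])
}

#' Write a system structure as a GRO file
#'
#' Coordinates are written in nm (native GRO units). One frame only.
#'
#' @param topo A `lipid_topology`.
#' @param coords `[n_beads, 3]` coordinate matrix (nm) for the frame.
#' @param box Length-3 box vector (nm).
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topo, coords, box, path, title = "lipidsites system") {
  at <- atoms_from_system(topo, coords)
  lines <- c(title, format(nrow(at)))
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            at$resno %% 100000L, substr(at$resname, 1, 5),
                            substr(at$atom, 1, 5), at$atomnum %% 100000L,
                            at$x, at$y, at$z))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO structure into a topology and coordinates
#'
#' @param path GRO file path.
#' @param role_map Named map from atom names to bead roles; unmapped atoms
#'   are an error.
#' @return List with `topology`, `coords` (`[n_beads, 3]`, nm) and `box`.
#' @export
read_gro <- function(path, role_map = DEFAULT_ROLE_MAP) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  al <- lines[3:(2 + n)]
  at <- data.frame(
    resno = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    atom = trimws(substr(al, 11, 15)),
    x = as.numeric(substr(al, 21, 28)),
    y = as.numeric(substr(al, 29, 36)),
    z = as.numeric(substr(al, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  sys <- build_system_from_atoms(at, role_map)
  sys$box <- box
  sys
}

#' Write a structure or pose as a PDB file
#'
#' Coordinates are converted from nm to Angstrom on write.
#'
#' @param topo A `lipid_topology`.
#' @param coords `[n_beads, 3]` coordinate matrix (nm).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_pdb <- function(topo, coords, path) {
  at <- atoms_from_system(topo, coords)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")]) * 10))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resname, eleno = at$atomnum,
                   elety = at$atom, chain = rep("A", nrow(at)))
  invisible(path)
}

#' Read a membrane-oriented structure from PDB
#'
#' Reads backbone positions (atom name `BB` for coarse-grained models, `CA`
#' otherwise) and returns a structure table in nm for the annotation and
#' rule modules.
#'
#' @param path PDB file path.
#' @param membrane_center_z z of the membrane center in the file's frame
#'   (Angstrom); subtracted so the returned z is membrane-centered, in nm.
#' @return Structure data.frame (`residue_id`, `name`, `chain`, `resno`,
#'   `x`, `y`, `z`).
#' @export
read_structure_pdb <- function(path, membrane_center_z = 0) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  bb <- a[a$elety == "BB", , drop = FALSE]
  if (!nrow(bb)) bb <- a[a$elety == "CA", , drop = FALSE]
  if (!nrow(bb)) stop("no BB or CA atoms in ", path)
  data.frame(residue_id = seq_len(nrow(bb)), name = toupper(bb$resid),
             chain = ifelse(is.na(bb$chain), "A", bb$chain),
             resno = bb$resno, x = bb$x / 10, y = bb$y / 10,
             z = (bb$z - membrane_center_z) / 10)
}

#' Backbone structure table from a topology and trajectory frame
#'
#' The static input-model coordinates used by the annotation and rule
#' modules (frame 1 by default; the generator's protein is static anyway).
#'
#' @param topo A `lipid_topology`.
#' @param traj A `lipid_trajectory`.
#' @param frame Frame index (1-based).
#' @return Structure data.frame (`residue_id`, `name`, `chain`, `resno`,
#'   `x`, `y`, `z`).
#' @export
structure_from_topology <- function(topo, traj, frame = 1L) {
  res <- topo$residues
  bb <- vapply(res$residue_id, function(r)
    beads_of_residue(topo, r, roles = "BB")[1], integer(1))
  data.frame(residue_id = res$residue_id, name = res$name,
             chain = res$chain, resno = res$resno,
             x = traj$coords[frame, bb, 1], y = traj$coords[frame, bb, 2],
             z = traj$coords[frame, bb, 3])
}

#' Write a trajectory in the package's tabular format
#'
#' A plain TSV with columns `frame` (0-based), `time` (ns), `bead_id`,
#' `x`, `y`, `z` (nm), `box_x`, `box_y`, `box_z` (nm), one row per bead per
#' frame.
#'
#' @param traj A `lipid_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traj_table <- function(traj, path) {
  nf <- n_frames(traj)
  nb <- dim(traj$coords)[2]
  dt_ <- data.table::data.table(
    frame = rep(seq_len(nf) - 1L, each = nb),
    time = rep(traj$times, each = nb),
    bead_id = rep(seq_len(nb), nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])),
    box_x = rep(traj$box[, 1], each = nb),
    box_y = rep(traj$box[, 2], each = nb),
    box_z = rep(traj$box[, 3], each = nb))
  data.table::fwrite(dt_, path, sep = "\t")
  invisible(path)
}

#' Read a trajectory from the package's tabular format
#'
#' @param path TSV path written by [write_traj_table()].
#' @param stride Keep every `stride`-th frame.
#' @return A `lipid_trajectory`.
#' @export
read_traj_table <- function(path, stride = 1L) {
  dt_ <- data.table::fread(path, sep = "\t")
  frames <- sort(unique(dt_$frame))
  frames <- frames[seq(1, length(frames), by = stride)]
  dt_ <- dt_[dt_$frame %in% frames, ]
  data.table::setorderv(dt_, c("frame", "bead_id"))
  nb <- length(unique(dt_$bead_id))
  nf <- length(frames)
  coords <- array(NA_real_, c(nf, nb, 3))
  coords[, , 1] <- matrix(dt_$x, nf, nb, byrow = TRUE)
  coords[, , 2] <- matrix(dt_$y, nf, nb, byrow = TRUE)
  coords[, , 3] <- matrix(dt_$z, nf, nb, byrow = TRUE)
  first <- !duplicated(dt_$frame)
  trajectory(coords, times = dt_$time[first],
             box = cbind(dt_$box_x[first], dt_$box_y[first],
                         dt_$box_z[first]))
}

#' Write planted-site ground truth as JSON
#'
#' @param system A `lipid_system` from [generate_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(system, path) {
  gt <- lapply(system$ground_truth, function(g)
    list(residue_ids = g$residue_ids, lipid_id = g$lipid_id,
         lipid_type = g$site$lipid_type, p_on = g$site$p_on,
         p_off = g$site$p_off, leaflet = g$site$leaflet,
         state = as.integer(g$state)))
  jsonlite::write_json(list(seed = system$params$seed, sites = gt), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a system from structure and trajectory files
#'
#' Supported structure formats: GRO (nm) and PDB (Angstrom, converted).
#' Supported trajectory formats: the package's tabular TSV and DCD
#' (Angstrom, converted). With no trajectory, a single-frame trajectory is
#' built from the structure. The trajectory is shifted into the membrane
#' frame (phosphate z center of mass at 0) and leaflets are assigned from
#' the phosphate z sign in the first frame.
#'
#' @param structure_path Path to a GRO or PDB file.
#' @param trajectory_path Optional path to a TSV or DCD trajectory.
#' @param role_map Atom-name to bead-role map.
#' @param stride Keep every `stride`-th trajectory frame.
#' @param dt Frame spacing in ns for formats without times (DCD).
#' @return List with `topology` and `trajectory` in nm/ns.
#' @export
load_system <- function(structure_path, trajectory_path = NULL,
                        role_map = DEFAULT_ROLE_MAP, stride = 1L, dt = 1) {
  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "gro") {
    sys <- read_gro(structure_path, role_map)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(structure_path)
    a <- pdb$atom
    at <- data.frame(resno = a$resno, resname = toupper(a$resid),
                     atom = toupper(a$elety),
                     x = a$x / 10, y = a$y / 10, z = a$z / 10)
    sys <- build_system_from_atoms(at, role_map)
    sys$box <- c(max(at$x) - min(at$x) + 2, max(at$y) - min(at$y) + 2,
                 max(at$z) - min(at$z) + 2)
  } else stop("unknown structure format: .", ext)
  if (is.null(trajectory_path)) {
    traj <- trajectory(sys$coords, times = 0, box = sys$box)
  } else {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text %in% c("tsv", "txt", "traj")) {
      traj <- read_traj_table(trajectory_path, stride)
    } else if (text == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path)
      xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
      nf <- nrow(xyz); nb <- ncol(xyz) / 3
      coords <- array(NA_real_, c(nf, nb, 3))
      for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3)] / 10
      traj <- trajectory(coords, times = (seq_len(nf) - 1) * dt,
                         box = sys$box)
    } else stop("unknown trajectory format: .", text)
  }
  traj <- center_membrane(traj, sys$topology)
  topo <- assign_leaflets(traj, sys$topology)
  list(topology = topo, trajectory = traj)
}
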
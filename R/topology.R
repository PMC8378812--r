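#' Residue chemical categories
#'
#' Category sets used throughout the analyses. Basic residues are Arg and Lys
#' only: His is treated as neutral at membrane pH in the coarse-grained model
#' and is counted among the polar residues instead.
#'
#' @param basic,polar,aromatic Character vectors of three-letter residue
#'   names (upper case).
#' @return A named list with elements `basic`, `polar`, `aromatic`.
#' @export
residue_categories <- function(basic = c("ARG", "LYS"),
                               polar = c("SER", "THR", "HIS"),
                               aromatic = c("PHE", "TRP", "TYR")) {
  list(basic = toupper(basic), polar = toupper(polar),
       aromatic = toupper(aromatic))
}

#' Bead roles forming the cardiolipin headgroup
#' @keywords internal
CDL_HEADGROUP_ROLES <- c("GL0", "PO1", "PO2")

#' Bead roles treated as phosphates (membrane frame, leaflet assignment)
#' @keywords internal
PHOSPHATE_ROLES <- c("PO4", "PO1", "PO2")

#' Headgroup bead roles for a lipid type
#'
#' @param lipid_type Lipid type label, e.g. `"CDL"`, `"POPE"`, `"POPG"`.
#' @return Character vector of bead roles making up the headgroup.
#' @export
headgroup_roles <- function(lipid_type) {
  if (toupper(lipid_type) == "CDL") CDL_HEADGROUP_ROLES else "PO4"
}

#' Construct a coarse-grained system topology
#'
#' A topology describes which beads belong to which protein residue or lipid,
#' the role each bead plays (backbone `BB`, side chain `SC1`, phosphates
#' `PO4`/`PO1`/`PO2`, central glycerol `GL0`, tail beads), and the leaflet
#' each lipid sits in.
#'
#' @param residues data.frame with columns `residue_id` (integer, unique),
#'   `name` (three-letter residue name), `chain`, `resno`.
#' @param lipids data.frame with columns `lipid_id` (integer, unique),
#'   `type`, `leaflet` (`"inner"` or `"outer"`).
#' @param beads data.frame with columns `bead_id` (integer, 1..n, the row
#'   index into trajectory coordinates), `owner` (`"residue"` or `"lipid"`),
#'   `owner_id`, `role`.
#' @param categories Residue category sets, see [residue_categories()].
#' @return An object of class `lipid_topology`.
#' @export
system_topology <- function(residues, lipids, beads,
                            categories = residue_categories()) {
  residues <- as.data.frame(residues)
  lipids <- as.data.frame(lipids)
  beads <- as.data.frame(beads)
  stopifnot(all(c("residue_id", "name", "chain", "resno") %in% names(residues)),
            all(c("lipid_id", "type", "leaflet") %in% names(lipids)),
            all(c("bead_id", "owner", "owner_id", "role") %in% names(beads)))
  if (anyDuplicated(residues$residue_id))
    stop("duplicate residue_id in topology")
  if (anyDuplicated(lipids$lipid_id))
    stop("duplicate lipid_id in topology")
  if (anyDuplicated(beads$bead_id))
    stop("each bead must belong to exactly one residue or lipid")
  if (!all(beads$owner %in% c("residue", "lipid")))
    stop("bead owner must be 'residue' or 'lipid'")
  if (nrow(lipids) && !all(lipids$leaflet %in% c("inner", "outer")))
    stop("every lipid needs a leaflet label 'inner' or 'outer'")
  bad_res <- setdiff(beads$owner_id[beads$owner == "residue"],
                     residues$residue_id)
  bad_lip <- setdiff(beads$owner_id[beads$owner == "lipid"], lipids$lipid_id)
  if (length(bad_res) || length(bad_lip))
    stop("bead owner_id not present in residue/lipid tables")
  cdl <- lipids$lipid_id[toupper(lipids$type) == "CDL"]
  for (id in cdl) {
    roles <- beads$role[beads$owner == "lipid" & beads$owner_id == id]
    if (!all(CDL_HEADGROUP_ROLES %in% roles))
      stop("CDL lipid ", id, " must expose beads GL0, PO1 and PO2")
  }
  rownames(residues) <- rownames(lipids) <- rownames(beads) <- NULL
  structure(list(residues = residues, lipids = lipids, beads = beads,
                 categories = categories),
            class = "lipid_topology")
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat("CG system topology:", nrow(x$residues), "protein residues,",
      nrow(x$lipids), "lipids,", nrow(x$beads), "beads\n")
  if (nrow(x$lipids)) {
    tab <- table(x$lipids$type, x$lipids$leaflet)
    print(tab)
  }
  invisible(x)
}

#' Bead ids belonging to a residue or lipid
#'
#' @param topo A `lipid_topology`.
#' @param residue_id,lipid_id Identifier of the owner.
#' @param roles Optional character vector restricting to bead roles.
#' @return Integer vector of bead ids.
#' @export
beads_of_residue <- function(topo, residue_id, roles = NULL) {
  if (!residue_id %in% topo$residues$residue_id)
    stop("unknown residue_id: ", residue_id)
  b <- topo$beads
  sel <- b$owner == "residue" & b$owner_id == residue_id
  if (!is.null(roles)) sel <- sel & b$role %in% roles
  ids <- b$bead_id[sel]
  if (!length(ids)) stop("no beads left for residue ", residue_id,
                         " after role filtering")
  ids
}

#' @rdname beads_of_residue
#' @export
beads_of_lipid <- function(topo, lipid_id, roles = NULL) {
  if (!lipid_id %in% topo$lipids$lipid_id)
    stop("unknown lipid_id: ", lipid_id)
  b <- topo$beads
  sel <- b$owner == "lipid" & b$owner_id == lipid_id
  if (!is.null(roles)) sel <- sel & b$role %in% roles
  ids <- b$bead_id[sel]
  if (!length(ids)) stop("no beads left for lipid ", lipid_id,
                         " after role filtering")
  ids
}

#' All protein bead ids
#' @param topo A `lipid_topology`.
#' @return Integer vector of bead ids.
#' @export
protein_bead_ids <- function(topo) {
  topo$beads$bead_id[topo$beads$owner == "residue"]
}

#' Lipid ids, optionally restricted by type and leaflet
#' @param topo A `lipid_topology`.
#' @param type Optional lipid type label.
#' @param leaflet Optional `"inner"` or `"outer"`.
#' @return Integer vector of lipid ids.
#' @export
lipid_ids <- function(topo, type = NULL, leaflet = NULL) {
  l <- topo$lipids
  sel <- rep(TRUE, nrow(l))
  if (!is.null(type)) sel <- sel & toupper(l$type) == toupper(type)
  if (!is.null(leaflet)) sel <- sel & l$leaflet == leaflet
  l$lipid_id[sel]
}

#' Residue name lookup
#' @keywords internal
residue_name <- function(topo, residue_id) {
  topo$residues$name[match(residue_id, topo$residues$residue_id)]
}
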
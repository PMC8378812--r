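#' Thresholds of the cardiolipin-site rule engine
#'
#' A high-affinity CDL site on a bacterial membrane protein is characterized
#' by (1) two to three basic residues within 0.8 nm of each other, in the
#' same membrane plane (|dz| within `z_tolerance`) and roughly 1.8 nm from
#' the membrane center; (2) at least one polar residue (Ser/Thr/His); and
#' (3) one or more aromatic residues slightly deeper within the membrane
#' than the basic cluster. The depth band and the "slightly deeper" margin
#' are configurable since only approximate values are physically motivated.
#'
#' @param adjacency_nm Maximum pairwise basic-basic distance (default 0.8).
#' @param z_tolerance_nm Maximum pairwise |dz| within the basic cluster
#'   (default 0.3).
#' @param depth_nm Target distance of the basic cluster from the membrane
#'   center (default 1.8).
#' @param depth_tolerance_nm Half-width of the accepted depth band
#'   (default 0.5).
#' @param aromatic_margin_nm How much deeper (toward z = 0) an aromatic must
#'   sit relative to the basic cluster's mean depth (default 0.2).
#' @param expand_nm Radius around the basic cluster within which residues
#'   are included in a scanned candidate (default 1.0).
#' @param include_tyr Count Tyr among the aromatics (default TRUE).
#' @return An object of class `rule_params`.
#' @export
rule_params <- function(adjacency_nm = 0.8, z_tolerance_nm = 0.3,
                        depth_nm = 1.8, depth_tolerance_nm = 0.5,
                        aromatic_margin_nm = 0.2, expand_nm = 1.0,
                        include_tyr = TRUE) {
  structure(list(adjacency_nm = adjacency_nm,
                 z_tolerance_nm = z_tolerance_nm, depth_nm = depth_nm,
                 depth_tolerance_nm = depth_tolerance_nm,
                 aromatic_margin_nm = aromatic_margin_nm,
                 expand_nm = expand_nm, include_tyr = include_tyr),
            class = "rule_params")
}

rule_aromatics <- function(params, categories = residue_categories()) {
  ar <- categories$aromatic
  if (!params$include_tyr) ar <- setdiff(ar, "TYR")
  ar
}

# enumerate basic clusters (pairs and triples) satisfying rule-1 geometry;
# returns a list of lists with ids, max pairwise distance, max |dz|, mean |z|
basic_clusters <- function(st, params, categories = residue_categories()) {
  bas <- st[toupper(st$name) %in% categories$basic, , drop = FALSE]
  n <- nrow(bas)
  out <- list()
  if (n < 2) return(out)
  cmb <- utils::combn(n, 2, simplify = FALSE)
  if (n >= 3) cmb <- c(cmb, utils::combn(n, 3, simplify = FALSE))
  for (idx in cmb) {
    sub <- bas[idx, , drop = FALSE]
    dm <- as.matrix(stats::dist(sub[, c("x", "y", "z")]))
    maxd <- max(dm)
    dzm <- max(abs(outer(sub$z, sub$z, `-`)))
    mz <- mean(abs(sub$z))
    if (maxd < params$adjacency_nm && dzm <= params$z_tolerance_nm &&
        abs(mz - params$depth_nm) <= params$depth_tolerance_nm)
      out[[length(out) + 1L]] <- list(ids = sub$residue_id,
                                      max_distance_nm = maxd,
                                      max_dz_nm = dzm, mean_abs_z_nm = mz)
  }
  out
}

#' Score a candidate residue set against the cardiolipin-site rules
#'
#' Coordinates must be in the membrane frame (bilayer center at z = 0);
#' `membrane_center_z` shifts them if not. Rule 1 passes when at least two
#' basic residues form a cluster meeting the adjacency, z-planarity and
#' depth thresholds; rule 2 when a polar residue (Ser/Thr/His) is present;
#' rule 3 when an aromatic residue sits at least `aromatic_margin_nm` deeper
#' (toward the membrane center) than the basic cluster's mean depth.
#'
#' @param candidate Structure data.frame rows forming the candidate
#'   (columns `residue_id`, `name`, `x`, `y`, `z`).
#' @param params A [rule_params()] object.
#' @param membrane_center_z z of the membrane center in the input frame.
#' @param categories Residue category sets.
#' @return An object of class `rule_report`: per-rule pass flags with
#'   measured geometry and `overall` (number of rules passed, 0-3).
#' @export
score_cdl_site <- function(candidate, params = rule_params(),
                           membrane_center_z = 0,
                           categories = residue_categories()) {
  st <- as.data.frame(candidate)
  if (!nrow(st)) stop("empty candidate")
  if (anyNA(st[, c("x", "y", "z")])) stop("candidate coordinates missing")
  st$z <- st$z - membrane_center_z
  nms <- toupper(st$name)
  basics <- st[nms %in% categories$basic, , drop = FALSE]

  clusters <- basic_clusters(st, params, categories)
  rule1 <- list(pass = length(clusters) > 0, n_basics = nrow(basics))
  best <- NULL
  if (length(clusters)) {
    # prefer larger then more compact clusters
    ord <- order(-vapply(clusters, function(cl) length(cl$ids), numeric(1)),
                 vapply(clusters, `[[`, numeric(1), "max_distance_nm"))
    best <- clusters[[ord[1]]]
    rule1 <- c(rule1, best[c("ids", "max_distance_nm", "max_dz_nm",
                             "mean_abs_z_nm")])
  }
  polars <- nms[nms %in% categories$polar]
  rule2 <- list(pass = length(polars) > 0, polar_residues = unique(polars))

  ar_names <- rule_aromatics(params, categories)
  aro <- st[nms %in% ar_names, , drop = FALSE]
  ref_depth <- if (!is.null(best)) best$mean_abs_z_nm else
    if (nrow(basics)) mean(abs(basics$z)) else NA_real_
  rule3 <- list(pass = FALSE, aromatic_residues = character(0),
                aromatic_depths_nm = numeric(0), reference_depth_nm = ref_depth)
  if (nrow(aro) && !is.na(ref_depth)) {
    deep <- abs(aro$z) < (ref_depth - params$aromatic_margin_nm)
    rule3$pass <- any(deep)
    rule3$aromatic_residues <- toupper(aro$name[deep])
    rule3$aromatic_depths_nm <- abs(aro$z[deep])
  }
  structure(list(rule1_basics = rule1, rule2_polar = rule2,
                 rule3_aromatic = rule3,
                 overall = sum(rule1$pass, rule2$pass, rule3$pass),
                 residue_ids = sort(st$residue_id),
                 has_gly = "GLY" %in% nms),
            class = "rule_report")
}

#' @export
print.rule_report <- function(x, ...) {
  ok <- function(p) if (p) "pass" else "fail"
  cat("CDL site rule report (", x$overall, "/3 )\n", sep = "")
  r1 <- x$rule1_basics
  cat("  1. adjacent basics:", ok(r1$pass))
  if (r1$pass)
    cat(sprintf("  [%s; max d %.2f nm, max |dz| %.2f nm, depth %.2f nm]",
                paste(r1$ids, collapse = ","), r1$max_distance_nm,
                r1$max_dz_nm, r1$mean_abs_z_nm))
  cat("\n  2. polar residue:  ", ok(x$rule2_polar$pass), " ",
      paste(x$rule2_polar$polar_residues, collapse = ","), "\n", sep = "")
  cat("  3. deeper aromatic:", ok(x$rule3_aromatic$pass),
      paste(x$rule3_aromatic$aromatic_residues, collapse = ","), "\n")
  invisible(x)
}

#' Scan a membrane-oriented structure for rule-conforming CDL sites
#'
#' Enumerates basic pairs/triples satisfying the rule-1 geometry, expands
#' each cluster by all residues within `expand_nm` of any cluster member,
#' scores each candidate with [score_cdl_site()], deduplicates identical
#' residue sets, and ranks by rules passed (descending), then basic-cluster
#' compactness, then lowest residue id -- a deterministic ordering.
#'
#' @param structure Structure data.frame (`residue_id`, `name`, `chain`,
#'   `resno`, `x`, `y`, `z`), membrane frame (z = 0 at bilayer center).
#' @param params A [rule_params()] object.
#' @param membrane_center_z z of the membrane center in the input frame.
#' @param categories Residue category sets.
#' @return List of `rule_report` objects (possibly empty, with attribute
#'   `no_basics = TRUE` when the structure has no qualifying basic pair).
#' @export
scan_structure <- function(structure, params = rule_params(),
                           membrane_center_z = 0,
                           categories = residue_categories()) {
  st <- as.data.frame(structure)
  st$z <- st$z - membrane_center_z
  clusters <- basic_clusters(st, params, categories)
  if (!length(clusters)) {
    out <- list()
    attr(out, "no_basics") <- TRUE
    return(out)
  }
  reports <- list()
  seen <- character(0)
  for (cl in clusters) {
    anchor <- st[st$residue_id %in% cl$ids, c("x", "y", "z"), drop = FALSE]
    d2anchor <- apply(st[, c("x", "y", "z")], 1, function(p)
      min(sqrt(colSums((t(as.matrix(anchor)) - p)^2))))
    cand <- st[d2anchor < params$expand_nm | st$residue_id %in% cl$ids, ,
               drop = FALSE]
    key <- paste(sort(cand$residue_id), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rep_ <- score_cdl_site(cand, params, membrane_center_z = 0,
                           categories = categories)
    rep_$seed_cluster <- cl
    reports[[length(reports) + 1L]] <- rep_
  }
  ord <- order(-vapply(reports, `[[`, numeric(1), "overall"),
               vapply(reports, function(r) r$seed_cluster$max_distance_nm,
                      numeric(1)),
               vapply(reports, function(r) min(r$residue_ids), numeric(1)))
  reports[ord]
}

#' Tabulate rule reports
#'
#' One row per scanned candidate: rules passed and measured geometry, in the
#' style of a structure-audit summary table.
#'
#' @param reports List of `rule_report` objects from [scan_structure()].
#' @return data.frame.
#' @export
rule_report_table <- function(reports) {
  if (!length(reports))
    return(data.frame(rank = integer(0)))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    r1 <- r$rule1_basics
    data.frame(rank = i,
               residues = paste(r$residue_ids, collapse = ","),
               overall = r$overall,
               rule1 = r1$pass, rule2 = r$rule2_polar$pass,
               rule3 = r$rule3_aromatic$pass,
               n_basics = r1$n_basics,
               basic_max_distance_nm = if (r1$pass) r1$max_distance_nm else NA,
               basic_max_dz_nm = if (r1$pass) r1$max_dz_nm else NA,
               basic_depth_nm = if (r1$pass) r1$mean_abs_z_nm else NA,
               has_gly = r$has_gly)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
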
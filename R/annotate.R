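#' Adjacent basic residue pairs within a site
#'
#' Finds all Arg/Lys pairs of a site whose backbone beads lie within
#' `cutoff` of each other in 3-D, using the static input-model coordinates
#' (not trajectory averages). Each pair carries its distance and |dz|,
#' the separation along the membrane normal.
#'
#' @param site Integer vector of residue ids.
#' @param structure Structure data.frame with columns `residue_id`, `name`,
#'   `x`, `y`, `z` (backbone-bead coordinates, nm).
#' @param cutoff Adjacency cutoff in nm (default 0.8).
#' @param categories Residue category sets, see [residue_categories()].
#' @return data.frame with columns `residue_i`, `residue_j`, `distance_nm`,
#'   `z_separation_nm` (zero rows when no pair qualifies).
#' @export
find_adjacent_basics <- function(site, structure, cutoff = 0.8,
                                 categories = residue_categories()) {
  rows <- structure[structure$residue_id %in% site, , drop = FALSE]
  if (!nrow(rows)) stop("site has no coordinates in the structure")
  bas <- rows[toupper(rows$name) %in% categories$basic, , drop = FALSE]
  out <- data.frame(residue_i = integer(0), residue_j = integer(0),
                    distance_nm = numeric(0), z_separation_nm = numeric(0))
  if (nrow(bas) < 2) return(out)
  for (i in seq_len(nrow(bas) - 1L)) {
    for (j in (i + 1L):nrow(bas)) {
      d <- sqrt(sum((unlist(bas[i, c("x", "y", "z")]) -
                       unlist(bas[j, c("x", "y", "z")]))^2))
      if (d < cutoff)
        out[nrow(out) + 1L, ] <- list(bas$residue_id[i], bas$residue_id[j],
                                      d, abs(bas$z[i] - bas$z[j]))
    }
  }
  out
}

# size of the largest connected cluster of mutually adjacent basics
largest_adjacent_cluster <- function(basic_ids, pairs) {
  if (!length(basic_ids)) return(0L)
  if (!nrow(pairs)) return(as.integer(length(basic_ids) > 0) * 1L)
  g <- igraph::graph_from_data_frame(
    pairs[, c("residue_i", "residue_j")], directed = FALSE,
    vertices = data.frame(name = as.character(basic_ids)))
  max(igraph::components(g)$csize)
}

#' Annotate sites by basic-residue content and composition
#'
#' For each site: the number of Arg/Lys residues, the adjacent basic pairs
#' (backbone beads within the adjacency cutoff), the size of the largest
#' mutually adjacent basic cluster, presence flags for Gly/His/Pro/Ser/Thr,
#' and the leaflet the site faces (sign of the mean backbone z).
#'
#' @param sites A `binding_sites` object or a list of site records with
#'   `residue_ids` and `occupancy`.
#' @param structure Structure data.frame (see [find_adjacent_basics()]).
#' @param adjacency_cutoff Adjacency cutoff in nm (default 0.8).
#' @param categories Residue category sets.
#' @return data.frame of class `site_annotations`, one row per site, with an
#'   `adjacent_pairs` attribute (list of pair tables per site).
#' @export
annotate_sites <- function(sites, structure, adjacency_cutoff = 0.8,
                           categories = residue_categories()) {
  if (inherits(sites, "binding_sites")) sites <- sites$sites
  comp_flags <- c("GLY", "HIS", "PRO", "SER", "THR")
  rows <- list()
  pair_list <- list()
  for (s in sites) {
    ids <- sort(s$residue_ids)
    st <- structure[structure$residue_id %in% ids, , drop = FALSE]
    nms <- toupper(st$name)
    basic_ids <- st$residue_id[nms %in% categories$basic]
    pairs <- find_adjacent_basics(ids, structure, adjacency_cutoff,
                                  categories)
    flags <- stats::setNames(comp_flags %in% nms, paste0("has_", tolower(comp_flags)))
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = s$site_id,
      n_residues = length(ids),
      occupancy = s$occupancy,
      residence_ns = if (!is.null(s$residence_ns)) s$residence_ns else NA_real_,
      n_basic = length(basic_ids),
      n_adjacent_pairs = nrow(pairs),
      has_adjacent_basics = nrow(pairs) > 0,
      max_adjacent_cluster = largest_adjacent_cluster(basic_ids, pairs),
      t(as.data.frame(flags)),
      leaflet = if (mean(st$z) < 0) "inner" else "outer",
      row.names = NULL)
    pair_list[[length(pair_list) + 1L]] <- pairs
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = integer(0))
  rownames(out) <- NULL
  attr(out, "adjacent_pairs") <- pair_list
  class(out) <- c("site_annotations", "data.frame")
  out
}

#' Two-sample two-tailed t-test on site occupancies
#'
#' Welch (unequal variance) by default, pooled-variance optionally.
#'
#' @param x,y Numeric samples.
#' @param var_equal Use the pooled-variance (Student) form.
#' @return List with `t`, `df`, `p`, `n_x`, `n_y` (`t`/`p` are `NA` when a
#'   group is degenerate, i.e. fewer than two values).
#' @export
occupancy_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                n_x = length(x), n_y = length(y)))
  tt <- stats::t.test(x, y, alternative = "two.sided",
                      var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_x = length(x), n_y = length(y))
}

strata_row <- function(label, occ) {
  q <- stats::quantile(occ, c(0.25, 0.5, 0.75), names = FALSE,
                       na.rm = TRUE)
  data.frame(stratum = label, n = length(occ),
             median = if (length(occ)) q[2] else NA_real_,
             q1 = if (length(occ)) q[1] else NA_real_,
             q3 = if (length(occ)) q[3] else NA_real_)
}

#' Occupancy stratification by basic-residue content and composition
#'
#' Reproduces the occupancy strata of annotated sites -- all sites, sites
#' with any Arg/Lys, with none, exactly one, two or more, two or more
#' adjacent, three or more adjacent -- plus composition contrasts
#' (with/without Gly, His, Pro, Ser, Thr among sites with >= 2 adjacent
#' basics), each contrast tested with a two-tailed t-test. The mean basic
#' count of basic-containing sites is reported with both SD and SEM.
#'
#' @param annotations A `site_annotations` data.frame.
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] for the composition contrasts (default `"none"`,
#'   matching raw-p reporting; `"BH"` available).
#' @return List with `strata` (n, median, IQR per stratum), `contrasts`
#'   (t, df, p per composition flag), and `basic_count` (mean, sd, sem).
#' @export
stratify_occupancies <- function(annotations, var_equal = FALSE,
                                 p_adjust = "none") {
  a <- as.data.frame(annotations)
  occ <- a$occupancy
  strata <- rbind(
    strata_row("all", occ),
    strata_row("KR", occ[a$n_basic >= 1]),
    strata_row("no KR", occ[a$n_basic == 0]),
    strata_row("1 KR", occ[a$n_basic == 1]),
    strata_row(">=2 KR", occ[a$n_basic >= 2]),
    strata_row(">=2 KR adj", occ[a$max_adjacent_cluster >= 2]),
    strata_row(">=3 KR adj", occ[a$max_adjacent_cluster >= 3]))
  adj2 <- a[a$max_adjacent_cluster >= 2, , drop = FALSE]
  flags <- grep("^has_", names(a), value = TRUE)
  flags <- setdiff(flags, "has_adjacent_basics")
  contrasts <- list()
  for (f in flags) {
    with_f <- adj2$occupancy[adj2[[f]]]
    without_f <- adj2$occupancy[!adj2[[f]]]
    tt <- occupancy_t_test(with_f, without_f, var_equal)
    contrasts[[length(contrasts) + 1L]] <- data.frame(
      flag = sub("^has_", "", f), n_with = tt$n_x, n_without = tt$n_y,
      median_with = stats::median(with_f), median_without = stats::median(without_f),
      t = tt$t, df = tt$df, p = tt$p)
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame()
  if (nrow(contrasts)) {
    contrasts$p_adjusted <- stats::p.adjust(contrasts$p, method = p_adjust)
    rownames(contrasts) <- NULL
  }
  nb <- a$n_basic[a$n_basic >= 1]
  basic_count <- list(mean = mean(nb), sd = stats::sd(nb),
                      sem = stats::sd(nb) / sqrt(length(nb)), n = length(nb))
  list(strata = strata, contrasts = contrasts, basic_count = basic_count)
}
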
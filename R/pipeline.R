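#' Pipeline configuration
#'
#' All stage parameters in one serializable object; defaults are the
#' analysis defaults used throughout the package (0.6 nm contact cutoff,
#' 0.55/1.0 nm dual cutoffs, 10 ns residence filter, 10% residue-occupancy
#' floor, 0.8 nm basic adjacency).
#'
#' @param structure,trajectory Input file paths (optional when a system
#'   object is passed to [run_pipeline()] directly).
#' @param out_dir Output directory.
#' @param lipid_type Lipid type analyzed for sites (default `"CDL"`).
#' @param contact_cutoff,skip_fraction,min_contact_prob,z_bin_width
#'   Contact-analysis parameters (nm / fraction).
#' @param lower_cutoff,upper_cutoff Dual cutoffs (nm).
#' @param edge_threshold Co-binding edge retention threshold.
#' @param min_residence_ns,residue_occupancy_floor Site filters.
#' @param estimator Residence-time estimator (`"mean"` or `"survival"`).
#' @param adjacency_nm Basic-adjacency cutoff for annotation (nm).
#' @param propensity_scope `"leaflet"` or `"membrane"`.
#' @param stride Trajectory frame stride on load.
#' @param seed RNG seed (community detection etc.).
#' @param run_rules Also run the rule engine on the input structure.
#' @param rules Rule thresholds, a [rule_params()] object or list.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(structure = NULL, trajectory = NULL,
                            out_dir = ".", lipid_type = "CDL",
                            contact_cutoff = 0.6, skip_fraction = 0.1,
                            min_contact_prob = 0.10, z_bin_width = 0.1,
                            lower_cutoff = 0.55, upper_cutoff = 1.0,
                            edge_threshold = 0.3, min_residence_ns = 10,
                            residue_occupancy_floor = 0.10,
                            estimator = "mean", adjacency_nm = 0.8,
                            propensity_scope = "leaflet", stride = 1L,
                            seed = 1L, run_rules = FALSE,
                            rules = rule_params()) {
  cfg <- list(structure = structure, trajectory = trajectory,
              out_dir = out_dir, lipid_type = lipid_type,
              contact_cutoff = contact_cutoff,
              skip_fraction = skip_fraction,
              min_contact_prob = min_contact_prob,
              z_bin_width = z_bin_width, lower_cutoff = lower_cutoff,
              upper_cutoff = upper_cutoff, edge_threshold = edge_threshold,
              min_residence_ns = min_residence_ns,
              residue_occupancy_floor = residue_occupancy_floor,
              estimator = estimator, adjacency_nm = adjacency_nm,
              propensity_scope = propensity_scope,
              stride = as.integer(stride), seed = as.integer(seed),
              run_rules = run_rules, rules = unclass(rules))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' The write -> read round trip reproduces the configuration exactly.
#'
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @return `path` invisibly (write); a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stride <- as.integer(cfg$stride)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; embedded in every output file
#' so results can be traced back to the exact parameters that produced
#' them. The output directory is excluded: it affects where results land,
#' not what they are.
#'
#' @param config A `pipeline_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  hashed <- unclass(config)
  hashed$out_dir <- NULL
  yaml::write_yaml(hashed, tf)
  unname(tools::md5sum(tf))
}

output_header <- function(config) {
  sprintf("# lipidsites %s config=%s seed=%d",
          as.character(utils::packageVersion("lipidsites")),
          config_hash(config), config$seed)
}

write_output_csv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(output_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes contacts -> sites -> annotate (and the rule engine when a
#' structure is available and `run_rules` is set), writing CSV/JSON outputs
#' to `out_dir`, each embedding the config hash and seed. With a fixed seed
#' the outputs are byte-identical between runs.
#'
#' @param config A [pipeline_config()].
#' @param system Optional in-memory `lipid_system` (from
#'   [generate_system()]); otherwise inputs are loaded from the configured
#'   paths. A rules-only configuration (structure but no trajectory and
#'   `run_rules = TRUE`) runs the rule engine alone.
#' @return Invisibly, a list with the stage results (`propensity`,
#'   `z_profile`, `bead_profile`, `sites`, `annotations`, `strata`,
#'   `rule_reports`) and `files` (paths written).
#' @export
run_pipeline <- function(config, system = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  rules_only <- is.null(system) && is.null(config$trajectory) &&
    !is.null(config$structure) && isTRUE(config$run_rules)
  res <- list()

  if (!rules_only) {
    if (!is.null(system)) {
      topo <- system$topology; traj <- system$trajectory
    } else {
      if (is.null(config$structure)) stop("pipeline stage 'load': no structure configured")
      sys <- load_system(config$structure, config$trajectory,
                         stride = config$stride)
      topo <- sys$topology; traj <- sys$trajectory
    }
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "': ", conditionMessage(e),
             call. = FALSE))
    }
    res$propensity <- stage("contacts", lipid_binding_propensity(
      traj, topo, cutoff = config$contact_cutoff,
      skip_fraction = config$skip_fraction, scope = config$propensity_scope))
    write_output_csv(as.data.frame(res$propensity), out("propensity.csv"),
                     config)
    files <- c(files, out("propensity.csv"))
    res$z_profile <- stage("contacts", contacting_residue_z_profile(
      traj, topo, cutoff = config$contact_cutoff,
      min_contact_probability = config$min_contact_prob,
      bin_width = config$z_bin_width))
    write_output_csv(res$z_profile$histogram, out("z_profile.csv"), config)
    files <- c(files, out("z_profile.csv"))
    res$bead_profile <- stage("contacts", bead_residue_profile(
      traj, topo, config$lipid_type, cutoff = config$contact_cutoff))
    write_output_csv(res$bead_profile$counts, out("bead_profile.csv"),
                     config)
    files <- c(files, out("bead_profile.csv"))

    res$sites <- stage("sites", find_binding_sites(
      traj, topo, lipid_type = config$lipid_type,
      lower = config$lower_cutoff, upper = config$upper_cutoff,
      edge_threshold = config$edge_threshold, seed = config$seed,
      estimator = config$estimator,
      min_residence_ns = config$min_residence_ns,
      residue_occupancy_floor = config$residue_occupancy_floor))
    sites_to_json(res$sites, out("sites.json"))
    files <- c(files, out("sites.json"))

    struct <- structure_from_topology(topo, traj)
    res$annotations <- stage("annotate", annotate_sites(
      res$sites, struct, adjacency_cutoff = config$adjacency_nm))
    write_output_csv(as.data.frame(res$annotations), out("sites.csv"),
                     config)
    files <- c(files, out("sites.csv"))
    if (nrow(res$annotations) >= 2) {
      res$strata <- stage("annotate", stratify_occupancies(res$annotations))
      write_output_csv(res$strata$strata, out("strata.csv"), config)
      files <- c(files, out("strata.csv"))
    }
    if (isTRUE(config$run_rules)) {
      rp <- do.call(rule_params, config$rules)
      res$rule_reports <- stage("rules", scan_structure(struct, rp))
      write_output_csv(rule_report_table(res$rule_reports),
                       out("rules.csv"), config)
      files <- c(files, out("rules.csv"))
    }
  } else {
    struct <- read_structure_pdb(config$structure)
    rp <- do.call(rule_params, config$rules)
    res$rule_reports <- scan_structure(struct, rp)
    write_output_csv(rule_report_table(res$rule_reports), out("rules.csv"),
                     config)
    files <- c(files, out("rules.csv"))
  }
  res$files <- files
  invisible(res)
}
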
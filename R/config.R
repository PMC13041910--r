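#' Pipeline run configuration
#'
#' Bundles every stage parameter with its default. The sampling-cylinder
#' dimensions (60 nm diameter, 15 nm height, 5 nm step), the 2 nm resampling
#' interval, the 1 nm binding threshold, the 100 nm writhe-density unit and
#' the 10.5 bp/turn helical repeat follow the published tracing protocol;
#' the remaining defaults are this package's own operating points (see the
#' methods vignette). All geometry is in nm.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `run_config` (a validated named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    # spine stage
    spine_smoothing_sigma = 8,       # nm; merges the two strands into a tube
    spine_threshold_quantile = 0.90, # of positive voxel densities
    spine_prune_length = 15,         # nm; skeleton spur pruning
    # sampling cylinder
    cylinder_diameter = 60,          # nm
    cylinder_height = 15,            # nm
    cylinder_step = 5,               # nm
    center_threshold_quantile = 0.90,
    min_center_separation = 3,       # nm; below this the split is degenerate
    sample_end_extension = 20,       # nm; reach apical caps past skeleton ends
    # linking
    link_max_gap = 25,               # nm
    link_max_turn = 130,             # degrees
    link_dedup_dist = 3,             # nm
    # refinement
    resample_spacing = 2,            # nm
    refine_smooth_window = 10,       # nm
    # topology
    apex_smooth_window = 10,         # nm
    apex_min_prominence = 0.05,      # 1/nm
    apex_min_separation = 30,        # nm
    axis_min_arc_sep = 20,           # nm
    junction_radius = 15,            # nm
    writhe_density_unit = 100,       # nm
    # localization
    binding_threshold = 1,           # nm
    apex_window = 20,                # nm
    # linking-number arithmetic
    helical_repeat = 10.5,           # bp per turn
    # randomness (generators only; tracing is deterministic)
    seed = 1L,
    units = "nm"
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  pos <- c("spine_smoothing_sigma", "spine_prune_length", "cylinder_diameter",
           "cylinder_height", "cylinder_step", "min_center_separation",
           "sample_end_extension",
           "link_max_gap", "link_dedup_dist", "resample_spacing",
           "refine_smooth_window", "apex_smooth_window", "apex_min_prominence",
           "apex_min_separation", "axis_min_arc_sep", "junction_radius",
           "writhe_density_unit", "binding_threshold", "apex_window",
           "helical_repeat")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("config parameter %s must be a positive number", p))
    }
  }
  for (q in c("spine_threshold_quantile", "center_threshold_quantile")) {
    v <- cfg[[q]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(sprintf("config parameter %s must lie in (0, 1)", q))
    }
  }
  if (cfg$link_max_turn <= 0 || cfg$link_max_turn > 180) {
    stop("link_max_turn must lie in (0, 180] degrees")
  }
  if (!identical(cfg$units, "nm")) stop("only nm units are supported")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config (", config_hash(x), "):\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; embedded in output files for
#' provenance.
#'
#' @param config a `run_config`.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

package_version_string <- function() {
  as.character(utils::packageVersion("plectotrace"))
}
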
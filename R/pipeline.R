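#' Read a pipeline configuration file
#'
#' Single YAML document driving the analysis stages: simulation
#' parameters, per-analysis filter blocks, association settings and the
#' master seed. Missing keys fall back to documented defaults; the FDR
#' level must lie in (0, 1).
#'
#' @param path YAML file path
#' @return a named list of class `pipeline_config` with elements `paths`,
#'   `filters`, `association`, `simulation`, `seed`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    paths = list(output_dir = "results"),
    filters = list(haplotype = list(info_min = 0.9, drop_maf_zero = TRUE,
                                    max_snp_missing = 0.25,
                                    max_sample_missing = 0.50)),
    association = list(reference_like_group = "REF_GROUP", fdr_level = 0.05),
    simulation = list(),
    seed = 1
  )
  merge2 <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(b[[k]]) && is.list(a[[k]])) merge2(a[[k]], b[[k]]) else b[[k]]
    }
    a
  }
  cfg <- merge2(defaults, cfg)
  lvl <- cfg$association$fdr_level
  if (!is.numeric(lvl) || lvl <= 0 || lvl >= 1)
    stop("association.fdr_level must be in (0, 1)")
  cfg$config_path <- path
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write a run manifest
#'
#' Records what a stage run actually did: config file hash, package
#' version, timestamp, and the input/output dimensions (and thresholds)
#' of each stage, so every applied filter is auditable.
#'
#' @param path output JSON path
#' @param config a `pipeline_config` (or NULL)
#' @param stages named list of per-stage records (free-form, e.g. filter
#'   reports, dimensions)
#' @return `path`, invisibly
#' @export
write_run_manifest <- function(path, config = NULL, stages = list()) {
  manifest <- list(
    package = "nrhap",
    version = as.character(utils::packageVersion("nrhap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = if (!is.null(config$config_path) && file.exists(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA,
    seed = config$seed,
    stages = stages
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
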
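#' Run the allelic-imbalance detector on a marker table
#'
#' The statistical core of the pipeline: compute the genome-wide RAF
#' threshold (median RAF unless overridden), assign excess alleles by
#' frequency-based phasing, optionally calibrate the concordance emission
#' probability by EM, compute per-marker posteriors by forward-backward,
#' and segment them into events.
#'
#' @param table A `marker_table` (sites with depths, RAF and phased
#'   haplotypes).
#' @param threshold Optional RAF threshold override.
#' @param params An [hmm_params()] object; `gamma` is the EM starting
#'   value when `em = TRUE`.
#' @param em Re-estimate `gamma` from the data before computing
#'   posteriors. Recommended: the true concordance rate depends on the
#'   unknown aberrant-cell fraction and depth.
#' @param em_max_iter,em_tol EM stopping controls.
#' @param posterior_cut,min_event_markers Event-calling controls (see
#'   [call_events()]).
#' @return A list of class `ai_fit`: the augmented `table` (with
#'   `excess_allele`, `z`, `p_ai`), `events`, `threshold`, final `params`,
#'   `posterior` track, EM diagnostics, and the calling settings.
#' @export
detect_ai <- function(table, threshold = NULL, params = hmm_params(),
                      em = TRUE, em_max_iter = 50L, em_tol = 1e-4,
                      posterior_cut = 0.90, min_event_markers = 10L) {
  t_raf <- compute_threshold(table, override = threshold)
  table <- frequency_based_phase(table, t_raf)
  em_fit <- NULL
  if (em && sum(!is.na(table$z)) >= 100L) {
    em_fit <- estimate_gamma_em(table$z, params, max_iter = em_max_iter,
                                tol = em_tol, chrom = table$chrom)
    params <- em_fit$params
  }
  post <- forward_backward(table$z, params, chrom = table$chrom)
  table$p_ai <- post$p_ai
  events <- call_events(post, table, posterior_cut = posterior_cut,
                        min_event_markers = min_event_markers)
  structure(list(table = table, events = events, threshold = t_raf,
                 params = params, posterior = post, em = em_fit,
                 posterior_cut = posterior_cut,
                 min_event_markers = min_event_markers),
            class = "ai_fit")
}

#' Assemble a run configuration
#'
#' Collects every tunable of the detect / simulate / power workflow into
#' one serializable list. Values resolve with precedence command line >
#' config file > defaults; [run_detect()] writes the resolved
#' configuration next to its outputs so any run can be reproduced exactly.
#'
#' @param vcf,phased_vcf Input paths for detection.
#' @param sample_name Sample in a multi-sample VCF.
#' @param min_depth Het-site depth filter.
#' @param threshold RAF threshold override (default: genome-wide median).
#' @param preset `"wes"` or `"wgs"`; sets `mean_event_markers` (200 / 2000)
#'   and the simulator defaults.
#' @param prevalence,mean_event_markers,gamma,switch_rate HMM parameters
#'   (see [hmm_params()]); `mean_event_markers = NULL` defers to the
#'   preset.
#' @param em Calibrate gamma by EM.
#' @param posterior_cut,min_event_markers_event Event calling controls.
#' @param out_dir Output directory.
#' @param seed Seed for any simulation subcommand.
#' @param region_length,het_spacing,mean_depth,depth_model,rho,switch_error_rate,events
#'   Simulator settings (see [sim_config()]).
#' @param fractions,replicates Power-experiment grid.
#' @param config_file Optional JSON file with the same keys, overridden by
#'   explicitly supplied arguments.
#' @param verbose Emit per-stage log lines to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, phased_vcf = NULL, sample_name = NULL,
                       min_depth = 10L, threshold = NULL,
                       preset = "wes", prevalence = 0.05,
                       mean_event_markers = NULL, gamma = 0.65,
                       switch_rate = 0.02, em = TRUE,
                       posterior_cut = 0.90, min_event_markers_event = 10L,
                       out_dir = ".", seed = 1L,
                       region_length = 1e8, het_spacing = NULL,
                       mean_depth = NULL, depth_model = "poisson", rho = 0,
                       switch_error_rate = 0.02, events = NULL,
                       fractions = c(0.04, 0.08, 0.12, 0.16, 0.20,
                                     0.28, 0.40, 0.56, 0.80),
                       replicates = 20L, config_file = NULL,
                       verbose = TRUE) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    file_cfg <- jsonlite::fromJSON(config_file, simplifyVector = TRUE)
    supplied <- names(match.call())[-1L]
    for (k in setdiff(names(file_cfg), c(supplied, "config_file"))) {
      if (k %in% names(cfg)) cfg[[k]] <- file_cfg[[k]]
    }
  }
  if (is.null(cfg$mean_event_markers)) {
    cfg$mean_event_markers <- if (cfg$preset == "wgs") 2000 else 200
  }
  structure(cfg, class = "run_config")
}

log_stage <- function(verbose, stage, ...) {
  if (!verbose) return(invisible())
  kv <- c(...)
  msg <- if (length(kv)) paste(names(kv), kv, sep = "=", collapse = " ") else ""
  message(sprintf("[%s] %s", stage, msg))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

config_params <- function(config) {
  hmm_params(prevalence = config$prevalence,
             mean_event_markers = config$mean_event_markers,
             gamma = config$gamma, switch_rate = config$switch_rate)
}

write_resolved_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$verbose <- NULL
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Detect allelic imbalance end to end
#'
#' Reads the sample VCF and phased haplotypes, runs [detect_ai()], and
#' writes the per-site posterior report (`site_report.tsv`), the called
#' events (`events.bed`), and the resolved configuration
#' (`run_config.json`) into `config$out_dir`. Stage-by-stage counts go to
#' stderr. No paired normal sample is involved at any point.
#'
#' @param config A [run_config()].
#' @return The `ai_fit` (invisibly), with an added `paths` element.
#' @export
run_detect <- function(config) {
  v <- isTRUE(config$verbose)
  sites <- with_stage("read_sample_vcf", {
    if (is.null(config$vcf)) stop("no input VCF given")
    read_sample_vcf(config$vcf, min_depth = config$min_depth,
                    sample_name = config$sample_name)
  })
  log_stage(v, "read_sample_vcf", c(n_sites = nrow(sites)))
  table <- with_stage("read_phased_haplotypes", {
    if (is.null(config$phased_vcf) || !file.exists(config$phased_vcf)) {
      stop("phase file missing: ", config$phased_vcf %||% "<NULL>")
    }
    read_phased_haplotypes(config$phased_vcf, sites,
                           sample_name = config$sample_name)
  })
  log_stage(v, "read_phased_haplotypes", c(n_markers = nrow(table)))
  fit <- with_stage("detect_ai", {
    detect_ai(table, threshold = config$threshold,
              params = config_params(config), em = config$em,
              posterior_cut = config$posterior_cut,
              min_event_markers = config$min_event_markers_event)
  })
  log_stage(v, "detect_ai",
            c(threshold = sprintf("%.4f", fit$threshold),
              gamma = sprintf("%.4f", fit$params$gamma),
              n_events = nrow(fit$events)))
  with_stage("write_outputs", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(site_report = file.path(config$out_dir, "site_report.tsv"),
                  events_bed = file.path(config$out_dir, "events.bed"),
                  config = file.path(config$out_dir, "run_config.json"))
    write_site_report(fit$table, fit$table$p_ai, paths$site_report)
    write_events_bed(fit$events, paths$events_bed)
    write_resolved_config(config, paths$config)
    fit$paths <- paths
  })
  log_stage(v, "write_outputs", c(out_dir = config$out_dir))
  invisible(fit)
}

config_sim <- function(config, events = NULL) {
  sim_config(preset = config$preset, region_length = config$region_length,
             het_spacing = config$het_spacing,
             mean_depth = config$mean_depth,
             depth_model = config$depth_model, rho = config$rho,
             switch_error_rate = config$switch_error_rate,
             events = events %||% config$events, seed = config$seed)
}

#' Simulate a dataset from a run configuration
#'
#' Wraps [simulate_dataset()]: emits `sample.vcf`, `phased.vcf` and
#' `truth.tsv` into `config$out_dir`.
#'
#' @param config A [run_config()] with simulator settings.
#' @return The `sim_dataset` (invisibly).
#' @export
run_simulate <- function(config) {
  v <- isTRUE(config$verbose)
  sim <- with_stage("simulate_dataset", {
    cfg <- config_sim(config)
    simulate_dataset(cfg, out_dir = config$out_dir)
  })
  log_stage(v, "simulate_dataset",
            c(n_markers = nrow(sim$markers),
              n_events = if (is.null(sim$events)) 0L else nrow(sim$events),
              out_dir = config$out_dir))
  invisible(sim)
}

#' Run the sensitivity (power) experiment
#'
#' Wraps [purity_grid_experiment()] over `config$fractions` with
#' `config$replicates` replicates per fraction, writing the detection-rate
#' table to `power.tsv` in `config$out_dir`.
#'
#' @param config A [run_config()]; `config$events` must define at least one
#'   event (placement and type; fractions come from the grid).
#' @return The `power_table` (invisibly).
#' @export
run_power <- function(config) {
  v <- isTRUE(config$verbose)
  tab <- with_stage("purity_grid_experiment", {
    base <- config_sim(config)
    if (is.null(base$events)) stop("power experiment needs config$events")
    purity_grid_experiment(
      base, fractions = config$fractions, replicates = config$replicates,
      detect_args = list(min_depth = config$min_depth,
                         params = config_params(config), em = config$em,
                         posterior_cut = config$posterior_cut,
                         min_event_markers = config$min_event_markers_event),
      seed = config$seed)
  })
  with_stage("write_outputs", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tab, file.path(config$out_dir, "power.tsv"),
                       sep = "\t", quote = FALSE)
  })
  log_stage(v, "purity_grid_experiment",
            c(n_fractions = length(config$fractions),
              out_dir = config$out_dir))
  invisible(tab)
}
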
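# md5 of a serialized R object; used to stamp outputs with the
# configuration they came from
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML (or JSON) with any of the stages below; see
#' [run_pipeline()] for the recognized fields.
#'
#' @param path YAML/JSON file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

config_protocol <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  if (is.character(cfg)) return(protocol_preset(cfg))
  if (!is.null(cfg$preset)) return(protocol_preset(cfg$preset))
  steps <- lapply(cfg$steps, function(s) c(s$rate_ul_min, s$duration_min))
  infusion_protocol(steps, name = cfg$name %||% "custom")
}

#' Run a configured analysis pipeline
#'
#' Chains the package's stages as configured and writes a single JSON result
#' bundle stamped with the seed, the configuration hash and the package
#' version. Recognized top-level fields:
#' \describe{
#'   \item{`protocol`}{preset name, or `{name, steps: [{rate_ul_min,
#'     duration_min}, ...]}`; reports totals.}
#'   \item{`simulate`}{arguments for [make_trajectories()] (`n_per_group`,
#'     `group_slopes`, `slope_sd`, `noise_sd`, `n_points`, `max_infused`);
#'     simulated trials are written as CSV next to the results.}
#'   \item{`trajectories`}{path to a trajectory CSV to load instead of (or in
#'     addition to) simulation.}
#'   \item{`mixed_model`}{logical; fit [fit_mixed_model()] on the loaded or
#'     simulated agar/NHP trials and report slopes and interaction.}
#'   \item{`diffusion_match`}{`{ref_volumes, tolerance}` plus either
#'     simulated post-infusion series or `series_csv`.}
#'   \item{`seed`}{integer; seeds every stochastic stage (overridden by the
#'     `seed` argument).}
#'   \item{`out_dir`}{output directory (default `"."`).}
#' }
#'
#' @param config a named list or a path to a YAML/JSON file.
#' @param seed overrides the config seed.
#' @param out_dir overrides the config output directory.
#' @param quiet suppress stage messages.
#' @return The result bundle, invisibly; also written to
#'   `<out_dir>/results.json`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  seed <- seed %||% config$seed
  out_dir <- out_dir %||% config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(seed = seed, config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("cedphantom")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  proto <- stage("protocol", config_protocol(config$protocol))
  if (!is.null(proto)) {
    say("protocol '%s'", proto$name)
    tot <- protocol_totals(proto)
    res$protocol <- list(name = proto$name,
                         total_volume_ul = unname(tot["volume_ul"]),
                         total_time_min = unname(tot["time_min"]))
  }

  agar <- list(); nhp <- list()
  if (!is.null(config$trajectories)) {
    trials <- stage("trajectories", read_trajectories(config$trajectories))
    agar <- Filter(function(tr) tr$group[1] == "agar", trials)
    nhp <- Filter(function(tr) tr$group[1] == "nhp", trials)
    say("loaded %d agar + %d nhp trials", length(agar), length(nhp))
  }
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", do.call(make_trajectories,
                                     c(config$simulate, list(seed = seed))))
    agar <- c(agar, sim$agar); nhp <- c(nhp, sim$nhp)
    write_trajectories(c(sim$agar, sim$nhp),
                       file.path(out_dir, "simulated_trajectories.csv"))
    say("simulated %d agar + %d nhp trials", length(sim$agar), length(sim$nhp))
  }

  if (isTRUE(config$mixed_model)) {
    fit <- stage("mixed_model", fit_mixed_model(agar, nhp))
    res$mixed_model <- list(base_slope = fit$base_slope,
                            interaction = fit$interaction,
                            interaction_se = fit$interaction_se,
                            method = fit$method,
                            trial_slopes = as.list(fit$trial_slopes))
  }

  if (!is.null(config$diffusion_match)) {
    dm_cfg <- config$diffusion_match
    series <- stage("diffusion_match", {
      if (!is.null(dm_cfg$series_csv)) {
        lapply(read_trajectories(dm_cfg$series_csv), function(tr)
          data.frame(time_min = tr$time_min, volume_ul = tr$measured_uL))
      } else stop("diffusion_match needs series_csv")
    })
    dm <- stage("diffusion_match",
                match_diffusion(series, dm_cfg$ref_volumes,
                                tolerance = dm_cfg$tolerance %||% 5))
    res$diffusion_match <- list(t_star = dm$t_star, agar_mean = dm$agar_mean,
                                ref_mean = dm$ref_mean,
                                percent_error = dm$percent_error)
  }

  jsonlite::write_json(res, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
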
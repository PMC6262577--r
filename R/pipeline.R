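#' Run the stopped-flow permeability pipeline end to end
#'
#' Composes the analysis stages: baseline subtraction, per-run volume
#' calibration on the sorbitol shock, per-trace Pf fitting, and (when a
#' permeant shock is present) per-trace PGly fitting with Pf frozen at
#' the run's sorbitol estimate. Input runs are either passed in directly
#' (as produced by [generate_stopped_flow_pair()]) or generated from a
#' named scenario preset.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{runs}{List of runs, each with `sorbitol`/`glycerol` elements
#'       holding `shock` and `baseline` fluorescence traces. Optional if
#'       `scenario` is given.}
#'     \item{scenario}{Name of a preset in [load_scenarios()] used to
#'       generate `n_runs` synthetic runs when `runs` is absent.}
#'     \item{n_runs, seed, noise_sd_frac}{Generator settings for the
#'       scenario path (defaults 5, 1, 0.01).}
#'     \item{geometry, shock}{Optional overrides for [cell_geometry()]
#'       and [shock_protocol()] fields.}
#'     \item{fit_pgly}{Logical, default `TRUE`.}
#'     \item{out}{Optional path for the JSON report.}
#'   }
#' @return A report list with `pf`, `pgly` (permeability estimates),
#'   per-run values, and provenance (seed, package version, scenario).
#' @export
run_permeability_pipeline <- function(config) {
  config <- load_config(config)
  geom <- do.call(cell_geometry, config$geometry %||% list())
  shock_args <- config$shock %||% list(tonicity = 1.25,
                                       permeant_gradient = 0.35)
  shock_gly <- do.call(shock_protocol, shock_args)
  shock_sorb <- shock_protocol(shock_gly$tonicity, 0, shock_gly$temperature)

  runs <- config$runs
  if (is.null(runs)) {
    if (is.null(config$scenario)) {
      stop("config validation error [input]: need either 'runs' or 'scenario'")
    }
    sc <- load_scenarios()$stopped_flow[[config$scenario]]
    if (is.null(sc)) {
      stop("config validation error [input]: unknown scenario '",
           config$scenario, "'")
    }
    runs <- generate_stopped_flow_pair(
      geom, permeability_params(pf = sc$pf, pgly = sc$pgly), shock_gly,
      spec = generator_spec(seed = config$seed %||% 1L,
                            noise_sd_frac = config$noise_sd_frac %||% 0.01,
                            n_replicates = config$n_runs %||% 5L))
  }
  if (!length(runs)) stop("config validation error [input]: no runs")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  per_run <- lapply(runs, function(run) {
    corr_sorb <- stage("baseline", subtract_baseline(run$sorbitol$shock,
                                                     run$sorbitol$baseline))
    cal <- stage("calibration", fit_calibration(corr_sorb, shock_sorb, geom))
    v_sorb <- apply_calibration(corr_sorb, cal)
    pf_fit <- stage("pf-fit", estimate_pf(v_sorb, geom, shock_sorb))
    out <- list(pf = pf_fit$value, calibration = cal[c("a", "b")])
    if (isTRUE(config$fit_pgly %||% TRUE) && !is.null(run$glycerol)) {
      corr_gly <- stage("baseline", subtract_baseline(run$glycerol$shock,
                                                      run$glycerol$baseline))
      v_gly <- apply_calibration(corr_gly, cal)
      pgly_fit <- stage("pgly-fit",
                        estimate_pgly(v_gly, geom, shock_gly,
                                      pf_fixed = pf_fit$value))
      out$pgly <- pgly_fit$value
    }
    out
  })

  pf_values <- vapply(per_run, `[[`, numeric(1), "pf")
  report <- list(
    schema = "aqpflux/permeability-report/v1",
    pf = summarize_mean_sem(pf_values),
    per_run_pf = pf_values,
    n_runs = length(per_run),
    provenance = list(seed = config$seed %||% NA_integer_,
                      scenario = config$scenario %||% NA_character_,
                      package_version =
                        as.character(utils::packageVersion("aqpflux")))
  )
  pgly_values <- unlist(lapply(per_run, function(x) x$pgly))
  if (length(pgly_values)) {
    report$pgly <- summarize_mean_sem(pgly_values)
    report$per_run_pgly <- pgly_values
  }
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  report
}

#' Run the MD permeation pipeline end to end
#'
#' Composes crossing counting, the transport rate k_o, the single-file
#' diffusion constant, the per-simulation glycerol passage summary, and
#' (optionally) pore-profile averaging. Trajectory sets can be labelled
#' into two groups (e.g. two pH conditions); per-group means +/- SEM and
#' the unpaired t-test on total crossings are then reported.
#'
#' @param config A list (or YAML path) with fields:
#'   \describe{
#'     \item{trajectories}{List of [trajectory()] objects or CSV paths.}
#'     \item{region}{[channel_region()] or a list of its arguments.}
#'     \item{kind}{"water" or "glycerol" (default "water").}
#'     \item{z_spacing}{Single-file spacing in Angstrom; required for the
#'       diffusion constant when `kind = "water"`.}
#'     \item{groups}{Optional factor/character labels, one per
#'       trajectory.}
#'     \item{pore_profiles}{Optional list of pore-profile data frames or
#'       CSV paths to average.}
#'     \item{out}{Optional JSON report path.}
#'   }
#' @return A report list with per-simulation crossing results, `k_o`
#'   values, `d_w` (when applicable), the passage summary, and group
#'   comparisons.
#' @export
run_md_pipeline <- function(config) {
  config <- load_config(config)
  trajs <- config$trajectories
  if (!length(trajs)) {
    stop("config validation error [input]: no trajectories")
  }
  trajs <- lapply(trajs, function(tr) {
    if (is.character(tr)) read_trajectory_csv(tr) else tr
  })
  region <- config$region %||% default_channel_region()
  if (!inherits(region, "channel_region")) {
    region <- do.call(channel_region, region)
  }
  kind <- config$kind %||% "water"

  crossings <- lapply(trajs, count_crossings, region = region, kind = kind)
  totals <- vapply(crossings, `[[`, numeric(1), "total")
  k_o <- vapply(crossings, `[[`, numeric(1), "k_o")

  report <- list(
    schema = "aqpflux/md-report/v1",
    kind = kind,
    per_simulation = lapply(crossings, function(cr) {
      cr[c("total_down", "total_up", "total", "sim_length_s", "k_o")]
    }),
    passage_summary = glycerol_passage_summary(totals)
  )
  if (kind == "water" && !is.null(config$z_spacing)) {
    report$d_w <- lapply(k_o, function(k) {
      water_diffusion_constant(k, config$z_spacing)$d_w
    })
    report$d_w_summary <- summarize_mean_sem(unlist(report$d_w))
    report$z_spacing <- config$z_spacing
  }
  if (!is.null(config$groups)) {
    groups <- as.character(config$groups)
    if (length(groups) != length(trajs)) {
      stop("config validation error [groups]: one label per trajectory")
    }
    lv <- unique(groups)
    report$group_summaries <- lapply(stats::setNames(lv, lv), function(g) {
      summarize_mean_sem(totals[groups == g])
    })
    if (length(lv) == 2L &&
        all(table(groups) >= 2L)) {
      report$group_test <- two_sample_t(totals[groups == lv[1]],
                                        totals[groups == lv[2]])
    }
  }
  if (!is.null(config$pore_profiles)) {
    profiles <- lapply(config$pore_profiles, function(p) {
      if (is.character(p)) read_pore_profile_csv(p) else p
    })
    report$pore_profile <- average_pore_profile(profiles)
  }
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  report
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config validation error [input]: file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
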
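#' Default pipeline configuration
#'
#' Configuration for [run_pipeline()]: which stages to run, the seed, and
#' per-stage parameter blocks. Stages read their inputs from earlier
#' stages' outputs.
#'
#' @param stages Ordered subset of
#'   `c("simulate-data", "kinetics", "viscosity", "simulate", "fit", "probe")`.
#' @param seed Integer seed used by every stochastic stage.
#' @param params Named list of per-stage parameter blocks overriding the
#'   defaults (`simulate_data`, `kinetics`, `viscosity`, `simulate`,
#'   `fit`, `probe`).
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c(
                         "simulate-data", "kinetics", "viscosity",
                         "simulate", "probe"
                       ),
                       seed = 1L,
                       params = list()) {
  known <- c("simulate-data", "kinetics", "viscosity", "simulate", "fit", "probe")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort_bad_arg(paste0("Unknown stage(s): ", paste(bad, collapse = ", "), "."))
  }
  defaults <- list(
    simulate_data = list(n_embryos = 10, noise_sd_scale = 1),
    kinetics = list(half_window = 3, flux_window = c(21, 45)),
    viscosity = list(error_mode = "paper"),
    simulate = list(t_span = c(30, 48), dt = 0.005, puncture_t = 32, loss_fraction = 0.35),
    fit = list(free = "Omega0", dt = 0.02, n_boot = 0),
    probe = list(grid_n = 129, tip_diameters = c(5, 10, 15), t_end_min = 15)
  )
  structure(
    list(
      stages = stages,
      seed = as.integer(seed),
      params = utils::modifyList(defaults, params)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with optional keys `stages`, `seed`, `params`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    stages = y$stages %||% c("simulate-data", "kinetics", "viscosity", "simulate", "probe"),
    seed = y$seed %||% 1L,
    params = y$params %||% list()
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order — synthetic-data generation,
#' kinetic analysis, viscosity table, feedback-model simulation with a
#' puncture, model fit, probe validation — writing per-stage CSV/JSON
#' artifacts when `out_dir` is given and returning a summary list with
#' the headline quantities (mean flux, break-even time, catch-up gain,
#' viscosity table, plate coefficient, compliance margin, dilution
#' fractions).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return The summary list, invisibly when `out_dir` is given.
#' @export
#' @examples
#' \donttest{
#' summary <- run_pipeline(run_config(stages = c("simulate-data", "kinetics")))
#' summary$kinetics$flux_mean
#' }
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, obj, writer = NULL) {
    if (is.null(out_dir)) {
      return(invisible(NULL))
    }
    path <- file.path(out_dir, name)
    if (is.null(writer)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      writer(obj, path)
    }
    invisible(path)
  }

  summary <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("otomorph")),
    stages = config$stages
  )
  cohort <- NULL
  if (length(config$stages) == 0) {
    return(summary)
  }

  for (stage in config$stages) {
    if (stage == "simulate-data") {
      p <- config$params$simulate_data
      spec <- generator_spec(
        n_embryos = p$n_embryos,
        noise_sd_scale = p$noise_sd_scale, seed = config$seed
      )
      cohort <- generate_wildtype_cohort(spec)
      emit("cohort.csv", cohort, write_cohort_csv)
    } else if (stage == "kinetics") {
      if (is.null(cohort)) {
        abort_bad_arg("Stage `kinetics` needs a cohort from `simulate-data`.")
      }
      p <- config$params$kinetics
      rep <- kinetics_report(cohort,
        half_window = p$half_window,
        flux_window = p$flux_window
      )
      pairs <- lapply(1:10, function(i) {
        generate_puncture_experiment(
          generator_spec(seed = config$seed + i),
          seed = config$seed + i
        )
      })
      rep$kappa_hat <- flux_deficit_regression(pairs)$kappa_hat
      summary$kinetics <- rep
      emit("kinetics.json", rep)
    } else if (stage == "viscosity") {
      p <- config$params$viscosity
      vt <- viscosity_table(error_mode = p$error_mode)
      summary$viscosity <- vt
      emit("viscosity.csv", vt, function(obj, path) {
        utils::write.csv(obj, path, row.names = FALSE)
      })
    } else if (stage == "simulate") {
      p <- config$params$simulate
      ctrl <- simulate_vesicle(t_span = p$t_span, dt = p$dt)
      pun <- simulate_vesicle(
        t_span = p$t_span, dt = p$dt,
        events = tibble::tibble(
          t = p$puncture_t, kind = "puncture",
          params = list(list(loss_fraction = p$loss_fraction))
        )
      )
      post <- pun$t > p$puncture_t + 5 / 60
      summary$simulate <- list(
        flux_ratio_peak = max(pun$Omega[post] / ctrl$Omega[post]),
        final_deficit = (tail(ctrl$Vl, 1) - tail(pun$Vl, 1)) / tail(ctrl$Vl, 1),
        P_range = range(ctrl$P)
      )
      emit("trajectory_control.csv", ctrl, function(obj, path) {
        utils::write.csv(tibble::as_tibble(obj), path, row.names = FALSE)
      })
      emit("simulate.json", summary$simulate)
    } else if (stage == "fit") {
      p <- config$params$fit
      obs <- simulate_vesicle(t_span = c(30, 45), dt = p$dt)
      obs_sub <- obs[seq(1, nrow(obs), length.out = 31), c("t", "R")]
      fit <- fit_vesicle_parameters(obs_sub,
        free = p$free, dt = p$dt,
        n_boot = p$n_boot, seed = config$seed
      )
      summary$fit <- list(estimates = as.list(fit$estimates))
      emit("fit.json", summary$fit)
    } else if (stage == "probe") {
      p <- config$params$probe
      coef <- plate_center_coefficient(grid_n = p$grid_n)
      compliance <- sensor_compliance_check(
        plate_spec(t_mem = 5),
        grid_n = p$grid_n
      )
      dil <- lapply(p$tip_diameters, function(d) {
        sim <- dilution_simulation(
          dilution_spec(tip_inner_diameter = d),
          t_end_min = p$t_end_min
        )
        list(
          tip = d,
          frac_at_30s = stats::approx(sim$t_min, sim$conc_fraction, xout = 0.5)$y,
          t10_min = time_to_fraction(sim, 0.10)
        )
      })
      summary$probe <- list(
        plate_center_coefficient = coef,
        compliance_margin = compliance$margin,
        dilution = dil
      )
      emit("probe.json", summary$probe)
    }
  }
  emit("summary.json", summary)
  if (is.null(out_dir)) summary else invisible(summary)
}
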
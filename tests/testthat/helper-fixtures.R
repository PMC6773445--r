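# Shared fixtures, built once per test run. Sizes follow the study
# conditions (n = 10 embryos, hourly sampling 16-45 hpf).

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

default_cohort <- function() {
  fixture("default_cohort", function() {
    generate_wildtype_cohort(generator_spec(seed = 1L))
  })
}

noisefree_cohort <- function() {
  fixture("noisefree_cohort", function() {
    generate_wildtype_cohort(generator_spec(noise_sd_scale = 0, n_embryos = 1))
  })
}

puncture_pairs <- function() {
  fixture("puncture_pairs", function() {
    lapply(1:10, function(i) {
      generate_puncture_experiment(
        generator_spec(seed = 100L + i),
        t_puncture = 30, seed = 100L + i
      )
    })
  })
}

control_trajectory <- function() {
  fixture("control_trajectory", function() simulate_vesicle())
}

punctured_trajectory <- function() {
  fixture("punctured_trajectory", function() {
    simulate_vesicle(events = tibble::tibble(
      t = 32, kind = "puncture",
      params = list(list(loss_fraction = 0.35))
    ))
  })
}
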
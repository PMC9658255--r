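## Synthetic rheometer time sweeps: forward-model curves with a
## multiplicative log-normal noise model and an instrument floor, plus the
## scenario presets mirroring the experimental design grids.

#' Measurement noise model for synthetic time sweeps
#'
#' Rheometer relative error grows with signal while small readings saturate
#' at the instrument resolution; the emulation is multiplicative log-normal
#' noise with an additive-free floor:
#' `G~ = max(G exp(sigma_rel Z), floor)` with standard normal `Z`,
#' independent per channel and time point.
#'
#' @param sigma_rel relative log-normal scale (dimensionless).
#' @param floor instrument resolution floor, Pa.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma_rel = 0.05, floor = 1e-3) {
  if (sigma_rel < 0 || floor < 0) abort("noise parameters must be >= 0")
  structure(list(sigma_rel = sigma_rel, floor = floor),
            class = "noise_model")
}

#' Define a synthetic time-sweep scenario
#'
#' A scenario bundles the kinetic condition (concentration, stoichiometry,
#' rate scales), the frequencies to sweep, the sampling window and the RNG
#' seed. `C0` is derived from `seed_conc` (linear mapping) when not given
#' directly.
#'
#' @param name scenario label.
#' @param seed_conc seed weight concentration, g/100 mL.
#' @param C0 total galacturonic acid concentration, mol/L (overrides the
#'   seed mapping when supplied).
#' @param tau_Ca calcium-binding characteristic time, s.
#' @param Rmax stoichiometry ratio.
#' @param omega angular frequencies to sweep, rad/s.
#' @param t_max sweep duration, s.
#' @param dt sampling cadence, s (default one point per 10 s).
#' @param kE enzymatic rate constant, 1/s.
#' @param k1 forward binding rate constant, 1/(M^2 s).
#' @param cm0_frac initial methoxylated fraction.
#' @param rng_seed integer seed for the noise draws.
#' @param clamp_phi_product passed to the forward model.
#' @return An object of class `"gel_scenario"`.
#' @export
scenario <- function(name, seed_conc = NULL, C0 = NULL, tau_Ca, Rmax,
                     omega = 10, t_max, dt = 10, kE = 1e-4, k1 = 50,
                     cm0_frac = 0.6, rng_seed = 1,
                     clamp_phi_product = FALSE) {
  if (is.null(C0)) {
    if (is.null(seed_conc)) abort("supply `seed_conc` or `C0`")
    C0 <- seed_conc * .C0_per_seed
  }
  if (is.null(seed_conc)) seed_conc <- C0 / .C0_per_seed
  if (t_max <= 0) abort("`t_max` must be positive")
  n_points <- floor(t_max / dt) + 1
  if (n_points < 50) abort("scenario must have at least 50 samples")
  structure(list(name = name, seed_conc = seed_conc, C0 = C0,
                 tau_Ca = tau_Ca, Rmax = Rmax, omega = omega, t_max = t_max,
                 dt = dt, kE = kE, k1 = k1, cm0_frac = cm0_frac,
                 rng_seed = as.integer(rng_seed),
                 clamp_phi_product = clamp_phi_product,
                 n_points = n_points),
            class = "gel_scenario")
}

#' Kinetic parameters of a scenario
#'
#' @param sc a [scenario()] object.
#' @return A [kinetic_params()] object.
#' @export
scenario_params <- function(sc) {
  kinetic_params(kE = sc$kE, k1 = sc$k1, tau_Ca = sc$tau_Ca, C0 = sc$C0,
                 cm0_frac = sc$cm0_frac, Rmax = sc$Rmax)
}

.scenario_fields <- c("name", "seed_conc", "C0", "tau_Ca", "Rmax", "omega",
                      "t_max", "dt", "kE", "k1", "cm0_frac", "rng_seed",
                      "clamp_phi_product")

#' Serialize a scenario to a flat configuration list
#'
#' @param sc a [scenario()] object.
#' @return Named list suitable for [write_gel_config()].
#' @export
scenario_config <- function(sc) {
  cfg <- sc[.scenario_fields]
  cfg$clamp_phi_product <- as.numeric(cfg$clamp_phi_product)
  cfg
}

#' Rebuild a scenario from a configuration list
#'
#' @param config named list, e.g. from [read_gel_config()].
#' @return A [scenario()] object.
#' @export
scenario_from_config <- function(config) {
  bad <- setdiff(names(config), .scenario_fields)
  if (length(bad))
    abort(paste0("unknown scenario keys: ", paste(bad, collapse = ", ")))
  config$clamp_phi_product <- isTRUE(config$clamp_phi_product == 1)
  do.call(scenario, config)
}

#' Scenario presets mirroring the experimental design grids
#'
#' * `"fig1"`: the 2 g/100 mL natural-stoichiometry condition
#'   (`C0 = 5.22` mM, `tau_Ca = 980` s, `Rmax = 0.158`) swept at
#'   `omega = 1, 3, 10` rad/s.
#' * `"seed_series"`: the concentration series `C0 = 5.22, 6.53, 7.83,
#'   10.44, 13.05` mM with `tau_Ca = 980, 650, 460, 280, 190` s at
#'   `Rmax = 0.158`, `omega = 10` rad/s.
#' * `"rmax_series_2g"` / `"rmax_series_4g"`: the added-calcium grids
#'   `Rmax = 0.16, 0.56, 0.96, 1.36, 1.76` at 2 and 4 g/100 mL.
#'
#' Sweep windows cover roughly three gel times of each condition.
#'
#' @param name preset name.
#' @return A list of [scenario()] objects.
#' @export
preset_scenarios <- function(name = c("fig1", "seed_series",
                                      "rmax_series_2g", "rmax_series_4g")) {
  name <- match.arg(name)
  switch(name,
    fig1 = list(
      scenario("fig1", C0 = 5.22e-3, tau_Ca = 980, Rmax = 0.158,
               omega = c(1, 3, 10), t_max = 15000)),
    seed_series = {
      C0 <- c(5.22, 6.53, 7.83, 10.44, 13.05) * 1e-3
      tau <- c(980, 650, 460, 280, 190)
      tmax <- c(16000, 13000, 11000, 9000, 8000)
      purrr::pmap(list(C0, tau, tmax, seq_along(C0)), function(c0, tc, tm, i)
        scenario(paste0("seed_series_", i), C0 = c0, tau_Ca = tc,
                 Rmax = 0.158, omega = 10, t_max = tm))
    },
    rmax_series_2g = purrr::map(c(0.16, 0.56, 0.96, 1.36, 1.76), function(r)
      scenario(sprintf("rmax2g_%0.2f", r), C0 = 5.22e-3, tau_Ca = 980,
               Rmax = r, omega = 10, t_max = 15000,
               clamp_phi_product = r > 0.2)),
    rmax_series_4g = purrr::map(c(0.16, 0.56, 0.96, 1.36, 1.76), function(r)
      scenario(sprintf("rmax4g_%0.2f", r), C0 = 10.44e-3, tau_Ca = 280,
               Rmax = r, omega = 10, t_max = 9000,
               clamp_phi_product = r > 0.2))
  )
}

#' Noiseless forward profiles of a scenario
#'
#' Runs the kinetics and network model on the scenario grid, one profile
#' per frequency.
#'
#' @param sc a [scenario()] object.
#' @param network,solvent,lengths model parameter objects.
#' @return Named list of [forward_profile()] tibbles, one per `omega`.
#' @export
scenario_profiles <- function(sc, network = network_params(),
                              solvent = solvent_params(),
                              lengths = segment_lengths()) {
  params <- scenario_params(sc)
  tr <- solve_binding_ode(params, seq(0, sc$t_max, by = sc$dt))
  out <- lapply(sc$omega, function(w)
    forward_profile(tr, w, network, solvent, lengths,
                    clamp_phi_product = sc$clamp_phi_product))
  names(out) <- paste0("omega_", sc$omega)
  attr(out, "trajectory") <- tr
  out
}

#' Generate a synthetic rheometer time sweep
#'
#' Applies the noise model to the noiseless forward profiles of a scenario:
#' `G~ = max(G exp(sigma_rel Z), floor)`, independent standard-normal `Z`
#' per channel and time point, seeded for exact replay. Forward-model
#' failures (e.g. saturation of the enzyme-enhanced binding construction at
#' large `Rmax`) are reported as errors naming the scenario.
#'
#' @param sc a [scenario()] object.
#' @param noise a [noise_model()] object.
#' @param rng_seed integer seed; defaults to the scenario's.
#' @param dir optional directory: per-frequency sweep tables and a
#'   metadata sidecar (all true parameters plus the seed) are written there
#'   as delimited/structured text.
#' @param network,solvent,lengths model parameter objects.
#' @return A tibble with columns `time_s`, `omega_rad_s`, `Gp_Pa`,
#'   `Gpp_Pa`; the noiseless profiles are attached as attribute `"truth"`
#'   and the scenario as `"scenario"`.
#' @export
generate_time_sweep <- function(sc, noise = noise_model(), rng_seed = NULL,
                                dir = NULL, network = network_params(),
                                solvent = solvent_params(),
                                lengths = segment_lengths()) {
  rng_seed <- as.integer(rng_seed %||% sc$rng_seed)
  profs <- tryCatch(
    scenario_profiles(sc, network, solvent, lengths),
    error = function(e) abort(paste0("forward model failed for scenario '",
                                     sc$name, "': ", conditionMessage(e))))
  set.seed(rng_seed)
  noisy <- purrr::map2(profs, sc$omega, function(pr, w) {
    zp <- rnorm(nrow(pr)); zpp <- rnorm(nrow(pr))
    tibble(time_s = pr$time_s, omega_rad_s = w,
           Gp_Pa = pmax(pr$Gp_Pa * exp(noise$sigma_rel * zp), noise$floor),
           Gpp_Pa = pmax(pr$Gpp_Pa * exp(noise$sigma_rel * zpp), noise$floor))
  })
  out <- dplyr::bind_rows(noisy)
  attr(out, "truth") <- profs
  attr(out, "scenario") <- sc
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(sc$omega))
      write_time_sweep(noisy[[i]], file.path(dir,
        sprintf("sweep_%s_w%g.csv", sc$name, sc$omega[i])))
    meta <- c(scenario_config(sc),
              list(sigma_rel = noise$sigma_rel, floor = noise$floor,
                   applied_rng_seed = rng_seed))
    write_gel_config(meta, file.path(dir, sprintf("%s_meta.txt", sc$name)))
  }
  out
}
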
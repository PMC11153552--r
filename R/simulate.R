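#' Group specification for the synthetic plate generator
#'
#' Describes one genotype/treatment group of wells. Each well holds a
#' population (nominally ~50 animals) whose aggregate luciferase output is
#' simulated; per-well ground truth (rhythmic or not, endogenous period,
#' entrained acrophase) is recorded so every analysis stage can be validated
#' against a known answer.
#'
#' @param label Group label.
#' @param n_wells Number of wells.
#' @param period_mean_h,period_sd_h Mean and SD (hours) of the per-well
#'   endogenous free-running period; draws are clipped to the analysis band
#'   `[18, 35]` h so generator truth is always recoverable in-band.
#' @param rhythmic_fraction Probability that a well is rhythmic (wells of
#'   real recordings are only partially rhythmic, roughly 40-65%).
#' @param amplitude_rel Oscillation amplitude relative to the baseline
#'   envelope (default 0.3).
#' @param damping_per_day Exponential amplitude damping per day after release
#'   into constant conditions (default 0.15/day), mimicking population
#'   desynchronization in free run.
#' @param acrophase_zt_h Entrained peak phase in ZT hours (default 15,
#'   mid-subjective-evening peak of the reporter); each well gets uniform
#'   jitter of +/- 1 h around it.
#' @param masking_rel Relative amplitude of the additive transient in the
#'   first hour after each lights-on/lights-off transition (default 0.1);
#'   masking is a direct, clock-independent effect of the stimulus and is
#'   simulated separately from entrainment.
#' @return A `group_sim_spec` list.
#' @export
group_sim_spec <- function(label, n_wells, period_mean_h, period_sd_h = 1,
                           rhythmic_fraction = 0.6, amplitude_rel = 0.3,
                           damping_per_day = 0.15, acrophase_zt_h = 15,
                           masking_rel = 0.1) {
  stopifnot(n_wells >= 1, period_sd_h >= 0,
            rhythmic_fraction >= 0, rhythmic_fraction <= 1, amplitude_rel >= 0)
  structure(
    list(label = label, n_wells = as.integer(n_wells),
         period_mean_h = period_mean_h, period_sd_h = period_sd_h,
         rhythmic_fraction = rhythmic_fraction, amplitude_rel = amplitude_rel,
         damping_per_day = damping_per_day, acrophase_zt_h = acrophase_zt_h,
         masking_rel = masking_rel),
    class = "group_sim_spec"
  )
}

#' Configuration of a synthetic plate
#'
#' The generated signal of a well is
#' `L(t) = background + B(t) * (1 + a(t) * cos(psi(t))) + mask(t) + eps(t)`
#' where `B(t) = baseline_counts * (1 - exp(-t/accum_tau_h)) * exp(-t/decay_tau_h)`
#' is the baseline envelope (luciferase accumulation onset times slow
#' substrate/ageing decline), the oscillation is multiplicative on that
#' envelope, `psi` is phase-locked to the zeitgeber during cyclic epochs
#' (peak at the well's acrophase regardless of its endogenous period) and
#' advances at the well's endogenous period from the moment of release,
#' `a(t)` is the (damped, free-run only) relative amplitude, `mask(t)` adds a
#' short transient after each lights transition during cyclic epochs, and
#' `eps` is counting noise. Blank wells contain `background + eps` only.
#'
#' @param seed Integer seed; the output is bit-reproducible for a fixed
#'   configuration. Each well uses a substream derived deterministically from
#'   `(seed, well index)`, so adding wells never perturbs existing ones.
#' @param groups List of [group_sim_spec()] objects.
#' @param schedule A [protocol_schedule()]; default 3 days cyclic + 4 days
#'   free run.
#' @param sampling_h Sampling interval in hours (default 0.5).
#' @param baseline_counts Peak scale of the baseline envelope (default 5000
#'   counts per integration).
#' @param accum_tau_h Luciferase accumulation time constant (default 8 h).
#' @param decay_tau_h Slow decline time constant (default 120 h).
#' @param noise_model `"POISSON_LIKE"` (Gaussian with SD
#'   `noise_scale * sqrt(max(mean, 1))`, emulating photon-counting noise),
#'   `"GAUSSIAN"` (constant SD `gaussian_sd`), or `"NONE"`.
#' @param noise_scale Multiplier on the Poisson-like SD (default 1).
#' @param gaussian_sd SD in counts for the plain-Gaussian model.
#' @param background_counts Instrument + medium background level.
#' @param n_blank_wells Number of blank (background-only) wells.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, groups, schedule = standard_schedule(),
                       sampling_h = 0.5, baseline_counts = 5000,
                       accum_tau_h = 8, decay_tau_h = 120,
                       noise_model = c("POISSON_LIKE", "GAUSSIAN", "NONE"),
                       noise_scale = 1, gaussian_sd = 50,
                       background_counts = 200, n_blank_wells = 2) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(schedule, "protocol_schedule"), sampling_h > 0,
            baseline_counts > 0, accum_tau_h > 0, decay_tau_h > 0,
            n_blank_wells >= 0)
  if (inherits(groups, "group_sim_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "group_sim_spec")))
  structure(
    list(seed = as.integer(seed), groups = groups, schedule = schedule,
         sampling_h = sampling_h, baseline_counts = baseline_counts,
         accum_tau_h = accum_tau_h, decay_tau_h = decay_tau_h,
         noise_model = noise_model, noise_scale = noise_scale,
         gaussian_sd = gaussian_sd, background_counts = background_counts,
         n_blank_wells = as.integer(n_blank_wells)),
    class = "sim_config"
  )
}

#' Two-group study configuration
#'
#' A ready-made configuration emulating a control-versus-long-period-mutant
#' luminescence experiment: two groups of 30 wells, per-well period SD 1.0 h,
#' 60% rhythmic wells, 3 days of 12:12 entrainment followed by 4 days of
#' constant conditions.
#'
#' @param control_period,mutant_period Group period means in hours.
#' @param seed Integer seed.
#' @param n_wells Wells per group.
#' @param rhythmic_fraction Probability a well is rhythmic.
#' @param noise_model Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_study_config <- function(control_period = 24.4, mutant_period = 26.4,
                                 seed = 1L, n_wells = 30,
                                 rhythmic_fraction = 0.6,
                                 noise_model = "POISSON_LIKE") {
  sim_config(
    seed = seed,
    groups = list(
      group_sim_spec("control", n_wells, control_period, 1.0, rhythmic_fraction),
      group_sim_spec("mutant", n_wells, mutant_period, 1.0, rhythmic_fraction)
    ),
    schedule = standard_schedule(cyclic_days = 3, freerun_days = 4),
    noise_model = noise_model
  )
}

# Deterministic per-well substream seed (kept below 2^31).
well_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 1000003) %% 2147483629
}

#' Simulate a synthetic plate recording
#'
#' Generates one plate under a [sim_config()], returning both the recording
#' and the per-well ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `recording` (a [plate_recording()]) and
#'   `truth` (tibble: `well`, `group`, `rhythmic`, `true_period_h`,
#'   `true_acrophase_h`).
#' @examples
#' sim <- simulate_plate(default_study_config(seed = 42))
#' sim$truth
#' @export
simulate_plate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sched <- cfg$schedule
  span <- max(sched$epochs$end_h)
  t <- seq(0, span, by = cfg$sampling_h)
  B <- cfg$baseline_counts * (1 - exp(-t / cfg$accum_tau_h)) * exp(-t / cfg$decay_tau_h)
  fr <- schedule_freerun_epoch(sched)
  cyc <- schedule_cyclic_epoch(sched)
  t_release <- if (is.null(fr)) span else fr$start_h
  zt <- t - sched$zt0_recording_offset # unwrapped zeitgeber hours
  zt_period <- sched$epochs$zeitgeber_period[1L]

  in_cyclic <- rep(FALSE, length(t))
  mask_on <- rep(FALSE, length(t))
  if (!is.null(cyc)) {
    in_cyclic <- t >= cyc$start_h & t < cyc$end_h
    zt_mod <- mod_pos(zt, zt_period)
    trans <- (zt_mod >= cyc$lights_on_zt & zt_mod < cyc$lights_on_zt + 1) |
      (zt_mod >= cyc$lights_off_zt & zt_mod < cyc$lights_off_zt + 1)
    mask_on <- in_cyclic & trans
  }
  days_fr <- pmax(0, t - t_release) / 24

  noise <- function(mu, n) {
    switch(cfg$noise_model,
      POISSON_LIKE = rnorm(n, 0, cfg$noise_scale * sqrt(pmax(mu, 1))),
      GAUSSIAN = rnorm(n, 0, cfg$gaussian_sd),
      NONE = numeric(n)
    )
  }

  all_series <- list()
  truth <- list()
  meta <- list()
  idx <- 0L
  n_total <- sum(vapply(cfg$groups, `[[`, integer(1), "n_wells")) + cfg$n_blank_wells
  wid <- function(i) sprintf("W%0*d", nchar(n_total), i)

  for (g in cfg$groups) {
    for (k in seq_len(g$n_wells)) {
      idx <- idx + 1L
      set.seed(well_seed(cfg$seed, idx))
      rhythmic <- rbinom(1L, 1L, g$rhythmic_fraction) == 1L
      tau <- min(35, max(18, rnorm(1L, g$period_mean_h, g$period_sd_h)))
      phi <- g$acrophase_zt_h + runif(1L, -1, 1)
      # phase-locked to the zeitgeber while cyclic; continues at tau from release
      psi_cyc <- 2 * pi * (zt - phi) / zt_period
      psi_rel <- 2 * pi * ((t_release - sched$zt0_recording_offset) - phi) / zt_period
      psi <- ifelse(t < t_release, psi_cyc, psi_rel + 2 * pi * (t - t_release) / tau)
      amp <- g$amplitude_rel * as.numeric(rhythmic) * exp(-g$damping_per_day * days_fr)
      mu <- cfg$background_counts + B * (1 + amp * cos(psi)) +
        g$masking_rel * B * as.numeric(mask_on)
      v <- mu + noise(mu, length(t))
      w <- wid(idx)
      all_series[[idx]] <- tibble::tibble(well = w, time_h = t, value = v)
      truth[[idx]] <- tibble::tibble(
        well = w, group = g$label, rhythmic = rhythmic,
        true_period_h = tau, true_acrophase_h = mod_pos(phi, zt_period)
      )
      meta[[idx]] <- tibble::tibble(well = w, group = g$label,
                                    n_worms = 50L, is_blank = FALSE)
    }
  }
  for (k in seq_len(cfg$n_blank_wells)) {
    idx <- idx + 1L
    set.seed(well_seed(cfg$seed, idx))
    mu <- rep(cfg$background_counts, length(t))
    v <- mu + noise(mu, length(t))
    w <- wid(idx)
    all_series[[idx]] <- tibble::tibble(well = w, time_h = t, value = v)
    meta[[idx]] <- tibble::tibble(well = w, group = "blank",
                                  n_worms = 0L, is_blank = TRUE)
  }

  rec <- plate_recording(dplyr::bind_rows(all_series), sched,
                         meta = dplyr::bind_rows(meta))
  list(recording = rec, truth = dplyr::bind_rows(truth))
}

#' Read a simulation configuration from JSON
#'
#' JSON mirror of [sim_config()]: top-level scalar fields plus a `groups`
#' array of [group_sim_spec()] fields and an optional inline `schedule`
#' object (same shape as [read_schedule_json()]).
#'
#' @param path JSON file path.
#' @return A `sim_config`.
#' @export
read_sim_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$groups)) abort("Simulation config JSON must contain `groups`.")
  gdf <- tibble::as_tibble(x$groups)
  groups <- purrr::pmap(gdf, function(...) do.call(group_sim_spec, list(...)))
  sched <- if (!is.null(x$schedule)) {
    protocol_schedule(tibble::as_tibble(x$schedule$epochs),
                      zt0_recording_offset = x$schedule$zt0_recording_offset %||% 0)
  } else {
    standard_schedule()
  }
  args <- x[setdiff(names(x), c("groups", "schedule"))]
  do.call(sim_config, c(list(groups = groups, schedule = sched), args))
}
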
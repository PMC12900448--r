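#' Bundled experiment presets
#'
#' Default configurations for every experiment the package ships. Parameter
#' keys carry their unit as a suffix (e.g. `tau_pre_ms`, `a_pre_us`) so that
#' configurations cannot silently mix the millisecond/second/minute and
#' microsiemens/nanoampere/millivolt scales used across the different rules.
#'
#' @return Named list of preset configurations.
#' @export
experiment_presets <- function() {
  list(
    "stdp-single" = list(
      experiment = "stdp-single", seed = 1,
      duration_ms = 10000, rate_exc_hz = 25, rate_inh_hz = 25,
      w0_us = 1.0, tau_pre_ms = 20, tau_post_ms = 10,
      a_pre_us = 0.3, a_post_us = -0.2, w_max_us = 10,
      w_inh_us = 1.0, dt_ms = 0.1),
    "stdp-curve" = list(
      experiment = "stdp-curve", seed = 1,
      dt_min_ms = -100, dt_max_ms = 100, dt_step_ms = 5,
      w0_us = 1.0, tau_pre_ms = 20, tau_post_ms = 20,
      a_pre_us = 0.01, a_post_us = -0.0105, w_max_us = 10),
    "homeostasis" = list(
      experiment = "homeostasis", seed = 1,
      duration_ms = 60000, rate_plastic_hz = 50,
      w_init_na = 0, w_max_na = 5, dw_plus_na = 0.35, dw_minus_na = -0.35,
      w_varying_na = 3.5, trials = 1, plasticity = TRUE),
    "gb-curve" = list(
      experiment = "gb-curve", seed = 1,
      dt_grid_ms = c(-10, 10), n_pairs = 60, pair_rate_hz = 1,
      trials = 100, dt_ms = 1,
      w_star = 0.5, tc_delay_ms = 13.7, c_pre = 1, c_post = 2,
      tau_c_ms = 20, tau_w_s = 150, gamma_p = 321.808, gamma_d = 200,
      theta_p = 1.3, theta_d = 1, sigma_pl = 2.8248),
    "hetero" = list(
      experiment = "hetero", seed = 1,
      stim_duration_ms = 1000, duration_ms = 3000, stim_interval_ms = 10,
      dt_ms = 0.1, gamma_p_per_s = 90, gamma_d_per_s = 0.01,
      theta_p_umol_l = 0.11, theta_d_umol_l = 0.05,
      r_head_um = 1, l_head_um = 1, r_dendrite_um = 1, l_dendrite_um = 80,
      dl_comp_um = 1, tau_c_ms = 100, tau_i_ms = 1, gamma_ca = 0.11,
      i0_pa = 0.65, d_ca_m2_s = 2.2e-10, w_init = 0.5),
    "stc-single" = list(
      experiment = "stc-single", seed = 1,
      pre_times_ms = c(100, 500, 1000, 2000, 4000), duration_ms = 6000,
      dt_ms = 0.5, in_vivo = FALSE, noise = TRUE),
    "stc-protocols" = list(
      experiment = "stc-protocols", seed = 1,
      protocols = c("STET", "WTET", "SLFS", "WLFS"), trials = 1,
      dt_ms = 0.5, t_total_h = 8, noise = TRUE),
    "stc-network" = list(
      experiment = "stc-network", seed = 1,
      n = 200, n_exc = 160, p_conn = 0.1, assembly_size = 24,
      recall_after_ms = 2000, dt_ms = 0.5, learn = TRUE,
      w_ei_mv = 2, w_ie_mv = 4, w_ii_mv = 4),
    "morpho-network" = list(
      experiment = "morpho-network", seed = 1,
      n = 200, n_exc = 160, p_conn = 0.1, assembly_size = 24,
      recall_after_ms = 2000, dt_ms = 0.5, learn = TRUE,
      cell_size = "small", dendrites = "long",
      d_sps_m2_s = 1e-11, d_p_m2_s = 1e-11,
      w_ei_mv = 2, w_ie_mv = 4, w_ii_mv = 4),
    "busyring" = list(
      experiment = "busyring", seed = 1,
      n_cells = 8, k = 4, s = 10, t_delay_ms = 5, w_ring_us = 0.1,
      tree_depth = 1, duration_ms = 200, dt_ms = 0.025, stdp = FALSE))
}

#' Parse an experiment configuration
#'
#' Reads a YAML configuration, validates it against the bundled preset for
#' its `experiment` entry (unknown keys are rejected, with the nearest
#' valid key suggested), and fills unset keys from the preset.
#'
#' @param path path to a YAML file.
#' @return The merged configuration (class `experiment_config`).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment))
    stop("config must name an 'experiment'")
  presets <- experiment_presets()
  if (!raw$experiment %in% names(presets))
    stop("unknown experiment '", raw$experiment, "'; available: ",
         paste(names(presets), collapse = ", "))
  preset <- presets[[raw$experiment]]
  unknown <- setdiff(names(raw), names(preset))
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(preset))
      names(preset)[which.min(d)]
    }, character(1))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, hint),
               collapse = ", "))
  }
  cfg <- utils::modifyList(preset, raw)
  class(cfg) <- "experiment_config"
  cfg
}

#' Write a configuration to YAML
#'
#' @param config an `experiment_config` (or plain named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable hash of a configuration (canonicalized YAML, md5)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run a configured experiment
#'
#' Dispatches to the named experiment, writes its outputs (raster text,
#' trace CSV, summary JSON) into `outdir`, and returns a run manifest
#' (configuration hash, seed, output file list). Reruns with an equal
#' configuration produce byte-identical numeric outputs.
#'
#' @param config an `experiment_config` from [parse_config()], a preset
#'   name, or a named list with at least `experiment`.
#' @param outdir output directory (created if missing).
#' @return The manifest (class `run_manifest`), invisibly; its `summary`
#'   element holds the experiment's headline numbers.
#' @export
run_experiment <- function(config, outdir = tempfile("plastnet_run_")) {
  if (is.character(config)) {
    presets <- experiment_presets()
    if (!config %in% names(presets))
      stop("unknown experiment '", config, "'; available: ",
           paste(names(presets), collapse = ", "))
    config <- presets[[config]]
  }
  if (is.null(config$experiment)) stop("config must name an 'experiment'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  name <- config$experiment
  seed <- config$seed
  files <- character(0)
  emit_csv <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.csv(format(df, digits = 15), p, row.names = FALSE,
                     quote = FALSE)
    files <<- c(files, p)
  }
  summary <- switch(
    name,
    "stdp-single" = {
      res <- run_stdp_experiment(
        duration = config$duration_ms, rate_exc = config$rate_exc_hz,
        rate_inh = config$rate_inh_hz,
        params = stdp_params("detailed", w0 = config$w0_us,
                             tau_pre = config$tau_pre_ms,
                             tau_post = config$tau_post_ms,
                             A_pre = config$a_pre_us,
                             A_post = config$a_post_us,
                             w_max = config$w_max_us),
        w_inh = config$w_inh_us, dt = config$dt_ms, seed = seed)
      emit_csv(res$trace, "weight_trace.csv")
      list(w_end_us = res$synapse$w, n_post = length(res$t_post),
           n_pre = res$counters$n_pre)
    },
    "stdp-curve" = {
      dts <- seq(config$dt_min_ms, config$dt_max_ms, by = config$dt_step_ms)
      dts <- dts[dts != 0]
      p <- stdp_params("classic", w0 = config$w0_us,
                       tau_pre = config$tau_pre_ms,
                       tau_post = config$tau_post_ms,
                       A_pre = config$a_pre_us, A_post = config$a_post_us,
                       w_max = config$w_max_us)
      df <- data.frame(dt_ms = dts, dw_closed_us = stdp_window(dts, p),
                       dw_sim_us = stdp_window_sim(dts, p))
      emit_csv(df, "stdp_curve.csv")
      list(max_abs_diff_us = max(abs(df$dw_closed_us - df$dw_sim_us)))
    },
    "homeostasis" = {
      rates <- vapply(seq_len(config$trials), function(tr) {
        res <- run_homeostasis_experiment(
          duration = config$duration_ms,
          rate_plastic = config$rate_plastic_hz,
          params = homeo_params(w_init = config$w_init_na,
                                w_max = config$w_max_na,
                                dw_plus = config$dw_plus_na,
                                dw_minus = config$dw_minus_na,
                                w_varying = config$w_varying_na),
          plasticity = isTRUE(config$plasticity),
          stream_pre = noise_stream(seed = seed, cell = tr, mechanism = 1),
          stream_var = noise_stream(seed = seed, cell = tr, mechanism = 2))
        mean_rate_outside_silence(res)
      }, numeric(1))
      list(mean_rate_hz = mean(rates), trials = config$trials)
    },
    "gb-curve" = {
      curve <- gb_dp_curve(
        config$dt_grid_ms, n_pairs = config$n_pairs,
        pair_rate = config$pair_rate_hz, n_trials = config$trials,
        params = gb_params(w_star = config$w_star,
                           tc_delay = config$tc_delay_ms,
                           c_pre = config$c_pre, c_post = config$c_post,
                           tau_c = config$tau_c_ms,
                           tau_w = config$tau_w_s * 1000,
                           gamma_p = config$gamma_p,
                           gamma_d = config$gamma_d,
                           theta_p = config$theta_p,
                           theta_d = config$theta_d,
                           sigma_pl = config$sigma_pl),
        seed = seed, dt = config$dt_ms)
      emit_csv(curve, "gb_curve.csv")
      as.list(stats::setNames(curve$mean_dw,
                              paste0("mean_dw_at_", curve$dt, "ms")))
    },
    "hetero" = {
      res <- run_hetero_experiment(
        params = hetero_params(
          gamma_p = config$gamma_p_per_s, gamma_d = config$gamma_d_per_s,
          theta_p = config$theta_p_umol_l, theta_d = config$theta_d_umol_l,
          r_head = config$r_head_um, l_head = config$l_head_um,
          r_dendrite = config$r_dendrite_um,
          l_dendrite = config$l_dendrite_um, dl = config$dl_comp_um,
          tau_c = config$tau_c_ms, tau_i = config$tau_i_ms,
          gamma_ca = config$gamma_ca, i0 = config$i0_pa,
          d_ca = config$d_ca_m2_s, w_init = config$w_init),
        stim_duration = config$stim_duration_ms,
        duration = config$duration_ms,
        stim_interval = config$stim_interval_ms, dt = config$dt_ms)
      emit_csv(data.frame(t = res$time, w = res$w, conc = res$conc),
               "hetero_traces.csv")
      list(w_end = as.list(stats::setNames(res$w_end,
                                           paste0("spine", 1:4))),
           balance_residual = res$balance_residual)
    },
    "stc-single" = {
      res <- stc_single_run(config$pre_times_ms, config$duration_ms,
                            seed = seed,
                            params = stc_params(in_vivo = config$in_vivo),
                            dt = config$dt_ms, noise = config$noise)
      emit_csv(res$trace, "stc_trace.csv")
      list(h_end_mv = res$state[1], z_end = res$state[2],
           c_end = res$state[3], p_end_umol_l = res$state[4])
    },
    "stc-protocols" = {
      out <- lapply(config$protocols, function(pn) {
        r <- stc_protocol(pn, seed = seed, dt = config$dt_ms,
                          t_total = config$t_total_h * 3600e3,
                          noise = config$noise)
        list(protocol = pn, h_end_mv = r$h_end, z_end = r$z_end,
             crossed_tag = r$crossed_tag, crossed_pro = r$crossed_pro)
      })
      names(out) <- config$protocols
      out
    },
    "stc-network" = ,
    "morpho-network" = {
      variant <- if (name == "morpho-network")
        morpho_cell_spec(config$cell_size, config$dendrites) else NULL
      rec <- network_recipe(n = config$n, n_exc = config$n_exc,
                            p_conn = config$p_conn, seed = seed,
                            dt = config$dt_ms, w_ei = config$w_ei_mv,
                            w_ie = config$w_ie_mv, w_ii = config$w_ii_mv,
                            variant = variant)
      res <- recall_experiment(rec, assembly_size = config$assembly_size,
                               recall_after = config$recall_after_ms,
                               learn = isTRUE(config$learn))
      rp <- file.path(outdir, "raster.txt")
      write_raster(res$raster$t, res$raster$gid, rp, seed = seed,
                   config_hash = .config_hash(config))
      files <- c(files, rp)
      list(Q = res$Q, rates_hz = as.list(res$rates))
    },
    "busyring" = {
      net <- busyring_build(n_cells = config$n_cells, k = config$k,
                            s = config$s, t_delay = config$t_delay_ms,
                            w_ring = config$w_ring_us,
                            tree_depth = config$tree_depth, seed = seed,
                            stdp = if (isTRUE(config$stdp))
                              stdp_params("classic") else NULL)
      res <- busyring_run(net, t_end = config$duration_ms,
                          dt = config$dt_ms)
      rp <- file.path(outdir, "raster.txt")
      write_raster(res$raster$t, res$raster$gid, rp, seed = seed,
                   config_hash = .config_hash(config))
      files <- c(files, rp)
      list(n_spikes = length(res$raster$t),
           rate_hz = length(res$raster$t) / config$n_cells /
             (config$duration_ms / 1000),
           expected_rate_hz = 1000 / (config$k * config$t_delay_ms),
           n_delivered = res$n_delivered)
    },
    stop("unknown experiment '", name, "'; available: ",
         paste(names(experiment_presets()), collapse = ", ")))
  sp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sp)
  manifest <- structure(
    list(experiment = name, config_hash = .config_hash(config),
         seed = seed, started = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("plastnet")),
         files = files, summary = summary),
    class = "run_manifest")
  jsonlite::write_json(manifest[setdiff(names(manifest), "summary")],
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Mean output rate outside the silent stage
#'
#' Helper for the homeostasis experiment: the time-averaged postsynaptic
#' rate over all schedule stages with non-zero input rate.
#'
#' @param res a [run_homeostasis_experiment()] result.
#' @return Rate in Hz.
#' @export
mean_rate_outside_silence <- function(res) {
  sched <- res$schedule
  act <- sched[sched$rate > 0, ]
  tot <- 0
  n <- 0
  for (k in seq_len(nrow(act))) {
    t1 <- min(act$t1[k], res$duration)
    if (t1 <= act$t0[k]) next
    tot <- tot + sum(res$t_post >= act$t0[k] & res$t_post < t1)
    n <- n + (t1 - act$t0[k])
  }
  tot / n * 1000
}
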
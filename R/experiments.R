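#' List the named experiments
#'
#' @return Data frame with experiment ids and descriptions.
#' @export
list_experiments <- function() {
  data.frame(
    id = paste0("E", 1:6),
    description = c(
      "Impedance magnitude sweep over clamp levels, with and without gNa",
      "Markov fluctuation PSD vs analytic spectrum, both models, 5/55 mV, with/without stimulus",
      "QSA linear coefficients, Q matrix and single-trial spectra, both models, 5/55 mV",
      "Five-curve normalized overlay: S_IK, S_L, S_D, S_R, |Ym|^2",
      "Averaged QSA power of Markov noise vs deterministic ODE at stimulus amplitudes 1 and 4 mV",
      "Membrane-area sweep of the averaged QSA Markov noise power at 1 mV"))
}

exp_default_config <- function(id) {
  base <- list(dt_ms = 0.01, params = NULL, A = 0.35, B = 4,
               rho_K = 18, area_um2 = 500)
  extra <- switch(id,
    E1 = list(V0 = c(-5, 0, 5, 10.2, 15.2, 25.2),
              f_Hz = 10^seq(-0.5, 3.5, length.out = 161)),
    E2 = list(models = c("n4", "p2"), V0 = c(5, 55), iterations = 128,
              duration_ms = 1000, amplitude_mV = 0.25, with_stimulus = TRUE),
    E3 = list(models = c("n4", "p2"), V0 = c(5, 55), amplitude_mV = 0.25,
              skip_ms = 100),
    E4 = list(models = c("n4", "p2"), V0 = c(5, 55), amplitude_mV = 0.25,
              n_trials = 128, n_freq = 21, skip_ms = 100,
              f_Hz = 10^seq(0, 3.3, length.out = 121)),
    E5 = list(model = "p2", V0 = 55, amplitudes_mV = c(1, 4),
              iterations = 16, skip_ms = 100),
    E6 = list(model = "p2", V0 = 55, amplitude_mV = 1,
              areas_um2 = c(50, 500, 5000, 50000), iterations = 16,
              skip_ms = 100),
    stop("unknown experiment id: ", id))
  c(base, extra)
}

merge_config <- function(default, config) {
  unknown <- setdiff(names(config), names(default))
  if (length(unknown))
    stop("invalid config fields for this experiment: ",
         paste(unknown, collapse = ", "))
  default[names(config)] <- config
  default
}

write_table <- function(df, out_dir, name, files) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(as.data.frame(df), path, row.names = FALSE)
  c(files, path)
}

# deterministic QSA run of one model: returns list(spec, response, result)
ode_qsa_run <- function(model, V0, spec, dt_ms, skip_ms, params, A, B,
                        area_um2 = NULL) {
  dur <- skip_ms + spec$period_s * 1000
  x <- synthesize_multisine(spec, dt_ms, dur, derivative = TRUE)
  tr <- integrate_voltage_clamp(model, V0 + x, dt_ms, params, A, B,
                                dVdt = attr(x, "dxdt"))
  resp <- if (is.null(area_um2)) tr$I_total
          else deterministic_potassium_current(tr, area_um2)
  base <- if (is.null(area_um2)) {
    ss0 <- integrate_voltage_clamp(model, rep(V0, 2), dt_ms, params, A, B)
    ss0$I_total[1] - ss0$Icap[1]
  } else {
    open <- if (model == "p2") p2_steady_state(V0, A, B)$p2_inf
            else hh_gate_rates(V0, "n")$x_inf^4
    params$gK * open * (V0 - params$VK) * area_um2 * 1e-2
  }
  list(spec = spec, response = resp,
       result = estimate_qsa(spec, resp, dt_ms, skip_ms, baseline = base))
}

# averaged |Q|^2 of Markov iterations plus the matching deterministic |Q|^2
markov_qsa_pair <- function(V0, amplitude_mV, population, iterations, seed,
                            dt_ms, skip_ms, params, A, B, model = "p2") {
  spec <- stimulus_spec(canonical_multipliers(), amplitude_mV = amplitude_mV,
                        seed = seed)
  dur <- skip_ms + spec$period_s * 1000
  x <- synthesize_multisine(spec, dt_ms, dur)
  base <- {
    open <- if (model == "p2") p2_steady_state(V0, A, B)$p2_inf
            else hh_gate_rates(V0, "n")$x_inf^4
    population$N_K * population$gamma_pS * open * (V0 - population$V_K) * 1e-3
  }
  responses <- lapply(seq_len(iterations), function(it) {
    tr <- simulate_markov(model, V0 + x, dt_ms, population,
                          seed = seed + it, A = A, B = B)
    fluctuating_current(tr, V0 + x, population)
  })
  avg <- qsa_markov_noise_power(spec, responses, dt_ms, skip_ms,
                                baseline = base)
  det <- ode_qsa_run(model, V0, spec, dt_ms, skip_ms, params, A, B,
                     area_um2 = population$area_um2)
  detQ2 <- abs(det$result$Q)^2
  list(spec = spec, avg_Q2 = avg, det_Q2 = detQ2,
       deviation = qsa_matrix_deviation(avg, detQ2))
}

q2_long <- function(M, nsig) {
  data.frame(i = rep(nsig, times = length(nsig)),
             j = rep(nsig, each = length(nsig)),
             f_out_Hz = as.vector(outer(nsig, nsig, function(a, b) b - a)),
             power = as.vector(M))
}

#' Run a named experiment
#'
#' Executes one of the registered frequency-domain experiments (see
#' [list_experiments()]) and writes its numeric tables as CSV together with
#' a JSON manifest (resolved configuration, seed, file checksums) that makes
#' the run bit-exact reproducible.
#'
#' @param id experiment id, `"E1"`..`"E6"`
#' @param config named list overriding the experiment defaults; unknown
#'   fields are rejected
#' @param seed integer seed for every stochastic component
#' @param out_dir output directory (created if needed)
#' @return Invisibly, a list with the resolved config and the summary
#'   object of the experiment.
#' @export
run_experiment <- function(id, config = list(), seed = 1,
                           out_dir = tempfile("experiment")) {
  cfg <- merge_config(exp_default_config(id), config)
  if (is.null(cfg$params)) cfg$params <- hh_parameters()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  message(sprintf("[%s] seed %d -> %s", id, seed, out_dir))
  summary <- NULL

  if (id == "E1") {
    p0 <- cfg$params
    pK <- hh_parameters(p0$Cm, p0$gL, p0$VL, p0$gK, p0$VK, 0, p0$VNa)
    for (tag in c("full", "gK_only")) {
      pp <- if (tag == "full") p0 else pK
      tab <- do.call(rbind, lapply(cfg$V0, function(v) {
        lr <- hh_admittance(v, cfg$f_Hz, pp)
        cbind(V0 = v, as.data.frame(lr))
      }))
      files <- write_table(tab, out_dir, paste0("impedance_", tag), files)
    }
    summary <- list(V0 = cfg$V0)
  } else if (id == "E2") {
    pop <- channel_population(cfg$rho_K, cfg$area_um2, cfg$params)
    rows <- list()
    for (model in cfg$models) for (v in cfg$V0)
      for (stim_on in unique(c(FALSE, cfg$with_stimulus))) {
        stim <- if (stim_on)
          stimulus_spec(canonical_multipliers(),
                        amplitude_mV = cfg$amplitude_mV, seed = seed)
        emp <- markov_psd(model, v, pop, cfg$duration_ms, cfg$dt_ms,
                          cfg$iterations, seed = seed, stimulus = stim,
                          A = cfg$A, B = cfg$B)
        ana <- if (model == "n4") n4_psd(emp$f_Hz, v, pop)
               else p2_psd(emp$f_Hz, v, pop, cfg$A, cfg$B)
        tag <- sprintf("%s_V%g_%s", model, v,
                       if (stim_on) "stim" else "nostim")
        files <- write_table(
          data.frame(f_Hz = emp$f_Hz, psd_empirical = emp$psd,
                     psd_analytic = ana$S_total),
          out_dir, paste0("psd_", tag), files)
        ex <- if (stim_on) {
          m <- canonical_multipliers()
          c(m, second_order_combinations(m)$value) / 1
        }
        cmp <- psd_bin_compare(emp, ana, exclude_f = ex)
        rows[[tag]] <- data.frame(condition = tag,
          max_abs_dlog10 = attr(cmp, "max_abs_dlog10"))
      }
    summary <- do.call(rbind, rows)
    files <- write_table(summary, out_dir, "psd_discrepancy", files)
  } else if (id == "E3") {
    for (model in cfg$models) for (v in cfg$V0) {
      spec <- stimulus_spec(canonical_multipliers(),
                            amplitude_mV = cfg$amplitude_mV, seed = seed)
      run <- ode_qsa_run(model, v, spec, cfg$dt_ms, cfg$skip_ms,
                         cfg$params, cfg$A, cfg$B)
      res <- run$result
      tag <- sprintf("%s_V%g", model, v)
      N <- length(res$multipliers)
      files <- write_table(
        data.frame(f_Hz = res$multipliers / spec$period_s,
                   Re_l = Re(res$L[(N + 1):(2 * N)]),
                   Im_l = Im(res$L[(N + 1):(2 * N)])),
        out_dir, paste0("qsa_L_", tag), files)
      ql <- q2_long(abs(res$Q)^2, res$n_signed)
      ql$Re_Q <- as.vector(Re(res$Q)); ql$Im_Q <- as.vector(Im(res$Q))
      files <- write_table(ql, out_dir, paste0("qsa_Q_", tag), files)
      sp <- single_trial_spectra(spec, run$response, cfg$dt_ms, cfg$skip_ms,
                                 include_column_power = TRUE)
      files <- write_table(do.call(rbind, lapply(sp, as.data.frame)),
                           out_dir, paste0("qsa_spectra_", tag), files)
    }
    summary <- list(models = cfg$models, V0 = cfg$V0)
  } else if (id == "E4") {
    pop <- channel_population(cfg$rho_K, cfg$area_um2, cfg$params)
    rows <- list()
    for (model in cfg$models) for (v in cfg$V0) {
      trials <- lapply(seq_len(cfg$n_trials), function(m) {
        mult <- generate_nonoverlapping_set(cfg$n_freq, c(1, 1000),
                                            seed = seed + 1000 * m)
        spec <- stimulus_spec(mult, amplitude_mV = cfg$amplitude_mV,
                              seed = seed + 1000 * m + 1)
        run <- ode_qsa_run(model, v, spec, cfg$dt_ms, cfg$skip_ms,
                           cfg$params, cfg$A, cfg$B,
                           area_um2 = cfg$area_um2)
        single_trial_spectra(spec, run$response, cfg$dt_ms, cfg$skip_ms,
                             include_column_power = TRUE)
      })
      avg <- accumulate_spectra(trials)
      ana <- if (model == "n4") n4_psd(cfg$f_Hz, v, pop)
             else p2_psd(cfg$f_Hz, v, pop, cfg$A, cfg$B)
      ym <- modified_admittance(v, cfg$f_Hz, if (model == "n4") "n4" else "p2",
                                cfg$params, cfg$A, cfg$B)
      curves <- list(S_IK = data.frame(f_Hz = ana$f_Hz, power = ana$S_total),
                     S_L = as.data.frame(avg$S_L),
                     S_D = as.data.frame(avg$S_D),
                     S_R = as.data.frame(avg$S_R),
                     Ym2 = data.frame(f_Hz = ym$f_Hz, power = ym$abs_Ym2))
      ov <- compare_overlay(curves, "unity_lowest")
      tag <- sprintf("%s_V%g", model, v)
      files <- write_table(ov, out_dir, paste0("overlay_", tag), files)
      rows[[tag]] <- cbind(condition = tag,
                           curve = rownames(attr(ov, "discrepancy")),
                           as.data.frame(attr(ov, "discrepancy")))
    }
    summary <- do.call(rbind, rows)
    files <- write_table(summary, out_dir, "overlay_discrepancy", files)
  } else if (id == "E5") {
    pop <- channel_population(cfg$rho_K, cfg$area_um2, cfg$params)
    rows <- list()
    for (amp in cfg$amplitudes_mV) {
      pr <- markov_qsa_pair(cfg$V0, amp, pop, cfg$iterations, seed,
                            cfg$dt_ms, cfg$skip_ms, cfg$params,
                            cfg$A, cfg$B, cfg$model)
      nsig <- attr(pr$avg_Q2, "n_signed")
      tag <- sprintf("amp%g", amp)
      files <- write_table(q2_long(pr$avg_Q2, nsig), out_dir,
                           paste0("qsa_markov_Q2_", tag), files)
      nod <- pr$avg_Q2; nod[outer(nsig, nsig, "+") == 0] <- 0
      files <- write_table(q2_long(nod, nsig), out_dir,
                           paste0("qsa_markov_Q2_nodiag_", tag), files)
      files <- write_table(q2_long(pr$det_Q2, nsig), out_dir,
                           paste0("qsa_ode_Q2_", tag), files)
      rows[[tag]] <- data.frame(amplitude_mV = amp, deviation = pr$deviation)
    }
    summary <- do.call(rbind, rows)
    files <- write_table(summary, out_dir, "qsa_markov_deviation", files)
  } else if (id == "E6") {
    rows <- list()
    for (area in cfg$areas_um2) {
      pop <- channel_population(cfg$rho_K, area, cfg$params)
      pr <- markov_qsa_pair(cfg$V0, cfg$amplitude_mV, pop, cfg$iterations,
                            seed, cfg$dt_ms, cfg$skip_ms, cfg$params,
                            cfg$A, cfg$B, cfg$model)
      tag <- sprintf("area%g", area)
      files <- write_table(q2_long(pr$avg_Q2, attr(pr$avg_Q2, "n_signed")),
                           out_dir, paste0("qsa_markov_Q2_", tag), files)
      rows[[tag]] <- data.frame(area_um2 = area, N_K = pop$N_K,
                                deviation = pr$deviation)
    }
    summary <- do.call(rbind, rows)
    files <- write_table(summary, out_dir, "area_sweep_deviation", files)
  }

  cfg_out <- cfg
  cfg_out$params <- unclass(cfg$params)
  manifest <- list(experiment = id, seed = seed, config = cfg_out,
                   package_version = as.character(utils::packageVersion("channelspectra")),
                   files = lapply(sort(unique(basename(files))), function(f)
                     list(name = f,
                          md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, summary = summary, out_dir = out_dir,
                 files = files))
}
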
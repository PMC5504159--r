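#' Benchmark scenarios
#'
#' A scenario bundles everything needed to replay a full joint-NUS
#' relaxation experiment: geometry, fixture parameters (peak count, SNR,
#' seed), schedule size, solver configuration and the sampling-level
#' sweep.  SNR is defined as the median peak amplitude divided by the
#' per-component noise standard deviation — i.e. signal strength of a
#' typical peak at the very first sample `(t1 = 0, smallest delay)`,
#' before any decay.
#'
#' @param name Scenario name.
#' @param geometry An [acquisition_geometry()].
#' @param n_peaks Number of fixture peaks.
#' @param snr Signal-to-noise ratio as defined above; `Inf` for noiseless.
#' @param seed Master integer seed; fixture, noise and subsampling seeds
#'   are derived from it by fixed offsets.
#' @param n_schedule Joint schedule size.
#' @param config A [solver_config()].
#' @param sweep_levels Sampling levels for the sweep (possibly empty).
#' @param n_sweep_seeds Number of subsampling seeds per sweep level.
#' @param peaks_per_column Number of peaks sharing each direct-dimension
#'   column.  The joint inversion runs independently per direct column
#'   (after the direct dimension has been Fourier processed), so this
#'   controls how many resonances each single inversion must resolve; in
#'   a protein HSQC most amide 1H positions carry one or two 15N
#'   partners.  Default 2.
#' @param normalize_laplace Reconstruct with unit-norm Laplace columns
#'   (see [joint_operator()]); default `TRUE` for scenarios, where the
#'   quantity of interest is the read-off rate and the shrinkage bias
#'   against fast-decaying components matters most.
#' @param sweep_config Optional separate [solver_config()] for the
#'   sampling-level sweep (which runs many reconstructions and can use a
#'   lighter iteration budget than the headline reconstruction); `NULL`
#'   reuses `config`.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, geometry, n_peaks, snr, seed, n_schedule,
                     config = solver_config(), sweep_levels = integer(),
                     n_sweep_seeds = 5L, peaks_per_column = 2L,
                     normalize_laplace = TRUE, sweep_config = NULL) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            inherits(config, "solver_config"),
            n_peaks >= 1, snr > 0, n_schedule >= 1, peaks_per_column >= 1)
  structure(list(name = name, geometry = geometry, n_peaks = as.integer(n_peaks),
                 snr = snr, seed = as.integer(seed),
                 n_schedule = as.integer(n_schedule), config = config,
                 sweep_levels = as.integer(sweep_levels),
                 n_sweep_seeds = as.integer(n_sweep_seeds),
                 peaks_per_column = as.integer(peaks_per_column),
                 normalize_laplace = isTRUE(normalize_laplace),
                 sweep_config = sweep_config),
            class = "scenario")
}

#' The reference protein-relaxometry scenario
#'
#' The conditions of a typical 15N T1 HSQC joint-NUS experiment on a
#' small globular protein: a 128-point t1 grid over a 3000 Hz indirect
#' width, relaxation delays 0.01-0.8 s on a 0.01 s mesh (80 candidate
#' delays), a 256-point joint schedule (2.5% of the 10240-cell joint
#' grid), a 256 x 256 reconstruction grid with the decay-rate band
#' 0.5-5 1/s, and 500 FISTA iterations.
#'
#' @param n_peaks Number of fixture peaks (default 20).
#' @param snr Signal-to-noise ratio (default 50).
#' @param seed Master seed (default 1).
#' @param n_recon Reconstruction grid size for both the frequency and the
#'   rate axis (default 256; 128 gives a scaled-down variant that runs
#'   several times faster at halved rate resolution).
#' @return A [scenario()].
#' @export
reference_scenario <- function(n_peaks = 20, snr = 50, seed = 1L,
                                n_recon = 256) {
  geo <- acquisition_geometry(n_t1 = 128, sw_indirect = 3000,
                              trelax_min = 0.01, trelax_max = 0.8,
                              trelax_mesh = 0.01,
                              n_f1_recon = n_recon, n_r_recon = n_recon,
                              r_min = 0.5, r_max = 5)
  scenario(name = "protein-T1-joint-NUS",
           geometry = geo, n_peaks = n_peaks, snr = snr, seed = seed,
           n_schedule = 256,
           config = solver_config(tau = 0.002, tau_mode = "relative",
                                  n_iter = 4000),
           sweep_levels = seq(128L, 256L, by = 16L),
           n_sweep_seeds = 5L,
           normalize_laplace = TRUE,
           sweep_config = solver_config(tau = 0.002, tau_mode = "relative",
                                        n_iter = 2500, n_power_iter = 30))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed seed-derivation offsets so every stage is independently replayable
scenario_seeds <- function(sc) {
  base <- sc$seed %% 100000L
  list(fixture = base + 11L, schedule = base + 23L, noise = base + 37L,
       sweep = base + 101L + seq_len(max(sc$n_sweep_seeds, 1L)) - 1L)
}

#' Run a scenario end to end
#'
#' Executes the full benchmark chain: simulate the fixture, generate the
#' joint schedule, reconstruct the cube, process the conventional
#' fully-sampled baseline, read off rates by both methods, correlate
#' them, and (when sweep levels are configured) run the sampling-level
#' sweep.  Deterministic given the scenario's seed.
#'
#' @param sc A [scenario()].
#' @param run_sweep Run the sampling-level sweep (default TRUE when the
#'   scenario has sweep levels).
#' @param out_dir Optional directory; when given, the rate tables, the
#'   r²-vs-level table, the convergence trace and a plain-text summary
#'   are written there as TSV/text.
#' @param record_objective Record the solver objective trace of the
#'   headline reconstruction (default TRUE; turning it off saves one
#'   operator application per iteration and empties the trace report).
#' @return List of class `"scenario_report"`: `peaks`, `schedule`,
#'   `cube`, `rates_joint`, `rates_baseline`, `truth_r2` (joint vs
#'   simulated truth), `cross_r2` (joint vs mono-exponential baseline),
#'   `within_one_bin` (count of unflagged peaks whose joint rate is
#'   within one rate-grid spacing of truth), `sweep` (or NULL).
#' @export
run_scenario <- function(sc, run_sweep = length(sc$sweep_levels) > 0,
                         out_dir = NULL, record_objective = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  seeds <- scenario_seeds(sc)
  geo <- sc$geometry
  peaks <- protein_fixture(sc$n_peaks, geo, seed = seeds$fixture)
  sigma <- if (is.finite(sc$snr)) stats::median(peaks$amplitude) / sc$snr else 0
  sched <- generate_schedule(geo, sc$n_schedule, seed = seeds$schedule)
  # the joint inversion runs per direct-dimension column; tile the fixture
  # peaks over columns the way amides spread over the 1H axis
  column <- (seq_len(nrow(peaks)) - 1L) %/% sc$peaks_per_column + 1L
  n_cols <- max(column)
  fid <- lapply(seq_len(n_cols), function(cc)
    simulate_joint_fid(peaks[column == cc, , drop = FALSE], geo, sched,
                       noise = noise_model(sigma, seeds$noise + cc)))
  cube <- reconstruct_cube(fid, sched, geo, sc$config,
                           normalize_laplace = sc$normalize_laplace,
                           record_objective = record_objective)
  plist <- data.frame(id = seq_len(nrow(peaks)), freq_hz = peaks$freq_hz,
                      column = column)
  rates_joint <- rates_from_cube(cube, plist)
  rates_base <- vector("list", n_cols)
  for (cc in seq_len(n_cols)) {
    series <- simulate_full_series(peaks[column == cc, , drop = FALSE], geo,
                                   noise = noise_model(sigma,
                                                       seeds$noise + 1000L + cc))
    proc <- conventional_process(series, geo)
    rates_base[[cc]] <- rates_from_series(proc,
                                          plist[column == cc, , drop = FALSE])
  }
  rates_base <- do.call(rbind, rates_base)
  class(rates_base) <- c("rate_estimate", "data.frame")
  truth <- data.frame(id = plist$id, rate_hz = peaks$rate_hz)
  truth_cor <- correlate_rates(rates_joint, truth)
  cross_cor <- correlate_rates(rates_joint, rates_base)
  dr <- diff(rate_grid(geo)[1:2])
  dev <- abs(rates_joint$rate_hz - peaks$rate_hz)
  within <- sum(dev <= dr & !rates_joint$edge_flag & !rates_joint$no_peak,
                na.rm = TRUE)
  sweep <- NULL
  if (run_sweep) {
    sweep <- sampling_level_sweep(fid, sched, geo, plist,
                                  baseline_rates = rates_base$rate_hz,
                                  levels = sc$sweep_levels,
                                  seeds = seeds$sweep,
                                  config = sc$sweep_config %||% sc$config,
                                  normalize_laplace = sc$normalize_laplace)
  }
  rep <- structure(list(scenario = sc, peaks = peaks, schedule = sched,
                        cube = cube, rates_joint = rates_joint,
                        rates_baseline = rates_base,
                        truth_r2 = truth_cor$r2, cross_r2 = cross_cor$r2,
                        within_one_bin = within, rate_spacing = dr,
                        sweep = sweep, sigma = sigma),
                   class = "scenario_report")
  if (!is.null(out_dir)) write_scenario_report(rep, out_dir)
  rep
}

write_scenario_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_rate_table(rep$rates_joint, file.path(out_dir, "rates_joint.tsv"))
  write_rate_table(rep$rates_baseline, file.path(out_dir, "rates_baseline.tsv"))
  tr <- attr(rep$cube, "solver_info")[[1]]$objective_trace
  utils::write.table(data.frame(iteration = seq_along(tr), objective = tr),
                     file.path(out_dir, "convergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rep$sweep))
    utils::write.table(rep$sweep, file.path(out_dir, "sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(print(rep)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.scenario_report <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Scenario '%s': %d peaks, SNR %s, %d-point schedule, seed %d\n",
              sc$name, sc$n_peaks, format(sc$snr), sc$n_schedule, sc$seed))
  cat(sprintf("  noise sigma (median amplitude / SNR): %.4g\n", x$sigma))
  cat(sprintf("  joint vs truth r^2:      %.5f\n", x$truth_r2))
  cat(sprintf("  joint vs baseline r^2:   %.5f\n", x$cross_r2))
  cat(sprintf("  peaks within one rate bin (%.4g 1/s) of truth: %d / %d\n",
              x$rate_spacing, x$within_one_bin, sc$n_peaks))
  if (!is.null(x$sweep)) {
    med <- attr(x$sweep, "median_r2")
    cat("  sampling-level sweep (median r^2 vs baseline):\n")
    for (i in seq_len(nrow(med)))
      cat(sprintf("    %4d points: %.5f\n", med$level[i], med$r2[i]))
  }
  invisible(x)
}

#' Write or read a scenario as a flat config file
#'
#' Plain `key = value` text, one entry per line, `#` comments allowed.
#' A scenario is fully determined by its serialized form.
#'
#' @param sc A [scenario()].
#' @param path File path.
#' @return `read_scenario()` returns a [scenario()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  g <- sc$geometry; cf <- sc$config
  kv <- c(name = sc$name,
          n_t1 = g$n_t1, sw_indirect = g$sw_indirect,
          trelax_min = g$trelax_min, trelax_max = g$trelax_max,
          trelax_mesh = g$trelax_mesh,
          n_f1_recon = g$n_f1_recon, n_r_recon = g$n_r_recon,
          r_min = g$r_min, r_max = g$r_max,
          n_peaks = sc$n_peaks, snr = sc$snr, seed = sc$seed,
          n_schedule = sc$n_schedule,
          tau = cf$tau, tau_mode = cf$tau_mode, n_iter = cf$n_iter,
          sweep_levels = paste(sc$sweep_levels, collapse = ","),
          n_sweep_seeds = sc$n_sweep_seeds,
          peaks_per_column = sc$peaks_per_column,
          normalize_laplace = sc$normalize_laplace,
          sweep_n_iter = if (is.null(sc$sweep_config)) ""
                         else sc$sweep_config$n_iter)
  writeLines(c("# nusrelax scenario", sprintf("%s = %s", names(kv), kv)), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  parts <- regmatches(raw, regexec("^\\s*([^=[:space:]]+)\\s*=\\s*(.*)$", raw))
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop(sprintf("malformed scenario line: '%s'", raw[bad[1]]))
  kv <- stats::setNames(trimws(vapply(parts, `[[`, "", 3)),
                        vapply(parts, `[[`, "", 2))
  num <- function(k) as.numeric(kv[[k]])
  geo <- acquisition_geometry(num("n_t1"), num("sw_indirect"),
                              num("trelax_min"), num("trelax_max"),
                              num("trelax_mesh"),
                              num("n_f1_recon"), num("n_r_recon"),
                              num("r_min"), num("r_max"))
  lv <- if (nzchar(kv[["sweep_levels"]]))
    as.integer(strsplit(kv[["sweep_levels"]], ",")[[1]]) else integer()
  scenario(name = kv[["name"]], geometry = geo,
           n_peaks = num("n_peaks"), snr = num("snr"), seed = num("seed"),
           n_schedule = num("n_schedule"),
           config = solver_config(tau = num("tau"),
                                  tau_mode = kv[["tau_mode"]],
                                  n_iter = num("n_iter")),
           sweep_levels = lv, n_sweep_seeds = num("n_sweep_seeds"),
           peaks_per_column = num("peaks_per_column"),
           normalize_laplace = identical(kv[["normalize_laplace"]], "TRUE"),
           sweep_config = if (nzchar(kv[["sweep_n_iter"]]))
             solver_config(tau = num("tau"), tau_mode = kv[["tau_mode"]],
                           n_iter = num("sweep_n_iter")) else NULL)
}
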
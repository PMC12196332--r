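# End-to-end analysis driver: WT-MTD -> gradient unbiasing -> subsets ->
# GPR hyperparameter sweep, alongside the umbrella-sampling/WHAM reference,
# with all artifacts written as text files.

#' Default pipeline configuration
#'
#' The study conditions of the full analysis: a 50 ns-equivalent
#' well-tempered metadynamics run (2.5e7 steps at dt = 2 fs; gamma = 20,
#' omega0 = 0.8 kJ/mol, sigma_G = 0.01 nm, one hill per ps) recorded every
#' 1000 steps into 25,000 gradient points; five random 5000-point training
#' subsets; 49 umbrella windows of 4 ns each (k = 5000 kJ/mol/nm^2) on
#' 0.206--0.99 nm with samples every 100 steps; and a GPR sweep over
#' delta 0.40--0.90 kJ/mol, sigma 0.05--0.15 and theta 0.20--0.35 nm.
#'
#' @param seed Base seed for every stochastic stage.
#' @return Nested configuration list for [run_full_pipeline()].
#' @export
default_config <- function(seed = 2024) {
  list(
    seed = as.numeric(seed),
    potential = list(preset = "mgcl"),
    thermo = list(temperature = 300, friction = 5, mass = 14.42, dt = 0.002),
    wtmtd = list(gamma = 20, omega0 = 0.8, sigma_g = 0.01, pace = 500,
                 n_steps = 2.5e7, record_stride = 1000),
    training = list(n_subsets = 5, subset_size = 5000),
    umbrella = list(span = c(0.206, 0.99), n_windows = 49, spring_k = 5000,
                    n_steps = 2e6, stride = 100, n_equil = 5e4,
                    bin_width = 0.002),
    gpr = list(deltas = c(0.40, 0.65, 0.90), sigmas = c(0.05, 0.10, 0.15),
               thetas = seq(0.20, 0.35, by = 0.01),
               mode = "sparse", grid_sizes = 50, noise_mode = "direct"),
    evaluation = list(n_points = 100, alignment = "mean",
                      span = c(0.206, 0.99))
  )
}

#' Run the full synthetic reconstruction pipeline
#'
#' Executes, on the configured synthetic system: (1) a well-tempered
#' metadynamics run; (2) gradient unbiasing into a training set plus random
#' subsets; (3) the scaled-bias reference free energy curve; (4) a GPR
#' hyperparameter sweep against that reference; (5) the umbrella-sampling /
#' WHAM reference; and (6) landmark reports. All artifacts are written
#' under `out_dir` as plain text (HILLS, COLVAR, training sets, FES tables,
#' window series + WHAM metadata, sweep CSV, landmark report), each file
#' carrying the config hash and seed in its header comments.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with the in-memory results: `hills`,
#'   `trajectory`, `training`, `subsets`, `reference_fes`, `sweep`,
#'   `wham`, `landmarks`.
#' @export
run_full_pipeline <- function(config = default_config(), out_dir = "fesgpr_run",
                              verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- .config_hash(config)
  prov <- c(sprintf("config_hash: %s", hash), sprintf("seed: %g", config$seed))
  write_config(config, file.path(out_dir, "config.txt"))

  model <- make_potential(config$potential$preset)
  thermo <- thermo_state(temperature = config$thermo$temperature,
                         friction = config$thermo$friction,
                         mass = config$thermo$mass, dt = config$thermo$dt,
                         seed = as.integer(config$seed))

  say("[1/6] well-tempered metadynamics (%g steps)...", config$wtmtd$n_steps)
  mtd <- run_wtmtd(model, thermo, gamma = config$wtmtd$gamma,
                   omega0 = config$wtmtd$omega0, sigma_g = config$wtmtd$sigma_g,
                   pace = config$wtmtd$pace, n_steps = config$wtmtd$n_steps,
                   record_stride = config$wtmtd$record_stride)
  write_hills(mtd$hills, file.path(out_dir, "HILLS"), comments = prov)
  write_colvar(mtd$trajectory, file.path(out_dir, "COLVAR"), comments = prov)

  say("[2/6] gradient unbiasing (%d frames, %d hills)...",
      nrow(mtd$trajectory), nrow(mtd$hills$hills))
  training <- unbias_gradients(mtd$trajectory, mtd$hills)
  write_training(training, file.path(out_dir, "training.dat"), comments = prov)
  subsets <- list()
  for (k in seq_len(config$training$n_subsets)) {
    subsets[[paste0("batch", k)]] <-
      subset_training(training, config$training$subset_size,
                      seed = as.integer(config$seed) + 1000L + k)
    write_training(subsets[[paste0("batch", k)]],
                   file.path(out_dir, sprintf("training_subset_%d.dat", k)),
                   comments = prov)
  }

  say("[3/6] scaled-bias reference free energy curve...")
  ev_span <- config$evaluation$span
  ref_grid <- seq(ev_span[1], ev_span[2], length.out = 401L)
  reference <- fes_from_bias(mtd$hills, ref_grid)
  write_fes(reference, file.path(out_dir, "reference_fes.dat"), comments = prov)

  say("[4/6] GPR hyperparameter sweep (%d x %d x %d cells x %d sets)...",
      length(config$gpr$deltas), length(config$gpr$sigmas),
      length(config$gpr$thetas), length(subsets))
  sweep <- run_sweep(subsets, reference,
                     deltas = config$gpr$deltas, sigmas = config$gpr$sigmas,
                     thetas = config$gpr$thetas, mode = config$gpr$mode,
                     grid_sizes = config$gpr$grid_sizes,
                     n_points = config$evaluation$n_points,
                     alignment = config$evaluation$alignment,
                     noise_mode = config$gpr$noise_mode, span = ev_span)
  write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  best <- sweep_argmin(sweep)
  best1 <- best[1, ]
  gpr_fit <- if (best1$mode == "dense")
    fit_gpr_dense(subsets[[best1$subset]],
                  gpr_hyper(best1$delta, best1$sigma, best1$theta),
                  noise_mode = config$gpr$noise_mode)
  else
    fit_gpr_sparse(subsets[[best1$subset]],
                   gpr_hyper(best1$delta, best1$sigma, best1$theta),
                   grid_size = best1$grid_size, span = ev_span,
                   noise_mode = config$gpr$noise_mode)
  gpr_fes <- predict_fes(gpr_fit, seq(ev_span[1], ev_span[2],
                                      length.out = config$evaluation$n_points))
  write_fes(gpr_fes, file.path(out_dir, "gpr_best_fes.dat"), comments = prov)

  say("[5/6] umbrella sampling + WHAM (%d windows)...", config$umbrella$n_windows)
  windows <- make_windows(config$umbrella$span, config$umbrella$n_windows,
                          config$umbrella$spring_k)
  sampled <- sample_windows(model, windows, thermo,
                            n_steps = config$umbrella$n_steps,
                            stride = config$umbrella$stride,
                            n_equil = config$umbrella$n_equil,
                            seed = as.integer(config$seed))
  win_dir <- file.path(out_dir, "windows")
  dir.create(win_dir, showWarnings = FALSE)
  rel_paths <- file.path("windows", sprintf("window_%02d.dat", seq_along(sampled)))
  for (i in seq_along(sampled))
    write_window_series(sampled[[i]], file.path(out_dir, rel_paths[i]))
  # paths are stored relative to the run directory, Grossfield-tool style
  write_wham_meta(rel_paths, windows, file.path(out_dir, "wham_meta.dat"))
  wham <- wham_solve(sampled,
                     bin_edges = seq(config$umbrella$span[1],
                                     config$umbrella$span[2],
                                     by = config$umbrella$bin_width),
                     temperature = config$thermo$temperature)
  write_fes(wham$fes, file.path(out_dir, "wham_fes.dat"), comments = prov)

  say("[6/6] landmark reports and sweep summary...")
  truth <- fes_curve(ref_grid,
                     evaluate_potential(model, ref_grid)$energy)
  landmarks <- list(truth = locate_landmarks(truth),
                    wtmtd = locate_landmarks(reference),
                    wham = locate_landmarks(wham$fes),
                    gpr = locate_landmarks(gpr_fes))
  summary <- summarize_sweep(sweep, landmarks)
  writeLines(summary$lines, file.path(out_dir, "report.txt"))

  invisible(list(model = model, hills = mtd$hills, trajectory = mtd$trajectory,
                 training = training, subsets = subsets,
                 reference_fes = reference, sweep = sweep, best = best,
                 gpr_fes = gpr_fes, wham = wham, landmarks = landmarks,
                 summary = summary, config = config))
}
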
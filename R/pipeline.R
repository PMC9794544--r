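#' End-to-end pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the day-indexed input stacks
#' (a synthetic [timecourse_config()] or a manifest of TIFF paths), analysis
#' settings, model parameters, optional stiffness observations, and the
#' output directory.
#'
#' @param stacks a [timecourse_config()], or a data frame with columns
#'   `day` and `path` pointing at multi-page grayscale TIFFs.
#' @param out_dir output directory (created if missing).
#' @param n_bins orientation histogram bins.
#' @param window_sigma structure-tensor Gaussian window, pixels.
#' @param max_planes plane count for the maximum projection used in
#'   densitometry.
#' @param weight_mode histogram weighting, see [orientation_histogram()].
#' @param params a [model_params()].
#' @param stiffness optional [stiffness_series()]/data frame or CSV path
#'   (columns `day` and `stiffness_N_per_mm` or `stiffness`) to fit against.
#' @param fit_window day range used for temporal fits and model fitting;
#'   samples outside it (consolidation phase) are analyzed but excluded from
#'   fitting.
#' @param pixel_size,z_spacing,bit_depth calibration applied when reading
#'   TIFF manifests.
#' @param seed global seed recorded in the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stacks, out_dir, n_bins = 90L, window_sigma = 2,
                            max_planes = 9L,
                            weight_mode = "energy",
                            params = model_params(),
                            stiffness = NULL, fit_window = c(0, 15),
                            pixel_size = 0.1444, z_spacing = 4.89,
                            bit_depth = 8L, seed = 1L) {
  if (!inherits(stacks, "timecourse_config")) {
    stacks <- as.data.frame(stacks)
    if (!all(c("day", "path") %in% names(stacks)))
      stop("stack manifest needs 'day' and 'path' columns")
    if (anyDuplicated(stacks$day)) stop("days must be unique")
    missing <- !file.exists(stacks$path)
    if (any(missing))
      stop("missing stack file(s): ", paste(stacks$path[missing], collapse = ", "))
  }
  structure(list(stacks = stacks, out_dir = out_dir, n_bins = as.integer(n_bins),
                 window_sigma = window_sigma, max_planes = as.integer(max_planes),
                 weight_mode = weight_mode, params = params,
                 stiffness = stiffness, fit_window = fit_window,
                 pixel_size = pixel_size, z_spacing = z_spacing,
                 bit_depth = as.integer(bit_depth), seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys: `out_dir`, `seed`, `analysis`
#' (`n_bins`, `window_sigma`, `max_planes`, `weight_mode`), `params`
#' (arguments of [model_params()]), `synthetic` (arguments of
#' [timecourse_config()] plus optional `template` arguments of
#' [stack_config()]), `manifest` (list of `{day, path}`), `stiffness_csv`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$out_dir)) stop("config must set out_dir")
  stacks <- if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    tmpl <- do.call(stack_config, syn$template %||% list())
    syn$template <- NULL
    do.call(timecourse_config, c(syn, list(template = tmpl)))
  } else if (!is.null(raw$manifest)) {
    as.data.frame(do.call(rbind, lapply(raw$manifest, as.data.frame)))
  } else stop("config must provide 'synthetic' or 'manifest'")
  args <- c(list(stacks = stacks, out_dir = raw$out_dir),
            raw$analysis %||% list(),
            list(params = do.call(model_params, raw$params %||% list()),
                 stiffness = raw$stiffness_csv,
                 seed = raw$seed %||% 1L))
  do.call(pipeline_config, args)
}

analyze_one_stack <- function(stack, cfg) {
  sp <- sum_projection(stack)
  field <- structure_tensor_orientation(sp, cfg$window_sigma)
  hist <- orientation_histogram(field, cfg$n_bins, cfg$weight_mode)
  mp <- max_projection(stack, min(cfg$max_planes, n_planes(stack)))
  mgv <- mean_gray_value(mp, n_planes_used = min(cfg$max_planes, n_planes(stack)),
                         z_spacing = stack$z_spacing)
  list(distribution = hist, sigma = distribution_std(hist),
       mean_gray = mgv$mean_gray_value, summary = mgv)
}

read_stiffness_csv <- function(x) {
  if (is.character(x)) x <- read.csv(x)
  x <- as.data.frame(x)
  if ("stiffness_N_per_mm" %in% names(x)) x$stiffness <- x$stiffness_N_per_mm
  if (!all(c("day", "stiffness") %in% names(x)))
    stop("stiffness input needs columns 'day' and 'stiffness' (or 'stiffness_N_per_mm')")
  x[order(x$day), c("day", "stiffness")]
}

#' Run the full callus analysis pipeline
#'
#' Executes, per day: sum projection, structure-tensor orientation
#' distribution (and its standard deviation), maximum-projection mean gray
#' value. Fits the affine temporal laws for spread and intensity over the
#' distraction window, evaluates the coefficient trajectory, and (when
#' stiffness observations are provided) fits the model parameters. All
#' artifacts are written into `out_dir` with deterministic names:
#' `image_summary.csv`, `distribution_day<d>.csv`, `trajectory.csv`,
#' `laws.json`, `fit.json`, `run_record.json`.
#'
#' @param config a [pipeline_config()] or a path accepted by
#'   [load_pipeline_config()].
#' @return A `callus_run` record (invisibly reusable by [report()]), with
#'   elements `image_summary`, `laws`, `trajectory`, `fit` (or `NULL`),
#'   `files`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  note("stage:stacks")
  entries <- if (inherits(config$stacks, "timecourse_config")) {
    generate_timecourse(config$stacks)
  } else {
    lapply(seq_len(nrow(config$stacks)), function(i)
      list(day = config$stacks$day[i],
           stack = read_fiber_stack(config$stacks$path[i],
                                    pixel_size = config$pixel_size,
                                    z_spacing = config$z_spacing,
                                    bit_depth = config$bit_depth)))
  }
  days <- vapply(entries, `[[`, numeric(1), "day")
  note("stacks: %d day(s): %s", length(days), paste(days, collapse = ", "))

  note("stage:imaging")
  files <- character(0)
  rows <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    res <- analyze_one_stack(entries[[i]]$stack, config)
    dfile <- file.path(config$out_dir,
                       sprintf("distribution_day%g.csv", days[i]))
    write.csv(data.frame(angle_rad = res$distribution$angles,
                         density = res$distribution$density),
              dfile, row.names = FALSE)
    files <- c(files, dfile)
    rows[[i]] <- data.frame(day = days[i], sigma_rad = res$sigma,
                            mean_gray = res$mean_gray)
  }
  image_summary <- do.call(rbind, rows)
  sfile <- file.path(config$out_dir, "image_summary.csv")
  write.csv(image_summary, sfile, row.names = FALSE)
  files <- c(files, sfile)

  note("stage:temporal_laws")
  w <- config$fit_window
  in_win <- image_summary$day >= w[1] & image_summary$day <= w[2]
  if (length(unique(image_summary$day[in_win])) < 3L)
    stop("insufficient time points inside the fit window for temporal fits (need >= 3 days)")
  if (any(!in_win))
    note("excluded %d consolidation-phase day(s) from fitting",
         sum(!in_win))
  sig_fit <- fit_linear(image_summary$day[in_win], image_summary$sigma_rad[in_win])
  rho_fit <- fit_linear(image_summary$day[in_win], image_summary$mean_gray[in_win])
  laws <- temporal_laws(sig_fit, rho_fit, check_window = w)
  params <- config$params
  if (is.na(params$rho0)) {
    d0 <- which(image_summary$day == 0)
    params$rho0 <- if (length(d0) == 1L) image_summary$mean_gray[d0]
                   else unname(rho_at(laws, 0))
    note("rho0 = %.4f (%s)", params$rho0,
         if (length(d0) == 1L) "measured day-0 mean gray" else "rho law at day 0")
  }
  lfile <- file.path(config$out_dir, "laws.json")
  jsonlite::write_json(list(
    sigma = list(intercept = laws$sigma[["intercept"]],
                 slope = laws$sigma[["slope"]],
                 r_squared = sig_fit$r_squared, p_value = sig_fit$p_value),
    rho = list(intercept = laws$rho[["intercept"]], slope = laws$rho[["slope"]],
               r_squared = rho_fit$r_squared, p_value = rho_fit$p_value),
    rho0 = params$rho0), lfile, auto_unbox = TRUE, digits = NA)
  files <- c(files, lfile)

  note("stage:trajectory")
  traj <- stiffness_trajectory(laws, seq(w[1], w[2]), params)
  tfile <- file.path(config$out_dir, "trajectory.csv")
  write.csv(traj, tfile, row.names = FALSE)
  files <- c(files, tfile)

  fit <- NULL
  if (!is.null(config$stiffness)) {
    note("stage:model_fit")
    obs <- read_stiffness_csv(config$stiffness)
    obs <- obs[obs$day >= w[1] & obs$day <= w[2], ]
    fit <- callus_fit(stiffness ~ day, obs, laws = laws, params = params)
    ffile <- file.path(config$out_dir, "fit.json")
    jsonlite::write_json(list(
      C1 = unname(coef(fit)["C1"]), t_prime = unname(coef(fit)["t_prime"]),
      K1 = unname(coef(fit)["K1"]), product_C1K1 = fit$product_C1K1,
      r_squared = fit$r_squared, p_value = fit$p_value,
      converged = fit$diagnostics$converged),
      ffile, auto_unbox = TRUE, digits = NA)
    files <- c(files, ffile)
  } else note("stage:model_fit skipped (no stiffness observations)")

  record <- structure(list(
    config = config, version = as.character(packageVersion("callusmod")),
    seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"),
    image_summary = image_summary, laws = laws, params = params,
    trajectory = traj, fit = fit, files = files, log = log),
    class = "callus_run")
  rfile <- file.path(config$out_dir, "run_record.json")
  jsonlite::write_json(list(version = record$version, seed = record$seed,
                            timestamp = record$timestamp, log = log,
                            files = basename(files)),
                       rfile, auto_unbox = TRUE)
  record$files <- c(files, rfile)
  record
}

#' @export
print.callus_run <- function(x, ...) {
  cat(sprintf("<callus_run> v%s, seed %s, %d file(s) in %s\n", x$version,
              x$seed, length(x$files), x$config$out_dir))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Assembles per-day imaging summaries, temporal-law diagnostics, and the
#' fitted model parameters (one row per fitted parameter) into a printable
#' report; sections without inputs are marked skipped. Optionally renders
#' the standard panels (per-day distributions, temporal laws, coefficient
#' trajectory, model vs observations) to a PDF.
#'
#' @param record a `callus_run` from [run_pipeline()].
#' @param plot_file optional path of a PDF to draw the panels into.
#' @return A `callus_report` object.
#' @export
report <- function(record, plot_file = NULL) {
  stopifnot(inherits(record, "callus_run"))
  missing <- record$files[!file.exists(record$files)]
  if (length(missing))
    stop("missing run artifacts: ", paste(missing, collapse = ", "))
  par_table <- if (is.null(record$fit)) NULL else {
    cf <- coef(record$fit)
    data.frame(parameter = names(cf), value = unname(cf),
               row.names = NULL)
  }
  law_table <- data.frame(
    law = c("sigma(t) [rad]", "rho(t) [gray]"),
    intercept = c(record$laws$sigma[["intercept"]], record$laws$rho[["intercept"]]),
    slope = c(record$laws$sigma[["slope"]], record$laws$rho[["slope"]]),
    r_squared = c(record$laws$sigma_diag$r_squared, record$laws$rho_diag$r_squared),
    p_value = c(record$laws$sigma_diag$p_value, record$laws$rho_diag$p_value))
  out <- structure(list(image_summary = record$image_summary,
                        laws = law_table, parameters = par_table,
                        fit = record$fit, trajectory = record$trajectory),
                   class = "callus_report")
  if (!is.null(plot_file)) {
    grDevices::pdf(plot_file, width = 8, height = 6)
    on.exit(grDevices::dev.off())
    par(mfrow = c(2, 2))
    plot(record$image_summary$day, record$image_summary$sigma_rad,
         xlab = "day", ylab = "distribution std (rad)")
    abline(record$laws$sigma[["intercept"]], record$laws$sigma[["slope"]])
    plot(record$image_summary$day, record$image_summary$mean_gray,
         xlab = "day", ylab = "mean gray value")
    abline(record$laws$rho[["intercept"]], record$laws$rho[["slope"]])
    plot(record$trajectory, which = "coefficients", main = "coefficients")
    if (!is.null(record$fit)) plot(record$fit, main = "model vs observations")
    else plot.new()
  }
  out
}

#' @export
print.callus_report <- function(x, ...) {
  cat("== Callus pipeline report ==\n\nPer-day imaging summary:\n")
  print(x$image_summary, row.names = FALSE)
  cat("\nTemporal laws:\n")
  print(x$laws, row.names = FALSE)
  cat("\nModel fit:\n")
  if (is.null(x$parameters)) {
    cat("  skipped (no stiffness observations provided)\n")
  } else {
    print(x$parameters, row.names = FALSE)
    cat(sprintf("  R^2 = %.4f, p = %.3g\n", x$fit$r_squared, x$fit$p_value))
  }
  invisible(x)
}
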
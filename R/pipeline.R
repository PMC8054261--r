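#' Validate and normalize a pipeline configuration
#'
#' Checks the configuration (a named list, typically parsed from YAML)
#' before any work is done, filling documented defaults for absent
#' sections and rejecting unknown or invalid fields with a message that
#' names every offending field.
#'
#' @param config named list, or path to a YAML file.
#' @return the normalized config list (class `"pipeline_config"`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "output_dir", "scene", "segmentation", "growth",
             "dose_response", "effects", "stats")
  unknown <- setdiff(names(config), known)
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, paste("unknown field(s):", paste(unknown, collapse = ", ")))
  if (is.null(config$seed) || !is.numeric(config$seed))
    problems <- c(problems, "'seed' (integer) is required")
  if (is.null(config$output_dir) || !is.character(config$output_dir))
    problems <- c(problems, "'output_dir' (path) is required")
  if (length(problems))
    stop("invalid pipeline config: ", paste(problems, collapse = "; "))

  defaults <- list(
    scene = list(image_shape = c(256L, 256L), pixel_size = 27,
                 n_cells_on = 40L, n_cells_off = 15L),
    segmentation = list(std_kernels = c(7L, 9L),
                        candidate_thresholds = c(60, 100),
                        struct_sizes = c(5L, 8L),
                        circularity_weight = 0.5),
    growth = list(n0 = 100, rate = 0.03, times = seq(0, 72, by = 12),
                  noise_cv = 0.05),
    dose_response = list(doses = c(0, 0.062, 0.185, 0.555, 1.667, 5),
                         hill_ic50 = 0.32, hill_slope = 1, n_replicates = 4L),
    effects = list(n_experiments = 4L, n_replicates = 3L),
    stats = list(chains = 2L, iter = 4000L, warmup = 1000L,
                 contrast = list(factor = "plate", a = "softwell_2kPa",
                                 b = "softwell_0.2kPa")))
  for (sec in names(defaults)) {
    user <- config[[sec]] %||% list()
    merged <- defaults[[sec]]
    merged[names(user)] <- user
    config[[sec]] <- merged
  }
  # YAML sequences may parse as lists; flatten the numeric-vector fields
  num <- function(x) as.numeric(unlist(x))
  config$scene$image_shape <- as.integer(unlist(config$scene$image_shape))
  config$growth$times <- num(config$growth$times)
  config$dose_response$doses <- num(config$dose_response$doses)
  config$segmentation$std_kernels <- as.integer(unlist(config$segmentation$std_kernels))
  config$segmentation$candidate_thresholds <- num(config$segmentation$candidate_thresholds)
  config$segmentation$struct_sizes <- as.integer(unlist(config$segmentation$struct_sizes))
  config$seed <- as.integer(config$seed)
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the full chain on synthetic data from one seeded
#' configuration: scene synthesis, disc segmentation (parameter sweep
#' with automated selection), cell registration, dose-response growth
#' simulation and exponential fitting, per-replicate IC50 interpolation,
#' and the comparative statistics (sign test on the top-dose rate change;
#' hierarchical growth-rate model on a generated multi-experiment table).
#' Every stage writes its artifact into `output_dir` and the run ends
#' with a manifest recording the seed, a hash of the normalized config
#' and an MD5 checksum per artifact, so reruns can be verified
#' bit-identical.
#'
#' @param config a [pipeline_config()], a named list, or a YAML path.
#' @param quiet suppress progress messages.
#' @return the manifest (named list), invisibly written to
#'   `manifest.json`.  On stage failure the run halts with the stage name
#'   after writing a partial manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- pipeline_config(config)
  out <- config$output_dir
  if (!dir.exists(out)) {
    dir.create(out, recursive = TRUE)
    if (!quiet) message("created output directory ", out)
  }
  seed <- config$seed
  say <- function(...) if (!quiet) message(...)
  manifest <- list(seed = seed,
                   config_hash = digest_config(config),
                   stages = list())
  artifacts <- character(0)
  finish_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(
      outputs = basename(files),
      md5 = unname(tools::md5sum(files)))
    artifacts <<- c(artifacts, files)
  }
  run_stage <- function(name, fn) {
    say("stage: ", name)
    tryCatch(fn(), error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  env <- new.env()

  run_stage("scene", function() {
    sc <- config$scene
    params <- disc_scene_params(image_shape = as.integer(sc$image_shape),
                                pixel_size = sc$pixel_size,
                                n_cells_on = sc$n_cells_on,
                                n_cells_off = sc$n_cells_off,
                                seed = derive_seed(seed, "scene"))
    env$scene <- gen_well_scene(params)
    f <- file.path(out, c("well.tif", "profile.tif", "scene_truth.json",
                          "detections.csv"))
    write_image_tiff(env$scene$image, f[1])
    write_image_tiff(env$scene$profile, f[2])
    write_scene_truth_json(env$scene, f[3])
    write_detections_csv(env$scene$cells[, setdiff(names(env$scene$cells), "on_disc")],
                         f[4])
    finish_stage("scene", f)
  })

  run_stage("segment", function() {
    sg <- config$segmentation
    grid <- default_segmentation_grid(as.integer(sg$std_kernels),
                                      sg$candidate_thresholds,
                                      as.integer(sg$struct_sizes))
    expected <- pi * env$scene$params$disc_radius^2
    sw <- sweep_segmentation(env$scene$image, env$scene$profile, grid,
                             expected_area = expected,
                             circularity_weight = sg$circularity_weight)
    env$mask <- sw$best
    f <- file.path(out, c("mask.png", "segmentation.json"))
    write_mask_png(sw$best, f[1])
    shape <- mask_shape(sw$best$mask)
    jsonlite::write_json(
      list(no_disc = sw$best$no_disc, score = sw$best$score,
           area_px = shape$area, circularity = shape$circularity,
           params = unclass(sw$best$params),
           ranking = sw$ranking),
      f[2], auto_unbox = TRUE, digits = NA)
    finish_stage("segment", f)
  })

  run_stage("register", function() {
    reg <- register_cells(env$scene$cells[, setdiff(names(env$scene$cells), "on_disc")],
                          env$mask)
    f <- file.path(out, c("registered.csv", "registration.json"))
    write_detections_csv(reg, f[1])
    jsonlite::write_json(registration_summary(reg), f[2],
                         auto_unbox = TRUE, digits = NA)
    env$registered <- reg
    finish_stage("register", f)
  })

  run_stage("growth_fits", function() {
    gw <- config$growth; dr <- config$dose_response
    rows <- list()
    env$ic50 <- list()
    for (rep_i in seq_len(dr$n_replicates)) {
      gp <- growth_params(n0 = gw$n0, rate = gw$rate, times = gw$times,
                          noise_cv = gw$noise_cv,
                          seed = derive_seed(seed, paste0("rep", rep_i)))
      series <- gen_dose_response(gp, doses = dr$doses,
                                  hill_ic50 = dr$hill_ic50,
                                  hill_slope = dr$hill_slope)
      fits <- lapply(series, fit_exponential)
      for (d in names(fits))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, dose_uM = as.numeric(d),
          n0_hat = fits[[d]]$n0_hat, rate_hat = fits[[d]]$rate_hat,
          rate_se = fits[[d]]$rate_se, rss = fits[[d]]$rss,
          converged = fits[[d]]$converged)
      env$ic50[[rep_i]] <- ic50_log_interp(build_curve(fits))
    }
    env$fits_table <- do.call(rbind, rows)
    f <- file.path(out, "fits.csv")
    write.csv(env$fits_table, f, row.names = FALSE)
    finish_stage("growth_fits", f)
  })

  run_stage("ic50", function() {
    tab <- do.call(rbind, lapply(seq_along(env$ic50), function(i)
      data.frame(replicate = i, ic50_uM = env$ic50[[i]]$value,
                 censored = env$ic50[[i]]$censored)))
    f <- file.path(out, "ic50.csv")
    write.csv(tab, f, row.names = FALSE)
    env$ic50_table <- tab
    finish_stage("ic50", f)
  })

  run_stage("stats", function() {
    st <- config$stats; ef <- config$effects
    # sign test: top-dose vs untreated fitted rates across replicates
    top <- max(env$fits_table$dose_uM)
    d <- env$fits_table$rate_hat[env$fits_table$dose_uM == top] -
      env$fits_table$rate_hat[env$fits_table$dose_uM == 0]
    sgn <- sign_test_two_sided(d)
    spec <- effects_table_spec(n_experiments = ef$n_experiments,
                               n_replicates = ef$n_replicates,
                               seed = derive_seed(seed, "effects"))
    tab <- gen_effects_table(spec)
    ct <- st$contrast
    hier <- fit_hierarchical_growth_model(
      tab, hier_model_spec(contrasts = setNames(
                             list(list(factor = ct$factor, a = ct$a, b = ct$b)),
                             "contrast"),
                           chains = st$chains, iter = st$iter,
                           warmup = st$warmup,
                           seed = derive_seed(seed, "hier")))
    f <- file.path(out, "stats.json")
    jsonlite::write_json(
      list(sign_test = unclass(sgn),
           hier_model = list(summary = hier$summary,
                             converged = hier$converged)),
      f, auto_unbox = TRUE, digits = NA)
    finish_stage("stats", f)
  })

  manifest$status <- "complete"
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline complete: ", length(artifacts), " artifacts in ", out)
  invisible(manifest)
}

# order-independent hash of the normalized config
digest_config <- function(config) {
  js <- jsonlite::toJSON(config[sort(names(unclass(config)))],
                         auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  writeLines(as.character(js), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

#' Run the shipped demo pipeline
#'
#' Copies the demo configuration shipped with the package, points it at
#' `dir` and runs [run_pipeline()].
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed.
#' @param quiet suppress progress messages.
#' @return the run manifest, invisibly.
#' @export
demo_pipeline <- function(dir = tempfile("discgrowth_demo"), seed = 1L,
                          quiet = FALSE) {
  cfg_path <- system.file("extdata", "demo-config.yaml", package = "discgrowth")
  cfg <- yaml::read_yaml(cfg_path)
  cfg$seed <- as.integer(seed)
  cfg$output_dir <- dir
  run_pipeline(cfg, quiet = quiet)
}
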
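# Pipeline orchestration: a validated configuration object and a resumable
# stage runner (frames -> calibrate -> train -> mesh/render -> evaluate).

pipeline_defaults <- function() {
  list(
    seed = 1,
    work_dir = "orbitnerf_run",
    resume = TRUE,
    scene = list(enabled = TRUE, n_leaves = 12, n_per_ring = 50,
                 image_size = 64, n_quad = 96,
                 exposure_exps = 0, blur_ids = integer(0), blur_sigma = 2,
                 r_real = 0.75, h1 = 0.35, h2 = 0.25),
    keyframes = list(target_per_view = 50, per_view = 45,
                     rel_threshold = 0.2, max_removed = 10),
    train = list(n_iter = 2000, batch = 256, n_c = 48, n_f = 96,
                 roi_frac = 0.75, hash_levels = 8, hash_table_size = 2^14,
                 hash_n_max = 256, coarse_levels = 4,
                 coarse_table_size = 2^12, coarse_n_max = 64, hidden = 32,
                 lr_hash = 1e-2, lr_mlp = 1e-3, lr_exposure = 1e-2,
                 lr_pose = 1e-3, optimize_exposure = TRUE,
                 optimize_pose = FALSE, lambda_E = 1e-4, lambda_p = 1e-4),
    mesh = list(resolution = 96, sigma_threshold = 25),
    evaluate = list(n_views = 2, max_i = 1))
}

merge_validate <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_validate(defaults[[k]], as.list(user[[k]]),
                                      paste0(path, k, "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' All tunables of every stage with defaults; unknown keys are rejected.  The
#' object round-trips losslessly through YAML via [write_pipeline_config()]
#' and [read_pipeline_config()].
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   `train = list(n_iter = 500)`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  structure(merge_validate(pipeline_defaults(), list(...)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_done <- function(work_dir, stage) {
  file.exists(file.path(work_dir, stage, "manifest.json"))
}

stage_finish <- function(work_dir, stage, info, t0) {
  info$stage <- stage
  info$seconds <- round(as.numeric(Sys.time()) - t0, 2)
  jsonlite::write_json(info, file.path(work_dir, stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("[%s] done in %.1f s", stage, info$seconds))
}

#' Run the full reconstruction pipeline
#'
#' Executes the stages in order -- `simulate` (optional synthetic capture),
#' `keyframes`, `calibrate`, `train`, `mesh`, `evaluate` -- under
#' `config$work_dir`.  Each stage writes its artifacts plus a
#' `manifest.json`; with `config$resume = TRUE`, stages whose manifest exists
#' are skipped, so deleting one stage directory re-runs only that stage and
#' those after it that depend on its outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the work directory and key artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$work_dir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, fun) {
    if (config$resume && stage_done(wd, stage)) {
      message(sprintf("[%s] cached, skipping", stage))
      return(invisible(NULL))
    }
    dir.create(file.path(wd, stage), recursive = TRUE, showWarnings = FALSE)
    t0 <- as.numeric(Sys.time())
    info <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_finish(wd, stage, info, t0)
  }

  capture_dir <- file.path(wd, "simulate", "capture")
  if (isTRUE(config$scene$enabled)) {
    run_stage("simulate", function() {
      sc <- config$scene
      field <- make_plant_field(seed = config$seed, n_leaves = sc$n_leaves)
      intr <- camera_intrinsics(0.75 * sc$image_size, 0.75 * sc$image_size,
                                sc$image_size / 2, sc$image_size / 2,
                                sc$image_size, sc$image_size)
      cap <- simulate_capture(field, trajectory_prior(sc$r_real, sc$h1,
                                                      sc$h2),
                              n_per_ring = sc$n_per_ring, intr = intr,
                              n_quad = sc$n_quad)
      cap <- degrade(cap, blur_ids = sc$blur_ids,
                     exposure_exps = sc$exposure_exps,
                     blur_sigma = sc$blur_sigma, seed = config$seed)
      write_capture(cap, capture_dir)
      saveRDS(field, file.path(wd, "simulate", "field.rds"))
      list(n_frames = length(cap$frames), capture = capture_dir)
    })
  }

  run_stage("keyframes", function() {
    frames <- read_frames(capture_dir)
    views <- sub("_\\d+\\.png$", "", names(frames))
    per_view <- split(frames, views)
    kf <- extract_keyframes(per_view,
                            target_per_view = config$keyframes$target_per_view,
                            rel_threshold = config$keyframes$rel_threshold,
                            max_removed = config$keyframes$max_removed,
                            per_view = config$keyframes$per_view,
                            seed = config$seed)
    man <- frame_manifest(kf)
    utils::write.csv(man, file.path(wd, "keyframes", "manifest.csv"),
                     row.names = FALSE)
    for (i in seq_along(kf$frames)) {
      png::writePNG(kf$frames[[i]], file.path(wd, "keyframes",
                                              man$filename[i]))
    }
    list(n_keyframes = nrow(man))
  })

  run_stage("calibrate", function() {
    model <- read_sfm_model(file.path(capture_dir, "sparse"))
    prior <- read_prior(file.path(capture_dir, "prior.yaml"))
    cal <- calibrate_poses(model$poses, prior)
    box <- compute_roi_aabb(cal$calibration, prior)
    write_sfm_model(file.path(wd, "calibrate", "sparse"), model$intrinsics,
                    cal$poses, model$image_names)
    yaml::write_yaml(list(
      R_vtr = as.numeric(cal$calibration$R_vtr),
      k = cal$calibration$k, t_s = cal$calibration$t_s,
      z_up = cal$calibration$z_up, z_low = cal$calibration$z_low,
      r_virtual = cal$calibration$r_virtual,
      aabb = list(min = box$min, max = box$max)),
      file.path(wd, "calibrate", "calibration.yaml"))
    list(k = cal$calibration$k, r_virtual = cal$calibration$r_virtual)
  })

  checkpoint <- file.path(wd, "train", "checkpoint.rds")
  run_stage("train", function() {
    man <- utils::read.csv(file.path(wd, "keyframes", "manifest.csv"))
    model <- read_sfm_model(file.path(wd, "calibrate", "sparse"))
    caly <- yaml::read_yaml(file.path(wd, "calibrate", "calibration.yaml"))
    box <- aabb(unlist(caly$aabb$min), unlist(caly$aabb$max))
    intr <- model$intrinsics
    frames <- lapply(man$filename, function(f) {
      undistort_image(read_frames(file.path(wd, "keyframes"),
                                  pattern = paste0("^", f, "$"))[[1]], intr)
    })
    poses <- model$poses[match(man$filename, model$image_names)]
    tc <- config$train
    field <- radiance_field(
      box, length(frames),
      fine_cfg = hash_grid_config(tc$hash_levels, tc$hash_table_size,
                                  n_max = tc$hash_n_max),
      coarse_cfg = hash_grid_config(tc$coarse_levels, tc$coarse_table_size,
                                    n_max = tc$coarse_n_max),
      hidden_density = tc$hidden, hidden_color = tc$hidden,
      seed = config$seed)
    field$n_c <- tc$n_c; field$n_f <- tc$n_f; field$roi_frac <- tc$roi_frac
    field$lambda_E <- tc$lambda_E; field$lambda_p <- tc$lambda_p
    field <- train_radiance_field(
      field, frames, poses, intr, n_iter = tc$n_iter, batch = tc$batch,
      lr_hash = tc$lr_hash, lr_mlp = tc$lr_mlp,
      lr_exposure = tc$lr_exposure, lr_pose = tc$lr_pose,
      optimize_exposure = tc$optimize_exposure,
      optimize_pose = tc$optimize_pose, seed = config$seed)
    saveRDS(field, checkpoint)
    utils::write.csv(field$log, file.path(wd, "train", "loss.csv"),
                     row.names = FALSE)
    list(final_loss = field$log$loss[nrow(field$log)],
         n_iter = tc$n_iter)
  })

  run_stage("mesh", function() {
    field <- readRDS(checkpoint)
    cfg <- mesh_config(config$mesh$resolution, config$mesh$sigma_threshold)
    mesh <- extract_mesh(field, field$aabb, cfg, vertex_colors = TRUE)
    write_mesh_obj(mesh, file.path(wd, "mesh", "plant.obj"))
    write_mesh_ply(mesh, file.path(wd, "mesh", "plant.ply"))
    list(n_vertices = nrow(mesh$vertices), n_faces = nrow(mesh$faces),
         height_m = if (nrow(mesh$vertices) > 0) mesh_height(mesh) else NA)
  })

  run_stage("evaluate", function() {
    field <- readRDS(checkpoint)
    man <- utils::read.csv(file.path(wd, "keyframes", "manifest.csv"))
    model <- read_sfm_model(file.path(wd, "calibrate", "sparse"))
    frames <- read_frames(file.path(wd, "keyframes"))
    ids <- round(seq(1, nrow(man), length.out = config$evaluate$n_views))
    poses <- model$poses[match(man$filename, model$image_names)]
    rep <- evaluate_views(field, frames[man$filename], poses,
                          model$intrinsics, ids = ids,
                          max_i = config$evaluate$max_i)
    utils::write.csv(rep, file.path(wd, "evaluate", "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mean_psnr = attr(rep, "mean_psnr"),
                              max_i = attr(rep, "max_i")),
                         file.path(wd, "evaluate", "report.json"),
                         auto_unbox = TRUE, digits = NA)
    list(mean_psnr = attr(rep, "mean_psnr"))
  })

  invisible(list(work_dir = wd, checkpoint = checkpoint,
                 mesh = file.path(wd, "mesh", "plant.obj"),
                 report = file.path(wd, "evaluate", "report.json")))
}
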
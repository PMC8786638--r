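#' Write and read trajectory tables
#'
#' The trajectory dialect is a comma-separated, newline-terminated, UTF-8
#' table with one row per frame x agent and units in the column names:
#' `trial_id, frame, t_s, agent_id, species, x_cm, y_cm, heading_rad`,
#' plus a `source` column (`observed`/`predicted`) for tracker output.
#' A `trial_recording` additionally writes two sidecars next to `path`:
#' `<stem>_attacks.csv` (the attack log) and `<stem>_config.yaml` (a
#' structured snapshot of geometry, coupling, treatment and seed), which
#' `read_trajectories` uses to restore the full recording.
#'
#' @param x A `trial_recording` or `track_set`.
#' @param path Output CSV path.
#' @param trial_id Identifier written into the table.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a `trial_recording` (when the config
#'   sidecar is present) or a `track_set`.
#' @export
write_trajectories <- function(x, path, trial_id = "trial") {
  UseMethod("write_trajectories")
}

trajectory_long <- function(x, trial_id) {
  n_frames <- nrow(x$x)
  n_agents <- ncol(x$x)
  data.table::data.table(
    trial_id = trial_id,
    frame = rep(seq_len(n_frames), n_agents),
    t_s = rep(seq_len(n_frames) - 1L, n_agents) / x$fps,
    agent_id = rep(x$agents$agent_id, each = n_frames),
    species = rep(x$agents$species, each = n_frames),
    x_cm = as.vector(x$x),
    y_cm = as.vector(x$y),
    heading_rad = if (!is.null(x$heading)) as.vector(x$heading) else NA_real_
  )
}

#' @export
write_trajectories.trial_recording <- function(x, path, trial_id = "trial") {
  dt <- trajectory_long(x, trial_id)
  data.table::fwrite(dt, path)
  stem <- sub("\\.csv$", "", path)
  data.table::fwrite(x$attacks, paste0(stem, "_attacks.csv"))
  cfg <- list(
    kind = "trial_recording", trial_id = trial_id,
    fps = x$fps, duration = x$duration, treatment = x$treatment,
    seed = x$seed,
    arena = list(diameter = x$geometry$diameter,
                 ring_width = x$geometry$ring_width,
                 n_rings = x$geometry$n_rings,
                 central_radius = x$geometry$central_radius,
                 water_depth = x$geometry$water_depth),
    coupling = unclass(x$coupling))
  yaml::write_yaml(cfg, paste0(stem, "_config.yaml"))
  invisible(path)
}

#' @export
write_trajectories.track_set <- function(x, path, trial_id = "trial") {
  dt <- trajectory_long(x, trial_id)
  dt$heading_rad <- NULL
  dt$source <- ifelse(as.vector(x$observed), "observed", "predicted")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.size(path) > 0) {
    stop("empty trajectory file: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path)
  need <- c("trial_id", "frame", "agent_id", "species", "x_cm", "y_cm")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(dt[, c("frame", "agent_id")]))
  if (length(dup)) {
    stop("duplicated (frame, agent_id) at row ", dup[1], call. = FALSE)
  }
  agent_ids <- unique(dt$agent_id)
  ord <- order(match(dt$agent_id, agent_ids), dt$frame)
  dt <- dt[ord, ]
  frames_per_agent <- table(dt$agent_id)
  if (length(unique(frames_per_agent)) != 1L) {
    stop("agents cover different frame ranges", call. = FALSE)
  }
  n_frames <- unname(frames_per_agent[1])
  fr <- dt$frame[seq_len(n_frames)]
  bad <- which(diff(fr) <= 0)
  if (length(bad)) {
    stop("non-monotone frame index at row ", bad[1] + 1L, call. = FALSE)
  }
  fps <- if ("t_s" %in% names(dt) && n_frames > 1L) {
    round(1 / (dt$t_s[2] - dt$t_s[1]), 6)
  } else 20
  to_mat <- function(col) {
    matrix(dt[[col]], nrow = n_frames,
           dimnames = list(NULL, agent_ids))
  }
  agents <- unique(data.frame(agent_id = dt$agent_id,
                              species = dt$species,
                              stringsAsFactors = FALSE))
  rownames(agents) <- NULL

  stem <- sub("\\.csv$", "", path)
  cfg_path <- paste0(stem, "_config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    geometry <- arena_geometry(cfg$arena$diameter, cfg$arena$ring_width,
                               cfg$arena$n_rings, cfg$arena$central_radius,
                               cfg$arena$water_depth)
    att_path <- paste0(stem, "_attacks.csv")
    attacks <- NULL
    if (file.exists(att_path) && file.size(att_path) > 0) {
      attacks <- as.data.frame(data.table::fread(att_path))
    }
    if (is.null(attacks) || nrow(attacks) == 0) {
      attacks <- data.frame(t_trigger_s = numeric(0),
                            target_id = character(0),
                            initial_distance_cm = numeric(0),
                            tier = character(0),
                            t_complete_s = numeric(0))
    }
    return(structure(
      list(fps = cfg$fps, duration = cfg$duration, n_frames = n_frames,
           agents = agents, x = to_mat("x_cm"), y = to_mat("y_cm"),
           heading = to_mat("heading_rad"), robot_speed = NULL,
           attacks = attacks, treatment = cfg$treatment,
           seed = cfg$seed,
           coupling = do.call(coupling_spec, cfg$coupling),
           geometry = geometry, scheduled_triggers = attacks$t_trigger_s),
      class = "trial_recording"))
  }

  observed <- if ("source" %in% names(dt)) {
    matrix(dt$source == "observed", nrow = n_frames,
           dimnames = list(NULL, agent_ids))
  } else {
    matrix(TRUE, n_frames, length(agent_ids),
           dimnames = list(NULL, agent_ids))
  }
  structure(
    list(x = to_mat("x_cm"), y = to_mat("y_cm"), observed = observed,
         agents = agents, fps = fps, cm_per_pixel = NA_real_,
         geometry = arena_geometry()),
    class = "track_set")
}

#' Default pipeline configuration
#'
#' One structured configuration with per-stage sections (`arena`, `agents`,
#' `coupling`, `robot`, `render`, `seeds`); all lengths are in cm, times in
#' seconds, angles in radians. A single global seed deterministically
#' derives the per-stage seeds.
#'
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    arena = list(diameter = 42, ring_width = 3, n_rings = 7,
                 central_radius = 15, water_depth = 10),
    agents = list(n_fish = 6, n_tad = 6, duration_s = 3600, fps = 20,
                  treatment = "robot_exposed"),
    coupling = list(fish_fear_gain = 1, tadpole_from_fish_gain = 0.5,
                    fish_from_tadpole_gain = 0),
    robot = list(accel = 20, vmax = 20, standoff = 1, hold_s = 1,
                 pursue_cap = 6, patrol_speed = 8, patrol_radius = 15,
                 attack_rate_per_min = 1, standardize_attacks = NULL),
    render = list(image_size = c(480, 480), cm_per_pixel = 0.1,
                  noise_sd = 4, miss_rate = 0),
    te = list(dt = 0.5, n_perm = 20000),
    seeds = list(global = seed)
  )
}

#' Read or write a pipeline configuration file (YAML)
#'
#' @param path File path.
#' @param config Configuration list (see [default_config()]).
#' @return `read_config` returns the configuration list merged over the
#'   defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(cfg)) {
    if (is.list(cfg[[sec]]) && sec %in% names(base)) {
      for (k in names(cfg[[sec]])) base[[sec]][[k]] <- cfg[[sec]][[k]]
    } else {
      base[[sec]] <- cfg[[sec]]
    }
  }
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# per-stage seeds derived deterministically from the global seed
stage_seed <- function(config, stage) {
  stages <- c(simulate = 101L, render = 211L, track = 307L,
              metrics = 401L, te = 503L)
  base <- as.integer(config$seeds$global)
  (base * 1103L + stages[[stage]]) %% .Machine$integer.max
}

# run manifest: provenance for every pipeline output
write_manifest <- function(dir, config_path, config, stage, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("roboprey")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_file = config_path,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    global_seed = config$seeds$global,
    stage_seed = stage_seed(config, stage),
    outputs = outputs)
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
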
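#' Default project configuration
#'
#' Nested configuration covering all pipeline stages. `profile = "full"`
#' mirrors the reference protocol (10,000 records split 8000/1000/1000,
#' full-width network); `profile = "reduced"` is a desk-scale profile (250
#' records, coarser phantom grid, narrower network, larger learning rate)
#' preserving the 8:1:1 split and every architectural element.
#'
#' @param profile `"reduced"` or `"full"`.
#' @param master_seed Master seed fanned out to all random streams.
#' @return A named list of class `project_config`.
#' @export
default_project_config <- function(profile = c("reduced", "full"),
                                   master_seed = 1L) {
  profile <- match.arg(profile)
  reduced <- profile == "reduced"
  cfg <- list(
    profile = profile,
    master_seed = as.integer(master_seed),
    phantom = list(
      grid_shape = if (reduced) c(200L, 100L) else c(400L, 200L),
      cell_size = if (reduced) 0.4 else 0.2,
      liver_radius_range = c(50, 80),
      vessel_count_max = 10L,
      vessel_radius_range = c(3, 50),
      layer_count_range = c(6L, 10L),
      layer_zone_depth = 30,
      scatterer_count_max_per_unit_area = 10L,
      scatterer_density_range = c(800, 1200),
      probe_curvature_radius = 60
    ),
    probe = list(
      n_channels = 64L,
      angles = c(-7.2, -3.6, 0, 3.6, 7.2),
      center_frequency = 3.0,
      sampling_rate = 12.0,
      pulse_cycles = 3,
      curvature_radius = 60,
      pitch = 0.6
    ),
    network = list(
      encoder_widths = if (reduced) c(8, 12, 16) else c(16, 32, 64),
      encoder_kernel = 7L,
      residual = TRUE,
      bgn_conv_layers = 4L,
      bgn_fc_layers = 4L,
      bgn_conv_channels = if (reduced) 4L else 8L,
      bgn_fc_width = if (reduced) 16L else 32L,
      trunk_widths = if (reduced) c(12, 16) else c(64, 128),
      head_width = if (reduced) 16L else 32L,
      input_shape = c(5L, 16L, 128L),
      bmode_shape = c(32L, 32L)
    ),
    training = list(
      n_records = if (reduced) 250L else 10000L,
      l2_weight = 1e-4,
      lr = if (reduced) 1e-3 else 5e-6,
      epochs = if (reduced) 100L else 300L,
      batch_size = if (reduced) 16L else 32L,
      patience = 20L,
      min_epochs = if (reduced) 50L else 10L,
      min_delta = 1e-4,
      snr_db = 40
    ),
    stats = list(
      boot_n = 2000L,
      rho_ac_pdff = 0.9
    )
  )
  class(cfg) <- c("project_config", "list")
  cfg
}

#' Load and validate a project configuration file
#'
#' YAML key-value text; keys absent from the file take their defaults, and
#' unknown keys are rejected with their full path. An empty file yields the
#' default configuration.
#'
#' @param path YAML file path.
#' @param profile Base profile supplying the defaults.
#' @return A `project_config`.
#' @export
load_config <- function(path, profile = "reduced") {
  if (!file.exists(path)) stop_input("config file '%s' not found", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$profile)) profile <- user$profile
  base <- default_project_config(
    profile, master_seed = user$master_seed %||% 1L
  )
  merge_validate <- function(base, user, path_prefix) {
    for (nm in names(user)) {
      key <- if (path_prefix == "") nm else paste0(path_prefix, ".", nm)
      if (!nm %in% names(base)) {
        stop_config("unknown configuration key '%s'", key)
      }
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        if (!is.list(user[[nm]])) {
          stop_config("configuration key '%s' must be a section", key)
        }
        base[[nm]] <- merge_validate(base[[nm]], user[[nm]], key)
      } else {
        val <- user[[nm]]
        if (is.numeric(base[[nm]]) && !is.numeric(val)) {
          stop_config("configuration key '%s' must be numeric", key)
        }
        base[[nm]] <- if (is.integer(base[[nm]]) && is.numeric(val)) {
          as.integer(val)
        } else if (is.list(val) && is.numeric(base[[nm]])) {
          unlist(val)
        } else {
          val
        }
      }
    }
    base
  }
  cfg <- merge_validate(unclass(base), user, "")
  class(cfg) <- c("project_config", "list")
  cfg
}

#' Save a project configuration
#' @param config A `project_config`.
#' @param path Output YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration (stamped into run outputs)
#' @param config A `project_config` (or any list).
#' @return Short hex hash string.
#' @export
config_hash <- function(config) {
  canon <- rapply(unclass(config), function(x) {
    if (is.numeric(x)) signif(as.numeric(x), 12) else x
  }, how = "replace")
  substr(rlang::hash(canon), 1, 12)
}

#' @export
print.project_config <- function(x, ...) {
  cat(sprintf("<project_config> profile=%s, master_seed=%d, hash=%s\n",
              x$profile, x$master_seed, config_hash(x)))
  invisible(x)
}

# builders mapping config sections onto the module constructors
spec_from_config <- function(cfg, seed = cfg$master_seed) {
  do.call(phantom_spec, c(cfg$phantom, list(seed = seed)))
}

probe_from_config <- function(cfg) {
  do.call(probe_config, cfg$probe)
}

netconfig_from_config <- function(cfg, seed = cfg$master_seed) {
  do.call(network_config, c(cfg$network, list(seed = seed)))
}

trainconfig_from_config <- function(cfg, seed = cfg$master_seed) {
  tr <- cfg$training
  train_config(
    l2_weight = tr$l2_weight, lr = tr$lr, epochs = tr$epochs,
    batch_size = tr$batch_size, patience = tr$patience,
    min_epochs = tr$min_epochs %||% 10L, min_delta = tr$min_delta, seed = seed
  )
}

#' Emit a timestamped log line
#'
#' ISO-8601 timestamp, module name, seed and configuration hash precede the
#' message, so every run is attributable to (config hash, master seed).
#'
#' @param module Module name.
#' @param msg Message (sprintf-style with `...`).
#' @param seed Seed in effect.
#' @param hash Configuration hash in effect.
#' @param ... sprintf arguments.
#' @export
log_line <- function(module, msg, seed = NA, hash = "-", ...) {
  message(sprintf(
    "%s [%s] seed=%s cfg=%s %s",
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), module,
    as.character(seed), hash, sprintf(msg, ...)
  ))
  invisible(NULL)
}
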
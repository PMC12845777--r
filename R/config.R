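# YAML run configuration: the single source of truth for model, attention
# and training settings.  Loading fills defaults, validates every key with a
# precise error path, and round-trips exactly through save_config().

config_defaults <- function() list(
  model = list(nc = 12L, depth_multiple = 0.33, width_multiple = 0.50,
               input_size = 640L,
               attention_placement = c("P2", "P3", "P4", "P5")),
  attention = list(variant = "gefa", groups = 32L, local_grid = 5L,
                   reduction = NULL, gamma = 2, b = 2, min_k = 3L,
                   group_kernel = 3L, group_width_factor = 2.875,
                   share_mixer = TRUE),
  train = list(epochs = 300L, batch_size = 40L, lr = 0.01, momentum = 0.937,
               optimizer = "SGD", early_stop_patience = 100L,
               image_size = 640L),
  data = list(path = "data/synth"),
  seed = 0L,
  log_level = "info")

merge_config <- function(def, usr, path = character()) {
  for (key in names(usr)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(def))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(def[[key]]) && !is.null(names(def[[key]]))) {
      if (!is.list(usr[[key]]))
        stop("configuration key ", here, " must be a mapping", call. = FALSE)
      def[[key]] <- merge_config(def[[key]], usr[[key]], c(path, key))
    } else {
      def[key] <- list(usr[[key]])  # list() wrapper keeps explicit NULLs
    }
  }
  def
}

validate_config <- function(cfg) {
  chk <- function(ok, path, msg)
    if (!isTRUE(ok)) stop("invalid configuration at ", path, ": ", msg,
                          call. = FALSE)
  chk(cfg$model$nc >= 1, "model.nc", "must be >= 1")
  chk(cfg$model$depth_multiple > 0, "model.depth_multiple", "must be > 0")
  chk(cfg$model$width_multiple > 0, "model.width_multiple", "must be > 0")
  chk(cfg$model$input_size %% 32 == 0, "model.input_size",
      "must be divisible by 32")
  variants <- c("none", "se", "eca", "ca", "cbam", "mlca", "gefa")
  chk(cfg$attention$variant %in% variants, "attention.variant",
      paste("must be one of", paste(variants, collapse = "/")))
  chk(cfg$attention$local_grid >= 1, "attention.local_grid", "must be >= 1")
  chk(cfg$attention$group_kernel %% 2 == 1, "attention.group_kernel",
      "must be odd")
  chk(cfg$train$epochs >= 1, "train.epochs", "must be >= 1")
  chk(cfg$train$lr > 0, "train.lr", "must be > 0")
  chk(cfg$train$early_stop_patience <= cfg$train$epochs,
      "train.early_stop_patience", "must be <= train.epochs")
  cfg
}

#' Load (and validate) a YAML run configuration
#'
#' Unknown keys and invalid values fail with the offending key path;
#' missing keys are filled from the defaults (attention gamma = b = 2,
#' local grid 5, 300 epochs, lr 0.01, ...).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  usr <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  }
  cfg <- validate_config(merge_config(config_defaults(), usr))
  structure(cfg, class = "run_config")
}

#' @describeIn load_config write a configuration back to YAML.
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @describeIn load_config stable MD5 hash of the resolved configuration.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  save_config(cfg, tf)
  unname(tools::md5sum(tf))
}

#' @describeIn load_config build the [model_spec()] a configuration denotes.
#' @export
config_model_spec <- function(cfg) {
  a <- cfg$attention
  sp <- attention_spec(a$variant, groups = a$groups, local_grid = a$local_grid,
                       reduction = a$reduction,
                       kernel_policy = eca_policy(a$gamma, a$b, a$min_k),
                       group_kernel = a$group_kernel,
                       group_width_factor = a$group_width_factor,
                       share_mixer = a$share_mixer)
  model_spec(nc = cfg$model$nc, depth_multiple = cfg$model$depth_multiple,
             width_multiple = cfg$model$width_multiple,
             input_size = cfg$model$input_size, attention = sp,
             attention_placement = cfg$model$attention_placement)
}

#' @describeIn load_config build the [train_config()] a configuration
#'   denotes.
#' @export
config_train <- function(cfg) {
  t <- cfg$train
  train_config(epochs = t$epochs, batch_size = t$batch_size, lr = t$lr,
               momentum = t$momentum, optimizer = t$optimizer,
               early_stop_patience = t$early_stop_patience,
               image_size = t$image_size, seed = cfg$seed)
}
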
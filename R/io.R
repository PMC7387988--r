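# Trial containers are plain text: a directory with one CSV per trial
# (channels as rows, first column the electrode label) plus manifest.csv
# carrying trial id, label, cue index, rate and shape.

#' Write a trial container
#'
#' @param trials List of [raw_trial()]s.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_container <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    file <- sprintf("trial_%04d.csv", i)
    df <- data.frame(channel = tr$channel_names, tr$data, check.names = FALSE)
    names(df)[-1] <- paste0("t", seq_len(ncol(tr$data)))
    readr::write_csv(df, file.path(dir, file), progress = FALSE)
    tibble::tibble(trial_id = i, label = tr$label, cue_index = tr$cue_index,
                   rate = tr$rate, n_channels = nrow(tr$data),
                   n_timepoints = ncol(tr$data), file = file)
  })
  readr::write_csv(dplyr::bind_rows(rows), file.path(dir, "manifest.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read a trial container
#'
#' @param dir Directory written by [write_trial_container()].
#' @return List of [raw_trial()]s with a `labels` attribute.
#' @export
read_trial_container <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop_sfcnn("no manifest.csv in ", dir)
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- readr::read_csv(file.path(dir, manifest$file[i]),
                          show_col_types = FALSE, progress = FALSE)
    X <- as.matrix(df[, -1])
    dimnames(X) <- NULL
    if (nrow(X) != manifest$n_channels[i] || ncol(X) != manifest$n_timepoints[i]) {
      stop_sfcnn("trial ", manifest$trial_id[i], ": shape ",
                 nrow(X), "x", ncol(X), " does not match manifest")
    }
    raw_trial(X, rate = manifest$rate[i], cue_index = manifest$cue_index[i],
              label = manifest$label[i], channel_names = df[[1]])
  })
  attr(trials, "labels") <- manifest$label
  trials
}

#' Write one energy map as delimited text
#'
#' Channels in rows; one column per subband, headed by its band edges
#' (`"8-12"` etc.).
#'
#' @param map An `energy_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_map <- function(map, path) {
  df <- data.frame(channel = map$channel_names, map$values, check.names = FALSE)
  names(df)[-1] <- sprintf("%g-%g", map$band_edges[, 1], map$band_edges[, 2])
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an energy map written by [write_energy_map()]
#' @param path CSV path.
#' @param normalized Whether the stored values are normalized.
#' @return An `energy_map`.
#' @export
read_energy_map <- function(path, normalized = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  edges <- do.call(rbind, lapply(strsplit(names(df)[-1], "-", fixed = TRUE),
                                 as.numeric))
  colnames(edges) <- c("lo", "hi")
  new_energy_map(as.matrix(df[, -1]), df[[1]], edges, normalized = normalized)
}

# A map archive is one long CSV holding all trials' (unnormalized) maps.
write_map_archive <- function(maps, labels, path) {
  tbl <- dplyr::bind_rows(lapply(seq_along(maps), function(i) {
    dplyr::mutate(as_tibble(maps[[i]]), trial_id = i, label = labels[i],
                  .before = 1)
  }))
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

read_map_archive <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ids <- unique(tbl$trial_id)
  first <- tbl[tbl$trial_id == ids[1], ]
  channels <- unique(first$channel)
  edges <- unique(first[, c("band_lo", "band_hi")])
  edges <- as.matrix(edges); colnames(edges) <- c("lo", "hi")
  maps <- lapply(ids, function(id) {
    sub <- tbl[tbl$trial_id == id, ]
    new_energy_map(matrix(sub$energy, length(channels), nrow(edges)),
                   channels, edges)
  })
  attr(maps, "labels") <- vapply(ids, function(id) {
    tbl$label[tbl$trial_id == id][1]
  }, character(1))
  maps
}

#' Save a fitted model checkpoint
#'
#' Serializes the architecture descriptor, best parameters, class levels and
#' channel names to JSON (full double precision), so the model can be
#' reloaded and evaluated elsewhere.
#'
#' @param fit A `cnn_fit`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "cnn_fit"))
  payload <- list(
    variant = fit$spec$variant,
    n_channels = fit$spec$input_shape[1],
    n_bands = fit$spec$input_shape[2],
    dropout_rate = fit$spec$dropout_rate,
    classes = fit$classes,
    channel_names = fit$channel_names,
    best_iteration = fit$best_iteration,
    init_seed = fit$params$init_seed,
    params = lapply(param_list(fit$params), function(a) {
      list(dim = dim(a) %||% length(a), data = as.numeric(a))
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path JSON path.
#' @return List with `spec` (`network_spec`), `params` (`parameter_set`),
#'   `classes`, `channel_names`, `best_iteration`.
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- switch(x$variant,
                 base = build_base_network(x$n_channels, x$n_bands,
                                           dropout_rate = x$dropout_rate),
                 cv = build_cv_network(x$n_channels, x$n_bands,
                                       dropout_rate = x$dropout_rate),
                 stop_sfcnn("unknown variant ", x$variant))
  flat <- lapply(x$params, function(item) {
    if (length(item$dim) == 2L) matrix(item$data, item$dim[1], item$dim[2])
    else as.numeric(item$data)
  })
  nd <- length(spec$hidden) + 1L
  params <- structure(list(
    W1 = flat$W1, b1 = flat$b1, W2 = flat$W2, b2 = flat$b2,
    Wd = unname(flat[paste0("Wd", seq_len(nd))]),
    bd = unname(flat[paste0("bd", seq_len(nd))]),
    init_seed = x$init_seed
  ), class = "parameter_set")
  list(spec = spec, params = params, classes = x$classes,
       channel_names = x$channel_names, best_iteration = x$best_iteration)
}

# ---- run configuration ----------------------------------------------------

run_config_schema <- list(
  seed = NULL,
  simulate = c("n_channels", "rate", "duration", "cue_s", "erd_channels",
               "erd_band", "erd_depth", "rhythm_amplitude", "noise_scale",
               "noise_exponent", "n_per_class"),
  preprocess = c("low", "high", "width", "overlap", "window", "channels",
                 "normalization_scope"),
  model = c("variant", "dropout_rate"),
  train = c("optimizer", "learning_rate", "max_iterations"),
  split = c("mode", "n_train", "n_test", "n_val", "ordered", "folds")
)

#' Default run configuration
#'
#' The nested settings document consumed by the `cmd_*` pipeline commands
#' (and the `sfcnn.R` command-line script): simulation parameters, filterbank
#' and window, model variant, training options and the evaluation split.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_channels = 21L, rate = 1000, duration = 4, cue_s = 1,
                    erd_channels = 9L, erd_band = c(10, 14), erd_depth = 0.5,
                    rhythm_amplitude = 10, noise_scale = 5,
                    noise_exponent = 1, n_per_class = 140L),
    preprocess = list(low = 8, high = 30, width = 4, overlap = 2,
                      window = c(0.5, 2.5), channels = NULL,
                      normalization_scope = "train"),
    model = list(variant = "base", dropout_rate = 0.5),
    train = list(optimizer = "adam", learning_rate = NULL,
                 max_iterations = 2000L),
    split = list(mode = "fixed", n_train = 224L, n_test = 28L, n_val = 28L,
                 ordered = FALSE, folds = 10L)
  )
}

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown)) {
    stop_sfcnn("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (section in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[section]]), run_config_schema[[section]])
    if (length(bad)) {
      stop_sfcnn("unknown key(s) in config section '", section, "': ",
                 paste(bad, collapse = ", "))
    }
  }
  config
}

#' Read a YAML run configuration
#'
#' Missing sections fall back to [default_run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return Validated nested list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_run_config(user)
  config <- default_run_config()
  for (section in names(user)) {
    if (section == "seed") config$seed <- user$seed
    else for (key in names(user[[section]])) {
      config[[section]][[key]] <- user[[section]][[key]]
    }
  }
  config
}

#' Write a run configuration as YAML
#' @param config Nested list (validated against the known schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}
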
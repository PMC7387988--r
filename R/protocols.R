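#' Fixed train/test/validation split
#'
#' In `ordered` mode the partitions are sequential slices of the sample
#' order: the first `n_train` samples train, the following `n_test` test,
#' the last `n_val` validate (the 260/10/10 convention for a 280-trial
#' session). In random mode a seeded permutation is drawn first and then
#' sliced the same way (the small-session convention, e.g. 92/12/12).
#'
#' @param n Number of samples, or a list/vector whose length is used.
#' @param n_train,n_test,n_val Partition sizes; their sum must not exceed `n`.
#' @param ordered Slice in given order (`TRUE`) or after a seeded shuffle.
#' @param seed Seed for the random draw (ignored when `ordered`).
#' @return A `data_split`: list of integer index vectors `train`, `test`,
#'   `val`.
#' @examples
#' fixed_split(280, 260, 10, 10, ordered = TRUE)
#' @export
fixed_split <- function(n, n_train, n_test, n_val, ordered = FALSE, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L) n <- length(n)
  n <- as.integer(n)
  if (n_train < 1L || n_test < 1L || n_val < 1L) {
    stop_sfcnn("all partition sizes must be >= 1")
  }
  if (n_train + n_test + n_val > n) {
    stop_sfcnn("partition sizes ", n_train, "+", n_test, "+", n_val,
               " exceed n = ", n)
  }
  order_ <- if (ordered) seq_len(n) else {
    set.seed(substream_seed(seed, "split"))
    sample.int(n)
  }
  structure(list(
    train = sort_if(order_[seq_len(n_train)], ordered),
    test = sort_if(order_[n_train + seq_len(n_test)], ordered),
    val = sort_if(order_[n_train + n_test + seq_len(n_val)], ordered)
  ), class = "data_split")
}

sort_if <- function(x, ordered) if (ordered) x else sort(x)

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train %d / test %d / val %d\n",
              length(x$train), length(x$test), length(x$val)))
  invisible(x)
}

# Stratified fold assignment: within each class, indices are shuffled with
# the seeded generator and cut into `folds` contiguous blocks; fold k pools
# block k of every class, so folds are class-balanced and disjoint.
assign_folds <- function(f, folds, seed) {
  set.seed(substream_seed(seed, "folds"))
  fold_id <- integer(length(f))
  for (cl in levels(f)) {
    idx <- sample(which(f == cl))
    blocks <- as.integer(cut(seq_along(idx), folds, labels = FALSE))
    fold_id[idx] <- blocks
  }
  fold_id
}

#' 10-fold cross-validation of the decoding pipeline
#'
#' Folds are stratified by class. In each fold the held-out part is tested
#' once; the remaining nine parts are split 90/10 into training and
#' validation (validation count floored at 1). Normalization statistics are
#' re-fitted on each fold's training portion only and applied to that fold's
#' validation and test maps, so no information leaks from held-out samples
#' (set `fit_stats_on = "all"` for the literal all-sample normalization).
#'
#' @param maps List of unnormalized `energy_map`s.
#' @param labels Class labels, one per map.
#' @param spec A `network_spec` matching the map shape.
#' @param config A [train_config()]; each fold derives its own training seed
#'   from `seed`.
#' @param folds Number of folds (default 10).
#' @param seed Master seed for fold assignment and inner splits.
#' @param fit_stats_on `"train"` (leakage-safe, default) or `"all"`.
#' @return A `cv_result`: `$folds` tibble (fold, n_train, n_val, n_test,
#'   accuracy, flagged), `$mean_accuracy`, `$splits` (per-fold index lists).
#' @export
ten_fold_cv <- function(maps, labels, spec, config = train_config(),
                        folds = 10L, seed = 1L, fit_stats_on = c("train", "all")) {
  fit_stats_on <- match.arg(fit_stats_on)
  f <- as_class_factor(labels)
  n <- length(f)
  if (n < folds) stop_sfcnn("need at least ", folds, " samples")
  fold_id <- assign_folds(f, folds, seed)
  sizes <- tabulate(fold_id, folds)
  if (any(sizes == 0L)) {
    stop_sfcnn("fold(s) ", paste(which(sizes == 0L), collapse = ", "),
               " would hold no test samples with n = ", n,
               "; use fewer folds")
  }
  stats_all <- if (fit_stats_on == "all") fit_normalization(maps) else NULL

  rows <- vector("list", folds); splits <- vector("list", folds)
  for (k in seq_len(folds)) {
    test_idx <- which(fold_id == k)
    rest <- which(fold_id != k)
    set.seed(substream_seed(seed, paste0("inner-", k)))
    rest <- sample(rest)
    n_val <- max(1L, round(0.1 * length(rest)))
    val_idx <- sort(rest[seq_len(n_val)])
    train_idx <- sort(rest[-seq_len(n_val)])
    splits[[k]] <- list(train = train_idx, val = val_idx, test = test_idx)

    flagged <- nlevels(droplevels(f[train_idx])) < 2L
    if (flagged) {
      warning("fold ", k, ": a class is absent from the training portion")
    }
    stats <- stats_all %||% fit_normalization(maps[train_idx])
    norm <- function(ix) lapply(maps[ix], apply_normalization, stats = stats)
    fold_config <- config
    fold_config$seed <- substream_seed(seed, paste0("train-", k))
    fit <- train_network(spec, norm(train_idx), f[train_idx],
                         norm(val_idx), f[val_idx], fold_config)
    acc <- evaluate(fit, norm(test_idx), f[test_idx])
    rows[[k]] <- tibble::tibble(fold = k, n_train = length(train_idx),
                                n_val = length(val_idx),
                                n_test = length(test_idx),
                                accuracy = acc, flagged = flagged)
  }
  fold_tbl <- dplyr::bind_rows(rows)
  structure(list(folds = fold_tbl,
                 mean_accuracy = mean(fold_tbl$accuracy),
                 splits = splits, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean accuracy %.3f\n",
              nrow(x$folds), x$mean_accuracy))
  print(x$folds)
  invisible(x)
}

#' Per-fold results of a cross-validation
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @exportS3Method
tidy.cv_result <- function(x, ...) x$folds

#' One-row cross-validation summary
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with fold count, mean and standard deviation of accuracy.
#' @exportS3Method
glance.cv_result <- function(x, ...) {
  tibble::tibble(folds = nrow(x$folds),
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$folds$accuracy))
}

#' Class-conditional mean energy maps
#'
#' Cell-wise arithmetic mean of the maps in each class — the standard way of
#' visualizing where (channel, band) energy differs between motor imagery and
#' rest, e.g. the contralateral mu-band attenuation.
#'
#' @param maps List of `energy_map`s of identical shape.
#' @param labels Class labels, one per map; every class must be non-empty.
#' @return Named list with one mean `energy_map` per class.
#' @export
class_mean_maps <- function(maps, labels) {
  labels <- as.character(labels)
  if (length(labels) != length(maps)) {
    stop_sfcnn("need one label per map")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 1L) stop_sfcnn("no classes given")
  arr <- maps_to_array(maps)
  out <- lapply(classes, function(cl) {
    ix <- which(labels == cl)
    if (!length(ix)) stop_sfcnn("class ", cl, " is empty")
    m <- maps[[ix[1]]]
    new_energy_map(apply(arr[, , ix, drop = FALSE], c(1, 2), mean),
                   m$channel_names, m$band_edges, normalized = m$normalized)
  })
  names(out) <- classes
  out
}
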
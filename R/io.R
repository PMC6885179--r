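#' Read a cohort from tidy long-format CSV
#'
#' The data file has columns `patient_id`, `day` (integer `1..T`), `variable`
#' and `value`; a missing measurement is an absent row or an empty `value`.
#' The label file has columns `patient_id` and `label` (0/1). Day range and
#' variable names are validated; unknown variables are an error.
#'
#' @param data_path Path to the measurements CSV.
#' @param labels_path Path to the labels CSV.
#' @param variable_names Optional expected variable set (and order); defaults
#'   to the sorted distinct variables present.
#' @param T Optional number of days; defaults to the maximum day present.
#' @return An `elstm_cohort`.
#' @export
read_cohort_csv <- function(data_path, labels_path, variable_names = NULL,
                            T = NULL) {
  df <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "variable", "value")
  if (!all(need %in% names(df)))
    stop("data CSV must have columns patient_id, day, variable, value")
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% names(lab)))
    stop("label CSV must have columns patient_id, label")
  if (any(!lab$label %in% c(0, 1))) stop("labels must be 0 or 1")
  if (is.null(variable_names)) variable_names <- sort(unique(df$variable))
  unknown <- setdiff(unique(df$variable), variable_names)
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  if (is.null(T)) T <- max(df$day)
  if (any(df$day < 1 | df$day > T | df$day != round(df$day)))
    stop(sprintf("`day` must be an integer in [1, %d]", T))
  d <- length(variable_names)
  df$value <- suppressWarnings(as.numeric(df$value))
  patients <- lapply(seq_len(nrow(lab)), function(i) {
    pid <- as.character(lab$patient_id[i])
    rows <- df[df$patient_id == pid & !is.na(df$value), , drop = FALSE]
    v <- matrix(NA_real_, d, T, dimnames = list(variable_names, NULL))
    if (nrow(rows))
      v[cbind(match(rows$variable, variable_names), rows$day)] <- rows$value
    patient_series(pid, v, lab$label[i])
  })
  new_cohort(patients, variable_names)
}

#' Write a cohort to tidy long-format CSV
#'
#' Inverse of [read_cohort_csv()]: only observed entries are written, so
#' missingness round-trips. Files are written atomically (temp file + rename).
#'
#' @param cohort An `elstm_cohort`.
#' @param data_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, data_path, labels_path) {
  rows <- lapply(cohort$patients, function(p) {
    idx <- which(p$observed, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(patient_id = p$id, day = idx[, 2],
               variable = cohort$variable_names[idx[, 1]],
               value = p$values[idx])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$patient_id, df$day, df$variable), ]
  lab <- data.frame(patient_id = vapply(cohort$patients, `[[`, "", "id"),
                    label = cohort_labels(cohort))
  write_atomic <- function(d, path) {
    tmp <- paste0(path, ".tmp")
    utils::write.csv(d, tmp, row.names = FALSE, quote = FALSE)
    file.rename(tmp, path)
  }
  write_atomic(df, data_path)
  write_atomic(lab, labels_path)
  invisible(c(data_path, labels_path))
}

params_to_json_list <- function(p) {
  list(w_f = p$w_f, w_i = p$w_i, w_o = p$w_o, w_c = p$w_c,
       b_f = p$b_f, b_i = p$b_i, b_o = p$b_o, b_c = p$b_c,
       w_ho = p$w_ho, b_ho = p$b_ho, H = p$H, m = p$m)
}

params_from_json_list <- function(l) {
  H <- as.integer(l$H); m <- as.integer(l$m)
  as_mat <- function(x) matrix(as.numeric(unlist(x)), H, H + m, byrow = TRUE)
  structure(list(w_f = as_mat(l$w_f), w_i = as_mat(l$w_i),
                 w_o = as_mat(l$w_o), w_c = as_mat(l$w_c),
                 b_f = as.numeric(unlist(l$b_f)), b_i = as.numeric(unlist(l$b_i)),
                 b_o = as.numeric(unlist(l$b_o)), b_c = as.numeric(unlist(l$b_c)),
                 w_ho = as.numeric(unlist(l$w_ho)), b_ho = as.numeric(l$b_ho),
                 H = H, m = m),
            class = "lstm_params")
}

#' Save a fitted ensemble as a plain-text model bundle
#'
#' Writes a directory with a JSON manifest (configuration, gamma, variable
#' names, format version), the normalisation statistics, and one JSON
#' parameter file per base learner. Numbers are written at full precision, so
#' [load_elstm()] restores the model bit-for-bit; the bundle is loadable
#' without the training data.
#'
#' @param model A fitted [elstm()] model.
#' @param dir Output directory (created; must not already contain a bundle).
#' @return Invisibly, `dir`.
#' @export
save_elstm <- function(model, dir) {
  stopifnot(inherits(model, "elstm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 17 significant digits round-trip IEEE doubles exactly
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = I(17), null = "null")
  ts <- model$config$train_settings
  wj(list(format = "elstm-bundle-1",
          n_learners = length(model$learners),
          gamma = model$gamma,
          variable_names = model$variable_names,
          subset_size = length(model$learners[[1]]$variable_indices),
          master_seed = model$config$master_seed,
          train_settings = unclass(ts)),
     "manifest.json")
  wj(list(mean = model$stats$mean, std = model$stats$std,
          variable_names = model$stats$variable_names), "stats.json")
  for (p in seq_along(model$learners)) {
    l <- model$learners[[p]]
    wj(list(variable_indices = l$variable_indices, seed = l$seed,
            params = params_to_json_list(l$params)),
       sprintf("learner_%04d.json", p))
  }
  invisible(dir)
}

#' Load a model bundle written by [save_elstm()]
#'
#' @param dir Bundle directory.
#' @return An `elstm` object (without training scores/labels).
#' @export
load_elstm <- function(dir) {
  rj <- function(f) jsonlite::read_json(file.path(dir, f))
  man <- rj("manifest.json")
  if (!identical(man$format, "elstm-bundle-1"))
    stop("not an elstm model bundle: ", dir)
  st <- rj("stats.json")
  stats <- structure(list(mean = as.numeric(unlist(st$mean)),
                          std = as.numeric(unlist(st$std)),
                          variable_names = as.character(unlist(st$variable_names))),
                     class = "norm_stats")
  learners <- lapply(seq_len(man$n_learners), function(p) {
    l <- rj(sprintf("learner_%04d.json", p))
    list(params = params_from_json_list(l$params),
         variable_indices = as.integer(unlist(l$variable_indices)),
         seed = as.integer(l$seed))
  })
  tsl <- man$train_settings
  ts <- train_settings(hidden_units = tsl$hidden_units,
                       dropout_rate = tsl$dropout_rate,
                       learning_rate = tsl$learning_rate,
                       max_epochs = tsl$max_epochs,
                       validation_fraction = tsl$validation_fraction,
                       early_stop = isTRUE(tsl$early_stop),
                       batch_size = tsl$batch_size,
                       beta1 = tsl$beta1, beta2 = tsl$beta2,
                       adam_eps = tsl$adam_eps, seed = tsl$seed)
  config <- elstm_config(n_learners = man$n_learners,
                         subset_size = man$subset_size,
                         train_settings = ts,
                         master_seed = man$master_seed)
  config$train_settings$early_stop <- isTRUE(tsl$early_stop)
  structure(list(learners = learners, stats = stats,
                 gamma = as.numeric(man$gamma),
                 variable_names = as.character(unlist(man$variable_names)),
                 config = config, labels = NULL, fitted = NULL,
                 call = quote(load_elstm(dir))),
            class = "elstm")
}
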
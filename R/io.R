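# Plain-text I/O: configs (YAML/JSON), connectivity matrices (TSV + JSON
# sidecar), recordings (one TSV per segment + manifest), experiment outputs.

#' Read a population configuration from YAML or JSON
#'
#' The file holds the fields of [population_config()] (unknown fields are an
#' error so typos fail loudly).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"population_config"`.
#' @export
read_population_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fields <- switch(ext,
                   yaml = ,
                   yml = yaml::read_yaml(path),
                   json = jsonlite::read_json(path, simplifyVector = TRUE),
                   stop_config("unsupported config format '.%s'", ext))
  known <- names(formals(population_config))
  bad <- setdiff(names(fields), known)
  if (length(bad))
    stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(population_config, fields)
}

#' Write a population configuration
#'
#' @param config A [population_config()].
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_population_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
         yaml = ,
         yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
         stop_config("unsupported config format '.%s'", ext))
  invisible(path)
}

#' Write a connectivity matrix as labelled TSV with a JSON sidecar
#'
#' The matrix goes to `path` as a tab-separated table with channel names as
#' header and row names; method, band and epoch count go to `<path>.json`.
#'
#' @param cm A `"connectivity_matrix"`.
#' @param path Destination `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$weights, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(list(method = cm$method, band = cm$band,
                            n_epochs_used = cm$n_epochs_used),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity_matrix()]
#'
#' @param path Path to the `.tsv` file (sidecar `<path>.json` must exist).
#' @return A `"connectivity_matrix"`.
#' @export
read_connectivity_matrix <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_connectivity_matrix(w, meta$method, as.numeric(meta$band),
                          as.integer(meta$n_epochs_used))
}

#' Write a continuous recording to a directory
#'
#' One TSV (samples x channels) per segment plus a `manifest.csv` recording
#' subject, session, segment durations and sampling rate.
#'
#' @param recording A `"continuous_recording"`.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "continuous_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("segment_%03d.tsv", seq_along(recording$segments))
  for (i in seq_along(recording$segments))
    utils::write.table(t(recording$segments[[i]]), file.path(dir, files[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = channel_names(recording$n_channels))
  manifest <- data.frame(
    file = files,
    subject_id = recording$subject_id,
    session_id = recording$session_id,
    duration_s = vapply(recording$segments, ncol, integer(1)) /
      recording$sampling_rate,
    sampling_rate = recording$sampling_rate)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing segment TSVs and `manifest.csv`.
#' @return A `"continuous_recording"`.
#' @export
read_recording <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  segments <- lapply(manifest$file, function(f) {
    t(as.matrix(utils::read.table(file.path(dir, f), sep = "\t",
                                  header = TRUE, check.names = FALSE)))
  })
  new_continuous_recording(manifest$subject_id[1], manifest$session_id[1],
                           segments, manifest$sampling_rate[1])
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result), file.path(dir, "reliability.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(experiment_scores(result)),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  excl <- experiment_exclusions(result)
  if (!is.null(excl) && nrow(excl))
    utils::write.csv(as.data.frame(excl), file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  cfg <- attr(result, "config")
  yaml::write_yaml(list(config = unclass(cfg), seed = attr(result, "seed")),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
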
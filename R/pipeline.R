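# End-to-end two-session reliability experiment:
# simulate -> segment/select -> spectra -> connectivity -> metrics -> ICC.

GRAPH_METRICS <- c("C_w", "C_w_norm", "L_w", "L_w_norm", "SWI")
ALL_METRICS <- c("whole_brain", GRAPH_METRICS)

metric_rows_for_set <- function(set, methods, metrics, band, n_surrogates,
                                seed, approach, n_sel, len) {
  coeffs <- fourier_coefficients(set)
  purrr::map_dfr(methods, function(method) {
    cm <- switch(method,
                 pli = pli_matrix(coeffs, band),
                 dbwpli = dbwpli_matrix(coeffs, band),
                 wpli = wpli_matrix(coeffs, band),
                 stop_config("unknown method '%s'", method))
    vals <- list()
    if ("whole_brain" %in% metrics)
      vals$whole_brain <- whole_brain(cm)
    want_graph <- intersect(metrics, GRAPH_METRICS)
    if (length(want_graph)) {
      gm <- surrogate_normalise(
        cm$weights, n_surrogates = n_surrogates,
        seed = substream_seed(seed, "surrogates", set$subject_id,
                              set$session_id, approach, n_sel,
                              round(100 * len), method),
        absolute = TRUE)
      for (g in want_graph) vals[[g]] <- gm[[g]]
    }
    tibble::tibble(subject_id = set$subject_id, session_id = set$session_id,
                   approach = approach, n_epochs = n_sel, epoch_length = len,
                   method = method, metric = names(vals),
                   value = unlist(vals, use.names = FALSE))
  })
}

session_scores <- function(rec, schemes, methods, metrics, band, n_surrogates,
                           seed, selection) {
  scores <- list()
  exclusions <- list()
  note_exclusion <- function(combos, avail) {
    exclusions[[length(exclusions) + 1L]] <<- tibble::tibble(
      subject_id = rec$subject_id, session_id = rec$session_id,
      approach = combos$approach, n_epochs = combos$n_epochs,
      epoch_length = combos$epoch_length, available = avail)
  }
  add <- function(rows) scores[[length(scores) + 1L]] <<- rows

  for (app in unique(schemes$approach)) {
    combos <- schemes[schemes$approach == app, ]
    if (app == "constant_amount") {
      es6 <- cut_epochs(rec, 6)
      parents <- max(combos$n_epochs[combos$epoch_length == 6], 20L)
      if (n_epochs(es6) < parents) {
        note_exclusion(combos, n_epochs(es6))
        next
      }
      sel6 <- sample_epochs(es6, parents,
                            substream_seed(seed, "select", rec$subject_id,
                                           rec$session_id, app))
      for (i in seq_len(nrow(combos))) {
        len <- combos$epoch_length[i]
        set <- if (len == 6) sel6 else nested_resegment(sel6, len)
        add(metric_rows_for_set(set, methods, metrics, band, n_surrogates,
                                seed, app, combos$n_epochs[i], len))
      }
    } else {
      for (len in unique(combos$epoch_length)) {
        sub <- combos[combos$epoch_length == len, ]
        sub <- sub[order(sub$n_epochs), ]
        es <- cut_epochs(rec, len)
        avail <- n_epochs(es)
        feasible <- sub$n_epochs <= avail
        if (any(!feasible)) note_exclusion(sub[!feasible, ], avail)
        sub <- sub[feasible, ]
        if (!nrow(sub)) next
        if (selection == "nested") {
          # common-random-number sweep: one draw at the largest feasible n,
          # smaller n's use its prefix, so ICC differences across n are paired
          sel_max <- sample_epochs(es, max(sub$n_epochs),
                                   substream_seed(seed, "select",
                                                  rec$subject_id,
                                                  rec$session_id, app,
                                                  round(100 * len)))
          for (i in seq_len(nrow(sub))) {
            n_sel <- sub$n_epochs[i]
            set <- new_epoch_set(sel_max$subject_id, sel_max$session_id,
                                 sel_max$epoch_length,
                                 sel_max$epochs[seq_len(n_sel)],
                                 sel_max$sampling_rate,
                                 sel_max$selection_seed)
            add(metric_rows_for_set(set, methods, metrics, band,
                                    n_surrogates, seed, app, n_sel, len))
          }
        } else {
          for (i in seq_len(nrow(sub))) {
            n_sel <- sub$n_epochs[i]
            set <- sample_epochs(es, n_sel,
                                 substream_seed(seed, "select",
                                                rec$subject_id,
                                                rec$session_id, app,
                                                round(100 * len), n_sel))
            add(metric_rows_for_set(set, methods, metrics, band,
                                    n_surrogates, seed, app, n_sel, len))
          }
        }
      }
    }
  }
  list(scores = dplyr::bind_rows(scores), exclusions = dplyr::bind_rows(exclusions))
}

#' Run the full two-session reliability experiment
#'
#' Simulates (or reuses) a two-session study, applies the requested
#' epoch-segmentation schemes with random epoch selection, computes PLI
#' and/or dbWPLI connectivity in the analysis band, reduces each matrix to
#' whole-brain connectivity and surrogate-normalised graph metrics, and
#' estimates ICC(3,1) across subjects for every
#' (scheme x method x metric) cell. Subjects without enough epochs for a
#' combination are excluded from that combination only; cells with fewer
#' than 3 surviving subjects are kept as rows with `NA` estimates.
#'
#' @param config A [population_config()].
#' @param schemes Tibble of combinations as from [segmentation_schemes()].
#' @param methods Subset of `c("dbwpli", "pli", "wpli")`.
#' @param metrics Subset of `c("whole_brain", "C_w", "C_w_norm", "L_w",
#'   "L_w_norm", "SWI")`. Graph metrics use absolute weights and surrogate
#'   normalisation; restricting to `"whole_brain"` is much faster.
#' @param band Analysis band in Hz (inclusive endpoints).
#' @param n_surrogates Surrogates per matrix for graph-metric normalisation.
#' @param seed Seed for selection/surrogate streams (defaults to
#'   `config$seed`; simulation uses `config$seed`).
#' @param selection `"independent"` draws epochs afresh for every
#'   combination (the reference behaviour); `"nested"` reuses one draw per
#'   epoch length and takes prefixes, pairing the sweep across epoch numbers.
#' @param study Optional pre-simulated study tibble from [simulate_study()].
#' @param output_dir If non-`NULL`, write `reliability.csv`, `scores.csv`,
#'   `exclusions.csv` and `manifest.yaml` there.
#' @return A `"reliability_table"`: tibble with one row per
#'   scheme x method x metric (columns `approach`, `n_epochs`,
#'   `epoch_length`, `method`, `metric`, `icc`, `icc_clipped`, `ci_low`,
#'   `ci_high`, `p_value`, `n_subjects`, `category`), with the per-subject
#'   `scores` and `exclusions` tibbles and the `config` attached as
#'   attributes (see [experiment_scores()]).
#' @examples
#' \donttest{
#' cfg <- population_config(n_subjects = 6, n_channels = 8,
#'                          sampling_rate = 64, segment_lengths = c(20, 16))
#' run_experiment(cfg,
#'                schemes = tibble::tibble(approach = "short_epochs",
#'                                         n_epochs = c(10L, 20L),
#'                                         epoch_length = 1),
#'                methods = "dbwpli", metrics = "whole_brain")
#' }
#' @export
run_experiment <- function(config,
                           schemes = segmentation_schemes("all"),
                           methods = c("dbwpli", "pli"),
                           metrics = c("whole_brain", "C_w_norm", "L_w_norm",
                                       "SWI"),
                           band = c(6, 8),
                           n_surrogates = 100,
                           seed = config$seed,
                           selection = c("independent", "nested"),
                           study = NULL,
                           output_dir = NULL) {
  stopifnot(inherits(config, "population_config"))
  selection <- match.arg(selection)
  methods <- match.arg(methods, c("dbwpli", "pli", "wpli"), several.ok = TRUE)
  if (!all(metrics %in% ALL_METRICS))
    stop_config("unknown metric(s): %s",
                paste(setdiff(metrics, ALL_METRICS), collapse = ", "))
  stopifnot(all(c("approach", "n_epochs", "epoch_length") %in% names(schemes)))
  if (is.null(study)) study <- simulate_study(config)

  per_session <- purrr::map(study$recording, session_scores,
                            schemes = schemes, methods = methods,
                            metrics = metrics, band = band,
                            n_surrogates = n_surrogates, seed = seed,
                            selection = selection)
  scores <- dplyr::bind_rows(purrr::map(per_session, "scores"))
  exclusions <- dplyr::bind_rows(purrr::map(per_session, "exclusions"))

  reliability <- reliability_from_scores(scores)
  # keep a row for every requested cell, even if unavailable
  grid <- tidyr::expand_grid(
    dplyr::distinct(schemes[c("approach", "n_epochs", "epoch_length")]),
    method = methods, metric = metrics)
  if (nrow(reliability) == 0)
    reliability <- dplyr::bind_cols(grid[0, ], reliability)
  reliability <- dplyr::left_join(
    grid, reliability,
    by = c("approach", "n_epochs", "epoch_length", "method", "metric"))
  # cells whose every subject was excluded never reach the ICC stage
  reliability$n_subjects[is.na(reliability$n_subjects)] <- 0L

  out <- tibble::new_tibble(reliability, class = "reliability_table")
  attr(out, "scores") <- scores
  attr(out, "exclusions") <- exclusions
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

#' ICC table from a long table of per-subject scores
#'
#' Groups a score table (columns `subject_id`, `session_id`, plus any cell
#' identifiers such as `approach`, `n_epochs`, `epoch_length`, `method`,
#' `metric`, and `value`) by the identifier columns, keeps subjects with both
#' sessions, and fits [icc_3_1()] per cell. Cells with fewer than 3 complete
#' subjects yield `NA` estimates.
#'
#' @param scores Long tibble of per-subject, per-session metric values.
#' @return Tibble with ICC estimate, CI, p-value, category and `n_subjects`
#'   per cell.
#' @export
reliability_from_scores <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0) {
    return(tibble::tibble(icc = numeric(), icc_clipped = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p_value = numeric(), n_subjects = integer(),
                          category = factor(character(),
                                            RELIABILITY_LEVELS,
                                            ordered = TRUE)))
  }
  cell_cols <- setdiff(names(scores), c("subject_id", "session_id", "value"))
  dplyr::group_modify(
    dplyr::group_by(scores, dplyr::across(dplyr::all_of(cell_cols))),
    function(d, key) {
      wide_ok <- dplyr::filter(dplyr::add_count(d, .data$subject_id),
                               .data$n == 2)
      n_complete <- length(unique(wide_ok$subject_id))
      if (n_complete < 3) {
        return(tibble::tibble(icc = NA_real_, icc_clipped = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p_value = NA_real_, n_subjects = n_complete,
                              category = factor(NA, RELIABILITY_LEVELS,
                                                ordered = TRUE)))
      }
      fit <- icc_3_1(wide_ok)
      tibble::tibble(icc = fit$icc, icc_clipped = fit$icc_clipped,
                     ci_low = fit$ci_low, ci_high = fit$ci_high,
                     p_value = fit$p_value, n_subjects = fit$n_subjects,
                     category = fit$category)
    }) |> dplyr::ungroup()
}

#' Per-subject scores of a reliability experiment
#'
#' @param x A `"reliability_table"` from [run_experiment()].
#' @return The long tibble of per-subject, per-session metric values.
#' @export
experiment_scores <- function(x) attr(x, "scores")

#' Per-scheme subject exclusions of a reliability experiment
#'
#' @param x A `"reliability_table"` from [run_experiment()].
#' @return Tibble of subject x scheme combinations skipped for lack of
#'   epochs, with the available count.
#' @export
experiment_exclusions <- function(x) attr(x, "exclusions")

#' @export
print.reliability_table <- function(x, ...) {
  cat(sprintf("# Reliability table: %d cells (%s)\n", nrow(x),
              paste(unique(x$method), collapse = ", ")))
  NextMethod()
}
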
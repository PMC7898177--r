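# CSV I/O for trial-level records and reputation ratings, with schema
# validation and an optional column-mapping adapter for externally
# formatted data.

.trial_columns <- c("participant", "cell_rep", "cell_strategy",
                    "cell_emotion", "round", "participant_move",
                    "counterpart_move", "outcome", "expression",
                    "participant_payoff", "counterpart_payoff")

#' Write / read trial-level records
#'
#' The trial CSV schema has columns \code{participant, cell_rep,
#' cell_strategy, cell_emotion, round, participant_move, counterpart_move,
#' outcome, expression, participant_payoff, counterpart_payoff}; moves are
#' serialized as C/D and outcomes as CC/CD/DC/DD. Reading validates labels
#' and the consistency of each outcome with its two moves. A header-only
#' file reads as an empty dataset.
#'
#' @param dataset an \code{\link{experiment_dataset}} or a trials data
#'   frame.
#' @param path CSV path.
#' @param column_map optional named character vector mapping schema column
#'   names to the names used in the file (adapter for external data, e.g.
#'   \code{c(participant = "subject_id")}).
#' @return \code{write_trials}: \code{path} invisibly; \code{read_trials}:
#'   a trials data frame in the schema.
#' @export
write_trials <- function(dataset, path) {
  tr <- if (is.data.frame(dataset)) dataset else dataset$trials
  stopifnot(all(.trial_columns %in% names(tr)))
  utils::write.csv(tr[.trial_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("trials file not found: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      file_name <- column_map[[schema_name]]
      if (!file_name %in% names(tr)) {
        stop("mapped column not in file: ", file_name)
      }
      names(tr)[names(tr) == file_name] <- schema_name
    }
  }
  missing <- setdiff(.trial_columns, names(tr))
  if (length(missing)) {
    stop("trials file missing column(s): ", paste(missing, collapse = ", "))
  }
  tr <- tr[.trial_columns]
  if (nrow(tr) == 0L) return(tr)
  check_outcomes(tr$outcome)
  if (!all(tr$participant_move %in% c("C", "D")) ||
      !all(tr$counterpart_move %in% c("C", "D"))) {
    stop("moves must be C or D")
  }
  implied <- outcome_from_moves(tr$participant_move, tr$counterpart_move)
  bad <- which(implied != tr$outcome)
  if (length(bad)) {
    stop("outcome inconsistent with moves in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  badex <- setdiff(unique(tr$expression), expressions)
  if (length(badex)) {
    stop("unknown expression label(s): ", paste(badex, collapse = ", "))
  }
  badrep <- setdiff(unique(tr$cell_rep), reputation_labels)
  if (length(badrep)) {
    stop("unknown reputation label(s): ", paste(badrep, collapse = ", "))
  }
  tr
}

#' Write / read per-participant reputation ratings
#'
#' Ratings CSV schema: \code{participant, initial_rating, final_rating},
#' both ratings on the -50..+50 scale.
#'
#' @param dataset an \code{\link{experiment_dataset}} or a ratings data
#'   frame.
#' @param path CSV path.
#' @param column_map optional named character vector as in
#'   \code{\link{read_trials}}.
#' @return \code{write_ratings}: \code{path} invisibly;
#'   \code{read_ratings}: a ratings data frame.
#' @export
write_ratings <- function(dataset, path) {
  rt <- if (is.data.frame(dataset)) dataset else dataset$ratings
  cols <- c("participant", "initial_rating", "final_rating")
  stopifnot(all(cols %in% names(rt)))
  utils::write.csv(rt[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      file_name <- column_map[[schema_name]]
      if (!file_name %in% names(rt)) {
        stop("mapped column not in file: ", file_name)
      }
      names(rt)[names(rt) == file_name] <- schema_name
    }
  }
  cols <- c("participant", "initial_rating", "final_rating")
  missing <- setdiff(cols, names(rt))
  if (length(missing)) {
    stop("ratings file missing column(s): ", paste(missing, collapse = ", "))
  }
  rt <- rt[cols]
  if (nrow(rt) &&
      (any(rt$initial_rating < -50 | rt$initial_rating > 50) ||
       any(rt$final_rating < -50 | rt$final_rating > 50))) {
    stop("ratings must lie in [-50, 50]")
  }
  rt
}

#' Assemble a dataset from trial and rating tables
#'
#' Wraps externally loaded (or freshly read) tables into the
#' \code{experiment_dataset} structure so the analysis functions can be
#' applied to them.
#'
#' @param trials trials data frame in the schema.
#' @param ratings ratings data frame.
#' @param config configuration used for model-based reconstructions
#'   (defaults to the shipped configuration).
#' @return An \code{\link{experiment_dataset}}.
#' @export
as_experiment_dataset <- function(trials, ratings,
                                  config = default_config()) {
  stopifnot(all(.trial_columns %in% names(trials)))
  stopifnot(all(c("participant", "initial_rating", "final_rating") %in%
                  names(ratings)))
  if (!setequal(unique(trials$participant), ratings$participant)) {
    stop("trials and ratings cover different participants")
  }
  rounds <- max(trials$round)
  structure(list(trials = trials, ratings = ratings, config = config,
                 n_per_cell = NA_integer_, rounds = rounds,
                 seed = NA_integer_),
            class = "experiment_dataset")
}
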
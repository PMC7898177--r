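# Counterpart agents, synthetic participants, and the 3x2x3 factorial
# experiment runner (the package's synthetic-data generator).

#' Design factor level sets
#'
#' Levels of the between-participants factors in their canonical order:
#' reputation (negative, unknown, positive), strategy (extortion, generous),
#' emotion (competitive, neutral, cooperative).
#'
#' @name design_levels
#' @format Character vectors.
NULL

#' @rdname design_levels
#' @export
strategy_labels <- c("extortion", "generous")

#' Counterpart cell specification
#'
#' One of the 18 cells of the factorial design: an initial reputation label,
#' a strategy label, and an emotion profile.
#'
#' @param reputation \code{"negative"}, \code{"unknown"} or \code{"positive"}.
#' @param strategy \code{"extortion"} or \code{"generous"}.
#' @param emotion \code{"competitive"}, \code{"neutral"} or
#'   \code{"cooperative"}.
#' @return Object of class \code{counterpart_spec}.
#' @export
counterpart_spec <- function(reputation, strategy, emotion) {
  reputation <- match.arg(reputation, reputation_labels)
  strategy <- match.arg(strategy, strategy_labels)
  emotion <- match.arg(emotion, emotion_profiles)
  structure(list(reputation = reputation, strategy = strategy,
                 emotion = emotion), class = "counterpart_spec")
}

#' All 18 design cells
#'
#' @return Data frame with columns \code{cell_rep}, \code{cell_strategy},
#'   \code{cell_emotion} in the canonical cell order (reputation varying
#'   slowest).
#' @export
design_cells <- function() {
  g <- expand.grid(cell_emotion = emotion_profiles,
                   cell_strategy = strategy_labels,
                   cell_rep = reputation_labels,
                   stringsAsFactors = FALSE)
  g[, c("cell_rep", "cell_strategy", "cell_emotion")]
}

#' Build a playable counterpart agent
#'
#' Binds a design cell to its configured strategy vector and display policy.
#' The returned agent samples its next move from the memory-one conditional
#' probabilities (using R's RNG) and reports the expression it displays
#' after an outcome.
#'
#' @param spec a \code{\link{counterpart_spec}} (or a list with the same
#'   fields).
#' @param config configuration list (see \code{\link{default_config}}).
#' @return List with the bound \code{strategy}
#'   (\code{\link{memory_one_strategy}}), the cell labels, and closures
#'   \code{next_move(prev_outcome)} (outcome from the agent's own
#'   perspective; \code{NULL} for the first round) and
#'   \code{display(outcome)} (agent's own perspective).
#' @export
make_counterpart <- function(spec, config = default_config()) {
  spec <- counterpart_spec(spec$reputation, spec$strategy, spec$emotion)
  sv <- config$strategies[[spec$strategy]]
  if (is.null(sv)) stop("no strategy vector configured for ", spec$strategy)
  strat <- memory_one_strategy(as.numeric(sv), p0 = config$strategies$p0,
                               name = spec$strategy)
  policy <- display_policy(config$display_policy)
  list(
    spec = spec,
    strategy = strat,
    next_move = function(prev_outcome = NULL) {
      pr <- if (is.null(prev_outcome)) strat$p0 else {
        check_outcomes(prev_outcome)
        strat$p[prev_outcome]
      }
      if (stats::runif(1) < pr) "C" else "D"
    },
    display = function(outcome) display_for(spec$emotion, outcome, policy)
  )
}

#' Synthetic-participant model
#'
#' Coefficients of the logistic cooperation model and the two rating
#' equations (see \code{\link{default_config}} for the meaning and defaults
#' of each field).
#'
#' @param b0,b_rep,b_recip,b_emo,b_round cooperation coefficients (log-odds).
#' @param a_rep,sigma_a initial-rating slope and noise SD (rating points).
#' @param w_rep,w_coop,w_emo,sigma_w final-rating weights and noise SD.
#' @return Object of class \code{participant_model}.
#' @export
participant_model <- function(b0 = 0, b_rep = 0, b_recip = 0, b_emo = 0,
                              b_round = 0, a_rep = 0, sigma_a = 0,
                              w_rep = 0, w_coop = 0, w_emo = 0, sigma_w = 0) {
  coefs <- c(b0 = b0, b_rep = b_rep, b_recip = b_recip, b_emo = b_emo,
             b_round = b_round, a_rep = a_rep, w_rep = w_rep,
             w_coop = w_coop, w_emo = w_emo)
  if (!all(is.finite(coefs))) stop("all coefficients must be finite")
  if (sigma_a < 0 || sigma_w < 0) stop("noise SDs must be >= 0")
  structure(c(as.list(coefs), list(sigma_a = sigma_a, sigma_w = sigma_w)),
            class = "participant_model")
}

#' Cooperation probability of the participant model
#'
#' \code{logistic(b0 + b_rep * rep + b_recip * last + b_emo * valence +
#' b_round * (round - 1))}. On round 1 the caller passes \code{last = 0} and
#' \code{valence = 0}, so only the reputation prior moves the first choice.
#'
#' @param model a \code{\link{participant_model}}.
#' @param rep_code numeric reputation code (see
#'   \code{\link{reputation_code}}).
#' @param last_move opponent's previous move coded +1 (cooperated) / -1
#'   (defected), 0 on round 1.
#' @param valence cumulative mean emotion valence observed so far, in
#'   [-1, 1]; 0 on round 1.
#' @param round round number, >= 1.
#' @return Probability of cooperating.
#' @examples
#' m <- participant_model(b_rep = 1)
#' cooperation_probability(m, rep_code = 1, 0, 0, round = 1)  # plogis(1)
#' @export
cooperation_probability <- function(model, rep_code, last_move, valence,
                                    round) {
  stopifnot(inherits(model, "participant_model"), round >= 1,
            abs(valence) <= 1 + 1e-12)
  stats::plogis(model$b0 + model$b_rep * rep_code +
                  model$b_recip * last_move + model$b_emo * valence +
                  model$b_round * (round - 1))
}

clip_rating <- function(x) pmin(50, pmax(-50, x))

#' Simulate one participant against a counterpart
#'
#' Runs the iterated match, recording moves, outcomes, expressions and
#' payoffs, plus the pre- and post-task reputation ratings on the -50..+50
#' scale. The initial rating is \code{a_rep * rep_scale} times the symmetric
#' reputation code (so an unknown counterpart starts at the scale midpoint)
#' plus Gaussian noise; the final rating weighs the behavioral reputation
#' code, the counterpart's observed cooperation frequency (centered at 0.5)
#' and the mean observed emotion valence, plus noise; both are clipped to
#' the slider range.
#'
#' @param model a \code{\link{participant_model}}.
#' @param spec a \code{\link{counterpart_spec}}.
#' @param config configuration list.
#' @param rounds number of rounds.
#' @param participant_id id recorded in the output rows.
#' @return List with \code{trials} (one data.frame row per round, trial CSV
#'   schema) and \code{ratings} (one-row data.frame: participant,
#'   initial_rating, final_rating).
#' @export
run_participant <- function(model, spec, config = default_config(),
                            rounds = config$design$rounds,
                            participant_id = 1L) {
  stopifnot(rounds >= 1)
  agent <- make_counterpart(spec, config)
  policy <- display_policy(config$display_policy)
  pm <- do.call(payoff_matrix, stats::setNames(
    as.list(as.numeric(config$payoffs[c("T", "R", "P", "S")])),
    c("temptation", "reward", "punishment", "sucker")))
  fv <- payoff_vectors(pm)
  rep_beh <- reputation_code(spec$reputation, config$participant$rep_coding)
  rep_sym <- reputation_code(spec$reputation, "symmetric")

  initial <- clip_rating(model$a_rep * rep_sym * config$participant$rep_scale +
                           stats::rnorm(1, 0, model$sigma_a))

  pmove <- cmove <- outcome <- expression <- character(rounds)
  valence <- numeric(rounds)
  last <- 0; vmean <- 0; prev_outcome <- NULL
  for (t in seq_len(rounds)) {
    p_coop <- cooperation_probability(model, rep_beh, last, vmean, t)
    pmove[t] <- if (stats::runif(1) < p_coop) "C" else "D"
    cmove[t] <- agent$next_move(prev_outcome)
    outcome[t] <- outcome_from_moves(pmove[t], cmove[t])
    cp_outcome <- swap_perspective(outcome[t])  # counterpart's perspective
    expression[t] <- agent$display(cp_outcome)
    valence[t] <- emotion_valence(cp_outcome, expression[t], policy)
    vmean <- mean(valence[seq_len(t)])
    last <- if (cmove[t] == "C") 1 else -1
    prev_outcome <- cp_outcome
  }
  coop_freq <- mean(cmove == "C")
  final <- clip_rating(model$w_rep * rep_beh +
                         model$w_coop * (coop_freq - 0.5) +
                         model$w_emo * mean(valence) +
                         stats::rnorm(1, 0, model$sigma_w))
  trials <- data.frame(
    participant = participant_id,
    cell_rep = spec$reputation, cell_strategy = spec$strategy,
    cell_emotion = spec$emotion,
    round = seq_len(rounds),
    participant_move = pmove, counterpart_move = cmove,
    outcome = outcome, expression = expression,
    participant_payoff = unname(fv$fX[outcome]),
    counterpart_payoff = unname(fv$fY[outcome]),
    stringsAsFactors = FALSE)
  ratings <- data.frame(participant = participant_id,
                        initial_rating = initial, final_rating = final)
  list(trials = trials, ratings = ratings)
}

# Deterministic sub-seed for a named substream, < 2^31.
sub_seed <- function(seed, name) {
  bytes <- utf8ToInt(name)
  h <- sum(bytes * seq_along(bytes))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Run the full factorial experiment
#'
#' Simulates \code{n_per_cell} synthetic participants in each of the 18
#' cells of the 3 (reputation) x 2 (strategy) x 3 (emotion)
#' between-participants design. Each participant's coefficients are drawn
#' from the configured population (means and between-participant SDs); all
#' randomness flows from the root seed through named substreams, so the
#' dataset is bit-identical under regeneration and adding participants never
#' perturbs earlier ones.
#'
#' @param config configuration list.
#' @param n_per_cell participants per cell (default from config; 40 per cell
#'   approximates the 711-participant study, 711/18 = 39.5).
#' @param seed root integer seed (default from config).
#' @return Object of class \code{experiment_dataset}: list with
#'   \code{trials} (rounds x participants rows), \code{ratings} (one row per
#'   participant), \code{config}, \code{n_per_cell}, \code{rounds},
#'   \code{seed}.
#' @examples
#' ds <- run_experiment(n_per_cell = 2, seed = 1)
#' nrow(ds$trials)  # 18 * 2 * 20
#' @export
run_experiment <- function(config = default_config(),
                           n_per_cell = config$design$n_per_cell,
                           seed = config$seed) {
  stopifnot(n_per_cell >= 1)
  validate_config(config)
  cells <- design_cells()
  n_total <- nrow(cells) * n_per_cell
  mu <- config$participant$mean
  sdv <- config$participant$sd

  set.seed(sub_seed(seed, "population"))
  coef_names <- names(mu)
  draws <- vapply(coef_names, function(nm) {
    stats::rnorm(n_total, mu[[nm]], sdv[[nm]])
  }, numeric(n_total))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)  # n_total == 1

  trials <- vector("list", n_total)
  ratings <- vector("list", n_total)
  pid <- 0L
  for (ci in seq_len(nrow(cells))) {
    spec <- counterpart_spec(cells$cell_rep[ci], cells$cell_strategy[ci],
                             cells$cell_emotion[ci])
    for (k in seq_len(n_per_cell)) {
      pid <- pid + 1L
      model <- do.call(participant_model, c(
        as.list(stats::setNames(draws[pid, ], coef_names)),
        list(sigma_a = config$participant$sigma_a,
             sigma_w = config$participant$sigma_w)))
      set.seed(sub_seed(seed, paste0("participant-", pid)))
      res <- run_participant(model, spec, config,
                             rounds = config$design$rounds,
                             participant_id = pid)
      trials[[pid]] <- res$trials
      ratings[[pid]] <- res$ratings
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 ratings = do.call(rbind, ratings),
                 config = config, n_per_cell = n_per_cell,
                 rounds = config$design$rounds, seed = seed),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf(paste0("experiment_dataset: %d participants (18 cells x %d), ",
                     "%d rounds each, seed %d\n"),
              nrow(x$ratings), x$n_per_cell, x$rounds, x$seed))
  invisible(x)
}

#' Per-round regressors of the participant model
#'
#' Reconstructs, from a dataset's trial records, the predictors the
#' synthetic participant conditioned on at each decision: the behavioral
#' reputation code, the counterpart's previous move (+1/-1, 0 on round 1),
#' the cumulative mean emotion valence observed before the current round
#' (0 on round 1), and the round index minus 1. Used for model fitting and
#' parameter recovery.
#'
#' @param dataset an \code{\link{experiment_dataset}} (or a list with
#'   \code{trials} and \code{config}).
#' @return Data frame with columns \code{participant}, \code{coop} (0/1
#'   response), \code{rep_code}, \code{last_move}, \code{valence},
#'   \code{round0}.
#' @export
participant_design_frame <- function(dataset) {
  tr <- dataset$trials
  policy <- display_policy(dataset$config$display_policy)
  coding <- dataset$config$participant$rep_coding
  tr <- tr[order(tr$participant, tr$round), ]
  val <- emotion_valence(swap_perspective(tr$outcome), tr$expression, policy)
  out <- do.call(rbind, lapply(split(seq_len(nrow(tr)), tr$participant),
    function(idx) {
      n <- length(idx)
      cmove <- tr$counterpart_move[idx]
      v <- val[idx]
      data.frame(
        participant = tr$participant[idx],
        coop = as.integer(tr$participant_move[idx] == "C"),
        rep_code = reputation_code(tr$cell_rep[idx], coding),
        last_move = c(0, ifelse(cmove[-n] == "C", 1, -1)),
        valence = c(0, cumsum(v)[-n] / seq_len(n - 1)),
        round0 = tr$round[idx] - 1)
    }))
  rownames(out) <- NULL
  out
}

#' Fit the participant cooperation model to a dataset
#'
#' Pooled logistic regression of the per-round cooperation indicator on the
#' reconstructed regressors (\code{\link{participant_design_frame}}).
#' Recovers the population coefficients when between-participant
#' heterogeneity is absent.
#'
#' @param dataset an \code{\link{experiment_dataset}}.
#' @return Data frame with columns \code{term}, \code{estimate},
#'   \code{std_error}; terms are \code{b0}, \code{b_rep}, \code{b_recip},
#'   \code{b_emo}, \code{b_round}.
#' @export
fit_participant_model <- function(dataset) {
  df <- participant_design_frame(dataset)
  fit <- stats::glm(coop ~ rep_code + last_move + valence + round0,
                    family = stats::binomial(), data = df)
  sm <- summary(fit)$coefficients
  data.frame(term = c("b0", "b_rep", "b_recip", "b_emo", "b_round"),
             estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
             stringsAsFactors = FALSE)
}
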
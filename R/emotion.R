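# Outcome-conditioned emotion display policies and signal interpretation.
#
# A display policy maps (emotion profile, outcome from the DISPLAYER's
# perspective) to one of four facial expressions. The cooperative pattern
# signals joy after mutual cooperation, regret after exploiting the other
# player, and anger after being exploited; the competitive pattern inverts
# the appraisals on the cooperation-relevant cells (regret after mutual
# cooperation — a missed chance to exploit — and joy after exploiting);
# the neutral pattern never emotes.

#' Expression and profile label sets
#'
#' @format Character vectors: the closed sets of expression labels
#'   (\code{joy, regret, anger, neutral}) and emotion-profile labels
#'   (\code{cooperative, neutral, competitive}).
#' @name emotion_labels
NULL

#' @rdname emotion_labels
#' @export
expressions <- c("joy", "regret", "anger", "neutral")

#' @rdname emotion_labels
#' @export
emotion_profiles <- c("cooperative", "neutral", "competitive")

.default_policy <- list(
  cooperative = c(CC = "joy", CD = "anger", DC = "regret", DD = "neutral"),
  neutral     = c(CC = "neutral", CD = "neutral", DC = "neutral",
                  DD = "neutral"),
  competitive = c(CC = "regret", CD = "anger", DC = "joy", DD = "neutral")
)

#' Build (or override) a display policy table
#'
#' Returns the default policy, optionally with per-cell overrides for
#' ablation experiments. A policy is a list keyed by profile, each element a
#' named character vector over outcomes (displayer's perspective).
#'
#' @param overrides optional nested list \code{list(profile = c(outcome =
#'   expression, ...))} replacing individual cells.
#' @return Policy list, validated to be total over profiles and outcomes.
#' @export
display_policy <- function(overrides = NULL) {
  policy <- .default_policy
  if (!is.null(overrides)) {
    for (prof in names(overrides)) {
      if (!prof %in% emotion_profiles) {
        stop("unknown emotion profile in override: ", prof)
      }
      cells <- overrides[[prof]]
      cells <- stats::setNames(as.character(unlist(cells)), names(cells))
      check_outcomes(names(cells))
      bad <- setdiff(cells, expressions)
      if (length(bad)) stop("unknown expression label(s): ",
                            paste(bad, collapse = ", "))
      policy[[prof]][names(cells)] <- cells
    }
  }
  policy
}

#' Expression displayed after an outcome
#'
#' @param profile emotion profile of the displayer (\code{"cooperative"},
#'   \code{"neutral"} or \code{"competitive"}).
#' @param outcome outcome label \emph{from the displayer's perspective}
#'   (first letter = displayer's move).
#' @param policy display policy table; defaults to the standard patterns.
#' @return Expression label (vectorized over \code{outcome}).
#' @examples
#' display_for("cooperative", "CC")  # joy
#' display_for("competitive", "CC")  # regret
#' @export
display_for <- function(profile, outcome, policy = display_policy()) {
  profile <- match.arg(profile, emotion_profiles)
  check_outcomes(outcome)
  unname(policy[[profile]][outcome])
}

#' Signed valence of an observed (outcome, expression) pair
#'
#' Scores an observed display against the cooperative and competitive policy
#' tables: +1 when the pair matches a non-neutral cell of the cooperative
#' policy only, -1 when it matches a non-neutral cell of the competitive
#' policy only, and 0 otherwise (cells shared by both policies, such as anger
#' after being exploited, and all neutral displays are uninformative about
#' the displayer's orientation). This three-level code is the minimal signal
#' carrying the cooperative/competitive contrast; expression intensities are
#' deliberately not modeled.
#'
#' @param outcome outcome label from the displayer's perspective (vectorized).
#' @param expression expression label shown (vectorized).
#' @param policy display policy table.
#' @return Integer vector in \{-1, 0, +1\}.
#' @examples
#' emotion_valence("CC", "joy")     # +1
#' emotion_valence("CC", "regret")  # -1
#' emotion_valence("CD", "anger")   #  0 (shared by both profiles)
#' @export
emotion_valence <- function(outcome, expression, policy = display_policy()) {
  check_outcomes(outcome)
  bad <- setdiff(unique(expression), expressions)
  if (length(bad)) stop("unknown expression label(s): ",
                        paste(bad, collapse = ", "))
  coop <- policy$cooperative[outcome] == expression &
    expression != "neutral"
  comp <- policy$competitive[outcome] == expression &
    expression != "neutral"
  as.integer(coop & !comp) - as.integer(comp & !coop)
}

#' Classify a sequence of displays into an emotion profile
#'
#' For each profile, the agreement score is the fraction of observed
#' (outcome, expression) pairs consistent with that profile's policy. The
#' best-matching profile is the argmax, with deterministic tie-break order
#' cooperative < neutral < competitive.
#'
#' @param outcomes outcome labels from the displayer's perspective.
#' @param observed expression labels, same length.
#' @param policy display policy table.
#' @return List with \code{scores} (named numeric, agreement per profile;
#'   all \code{NA} for empty input) and \code{best} (profile label, or
#'   \code{NA} for empty input).
#' @export
classify_profile <- function(outcomes, observed, policy = display_policy()) {
  stopifnot(length(outcomes) == length(observed))
  if (length(outcomes) == 0L) {
    return(list(scores = stats::setNames(rep(NA_real_, 3), emotion_profiles),
                best = NA_character_))
  }
  check_outcomes(outcomes)
  bad <- setdiff(unique(observed), expressions)
  if (length(bad)) stop("unknown expression label(s): ",
                        paste(bad, collapse = ", "))
  scores <- vapply(emotion_profiles, function(prof) {
    mean(policy[[prof]][outcomes] == observed)
  }, numeric(1))
  best <- emotion_profiles[which.max(scores)]  # first max wins the tie
  list(scores = scores, best = best)
}
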
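# Prisoner's-dilemma payoff structure and outcome bookkeeping.
#
# Outcomes are always ordered (CC, CD, DC, DD), first letter = focal player's
# move, second = opponent's. All serialization uses these labels, never indices.

#' Outcome labels of the one-shot prisoner's dilemma
#'
#' The four outcomes in the canonical order used throughout the package:
#' \code{CC, CD, DC, DD}. The first letter is the focal player's move
#' (C = cooperate, D = defect), the second the opponent's.
#'
#' @format Character vector of length 4.
#' @export
pd_outcomes <- c("CC", "CD", "DC", "DD")

#' Construct a prisoner's-dilemma payoff matrix
#'
#' Holds the four per-round payoffs: temptation \code{T} (unilateral
#' defection), reward \code{R} (mutual cooperation), punishment \code{P}
#' (mutual defection) and sucker's payoff \code{S} (unilateral cooperation).
#' The default \code{(T, R, P, S) = (5, 3, 1, 0)} is the standard matrix of
#' the zero-determinant literature. A valid iterated-PD matrix must satisfy
#' \code{T > R > P > S} and \code{2R > T + S}.
#'
#' @param temptation payoff for defecting against a cooperator (T).
#' @param reward payoff for mutual cooperation (R).
#' @param punishment payoff for mutual defection (P).
#' @param sucker payoff for cooperating against a defector (S).
#' @return An object of class \code{payoff_matrix}: a list with elements
#'   \code{T}, \code{R}, \code{P}, \code{S}.
#' @examples
#' pm <- payoff_matrix()
#' payoff_vectors(pm)$fX  # focal player's payoffs over (CC, CD, DC, DD)
#' @export
payoff_matrix <- function(temptation = 5, reward = 3, punishment = 1,
                          sucker = 0) {
  vals <- c(T = temptation, R = reward, P = punishment, S = sucker)
  if (!all(is.finite(vals))) {
    stop("payoff values must be finite numbers")
  }
  if (!(vals["T"] > vals["R"] && vals["R"] > vals["P"] &&
        vals["P"] > vals["S"])) {
    stop("payoff ordering violated: need T > R > P > S, got T=", vals["T"],
         " R=", vals["R"], " P=", vals["P"], " S=", vals["S"])
  }
  if (!(2 * vals["R"] > vals["T"] + vals["S"])) {
    stop("iterated-PD condition violated: need 2R > T + S")
  }
  structure(as.list(vals), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("Prisoner's dilemma payoffs: T=%g R=%g P=%g S=%g\n",
              x$T, x$R, x$P, x$S))
  invisible(x)
}

#' Per-outcome payoff vectors
#'
#' Payoffs of the focal player (\code{fX}) and the opponent (\code{fY}) over
#' the outcomes \code{(CC, CD, DC, DD)} taken from the focal player's
#' perspective: \code{fX = (R, S, T, P)}, \code{fY = (R, T, S, P)}. The two
#' vectors are permutations of each other under the CD/DC swap.
#'
#' @param payoff a \code{\link{payoff_matrix}}.
#' @return List with named numeric vectors \code{fX} and \code{fY}.
#' @export
payoff_vectors <- function(payoff) {
  stopifnot(inherits(payoff, "payoff_matrix"))
  fX <- c(CC = payoff$R, CD = payoff$S, DC = payoff$T, DD = payoff$P)
  fY <- c(CC = payoff$R, CD = payoff$T, DC = payoff$S, DD = payoff$P)
  list(fX = fX, fY = fY)
}

#' Swap the perspective of an outcome label
#'
#' Maps each outcome to the same round seen from the other player's side:
#' CD and DC swap, CC and DD are fixed.
#'
#' @param outcome character vector of outcome labels.
#' @return Character vector of the same length.
#' @examples
#' swap_perspective(c("CC", "CD", "DC", "DD"))
#' @export
swap_perspective <- function(outcome) {
  check_outcomes(outcome)
  map <- c(CC = "CC", CD = "DC", DC = "CD", DD = "DD")
  unname(map[outcome])
}

#' Combine two moves into an outcome label
#'
#' @param focal,opponent character vectors of moves, \code{"C"} or \code{"D"}.
#' @return Outcome labels from the focal player's perspective.
#' @export
outcome_from_moves <- function(focal, opponent) {
  if (!all(focal %in% c("C", "D")) || !all(opponent %in% c("C", "D"))) {
    stop("moves must be \"C\" or \"D\"")
  }
  paste0(focal, opponent)
}

check_outcomes <- function(outcome) {
  bad <- setdiff(unique(outcome), pd_outcomes)
  if (length(bad)) {
    stop("unknown outcome label(s): ", paste(bad, collapse = ", "))
  }
  invisible(outcome)
}
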
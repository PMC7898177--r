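# Match simulation between two memory-one strategies.

#' Simulate an iterated prisoner's-dilemma match
#'
#' First moves are drawn from each strategy's \code{p0}; subsequent moves
#' from the conditional cooperation probabilities given the previous
#' outcome. Reproducible under a fixed seed (the function uses R's RNG).
#'
#' @param pX focal player's \code{\link{memory_one_strategy}}.
#' @param pY opponent's \code{\link{memory_one_strategy}}.
#' @param rounds number of rounds (>= 1); the experimental task uses 20.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first.
#' @return Character vector of outcome labels of length \code{rounds}, from
#'   the focal player's perspective.
#' @examples
#' simulate_match(tit_for_tat(), always_defect(), rounds = 5)
#' @export
simulate_match <- function(pX, pY, rounds = 20L, seed = NULL) {
  stopifnot(inherits(pX, "memory_one_strategy"),
            inherits(pY, "memory_one_strategy"), rounds >= 1)
  if (!is.null(seed)) set.seed(seed)
  qx <- unname(pY$p[swap_perspective(pd_outcomes)])
  states <- .sim_match_cpp(unname(pX$p[pd_outcomes]), qx,
                           pX$p0, pY$p0, as.integer(rounds))
  pd_outcomes[states]
}

#' Empirical outcome frequencies of a long simulated chain
#'
#' Simulates the Markov chain induced by a transition matrix for a given
#' number of steps and returns the outcome frequencies. Serves as the
#' Monte-Carlo counterpart of \code{\link{stationary_distribution}}.
#'
#' @param M 4x4 row-stochastic transition matrix.
#' @param steps number of simulated steps.
#' @param start starting outcome label (default \code{"CC"}).
#' @return Named numeric vector of outcome frequencies summing to 1.
#' @export
simulate_chain_frequencies <- function(M, steps = 1e6, start = "CC") {
  stopifnot(is.matrix(M), all(dim(M) == 4L))
  check_outcomes(start)
  f <- .sim_chain_freq_cpp(M, match(start, pd_outcomes), as.integer(steps))
  stats::setNames(f, pd_outcomes)
}
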
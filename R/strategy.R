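# Memory-one strategies: cooperation probability conditioned on the previous
# outcome, plus a first-round cooperation probability.

#' Construct a memory-one strategy
#'
#' A memory-one strategy is the vector
#' \code{p = (p_CC, p_CD, p_DC, p_DD)} of probabilities of cooperating after
#' each previous-round outcome (seen from the strategy's own perspective),
#' together with \code{p0}, the probability of cooperating on the first round.
#'
#' @param p numeric vector of length 4, probabilities in order
#'   \code{(CC, CD, DC, DD)}.
#' @param p0 first-round cooperation probability. Defaults to 1 (cooperate):
#'   both shipped counterpart strategies are "nice" variants and round-1
#'   behavior is attributed to reputation alone in the experimental design.
#' @param name optional label used in printing.
#' @return Object of class \code{memory_one_strategy}.
#' @examples
#' tit_for_tat()
#' memory_one_strategy(c(11 / 13, 1 / 2, 7 / 26, 0), name = "Extort-3")
#' @export
memory_one_strategy <- function(p, p0 = 1, name = NULL) {
  if (length(p) != 4L || !is.numeric(p)) {
    stop("p must be a numeric vector of length 4 over (CC, CD, DC, DD)")
  }
  probs <- c(p, p0)
  labels <- c(paste0("p_", pd_outcomes), "p0")
  bad <- which(!is.finite(probs) | probs < 0 | probs > 1)
  if (length(bad)) {
    stop("probability outside [0,1]: ", labels[bad[1]], " = ", probs[bad[1]])
  }
  structure(list(p = stats::setNames(as.numeric(p), pd_outcomes),
                 p0 = as.numeric(p0), name = name),
            class = "memory_one_strategy")
}

#' @export
print.memory_one_strategy <- function(x, ...) {
  nm <- if (is.null(x$name)) "memory-one strategy" else x$name
  cat(sprintf("%s: p = (%s), p0 = %g\n", nm,
              paste(signif(x$p, 6), collapse = ", "), x$p0))
  invisible(x)
}

#' Shipped counterpart strategies and classic references
#'
#' \code{extortion_strategy()} is the canonical extortionate zero-determinant
#' strategy for the default payoffs (extortion factor 3, pivot at the
#' punishment payoff): \code{(11/13, 1/2, 7/26, 0)}. \code{generous_strategy()}
#' is its generous mirror from the same family (factor 3, pivot at the mutual
#' cooperation reward): \code{(1, 2/11, 1, 4/11)}. The remaining constructors
#' are the usual reference strategies.
#'
#' @param p0 first-round cooperation probability.
#' @return A \code{\link{memory_one_strategy}}.
#' @name shipped_strategies
NULL

#' @rdname shipped_strategies
#' @export
extortion_strategy <- function(p0 = 1) {
  memory_one_strategy(c(11 / 13, 1 / 2, 7 / 26, 0), p0 = p0,
                      name = "extortion (chi = 3)")
}

#' @rdname shipped_strategies
#' @export
generous_strategy <- function(p0 = 1) {
  memory_one_strategy(c(1, 2 / 11, 1, 4 / 11), p0 = p0,
                      name = "generous (chi = 3)")
}

#' @rdname shipped_strategies
#' @export
tit_for_tat <- function(p0 = 1) {
  memory_one_strategy(c(1, 0, 1, 0), p0 = p0, name = "tit-for-tat")
}

#' @rdname shipped_strategies
#' @export
always_cooperate <- function() {
  memory_one_strategy(c(1, 1, 1, 1), p0 = 1, name = "always cooperate")
}

#' @rdname shipped_strategies
#' @export
always_defect <- function() {
  memory_one_strategy(c(0, 0, 0, 0), p0 = 0, name = "always defect")
}

#' Draw a random memory-one strategy
#'
#' Uniform independent entries; useful for property checks against random
#' opponents. Uses the current RNG state.
#'
#' @param margin keep entries in \code{[margin, 1 - margin]} to guarantee an
#'   ergodic pairing; 0 allows absorbing chains.
#' @return A \code{\link{memory_one_strategy}}.
#' @export
random_strategy <- function(margin = 0) {
  stopifnot(margin >= 0, margin < 0.5)
  memory_one_strategy(stats::runif(4, margin, 1 - margin),
                      p0 = stats::runif(1, margin, 1 - margin))
}
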
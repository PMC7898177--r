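# Markov-chain analysis of a pair of memory-one strategies: transition
# matrix, stationary distribution (with a flagged Cesaro fallback for
# non-ergodic chains), expected per-round payoffs, and the Press-Dyson
# determinant form of the stationary dot product.

#' Transition matrix of a memory-one strategy pair
#'
#' Entry (i, j) is the probability that the next round's outcome is j given
#' that the current outcome is i, with outcomes ordered (CC, CD, DC, DD) from
#' the focal player's perspective. The opponent's strategy is conditioned on
#' the perspective-swapped outcome.
#'
#' @param p focal player's \code{\link{memory_one_strategy}}.
#' @param q opponent's \code{\link{memory_one_strategy}}.
#' @return 4x4 row-stochastic matrix with dimnames \code{pd_outcomes}.
#' @examples
#' build_transition_matrix(tit_for_tat(), always_defect())
#' @export
build_transition_matrix <- function(p, q) {
  stopifnot(inherits(p, "memory_one_strategy"),
            inherits(q, "memory_one_strategy"))
  a <- p$p[pd_outcomes]                       # focal coop prob by state
  b <- q$p[swap_perspective(pd_outcomes)]     # opponent coop prob by state
  M <- cbind(CC = a * b, CD = a * (1 - b), DC = (1 - a) * b,
             DD = (1 - a) * (1 - b))
  rownames(M) <- pd_outcomes
  M
}

#' Stationary (or long-run average) outcome distribution
#'
#' Solves \code{vM = v}, \code{sum(v) = 1}. When the unit eigenvalue of the
#' chain is not simple (absorbing sets make the stationary distribution
#' non-unique), the limit depends on where the chain starts; the function then
#' returns the Cesaro (running-average) limit from \code{fallback_initial} and
#' flags non-ergodicity via the \code{"non_ergodic"} attribute. Press-Dyson
#' theory assumes ergodicity; a flagged fallback is preferable to silent NaNs.
#'
#' @param M 4x4 row-stochastic matrix (from
#'   \code{\link{build_transition_matrix}}).
#' @param fallback_initial initial distribution used for the long-run average
#'   when the chain is non-ergodic; defaults to uniform.
#' @param tol tolerance for row-stochasticity and eigenvalue checks.
#' @return Named numeric vector of length 4 summing to 1, with logical
#'   attribute \code{non_ergodic}.
#' @export
stationary_distribution <- function(M, fallback_initial = rep(0.25, 4),
                                    tol = 1e-9) {
  stopifnot(is.matrix(M), all(dim(M) == 4L))
  if (any(M < -tol) || any(abs(rowSums(M) - 1) > tol)) {
    stop("M is not row-stochastic")
  }
  stopifnot(length(fallback_initial) == 4L,
            abs(sum(fallback_initial) - 1) < 1e-8, all(fallback_initial >= 0))
  ev <- eigen(t(M), only.values = TRUE)$values
  simple_unit <- sum(abs(ev - 1) < 1e-8) == 1L
  if (simple_unit) {
    A <- t(M) - diag(4)
    A[4L, ] <- 1
    v <- solve(A, c(0, 0, 0, 1))
    v[abs(v) < 1e-14] <- 0
    v <- v / sum(v)
    non_ergodic <- FALSE
  } else {
    # Cesaro average from the fallback start; converges for any finite chain.
    v_k <- as.numeric(fallback_initial)
    avg <- v_k
    for (k in seq_len(100000L)) {
      v_k <- as.numeric(v_k %*% M)
      new_avg <- (avg * k + v_k) / (k + 1)
      if (max(abs(new_avg - avg)) < 1e-13) {
        avg <- new_avg
        break
      }
      avg <- new_avg
    }
    v <- avg / sum(avg)
    non_ergodic <- TRUE
  }
  names(v) <- pd_outcomes
  attr(v, "non_ergodic") <- non_ergodic
  v
}

#' Expected per-round payoffs of a strategy pair
#'
#' Computes the stationary distribution of the induced chain and returns the
#' match statistics \code{s_X = v . fX} and \code{s_Y = v . fY}. A
#' non-ergodic chain triggers a warning (the long-run average from
#' \code{fallback_initial} is used).
#'
#' @inheritParams build_transition_matrix
#' @param payoff a \code{\link{payoff_matrix}}.
#' @param fallback_initial passed to \code{\link{stationary_distribution}}.
#' @return Object of class \code{match_statistics}: list with \code{v},
#'   \code{s_X}, \code{s_Y}, \code{non_ergodic}.
#' @examples
#' expected_payoffs(always_cooperate(), always_cooperate(), payoff_matrix())
#' @export
expected_payoffs <- function(p, q, payoff = payoff_matrix(),
                             fallback_initial = rep(0.25, 4)) {
  M <- build_transition_matrix(p, q)
  v <- stationary_distribution(M, fallback_initial)
  if (isTRUE(attr(v, "non_ergodic"))) {
    warning("non-ergodic chain: payoffs are long-run averages from the ",
            "fallback initial distribution")
  }
  fv <- payoff_vectors(payoff)
  structure(list(v = v,
                 s_X = as.numeric(v %*% fv$fX),
                 s_Y = as.numeric(v %*% fv$fY),
                 non_ergodic = isTRUE(attr(v, "non_ergodic"))),
            class = "match_statistics")
}

#' @export
print.match_statistics <- function(x, ...) {
  cat("stationary outcome distribution:\n")
  print(round(unclass(x$v), 6))
  cat(sprintf("expected payoffs: s_X = %.6f, s_Y = %.6f%s\n", x$s_X, x$s_Y,
              if (x$non_ergodic) "  [non-ergodic fallback]" else ""))
  invisible(x)
}

#' Press-Dyson determinant ratio
#'
#' Evaluates the stationary average of an arbitrary 4-vector of outcome
#' weights as a ratio of two 4x4 determinants, D(p, q, f) / D(p, q, 1),
#' without solving for the stationary distribution explicitly. The second and
#' third columns of the determinant matrix are the strategy columns
#' \code{p - (1,1,0,0)} and (after reordering to the focal perspective)
#' \code{q - (1,0,1,0)}; because the focal strategy column depends on p only,
#' setting it proportional to a combination of the payoff vectors enforces a
#' linear payoff relation unilaterally — the zero-determinant mechanism.
#'
#' @inheritParams expected_payoffs
#' @param weights numeric 4-vector over outcomes (CC, CD, DC, DD).
#' @return Scalar; for \code{weights = fX} equals \code{s_X} on ergodic
#'   chains.
#' @export
press_dyson_payoff <- function(p, q, payoff = payoff_matrix(), weights) {
  stopifnot(inherits(p, "memory_one_strategy"),
            inherits(q, "memory_one_strategy"),
            is.numeric(weights), length(weights) == 4L)
  pv <- unname(p$p[pd_outcomes])
  qv <- unname(q$p[swap_perspective(pd_outcomes)]) # opponent, focal ordering
  col1 <- pv * qv - c(1, 0, 0, 0)
  col2 <- pv - c(1, 1, 0, 0)
  col3 <- qv - c(1, 0, 1, 0)
  D <- function(f) det(cbind(col1, col2, col3, f))
  denom <- D(rep(1, 4))
  if (abs(denom) < 1e-12) {
    stop("degenerate chain: Press-Dyson normalizing determinant is ~0 ",
         "(the chain has no unique stationary distribution)")
  }
  D(weights) / denom
}
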
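# Zero-determinant certification: decompose a memory-one strategy into
# payoff-vector coordinates and classify it as extortionate, generous,
# other-ZD, or not ZD.

#' Certify a zero-determinant strategy
#'
#' A memory-one strategy p is zero-determinant when its strategy column
#' \code{ptilde = p - (1, 1, 0, 0)} can be written as
#' \code{alpha * fX + beta * fY + gamma * 1}; the strategy then unilaterally
#' enforces the linear payoff relation
#' \code{alpha * s_X + beta * s_Y + gamma = 0} against every opponent. The
#' decomposition is solved in the least-squares sense; a residual below
#' \code{tol} certifies the strategy as ZD. Writing the relation as
#' \code{s_X - pivot = chi * (s_Y - pivot)} with
#' \code{chi = -beta / alpha} and \code{pivot = -gamma / (alpha + beta)},
#' the strategy is classified as \emph{extortion} when the pivot equals the
#' punishment payoff P and \code{chi > 1} (the focal surplus over P is chi
#' times the opponent's), and \emph{generous} when the pivot equals the
#' reward R and \code{chi > 1} (the focal player absorbs the larger share of
#' any shortfall from mutual cooperation).
#'
#' @param p a \code{\link{memory_one_strategy}}.
#' @param payoff a \code{\link{payoff_matrix}}.
#' @param tol decomposition residual below which the strategy counts as ZD.
#' @return Object of class \code{zd_certificate}: list with \code{alpha},
#'   \code{beta}, \code{gamma}, \code{phi} (the scale, equal to alpha under
#'   the sign normalization \code{alpha > 0}), \code{chi}, \code{pivot}
#'   (numeric) and \code{pivot_name} ("P", "R" or NA), \code{class} (one of
#'   \code{"extortion"}, \code{"generous"}, \code{"other-ZD"},
#'   \code{"not-ZD"}), and \code{residual} (L2 norm of the decomposition
#'   misfit).
#' @examples
#' zd_certificate(extortion_strategy())  # class "extortion", chi = 3
#' zd_certificate(generous_strategy())   # class "generous",  chi = 3
#' zd_certificate(always_cooperate())    # class "not-ZD"
#' @export
zd_certificate <- function(p, payoff = payoff_matrix(), tol = 1e-9) {
  stopifnot(inherits(p, "memory_one_strategy"),
            inherits(payoff, "payoff_matrix"), tol > 0)
  fv <- payoff_vectors(payoff)
  ptilde <- unname(p$p[pd_outcomes]) - c(1, 1, 0, 0)
  X <- cbind(fX = unname(fv$fX), fY = unname(fv$fY), one = rep(1, 4))
  fit <- qr(X)
  coef <- qr.coef(fit, ptilde)
  residual <- sqrt(sum((ptilde - as.numeric(X %*% coef))^2))
  alpha <- coef[["fX"]]; beta <- coef[["fY"]]; gamma <- coef[["one"]]

  cls <- "not-ZD"; chi <- NA_real_; pivot <- NA_real_
  pivot_name <- NA_character_; phi <- NA_real_
  if (residual < tol) {
    # Normalize sign so the focal coefficient is non-negative; the enforced
    # relation alpha*s_X + beta*s_Y + gamma = 0 is sign-invariant.
    if (alpha < 0) {
      alpha <- -alpha; beta <- -beta; gamma <- -gamma
    }
    phi <- alpha
    if (abs(alpha) < 1e-12) {
      cls <- "other-ZD"   # equalizer-type: sets the opponent's score only
    } else {
      chi <- -beta / alpha
      if (abs(alpha + beta) < 1e-12) {
        cls <- "other-ZD"  # chi = 1: fair relation, pivot undefined
      } else {
        pivot <- -gamma / (alpha + beta)
        scale <- max(abs(unlist(payoff[c("T", "R", "P", "S")])), 1)
        if (chi > 1 && abs(pivot - payoff$P) < 1e-6 * scale) {
          cls <- "extortion"; pivot_name <- "P"
        } else if (chi > 1 && abs(pivot - payoff$R) < 1e-6 * scale) {
          cls <- "generous"; pivot_name <- "R"
        } else {
          cls <- "other-ZD"
        }
      }
    }
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, phi = phi,
                 chi = chi, pivot = pivot, pivot_name = pivot_name,
                 class = cls, residual = residual, tol = tol),
            class = "zd_certificate")
}

#' @export
print.zd_certificate <- function(x, ...) {
  cat(sprintf("zero-determinant certificate: class = %s\n", x$class))
  cat(sprintf("  residual = %.3g (tol %.3g)\n", x$residual, x$tol))
  if (x$class != "not-ZD") {
    cat(sprintf("  alpha = %.6g, beta = %.6g, gamma = %.6g, phi = %.6g\n",
                x$alpha, x$beta, x$gamma, x$phi))
    if (is.finite(x$chi)) {
      cat(sprintf("  extortion factor chi = %.6g, pivot = %s (%s)\n",
                  x$chi, format(x$pivot),
                  if (is.na(x$pivot_name)) "no named pivot" else x$pivot_name))
    }
  }
  invisible(x)
}
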
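# The statistical pipeline: per-participant cooperation rate, between-
# subjects factorial ANOVA with partial eta-squared (Type III sums of
# squares via effect coding, computed from first principles by model
# comparison on QR fits), Bonferroni pairwise post-hocs on the pooled error
# term, and one-sample t-tests.

#' Per-participant cooperation rate
#'
#' Fraction of rounds in which the participant cooperated, averaged across
#' all of that participant's rounds.
#'
#' @param dataset an \code{\link{experiment_dataset}} (or list with a
#'   \code{trials} data.frame in the trial CSV schema).
#' @return Data frame with one row per participant: \code{participant}, the
#'   three cell labels, and \code{coop_rate} in [0, 1].
#' @export
cooperation_rate <- function(dataset) {
  tr <- dataset$trials
  if (nrow(tr) == 0L) stop("dataset has no trial records")
  agg <- stats::aggregate(
    list(coop_rate = tr$participant_move == "C"),
    by = tr[c("participant", "cell_rep", "cell_strategy", "cell_emotion")],
    FUN = mean)
  agg[order(agg$participant), ]
}

# Precompute the design-matrix machinery for a fully-crossed factorial
# ANOVA with effect (sum-to-zero) coding: the full-model QR and, per effect,
# the QR of the model with that effect's columns dropped. Reusable across
# responses, which makes repeated-simulation calibration cheap.
anova_design <- function(factors) {
  stopifnot(is.data.frame(factors), ncol(factors) >= 1)
  fnames <- names(factors)
  factors[] <- lapply(factors, function(x) factor(as.character(x)))
  counts <- table(factors)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)
    lab <- apply(empty, 1L, function(i) {
      paste(mapply(function(d, j) dimnames(counts)[[d]][j],
                   seq_along(fnames), i), collapse = ":")
    })
    stop("empty design cell(s): ", paste(lab, collapse = ", "))
  }
  form <- stats::as.formula(paste("~", paste(fnames, collapse = "*")))
  contrasts <- stats::setNames(rep(list("contr.sum"), length(fnames)), fnames)
  mm <- stats::model.matrix(form, data = factors, contrasts.arg = contrasts)
  assign <- attr(mm, "assign")
  terms <- attr(stats::terms(form), "term.labels")
  qr_full <- qr(mm)
  if (qr_full$rank < ncol(mm)) stop("design matrix is rank deficient")
  qr_reduced <- lapply(seq_along(terms), function(ti) {
    qr(mm[, assign != ti, drop = FALSE])
  })
  list(n = nrow(mm), p = ncol(mm), n_cells = prod(dim(counts)),
       terms = terms, qr_full = qr_full, qr_reduced = qr_reduced)
}

# Type III sums of squares by model comparison on a prebuilt design.
anova_fit <- function(design, y) {
  stopifnot(length(y) == design$n)
  rss <- function(qrobj) sum(qr.resid(qrobj, y)^2)
  ss_error <- rss(design$qr_full)
  df_error <- design$n - design$p
  if (df_error < 1L) stop("no residual degrees of freedom")
  ss_effect <- vapply(design$qr_reduced, rss, numeric(1)) - ss_error
  ss_effect <- pmax(ss_effect, 0)
  df_effect <- vapply(design$qr_reduced, function(q) design$p - ncol(q$qr),
                      integer(1))
  ss_total <- sum((y - mean(y))^2)
  if (ss_error <= 1e-10 * max(ss_total, 1)) {
    stop("zero residual variance: ANOVA is degenerate")
  }
  ms_error <- ss_error / df_error
  Fval <- (ss_effect / df_effect) / ms_error
  pval <- stats::pf(Fval, df_effect, df_error, lower.tail = FALSE)
  tab <- data.frame(effect = design$terms, ss = ss_effect, df = df_effect,
                    F = Fval, df_den = df_error, p = pval,
                    partial_eta2 = ss_effect / (ss_effect + ss_error),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, ss_error = ss_error, df_error = df_error,
                 ms_error = ms_error, n = design$n),
            class = "anova_table")
}

#' Between-subjects factorial ANOVA with partial eta-squared
#'
#' Fully-crossed fixed-effects ANOVA for one response per participant.
#' Sums of squares are Type III, obtained with effect (sum-to-zero) coding
#' by comparing the full model against the model with each effect's columns
#' removed; on balanced data this coincides with the sequential (Type I)
#' decomposition. F = MS_effect / MS_error with the residual df equal to
#' N minus the number of cells; partial eta-squared is
#' SS_effect / (SS_effect + SS_error).
#'
#' @param data data frame holding the response and the factor columns.
#' @param response name of the numeric response column.
#' @param factors character vector of factor column names (1 or more).
#' @return Object of class \code{anova_table}: list with \code{table} (one
#'   row per effect: \code{effect}, \code{ss}, \code{df}, \code{F},
#'   \code{df_den}, \code{p}, \code{partial_eta2}), \code{ss_error},
#'   \code{df_error}, \code{ms_error}, \code{n}.
#' @examples
#' df <- data.frame(y = rnorm(36), a = gl(3, 12), b = gl(2, 6, 36))
#' factorial_anova(df, "y", c("a", "b"))
#' @export
factorial_anova <- function(data, response, factors) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)))
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y)) stop("response must be numeric without NAs")
  design <- anova_design(data[factors])
  anova_fit(design, y)
}

#' @export
print.anova_table <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Between-subjects ANOVA (N = %d, df_error = %d)\n",
              x$n, x$df_error))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s F(%d, %d) = %8.3f, p = %.4g, partial eta2 = %.3f\n",
                tab$effect[i], tab$df[i], tab$df_den[i], tab$F[i], tab$p[i],
                tab$partial_eta2[i]))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All k(k-1)/2 pairwise two-sample comparisons among the levels of one
#' factor, using the pooled one-way ANOVA error term (MS_error with N - k
#' df) as the variance estimate; adjusted p = min(1, raw p x number of
#' comparisons).
#'
#' @param values numeric response vector.
#' @param group factor (or coercible) of group labels, same length.
#' @return Data frame with one row per pair: \code{group1}, \code{group2},
#'   \code{mean_diff}, \code{t}, \code{df}, \code{p}, \code{p_adj}.
#' @export
bonferroni_pairwise <- function(values, group) {
  group <- factor(as.character(group))
  stopifnot(length(values) == length(group))
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups")
  n_g <- tapply(values, group, length)
  if (any(n_g < 2L)) {
    stop("singleton group(s): ",
         paste(levels(group)[n_g < 2L], collapse = ", "))
  }
  m_g <- tapply(values, group, mean)
  ss_within <- sum(tapply(values, group,
                          function(v) sum((v - mean(v))^2)))
  df_err <- length(values) - k
  mse <- ss_within / df_err
  if (mse <= 0) stop("zero pooled variance")
  pairs <- utils::combn(levels(group), 2L)
  n_comp <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(n_comp), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    diff <- m_g[[g1]] - m_g[[g2]]
    se <- sqrt(mse * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    tval <- diff / se
    p <- 2 * stats::pt(abs(tval), df_err, lower.tail = FALSE)
    data.frame(group1 = g1, group2 = g2, mean_diff = diff, t = tval,
               df = df_err, p = p, p_adj = min(1, p * n_comp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-sample t-test
#'
#' Two-sided t-test of the sample mean against \code{mu0}, computed from
#' the textbook formula \code{t = (mean - mu0) / (sd / sqrt(n))}.
#'
#' @param values numeric sample, n >= 2.
#' @param mu0 null value (default 0, the neutral reputation point).
#' @return Object of class \code{t_test_result}: list with \code{t},
#'   \code{df}, \code{p}, \code{mean}, \code{sd}, \code{n}.
#' @examples
#' one_sample_t(c(1, 2, 3))  # t = 3.4641, df = 2
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  m <- mean(values)
  tval <- (m - mu0) / (s / sqrt(n))
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE),
                 mean = m, sd = s, n = n),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("one-sample t: t(%d) = %.4f, p = %.4g (mean %.4f, sd %.4f)\n",
              x$df, x$t, x$p, x$mean, x$sd))
  invisible(x)
}

#' Per-participant reputation change
#'
#' Final minus initial reputation rating, in rating points.
#'
#' @param ratings data frame with columns \code{participant},
#'   \code{initial_rating}, \code{final_rating} (or an
#'   \code{\link{experiment_dataset}}).
#' @return Data frame with columns \code{participant} and \code{change}.
#' @export
reputation_change <- function(ratings) {
  if (inherits(ratings, "experiment_dataset")) ratings <- ratings$ratings
  stopifnot(all(c("participant", "initial_rating", "final_rating") %in%
                  names(ratings)))
  data.frame(participant = ratings$participant,
             change = ratings$final_rating - ratings$initial_rating)
}

#' Type-I error calibration of the factorial ANOVA
#'
#' Simulates null datasets (pure Gaussian noise on a fixed fully-crossed
#' 3x2x3 design) and records, per effect, the fraction of replicates with
#' p < alpha. The design machinery is built once and reused, so many
#' thousands of replicates are cheap.
#'
#' @param n_sims number of simulated datasets.
#' @param n_per_cell observations per cell.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return Named numeric vector of rejection rates, one per effect.
#' @export
anova_type1_calibration <- function(n_sims = 10000, n_per_cell = 10,
                                    alpha = 0.05, seed = 1) {
  cells <- design_cells()
  factors <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  design <- anova_design(factors)
  set.seed(seed)
  rej <- matrix(FALSE, n_sims, length(design$terms))
  for (i in seq_len(n_sims)) {
    y <- stats::rnorm(design$n)
    rej[i, ] <- anova_fit(design, y)$table$p < alpha
  }
  stats::setNames(colMeans(rej), design$terms)
}
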
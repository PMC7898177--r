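# Configuration: defaults, JSON round trip, and schema validation.

#' Default configuration
#'
#' The full configuration tree with the shipped defaults: the standard
#' ZD-literature payoff matrix, the extortion/generous counterpart strategy
#' vectors, the default display policy (no overrides), the calibrated
#' synthetic-participant population, the 3x2x3 design with 40 participants
#' per cell and 20 rounds, and the analysis options.
#'
#' Participant-model fields (log-odds scale unless noted): \code{b0}
#' intercept; \code{b_rep} reputation-prior effect; \code{b_recip}
#' reciprocity effect (opponent cooperated last round = +1, defected = -1);
#' \code{b_emo} effect of the cumulative mean emotion valence observed so
#' far; \code{b_round} per-round drift. Rating fields (points on the
#' -50..+50 scale): \code{a_rep} initial-rating slope (times
#' \code{rep_scale} per unit of symmetric reputation code); \code{w_rep},
#' \code{w_coop} (on the counterpart's observed cooperation frequency
#' centered at 0.5), \code{w_emo} (on the mean emotion valence) final-rating
#' weights; \code{sigma_a}, \code{sigma_w} rating noise SDs. \code{sd} gives
#' between-participant SDs of the coefficient draws.
#'
#' @return Nested list; see \code{\link{load_config}} for the JSON form.
#' @export
default_config <- function() {
  list(
    payoffs = list(T = 5, R = 3, P = 1, S = 0),
    strategies = list(
      extortion = c(11 / 13, 1 / 2, 7 / 26, 0),
      generous  = c(1, 2 / 11, 1, 4 / 11),
      p0 = 1
    ),
    display_policy = NULL,
    participant = list(
      mean = list(b0 = 0.2, b_rep = 0.4, b_recip = 1.1, b_emo = 0.3,
                  b_round = 0,
                  a_rep = 1, w_rep = 10, w_coop = 40, w_emo = 22),
      sd = list(b0 = 0.25, b_rep = 0.15, b_recip = 0.25, b_emo = 0.15,
                b_round = 0,
                a_rep = 0.1, w_rep = 1.5, w_coop = 3, w_emo = 2),
      sigma_a = 8,
      sigma_w = 12,
      rep_coding = "asymmetric",
      rep_scale = 30
    ),
    design = list(n_per_cell = 40, rounds = 20),
    analysis = list(alpha = 0.05, cell_correction = FALSE),
    seed = 1
  )
}

#' Numeric codes of the reputation labels
#'
#' Symmetric coding is (-1, 0, +1) for (negative, unknown, positive); the
#' asymmetric coding (-1, +0.5, +1) reflects that behavior toward unknown
#' counterparts resembles behavior toward positively-reputed ones, and is
#' the default behavioral coding of the shipped scenario.
#'
#' @param label character vector of reputation labels (\code{"negative"},
#'   \code{"unknown"}, \code{"positive"}).
#' @param coding \code{"symmetric"} or \code{"asymmetric"}.
#' @return Numeric vector of codes.
#' @export
reputation_code <- function(label, coding = c("asymmetric", "symmetric")) {
  coding <- match.arg(coding)
  bad <- setdiff(unique(label), reputation_labels)
  if (length(bad)) stop("unknown reputation label(s): ",
                        paste(bad, collapse = ", "))
  codes <- if (coding == "symmetric") {
    c(negative = -1, unknown = 0, positive = 1)
  } else {
    c(negative = -1, unknown = 0.5, positive = 1)
  }
  unname(codes[label])
}

#' Reputation labels
#' @format Character vector: negative (B), unknown (U), positive (G).
#' @export
reputation_labels <- c("negative", "unknown", "positive")

# Recursively merge user values into the default tree, rejecting unknown
# keys. `path` accumulates the JSON path for error messages.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (key in names(user)) {
    defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                    paste0(path, ".", key))
  }
  defaults
}

#' Validate a configuration tree
#'
#' Checks probability bounds (naming the offending entry), the payoff
#' ordering constraints, design sanity, and coefficient finiteness.
#'
#' @param config nested list as returned by \code{\link{default_config}}.
#' @return The config, invisibly, on success; otherwise an error.
#' @export
validate_config <- function(config) {
  # payoff constraints checked by the constructor
  do.call(payoff_matrix, stats::setNames(
    as.list(as.numeric(config$payoffs[c("T", "R", "P", "S")])),
    c("temptation", "reward", "punishment", "sucker")))
  for (nm in c("extortion", "generous")) {
    v <- as.numeric(config$strategies[[nm]])
    if (length(v) != 4L) stop("strategies.", nm, " must have 4 entries")
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad)) {
      stop("validation error: strategies.", nm, "[", bad[1],
           "] = ", v[bad[1]], " outside [0,1]")
    }
  }
  p0 <- config$strategies$p0
  if (!is.finite(p0) || p0 < 0 || p0 > 1) {
    stop("validation error: strategies.p0 = ", p0, " outside [0,1]")
  }
  display_policy(config$display_policy)  # validates overrides
  part <- config$participant
  coefs <- unlist(part$mean)
  if (!all(is.finite(coefs))) stop("participant.mean has non-finite entries")
  sds <- unlist(part$sd)
  if (!all(is.finite(sds)) || any(sds < 0)) {
    stop("participant.sd entries must be finite and >= 0")
  }
  if (part$sigma_a < 0 || part$sigma_w < 0) {
    stop("rating noise SDs sigma_a, sigma_w must be >= 0")
  }
  match.arg(part$rep_coding, c("asymmetric", "symmetric"))
  if (config$design$rounds < 1) stop("design.rounds must be >= 1")
  if (config$design$n_per_cell < 1) stop("design.n_per_cell must be >= 1")
  alpha <- config$analysis$alpha
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("analysis.alpha must be in (0,1)")
  }
  invisible(config)
}

#' Load a configuration from JSON
#'
#' Reads the file, fills unspecified fields with the defaults, rejects
#' unknown keys (with the offending path in the message), and validates.
#'
#' @param path path to a JSON configuration file.
#' @return Validated configuration list.
#' @seealso \code{\link{save_config}}, \code{\link{default_config}}
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Save a configuration to JSON
#'
#' @param config configuration list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
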
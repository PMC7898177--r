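# Shared fixtures, built in code.

default_pm <- payoff_matrix()
default_fv <- payoff_vectors(default_pm)

# A tiny hand-checkable dataset: 3 participants, 4 rounds each, one cell.
toy_trials <- function() {
  moves_p <- list(c("C", "C", "C", "C"),   # rate 1.0
                  c("C", "D", "C", "D"),   # rate 0.5
                  c("D", "D", "D", "C"))   # rate 0.25
  moves_c <- list(c("C", "C", "D", "C"),
                  c("C", "D", "C", "C"),
                  c("D", "C", "D", "D"))
  do.call(rbind, lapply(1:3, function(i) {
    out <- outcome_from_moves(moves_p[[i]], moves_c[[i]])
    data.frame(participant = i, cell_rep = "unknown",
               cell_strategy = "generous", cell_emotion = "cooperative",
               round = 1:4, participant_move = moves_p[[i]],
               counterpart_move = moves_c[[i]], outcome = out,
               expression = display_for("cooperative",
                                        swap_perspective(out)),
               participant_payoff = unname(default_fv$fX[out]),
               counterpart_payoff = unname(default_fv$fY[out]),
               stringsAsFactors = FALSE)
  }))
}

# Build a full-factorial ratings dataset with prescribed per-cell means for
# norm-derivation tests (noise sd fixed, seeded by the caller).
synthetic_cell_dataset <- function(cell_means, n = 40, noise_sd = 10) {
  cells <- design_cells()
  stopifnot(length(cell_means) == nrow(cells))
  trials <- list(); ratings <- list(); pid <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (k in seq_len(n)) {
      pid <- pid + 1L
      trials[[pid]] <- data.frame(
        participant = pid, cell_rep = cells$cell_rep[ci],
        cell_strategy = cells$cell_strategy[ci],
        cell_emotion = cells$cell_emotion[ci], round = 1L,
        participant_move = "C", counterpart_move = "C", outcome = "CC",
        expression = "neutral", participant_payoff = 3,
        counterpart_payoff = 3, stringsAsFactors = FALSE)
      ratings[[pid]] <- data.frame(
        participant = pid, initial_rating = 0,
        final_rating = max(-50, min(50, cell_means[ci] +
                                      rnorm(1, 0, noise_sd))))
    }
  }
  list(trials = do.call(rbind, trials), ratings = do.call(rbind, ratings),
       config = default_config())
}
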
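# Emotion-based social-norm tables: per-cell one-sample t-tests on final
# reputation and on reputation change classify each of the 18 design cells
# as negative (B), neutral (N) or positive (G), and as moving reputation
# down, not at all, or up.

.letter_of <- list(
  rep = c(negative = "B", unknown = "U", positive = "G"),
  strategy = c(extortion = "B", generous = "G"),
  emotion = c(competitive = "B", neutral = "N", cooperative = "G")
)

norm_letter <- function(kind, label) {
  map <- .letter_of[[kind]]
  out <- ifelse(label %in% map, label, unname(map[label]))
  if (anyNA(out)) {
    stop("unknown ", kind, " label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  }
  out
}

classify_mean <- function(tt, alpha) {
  if (tt$p < alpha) {
    if (tt$mean > 0) "G" else "B"
  } else "N"
}

#' Derive the emotion-based social-norm table from a dataset
#'
#' For each of the 18 (reputation x strategy x emotion) cells, runs
#' one-sample t-tests of the final reputation ratings and of the reputation
#' changes against 0 (the neutral point of the -50..+50 scale), and
#' classifies the cell: positive/G when the mean is significantly above 0,
#' negative/B when significantly below, neutral/N otherwise; analogously
#' up / neutral / down for the change direction.
#'
#' @param dataset an \code{\link{experiment_dataset}} or a list with
#'   \code{trials} and \code{ratings} in the CSV schemas.
#' @param alpha per-cell significance level (default 0.05, uncorrected
#'   across the 18 cells; set \code{correction = TRUE} for a Bonferroni
#'   correction over the cells).
#' @param correction logical; multiply per-cell p-values by 18 before
#'   thresholding.
#' @return Object of class \code{norm_table}: list with \code{cells} (18-row
#'   data frame: letter keys \code{rep}, \code{strategy}, \code{emotion};
#'   \code{n}; mean, t, df, p and class for both final rating and change;
#'   \code{change_dir} in \{down, neutral, up\}) and \code{meta} (alpha,
#'   correction flag, dataset fingerprint).
#' @export
derive_norm_table <- function(dataset, alpha = 0.05, correction = FALSE) {
  tr <- dataset$trials
  rt <- dataset$ratings
  first <- tr[!duplicated(tr$participant),
              c("participant", "cell_rep", "cell_strategy", "cell_emotion")]
  rt <- merge(rt, first, by = "participant")
  rt$change <- rt$final_rating - rt$initial_rating

  cells <- design_cells()
  have <- unique(rt[c("cell_rep", "cell_strategy", "cell_emotion")])
  missing <- !apply(cells, 1L, function(row) {
    any(have$cell_rep == row[1] & have$cell_strategy == row[2] &
          have$cell_emotion == row[3])
  })
  if (any(missing)) {
    stop("missing design cell(s): ",
         paste(apply(cells[missing, ], 1L, paste, collapse = ":"),
               collapse = ", "))
  }
  mult <- if (correction) nrow(cells) else 1
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    sel <- rt$cell_rep == cells$cell_rep[ci] &
      rt$cell_strategy == cells$cell_strategy[ci] &
      rt$cell_emotion == cells$cell_emotion[ci]
    if (sum(sel) < 2L) {
      stop("cell ", paste(cells[ci, ], collapse = ":"),
           " has fewer than 2 participants")
    }
    tf <- one_sample_t(rt$final_rating[sel])
    tc <- one_sample_t(rt$change[sel])
    tf$p <- min(1, tf$p * mult); tc$p <- min(1, tc$p * mult)
    fin <- classify_mean(tf, alpha)
    chg <- classify_mean(tc, alpha)
    data.frame(
      rep = norm_letter("rep", cells$cell_rep[ci]),
      strategy = norm_letter("strategy", cells$cell_strategy[ci]),
      emotion = norm_letter("emotion", cells$cell_emotion[ci]),
      n = sum(sel),
      final_mean = tf$mean, final_t = tf$t, final_df = tf$df, final_p = tf$p,
      final_class = fin,
      change_mean = tc$mean, change_t = tc$t, change_df = tc$df,
      change_p = tc$p,
      change_class = chg,
      change_dir = c(B = "down", N = "neutral", G = "up")[[chg]],
      stringsAsFactors = FALSE)
  })
  cells_df <- do.call(rbind, rows)
  rownames(cells_df) <- NULL
  fingerprint <- sprintf("n=%d;sumfinal=%.6f;suminit=%.6f", nrow(rt),
                         sum(rt$final_rating), sum(rt$initial_rating))
  structure(list(cells = cells_df,
                 meta = list(alpha = alpha, correction = correction,
                             dataset = fingerprint)),
            class = "norm_table")
}

#' Look up one cell of a norm table
#'
#' @param table a \code{\link{derive_norm_table}} result.
#' @param rep reputation key: letter (\code{"B"}, \code{"U"}, \code{"G"}) or
#'   label (\code{"negative"}, ...).
#' @param strategy strategy key: \code{"B"}/\code{"extortion"} or
#'   \code{"G"}/\code{"generous"}.
#' @param emotion emotion key: \code{"B"}/\code{"competitive"},
#'   \code{"N"}/\code{"neutral"}, \code{"G"}/\code{"cooperative"}.
#' @return List with \code{final_class} (\code{"B"}, \code{"N"} or
#'   \code{"G"}) and \code{change_dir} (\code{"down"}, \code{"neutral"},
#'   \code{"up"}).
#' @export
norm_lookup <- function(table, rep, strategy, emotion) {
  stopifnot(inherits(table, "norm_table"))
  r <- norm_letter("rep", rep)
  s <- norm_letter("strategy", strategy)
  e <- norm_letter("emotion", emotion)
  sel <- table$cells$rep == r & table$cells$strategy == s &
    table$cells$emotion == e
  if (sum(sel) != 1L) stop("no such cell: ", r, ":", s, ":", e)
  list(final_class = table$cells$final_class[sel],
       change_dir = table$cells$change_dir[sel])
}

#' Update a reputation label through a derived norm
#'
#' Deterministic reputation dynamics: the next label is the final-reputation
#' class of the norm cell indexed by the current label and the observed
#' behavior and emotion classes, mapped B to negative, N to unknown, G to
#' positive. This mapping of the three-class final reputation onto the three
#' experimental labels extrapolates beyond the original factorial design and
#' exists to enable iterated reputation dynamics.
#'
#' @param table a \code{\link{norm_table}}.
#' @param current current reputation label or letter.
#' @param behavior observed behavior class (strategy key).
#' @param emotion observed emotion class (emotion key).
#' @return Next reputation label (\code{"negative"}, \code{"unknown"} or
#'   \code{"positive"}).
#' @export
apply_norm <- function(table, current, behavior, emotion) {
  cell <- norm_lookup(table, current, behavior, emotion)
  c(B = "negative", N = "unknown", G = "positive")[[cell$final_class]]
}

#' Compare two norm tables cell by cell
#'
#' @param t1,t2 complete \code{\link{norm_table}} objects.
#' @return List with \code{final_agreement} and \code{change_agreement}
#'   (fractions of the 18 cells agreeing), and \code{disagreements}, a data
#'   frame listing the differing cells.
#' @export
compare_tables <- function(t1, t2) {
  stopifnot(inherits(t1, "norm_table"), inherits(t2, "norm_table"))
  key <- c("rep", "strategy", "emotion")
  m <- merge(t1$cells[, c(key, "final_class", "change_dir")],
             t2$cells[, c(key, "final_class", "change_dir")],
             by = key, suffixes = c("_1", "_2"))
  stopifnot(nrow(m) == 18L)
  fin_ok <- m$final_class_1 == m$final_class_2
  chg_ok <- m$change_dir_1 == m$change_dir_2
  list(final_agreement = mean(fin_ok),
       change_agreement = mean(chg_ok),
       disagreements = m[!(fin_ok & chg_ok), , drop = FALSE])
}

#' @export
print.norm_table <- function(x, ...) {
  cat(sprintf("emotion-based social-norm table (alpha = %g%s)\n",
              x$meta$alpha,
              if (x$meta$correction) ", Bonferroni over cells" else ""))
  cat(" rep strategy emotion | final change\n")
  for (i in seq_len(nrow(x$cells))) {
    r <- x$cells[i, ]
    cat(sprintf("  %s      %s       %s    |   %s   %s\n", r$rep, r$strategy,
                r$emotion, r$final_class,
                c(down = "v", neutral = "=", up = "^")[[r$change_dir]]))
  }
  invisible(x)
}

#' Serialize / read a norm table as JSON
#'
#' The JSON form stores all 18 cells with explicit keys and the supporting
#' test statistics, plus the derivation metadata.
#'
#' @param table a \code{\link{norm_table}}.
#' @param path output (input) path.
#' @return \code{path} invisibly (\code{write_norm_table}); a
#'   \code{norm_table} (\code{read_norm_table}).
#' @export
write_norm_table <- function(table, path) {
  stopifnot(inherits(table, "norm_table"))
  jsonlite::write_json(list(cells = table$cells, meta = table$meta), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_norm_table
#' @export
read_norm_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cells = as.data.frame(obj$cells), meta = as.list(obj$meta)),
            class = "norm_table")
}
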
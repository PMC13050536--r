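# Tie-break priority for equal signal values: H3K4me3 > H3K4me1 > CTCF >
# H3K27ac. The tied track earliest in this list takes the smaller (better)
# rank. Isolated here so the policy can be changed in one place.
DEFAULT_TIE_PRIORITY <- c("H3K4me3", "H3K4me1", "CTCF", "H3K27ac")

#' Rank four track signals within a region
#'
#' Rank 1 is the largest signal. Ties are broken by a fixed track priority so
#' that every row is a strict permutation of 1..4.
#'
#' @param signals Numeric vector of 4 non-negative values in [cre_tracks()]
#'   order (H3K4me1, H3K4me3, H3K27ac, CTCF).
#' @param tie_priority Track names, highest priority first.
#' @return Integer vector of 4 ranks (a permutation of 1:4).
#' @export
rank_row <- function(signals, tie_priority = DEFAULT_TIE_PRIORITY) {
  if (length(signals) != 4 || anyNA(signals)) {
    abort("`signals` must be 4 non-missing values in fixed track order")
  }
  if (any(signals < 0)) abort("negative signal value: signals must be >= 0")
  prio <- match(TRACKS, tie_priority)
  o <- order(-signals, prio)
  ranks <- integer(4)
  ranks[o] <- 1:4
  ranks
}

# Phase-1 clause sets, one logical per class. `s` = signals, `r` = ranks,
# both in t1..t4 order (t1=H3K4me1, t2=H3K4me3, t3=H3K27ac, t4=CTCF).
phase1_clauses <- function(s, r) {
  c(
    Enhancer = (r[1] == 1 && r[2] == 2) ||
               (r[1] == 1 && r[3] == 2) ||
               (r[1] == 2 && r[3] == 1) ||
               (r[1] == 1 && s[2] == 0 && s[3] == 0 && s[4] == 0),
    Promoter = (r[2] == 1 && r[1] == 2) ||
               (r[2] == 1 && r[3] == 2) ||
               (r[2] == 2 && r[3] == 1) ||
               (r[2] == 1 && s[1] == 0 && s[3] == 0 && s[4] == 0),
    CTCF     = (r[4] == 1 && r[3] == 2) ||
               (r[4] == 2 && r[3] == 1) ||
               (r[4] == 1 && s[1] == 0 && s[2] == 0 && s[3] == 0)
  )
}

# Phase-2 clause sets for the two hybrid classes.
phase2_clauses <- function(s, r) {
  c(
    `Enhancer/CTCF` = (r[4] == 1 && r[1] == 2 && s[1] != 0 && s[4] != 0) ||
                      (r[4] == 2 && r[1] == 1 && s[1] != 0 && s[4] != 0) ||
                      (s[1] != 0 && s[2] == 0 && s[3] != 0 && s[4] != 0),
    `Promoter/CTCF` = (r[4] == 1 && r[2] == 2 && s[2] != 0 && s[4] != 0) ||
                      (r[4] == 2 && r[2] == 1 && s[2] != 0 && s[4] != 0) ||
                      (s[1] == 0 && s[2] != 0 && s[3] != 0 && s[4] != 0)
  )
}

#' Phase-1 label: Enhancer, Promoter, CTCF or Not assigned
#'
#' Evaluates the phase-1 rule clauses on one region's signals and ranks. A row
#' whose four signals are all exactly zero is forced to "Not assigned": its
#' ranks are pure tie-break artifacts and must not fire the
#' "only-this-track-nonzero" clauses vacuously. Zero tests use exact equality
#' — a normalized signal is 0 only when the region has no peak coverage at
#' all.
#'
#' @param signals Numeric vector of 4 signals in track order.
#' @param ranks Ranks from [rank_row()] on the same signals.
#' @return One of "Enhancer", "Promoter", "CTCF", "Not assigned".
#' @export
assign_primary_label <- function(signals, ranks) {
  if (all(signals == 0)) return("Not assigned")
  cl <- phase1_clauses(signals, ranks)
  if (cl[["Enhancer"]]) return("Enhancer")
  if (cl[["Promoter"]]) return("Promoter")
  if (cl[["CTCF"]]) return("CTCF")
  "Not assigned"
}

#' Phase-2 label: detect CTCF-co-accessible enhancers and promoters
#'
#' When a phase-2 clause fires it overrides the phase-1 label; otherwise the
#' phase-1 label stands. If clauses for both hybrid classes fire
#' simultaneously (unreachable under strict ranks; covered for completeness),
#' the tie is resolved toward Enhancer/CTCF when the H3K4me1 signal exceeds
#' the H3K4me3 signal.
#'
#' @param signals,ranks As in [assign_primary_label()].
#' @param primary The phase-1 label.
#' @param hybrid_scope `"all"` evaluates the hybrid clauses on every region
#'   (Not assigned rows remain eligible for the sign-pattern clauses);
#'   `"phase1_labelled"` restricts them to regions phase 1 labelled Enhancer
#'   or Promoter.
#' @return The final label.
#' @export
assign_hybrid_label <- function(signals, ranks, primary,
                                hybrid_scope = c("all", "phase1_labelled")) {
  hybrid_scope <- match.arg(hybrid_scope)
  if (hybrid_scope == "phase1_labelled" &&
      !primary %in% c("Enhancer", "Promoter")) {
    return(primary)
  }
  if (all(signals == 0)) return(primary)
  cl <- phase2_clauses(signals, ranks)
  if (cl[["Enhancer/CTCF"]] && cl[["Promoter/CTCF"]]) {
    return(if (signals[1] > signals[2]) "Enhancer/CTCF" else "Promoter/CTCF")
  }
  if (cl[["Enhancer/CTCF"]]) return("Enhancer/CTCF")
  if (cl[["Promoter/CTCF"]]) return("Promoter/CTCF")
  primary
}

#' Active/inactive subclass for enhancer labels
#'
#' Enhancers (and Enhancer/CTCF elements) are active when their normalized
#' H3K27ac signal exceeds `threshold`; other labels are not applicable.
#'
#' @param signals Numeric vector of 4 signals in track order.
#' @param label Final regulatory label.
#' @param threshold Non-negative H3K27ac activity threshold (default 0:
#'   presence/absence).
#' @return "active", "inactive" or "not-applicable".
#' @export
classify_enhancer_activity <- function(signals, label, threshold = 0) {
  if (threshold < 0) abort("`threshold` must be >= 0")
  if (!label %in% c("Enhancer", "Enhancer/CTCF")) return("not-applicable")
  if (signals[3] > threshold) "active" else "inactive"
}

#' Classify all regions of a signal matrix
#'
#' Applies the rank transform, the phase-1 and phase-2 rule clauses, and the
#' enhancer activity subclassing to every row. Rows are independent and the
#' result is deterministic.
#'
#' @param signal_matrix Tibble with `chrom`, `start`, `end` and the four
#'   `A_*` signal columns (from [compute_signal_matrix()] or
#'   [read_signal_matrix()]).
#' @param activity_threshold H3K27ac threshold for the active/inactive
#'   enhancer subclass.
#' @param hybrid_scope See [assign_hybrid_label()].
#' @param tie_priority See [rank_row()].
#' @return A `cre_annotation` tibble: input columns plus `R_*` ranks, `label`
#'   (factor over [cre_labels()]) and `activity`.
#' @export
classify_regions <- function(signal_matrix, activity_threshold = 0,
                             hybrid_scope = c("all", "phase1_labelled"),
                             tie_priority = DEFAULT_TIE_PRIORITY) {
  hybrid_scope <- match.arg(hybrid_scope)
  x <- as_tibble(signal_matrix)
  sig_cols <- paste0("A_", TRACKS)
  missing <- setdiff(sig_cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("signal matrix lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(x)
  sig <- as.matrix(x[, sig_cols])
  ranks <- matrix(NA_integer_, n, 4)
  label <- character(n)
  activity <- character(n)
  for (i in seq_len(n)) {
    s <- sig[i, ]
    r <- rank_row(s, tie_priority)
    p1 <- assign_primary_label(s, r)
    lab <- assign_hybrid_label(s, r, p1, hybrid_scope)
    ranks[i, ] <- r
    label[i] <- lab
    activity[i] <- classify_enhancer_activity(s, lab, activity_threshold)
  }
  for (j in 1:4) x[[paste0("R_", TRACKS[j])]] <- ranks[, j]
  x$label <- factor(label, levels = CRE_LABELS)
  x$activity <- activity
  class(x) <- c("cre_annotation", class(x))
  x
}
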
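# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the rule evaluator is a table-driven re-statement
# of the clause sets, and the pileup oracle is a plain per-base loop.

TRK <- cre_tracks()

# ---- rule-engine oracle ----------------------------------------------------
# Each clause is a list of (kind, track index, value) conditions; a clause
# fires when all its conditions hold. kind "r" compares a rank, "z" requires
# signal == 0, "nz" requires signal != 0.
.cond <- function(kind, i, v = NULL) list(kind = kind, i = i, v = v)
.clause_fires <- function(clause, s, r) {
  all(vapply(clause, function(cd) {
    switch(cd$kind,
           r = r[cd$i] == cd$v,
           z = s[cd$i] == 0,
           nz = s[cd$i] != 0)
  }, logical(1)))
}

ORACLE_PHASE1 <- list(
  Enhancer = list(
    list(.cond("r", 1, 1), .cond("r", 2, 2)),
    list(.cond("r", 1, 1), .cond("r", 3, 2)),
    list(.cond("r", 1, 2), .cond("r", 3, 1)),
    list(.cond("r", 1, 1), .cond("z", 2), .cond("z", 3), .cond("z", 4))
  ),
  Promoter = list(
    list(.cond("r", 2, 1), .cond("r", 1, 2)),
    list(.cond("r", 2, 1), .cond("r", 3, 2)),
    list(.cond("r", 2, 2), .cond("r", 3, 1)),
    list(.cond("r", 2, 1), .cond("z", 1), .cond("z", 3), .cond("z", 4))
  ),
  CTCF = list(
    list(.cond("r", 4, 1), .cond("r", 3, 2)),
    list(.cond("r", 4, 2), .cond("r", 3, 1)),
    list(.cond("r", 4, 1), .cond("z", 1), .cond("z", 2), .cond("z", 3))
  )
)

ORACLE_PHASE2 <- list(
  `Enhancer/CTCF` = list(
    list(.cond("r", 4, 1), .cond("r", 1, 2), .cond("nz", 1), .cond("nz", 4)),
    list(.cond("r", 4, 2), .cond("r", 1, 1), .cond("nz", 1), .cond("nz", 4)),
    list(.cond("nz", 1), .cond("z", 2), .cond("nz", 3), .cond("nz", 4))
  ),
  `Promoter/CTCF` = list(
    list(.cond("r", 4, 1), .cond("r", 2, 2), .cond("nz", 2), .cond("nz", 4)),
    list(.cond("r", 4, 2), .cond("r", 2, 1), .cond("nz", 2), .cond("nz", 4)),
    list(.cond("z", 1), .cond("nz", 2), .cond("nz", 3), .cond("nz", 4))
  )
)

oracle_fired <- function(clauses, s, r) {
  any(vapply(clauses, .clause_fires, logical(1), s = s, r = r))
}

# Full two-phase oracle label for one signal row (ranks supplied).
oracle_label <- function(s, r) {
  phase1 <- if (all(s == 0)) "Not assigned" else {
    fired <- names(ORACLE_PHASE1)[vapply(ORACLE_PHASE1, oracle_fired,
                                         logical(1), s = s, r = r)]
    if (length(fired) > 0) fired[1] else "Not assigned"
  }
  if (all(s == 0)) return(phase1)
  h <- vapply(ORACLE_PHASE2, oracle_fired, logical(1), s = s, r = r)
  if (h[["Enhancer/CTCF"]] && h[["Promoter/CTCF"]]) {
    return(if (s[1] > s[2]) "Enhancer/CTCF" else "Promoter/CTCF")
  }
  if (h[["Enhancer/CTCF"]]) return("Enhancer/CTCF")
  if (h[["Promoter/CTCF"]]) return("Promoter/CTCF")
  phase1
}

# Every consistent signal row covering all strict-rank permutations x
# zero/nonzero sign patterns: for each subset of zero tracks, all orders of
# distinct positive values over the remaining tracks.
enumerate_signal_rows <- function(values = c(40, 30, 20, 10)) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  rows <- list()
  for (zmask in 0:15) {
    zero <- which(bitwAnd(zmask, c(1L, 2L, 4L, 8L)) > 0)
    nonzero <- setdiff(1:4, zero)
    if (length(nonzero) == 0) {
      rows[[length(rows) + 1]] <- c(0, 0, 0, 0)
      next
    }
    for (p in perms(values[seq_along(nonzero)])) {
      s <- numeric(4)
      s[nonzero] <- p
      rows[[length(rows) + 1]] <- s
    }
  }
  rows
}

# ---- pileup oracle ---------------------------------------------------------
# Per-base coverage of a read table over a linear toy chromosome.
pileup_vector <- function(reads, genome_length) {
  v <- numeric(genome_length)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i] + 1
    e <- min(reads$end[i], genome_length)
    if (s <= e) v[s:e] <- v[s:e] + 1
  }
  v
}

# Brute-force normalized signal of one region against one track: per-base
# pileup summed over bases that are both in the region and in a peak.
oracle_signal <- function(region, peaks, reads, genome_length) {
  v <- pileup_vector(reads, genome_length)
  in_peak <- logical(genome_length)
  for (i in seq_len(nrow(peaks))) {
    in_peak[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
  }
  bases <- (region$start + 1):region$end
  num <- sum(v[bases][in_peak[bases]])
  1e6 * num / sum(v)
}

# ---- misc helpers ----------------------------------------------------------
random_intervals <- function(n, genome_length, min_w = 50, max_w = 400,
                             chrom = "chrT") {
  w <- floor(runif(n, min_w, max_w))
  s <- floor(runif(n, 0, genome_length - max_w - 1))
  tibble::tibble(chrom = chrom, start = s, end = s + w)
}

random_reads <- function(n, genome_length, read_length = 50, chrom = "chrT") {
  s <- floor(runif(n, 0, genome_length - read_length))
  tibble::tibble(chrom = chrom, start = s, end = s + read_length)
}

# one shared on-disk fixture per session for the pipeline-level tests
fixture_paths <- local({
  cache <- NULL
  function(count = 10, noise = 0, seed = 101, subdir = "fx-shared") {
    key <- paste(count, noise, seed, subdir)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$paths)
    ds <- simulate_dataset(cre_archetypes(count = count),
                           noise_level = noise, seed = seed)
    dir <- file.path(tempdir(), subdir)
    paths <- write_dataset(ds, dir)
    paths$dataset <- ds
    cache <<- list(key = key, paths = paths)
    paths
  }
})

fixture_config <- function(paths, out_dir, ...) {
  cre_config(accessibility_peaks = paths$accessibility_peaks,
             tracks = paths$tracks, out_dir = out_dir,
             genes = paths$genes, variants = paths$variants, ...)
}
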
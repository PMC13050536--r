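#' Area under the coverage curve over regions
#'
#' Summed per-base read coverage of each region: the integral of the pileup
#' restricted to the region. Disjoint regions are additive; an empty interval
#' set has auc 0.
#'
#' @param regions Interval tibble (may be empty).
#' @param source A `cre_alignments` object or a BAM path.
#' @return Numeric vector, one value per region row.
#' @export
auc <- function(regions, source) {
  source <- as_alignments(source)
  regions <- as_intervals(regions, "regions")
  if (nrow(regions) == 0) return(numeric())
  cov_sums(coverage_from_alignments(source), regions)
}

#' Genome-wide area under the coverage curve
#'
#' Equals the sum of aligned reference lengths over all retained reads, and is
#' the per-track normalization denominator.
#'
#' @param source A `cre_alignments` object or a BAM path.
#' @return A positive scalar.
#' @export
genome_auc <- function(source) {
  source <- as_alignments(source)
  if (nrow(source$reads) == 0) {
    abort("alignment source has no reads: genome-wide coverage is 0")
  }
  sum(source$reads$end - source$reads$start)
}

as_alignments <- function(x) {
  if (inherits(x, "cre_alignments")) return(x)
  if (is.character(x) && length(x) == 1) return(read_alignments(x))
  abort("expected a cre_alignments object or a BAM file path")
}

# base-level intersection of each region with a peak set; returns a tibble of
# pieces (chrom, start, end, region = originating row index)
region_peak_intersection <- function(regions, peaks) {
  if (nrow(regions) == 0 || nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  region = integer()))
  }
  gr_r <- iv_to_gr(regions)
  gr_p <- GenomicRanges::reduce(iv_to_gr(peaks))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_p, minoverlap = 1L)
  if (length(hits) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  region = integer()))
  }
  q <- S4Vectors::queryHits(hits)
  pieces <- GenomicRanges::pintersect(gr_r[q], gr_p[S4Vectors::subjectHits(hits)])
  out <- gr_to_iv(pieces)
  out$region <- q
  out
}

#' Depth-normalized signal matrix over candidate regions
#'
#' For each region r and track t, the signal is
#' `1e6 * auc(r intersect peaks_t) / genome_auc(t)`: per-base coverage summed
#' over the base-level intersection of the region with the track's peaks,
#' scaled to per-million of the track's genome-wide coverage. A region with no
#' peak overlap scores exactly 0 for that track — zeros are meaningful to the
#' classifier and no pseudocount is added.
#'
#' @param regions Interval tibble of candidate regions (order preserved).
#' @param peaks Named list of interval tibbles, one per track in
#'   [cre_tracks()].
#' @param alignments Named list of `cre_alignments` objects or BAM paths, one
#'   per track.
#' @param auc_mode `"area"` (summed per-base coverage, the default) or
#'   `"read_count"` (reads overlapping the intersection, normalized by total
#'   read count).
#' @param workers Number of parallel workers for per-region quantification.
#'   Results are identical for any worker count.
#' @return `regions` with four signal columns `A_H3K4me1`, `A_H3K4me3`,
#'   `A_H3K27ac`, `A_CTCF` appended.
#' @export
compute_signal_matrix <- function(regions, peaks, alignments,
                                  auc_mode = c("area", "read_count"),
                                  workers = 1L) {
  auc_mode <- match.arg(auc_mode)
  regions <- as_intervals(regions, "regions")
  for (t in TRACKS) {
    if (!t %in% names(peaks)) abort(sprintf("missing peak list for track %s", t))
    if (!t %in% names(alignments)) abort(sprintf("missing alignments for track %s", t))
  }
  n <- nrow(regions)
  out <- regions
  if (n == 0) {
    for (t in TRACKS) out[[paste0("A_", t)]] <- numeric()
    return(out)
  }
  if (.Platform$OS.type != "unix") workers <- 1L  # mclapply needs fork()
  chunk_idx <- if (workers > 1L) {
    split(seq_len(n), cut(seq_len(n), breaks = workers, labels = FALSE))
  } else {
    list(seq_len(n))
  }
  for (t in TRACKS) {
    aln <- as_alignments(alignments[[t]])
    pk <- as_intervals(peaks[[t]], sprintf("peaks$%s", t))
    denom <- if (auc_mode == "area") genome_auc(aln) else nrow(aln$reads)
    if (denom <= 0) abort(sprintf("track %s has zero genome-wide coverage", t))
    cov <- if (auc_mode == "area") coverage_from_alignments(aln) else NULL
    quantify <- function(idx) {
      pieces <- region_peak_intersection(regions[idx, , drop = FALSE], pk)
      vals <- numeric(length(idx))
      if (nrow(pieces) == 0) return(vals)
      if (auc_mode == "area") {
        piece_auc <- cov_sums(cov, pieces)
        agg <- rowsum(piece_auc, group = pieces$region)
      } else {
        gr_reads <- iv_to_gr(aln$reads)
        hits <- GenomicRanges::findOverlaps(gr_reads, iv_to_gr(pieces),
                                            minoverlap = 1L)
        pr <- unique(tibble(read = S4Vectors::queryHits(hits),
                            region = pieces$region[S4Vectors::subjectHits(hits)]))
        if (nrow(pr) == 0) return(vals)
        agg <- rowsum(rep(1, nrow(pr)), group = pr$region)
      }
      vals[as.integer(rownames(agg))] <- agg[, 1]
      vals
    }
    res <- if (workers > 1L) {
      parallel::mclapply(chunk_idx, quantify, mc.cores = workers)
    } else {
      lapply(chunk_idx, quantify)
    }
    out[[paste0("A_", t)]] <- 1e6 * unlist(res, use.names = FALSE) / denom
  }
  out
}

#' Write / read the signal-matrix exchange TSV
#'
#' Plain TSV with `chrom`, `start`, `end` and the four `A_*` signal columns;
#' the interchange format between the quantification and classification
#' stages.
#'
#' @param signal_matrix Output of [compute_signal_matrix()].
#' @param path File path.
#' @return `path` (write) or the signal tibble (read).
#' @export
write_signal_matrix <- function(signal_matrix, path) {
  cols <- c("chrom", "start", "end", paste0("A_", TRACKS))
  x <- as_tibble(signal_matrix)[, cols]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  x <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(chrom = "character")))
  need <- c("chrom", "start", "end", paste0("A_", TRACKS))
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("signal matrix lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x[, need]
}
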
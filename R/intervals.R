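#' Validate an interval tibble
#'
#' Intervals are tibbles with columns `chrom` (character), `start`, `end`
#' (0-based half-open, in bp). Extra columns are carried along untouched.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return `x` as a tibble, invariants checked.
#' @export
as_intervals <- function(x, arg = "x") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks interval column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(x$start < 0)) abort(sprintf("`%s`: negative start coordinate", arg))
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf("`%s`: start >= end at row %d (zero-length intervals are invalid)",
                  arg, bad))
  }
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed). Extra columns dropped.
iv_to_gr <- function(x, seqlengths = NULL) {
  x <- as_intervals(x)
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) {
      s <- x$strand
      s[is.na(s) | !s %in% c("+", "-")] <- "*"
      s
    } else "*"
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

gr_to_iv <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Remove regions overlapping a blacklist
#'
#' A region is dropped on any overlap of one base or more with any blacklist
#' interval; regions are never trimmed. Coordinates are half-open, so a region
#' whose end equals a blacklist start merely touches it and is retained.
#'
#' @param regions Interval tibble.
#' @param blacklist Interval tibble of excluded regions (may have zero rows,
#'   or be `NULL`, in which case `regions` is returned unchanged).
#' @return The retained rows of `regions`, original order preserved.
#' @export
remove_blacklisted <- function(regions, blacklist = NULL) {
  regions <- as_intervals(regions, "regions")
  if (is.null(blacklist)) return(regions)
  blacklist <- as_intervals(blacklist, "blacklist")
  if (nrow(blacklist) == 0 || nrow(regions) == 0) return(regions)
  hits <- GenomicRanges::countOverlaps(iv_to_gr(regions), iv_to_gr(blacklist),
                                       minoverlap = 1L)
  regions[hits == 0L, , drop = FALSE]
}

# deterministic coordinate sort: chrom (C-locale lexicographic), start, end
sort_intervals <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}
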
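#' Build the candidate-region set from accessibility and CTCF peaks
#'
#' Concatenates the two peak lists, removes exact coordinate duplicates
#' (overlapping but non-identical peaks are both kept as distinct candidates),
#' filters against the blacklist, and returns the regions in deterministic
#' (chrom, start, end) order with a provenance column recording which source
#' contributed each region.
#'
#' @param accessibility_peaks Interval tibble of chromatin-accessibility peaks
#'   (ATAC/DNase).
#' @param ctcf_peaks Interval tibble of CTCF peaks. Ignored when
#'   `anchor_mode = "accessibility_only"`.
#' @param blacklist Optional interval tibble of excluded regions.
#' @param anchor_mode `"union"` (accessibility and CTCF peaks both anchor
#'   candidates) or `"accessibility_only"`.
#' @return Tibble with `chrom`, `start`, `end`, `provenance`
#'   (accessibility / CTCF / both).
#' @export
build_union_regions <- function(accessibility_peaks, ctcf_peaks,
                                blacklist = NULL,
                                anchor_mode = c("union", "accessibility_only")) {
  anchor_mode <- match.arg(anchor_mode)
  acc <- as_intervals(accessibility_peaks, "accessibility_peaks")[, c("chrom", "start", "end")]
  ctf <- as_intervals(ctcf_peaks, "ctcf_peaks")[, c("chrom", "start", "end")]
  if (anchor_mode == "accessibility_only") ctf <- ctf[0, ]
  # catch chr1-vs-1 style convention mismatches: no shared names, but names
  # agree once a leading "chr" is stripped
  if (nrow(acc) > 0 && nrow(ctf) > 0 &&
      length(intersect(unique(acc$chrom), unique(ctf$chrom))) == 0) {
    strip <- function(x) sub("^chr", "", unique(x))
    if (length(intersect(strip(acc$chrom), strip(ctf$chrom))) > 0) {
      abort(paste("accessibility and CTCF peaks share no chromosome names;",
                  "check the chromosome naming convention (e.g. chr1 vs 1)"))
    }
  }
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  acc_k <- unique(key(acc))
  ctf_k <- unique(key(ctf))
  all_tbl <- dplyr::distinct(dplyr::bind_rows(acc, ctf))
  k <- key(all_tbl)
  all_tbl$provenance <- dplyr::case_when(
    k %in% acc_k & k %in% ctf_k ~ "both",
    k %in% acc_k ~ "accessibility",
    TRUE ~ "CTCF"
  )
  all_tbl <- remove_blacklisted(all_tbl, blacklist)
  sort_intervals(all_tbl)
}

#' Per-region summed bigWig coverage for H3K4me1 and H3K4me3
#'
#' Entry (r, t) is the sum over all bases of region r of track t's coverage.
#' Used only for metaplot row ordering, never for classification.
#'
#' @param regions Interval tibble (the candidate regions).
#' @param me1,me3 Coverage tracks (`RleList`, e.g. from
#'   [read_coverage_track()]).
#' @return `regions` with columns `cov_H3K4me1` and `cov_H3K4me3` appended.
#' @export
compute_coverage_matrix <- function(regions, me1, me3) {
  regions <- as_intervals(regions, "regions")
  if (nrow(regions) == 0) abort("`regions` is empty")
  regions$cov_H3K4me1 <- cov_sums(me1, regions)
  regions$cov_H3K4me3 <- cov_sums(me3, regions)
  regions
}

#' Order regions by the H3K4me3 minus H3K4me1 coverage difference
#'
#' Returns the row indices of `cov` sorted by (me3 - me1) descending, ties
#' broken by (chrom, start, end) ascending. This is the stacking order of the
#' metaplot rows.
#'
#' @param cov Output of [compute_coverage_matrix()].
#' @return Integer permutation of `seq_len(nrow(cov))`.
#' @export
order_by_mark_difference <- function(cov) {
  need <- c("cov_H3K4me1", "cov_H3K4me3")
  if (!all(need %in% names(cov))) {
    abort("`cov` must carry cov_H3K4me1 and cov_H3K4me3 columns")
  }
  diff <- cov$cov_H3K4me3 - cov$cov_H3K4me1
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(-diff, cov$chrom, cov$start, cov$end)
}
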
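#' Strand-aware transcription start sites from gene records
#'
#' The TSS of a forward-strand gene is its start coordinate; of a
#' reverse-strand gene, its last covered base (`end - 1` in 0-based
#' half-open coordinates).
#'
#' @param genes Gene tibble from [read_gene_annotation()] (columns `chrom`,
#'   `start`, `end`, `strand`, `name`).
#' @return Tibble with `chrom`, `pos` (0-based TSS position), `strand`,
#'   `name`.
#' @export
build_tss_registry <- function(genes) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), pos = numeric(),
                  strand = character(), name = character()))
  }
  if (!"strand" %in% names(genes)) abort("`genes` lacks a strand column")
  ok <- genes$strand %in% c("+", "-")
  if (any(!ok)) {
    warn(sprintf("%d strandless gene record(s) skipped", sum(!ok)))
    genes <- genes[ok, , drop = FALSE]
  }
  tibble(
    chrom = genes$chrom,
    pos = ifelse(genes$strand == "+", genes$start, genes$end - 1),
    strand = genes$strand,
    name = if ("name" %in% names(genes)) genes$name else
      paste0("gene", seq_len(nrow(genes)))
  )
}

#' Log10 distance to the closest transcription start site
#'
#' For each region, `d` is the gap in bp to the nearest TSS: 0 when a TSS lies
#' inside the region, otherwise the edge-to-point distance (a TSS adjacent to
#' the region has d = 1). Returns `log10(d + 1)`. Regions on chromosomes with
#' no TSS get `NA` with a warning.
#'
#' @param regions Interval tibble.
#' @param tss TSS registry from [build_tss_registry()]; must be non-empty.
#' @return Numeric vector, one value per region.
#' @export
log_distance_to_tss <- function(regions, tss) {
  regions <- as_intervals(regions, "regions")
  if (nrow(tss) == 0) abort("TSS registry is empty")
  if (nrow(regions) == 0) return(numeric())
  gr_r <- iv_to_gr(regions)
  gr_t <- GenomicRanges::GRanges(tss$chrom,
                                 IRanges::IRanges(tss$pos + 1, width = 1))
  d <- rep(NA_real_, nrow(regions))
  nn <- GenomicRanges::distanceToNearest(gr_r, gr_t, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(nn)
  gap <- S4Vectors::mcols(nn)$distance
  inside <- GenomicRanges::countOverlaps(gr_r, gr_t) > 0
  d[q] <- gap + 1
  d[inside] <- 0
  if (anyNA(d)) {
    warn(sprintf("%d region(s) on chromosomes without any TSS: distance NA",
                 sum(is.na(d))))
  }
  log10(d + 1)
}

#' Intersect variant positions with annotated elements
#'
#' A variant is assigned to every element whose half-open interval contains
#' its position; a variant inside several overlapping elements contributes to
#' each of them and is flagged as a multi-hit.
#'
#' @param variants Tibble with `chrom`, `pos` (0-based bp) and optionally
#'   `id`.
#' @param annotations A `cre_annotation` tibble (or any interval tibble with a
#'   `label` column).
#' @return List of class `cre_variant_hits` with `per_variant` (one row per
#'   variant-element pair, unannotated variants labelled NA, `multi_hit`
#'   flag) and `per_label` (count of variants per label, plus an
#'   "unannotated" row; multi-hit variants count once per label they touch).
#' @export
intersect_variants <- function(variants, annotations) {
  variants <- as_tibble(variants)
  if (!all(c("chrom", "pos") %in% names(variants))) {
    abort("`variants` needs columns chrom and pos (0-based)")
  }
  if (any(variants$pos < 0)) abort("variant positions must be >= 0")
  if (!"id" %in% names(variants)) {
    variants$id <- paste0("var", seq_len(nrow(variants)))
  }
  ann <- as_intervals(annotations, "annotations")
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(gr_v, iv_to_gr(ann))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  nhits <- tabulate(q, nbins = nrow(variants))
  hit_tbl <- tibble(
    id = variants$id[q], chrom = variants$chrom[q], pos = variants$pos[q],
    element_chrom = ann$chrom[s], element_start = ann$start[s],
    element_end = ann$end[s],
    label = as.character(ann$label[s]),
    multi_hit = nhits[q] > 1
  )
  miss <- which(nhits == 0)
  if (length(miss) > 0) {
    hit_tbl <- dplyr::bind_rows(hit_tbl, tibble(
      id = variants$id[miss], chrom = variants$chrom[miss],
      pos = variants$pos[miss],
      element_chrom = NA_character_, element_start = NA_real_,
      element_end = NA_real_, label = NA_character_, multi_hit = FALSE
    ))
  }
  counts <- hit_tbl |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::distinct(.data$id, .data$label) |>
    dplyr::count(.data$label, name = "n_variants")
  counts <- dplyr::bind_rows(
    counts,
    tibble(label = "unannotated", n_variants = length(miss))
  )
  structure(list(per_variant = hit_tbl, per_label = counts),
            class = "cre_variant_hits")
}

#' @export
print.cre_variant_hits <- function(x, ...) {
  cat("<cre_variant_hits>\n")
  print(x$per_label)
  invisible(x)
}

#' Coverage metaplot matrix around region centres
#'
#' For each region, the window is `[centre - flank, centre + flank)` with
#' `centre = floor((start + end) / 2)`; each of the `2 * flank / bin_width`
#' bins holds the mean per-base coverage in that bin. Bases beyond chromosome
#' edges read 0.
#'
#' @param regions Interval tibble, already in the desired stacking order (see
#'   [order_by_mark_difference()]).
#' @param track Coverage `RleList`.
#' @param flank Half-window in bp (default 2000).
#' @param bin_width Bin size in bp (default 10); must divide `flank`.
#' @return A numeric matrix (`cre_metaplot`): regions x bins, with the
#'   region coordinates as row names.
#' @export
compute_metaplot <- function(regions, track, flank = 2000, bin_width = 10) {
  regions <- as_intervals(regions, "regions")
  if (flank %% bin_width != 0) abort("`flank` must be divisible by `bin_width`")
  nbin <- as.integer(2 * flank / bin_width)
  mat <- matrix(0, nrow(regions), nbin)
  for (i in seq_len(nrow(regions))) {
    centre <- floor((regions$start[i] + regions$end[i]) / 2)
    w0 <- centre - flank                      # 0-based window start
    vals <- numeric(2 * flank)
    ch <- regions$chrom[i]
    if (ch %in% names(track)) {
      r <- track[[ch]]
      lo <- max(w0, 0)
      hi <- min(w0 + 2 * flank, length(r))
      if (lo < hi) {
        vals[(lo - w0 + 1):(hi - w0)] <-
          as.numeric(IRanges::Views(r, start = lo + 1, end = hi)[[1]])
      }
    }
    mat[i, ] <- colMeans(matrix(vals, nrow = bin_width))
  }
  rownames(mat) <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  colnames(mat) <- seq(-flank, flank - bin_width, by = bin_width)
  class(mat) <- c("cre_metaplot", class(mat))
  attr(mat, "bin_width") <- bin_width
  attr(mat, "flank") <- flank
  mat
}

#' Label distribution over annotated regions
#'
#' Counts and percentages per regulatory label; "Not assigned" regions are
#' part of the denominator, so percentages sum to 100 within rounding.
#'
#' @param annotations A `cre_annotation` tibble.
#' @return Tibble with `label`, `n`, `percentage` (one row per label present).
#' @export
class_distribution <- function(annotations) {
  x <- as_tibble(annotations)
  if (nrow(x) == 0) {
    return(tibble(label = character(), n = integer(), percentage = numeric()))
  }
  x |>
    dplyr::count(label = as.character(.data$label)) |>
    dplyr::mutate(percentage = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
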
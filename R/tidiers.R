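#' Tidy a cre_annotation: one row per region-track observation
#'
#' Pivots the four signal and rank columns into long form, keeping the label
#' and activity subclass.
#'
#' @param x A `cre_annotation` tibble.
#' @param ... Unused.
#' @return Long tibble with `chrom`, `start`, `end`, `label`, `activity`,
#'   `track`, `signal`, `rank`.
#' @method tidy cre_annotation
#' @export
tidy.cre_annotation <- function(x, ...) {
  base <- as_tibble(x)[, c("chrom", "start", "end", "label", "activity")]
  sig <- as_tibble(x)[, paste0("A_", TRACKS)]
  rnk <- as_tibble(x)[, paste0("R_", TRACKS)]
  purrr::map_dfr(seq_along(TRACKS), function(j) {
    dplyr::mutate(base, track = TRACKS[j], signal = sig[[j]], rank = rnk[[j]])
  }) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' One-row summary of a cre_annotation
#'
#' @param x A `cre_annotation` tibble.
#' @param ... Unused.
#' @return Tibble with `n_regions`, `n_assigned`, `pct_assigned`, per-label
#'   counts, and active-enhancer count.
#' @method glance cre_annotation
#' @export
glance.cre_annotation <- function(x, ...) {
  lab <- as.character(x$label)
  counts <- setNames(
    lapply(CRE_LABELS, function(l) sum(lab == l)),
    paste0("n_", gsub("[ /]", "_", tolower(CRE_LABELS)))
  )
  dplyr::bind_cols(
    tibble(n_regions = nrow(x),
           n_assigned = sum(lab != "Not assigned"),
           pct_assigned = if (nrow(x) > 0)
             100 * sum(lab != "Not assigned") / nrow(x) else NA_real_),
    as_tibble(counts),
    tibble(n_active_enhancers = sum(x$activity == "active"))
  )
}

#' Long-form tidy of a metaplot matrix
#'
#' @param x A `cre_metaplot` matrix.
#' @param ... Unused.
#' @return Tibble with `row` (stacking index), `region`, `position` (bin
#'   start offset from centre, bp), `coverage`.
#' @method tidy cre_metaplot
#' @export
tidy.cre_metaplot <- function(x, ...) {
  m <- unclass(x)
  tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    region = rep(rownames(m), times = ncol(m)),
    position = rep(as.numeric(colnames(m)), each = nrow(m)),
    coverage = as.vector(m)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
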
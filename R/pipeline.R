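#' Assemble a pipeline configuration
#'
#' Collects the input paths (per-track BAM/bigWig/peak BED, accessibility
#' peaks, optional blacklist/genes/variants) and all tunable parameters.
#'
#' @param accessibility_peaks Path to the accessibility peak BED.
#' @param tracks Named list (names = [cre_tracks()]) of lists with elements
#'   `bam`, `bigwig`, `peaks`.
#' @param out_dir Output directory.
#' @param blacklist,genes,variants Optional input paths.
#' @param anchor_mode,auc_mode,hybrid_scope,activity_threshold,tie_priority
#'   Classifier and quantification options; see [build_union_regions()],
#'   [compute_signal_matrix()], [classify_regions()].
#' @param variant_convention `"bed"` (0-based positions, default) or
#'   `"1based"` for 1-based variant tables.
#' @param metaplot_flank,metaplot_bin Metaplot window half-width and bin size
#'   (bp).
#' @param compute_metaplots Whether [run_pipeline()] writes metaplot matrices.
#' @param workers Worker count for per-region quantification.
#' @return A `cre_config` list.
#' @export
cre_config <- function(accessibility_peaks, tracks, out_dir,
                       blacklist = NULL, genes = NULL, variants = NULL,
                       anchor_mode = "union", auc_mode = "area",
                       hybrid_scope = "all", activity_threshold = 0,
                       tie_priority = DEFAULT_TIE_PRIORITY,
                       variant_convention = "bed",
                       metaplot_flank = 2000, metaplot_bin = 10,
                       compute_metaplots = FALSE, workers = 1L) {
  structure(list(
    accessibility_peaks = accessibility_peaks, tracks = tracks,
    out_dir = out_dir, blacklist = blacklist, genes = genes,
    variants = variants, anchor_mode = anchor_mode, auc_mode = auc_mode,
    hybrid_scope = hybrid_scope, activity_threshold = activity_threshold,
    tie_priority = tie_priority, variant_convention = variant_convention,
    metaplot_flank = metaplot_flank, metaplot_bin = metaplot_bin,
    compute_metaplots = compute_metaplots, workers = workers
  ), class = "cre_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [cre_config()].
#' @return A `cre_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(cre_config, y)
}

#' Validate a pipeline configuration
#'
#' Checks that every required input exists (per-track BAM, bigWig and peak
#' BED; accessibility peaks), that BAM indexes are present or creatable, and
#' that the peak chromosome namespace is contained in the BAM namespace (a
#' heuristic for the inputs originating from the same processing run). An
#' accessibility BAM entry, if supplied, is flagged as unused.
#'
#' @param cfg A `cre_config`.
#' @param strict Abort on the first missing required input (default) rather
#'   than just reporting it.
#' @return Tibble with `check`, `status` (`ok` / `warning` / `error`),
#'   `detail`.
#' @export
validate_config <- function(cfg, strict = TRUE) {
  rows <- list()
  note <- function(check, status, detail) {
    rows[[length(rows) + 1]] <<- tibble(check = check, status = status,
                                        detail = detail)
  }
  req <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      note(what, "error", sprintf("required input missing: %s",
                                  if (is.null(path)) "(not configured)" else path))
      FALSE
    } else {
      note(what, "ok", path)
      TRUE
    }
  }
  req(cfg$accessibility_peaks, "accessibility / BED")
  for (t in TRACKS) {
    tr <- cfg$tracks[[t]]
    if (is.null(tr)) {
      note(sprintf("%s / (all)", t), "error", "track not configured")
      next
    }
    ok_bam <- req(tr$bam, sprintf("%s / BAM", t))
    req(tr$bigwig, sprintf("%s / bigWig", t))
    ok_bed <- req(tr$peaks, sprintf("%s / BED", t))
    if (ok_bam && ok_bed) {
      bam_chroms <- names(Rsamtools::scanBamHeader(tr$bam)[[1]]$targets)
      pk <- tryCatch(read_bed(tr$peaks), error = function(e) NULL)
      if (!is.null(pk) && nrow(pk) > 0 &&
          !all(unique(pk$chrom) %in% bam_chroms)) {
        note(sprintf("%s / namespace", t), "error",
             "peak chromosomes not all present in the BAM header")
      } else {
        note(sprintf("%s / namespace", t), "ok",
             "peak chromosomes within BAM namespace")
      }
    }
  }
  if (!is.null(cfg$tracks$accessibility$bam)) {
    note("accessibility / BAM", "warning",
         "accessibility BAM supplied but unused (only the peak BED is read)")
  }
  for (opt in c("blacklist", "genes", "variants")) {
    if (!is.null(cfg[[opt]]) && !file.exists(cfg[[opt]])) {
      note(opt, "error", sprintf("configured but missing: %s", cfg[[opt]]))
    }
  }
  report <- dplyr::bind_rows(rows)
  if (strict && any(report$status == "error")) {
    bad <- report[report$status == "error", ]
    abort(paste0("configuration invalid:\n",
                 paste(sprintf("  %s: %s", bad$check, bad$detail),
                       collapse = "\n")))
  }
  report
}

#' Run the full annotation pipeline
#'
#' Region building, blacklist filtering, signal quantification, two-phase
#' classification, and the optional downstream outputs (TSS distance, variant
#' intersection, metaplots), all from files on disk. Writes `annotation.bed`,
#' `signal_matrix.tsv`, `class_distribution.tsv`, `coverage_matrix.tsv`, a
#' `manifest.json` with input checksums, and the optional outputs.
#'
#' @param cfg A `cre_config` (validated first).
#' @return The `cre_annotation` tibble, invisibly; output paths in
#'   `attr(, "paths")`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage_time <- c()
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    stage_time[[stage]] <<- round(now - t0, 3)
    t0 <<- now
  }

  acc <- read_bed(cfg$accessibility_peaks)
  peaks <- lapply(setNames(TRACKS, TRACKS),
                  function(t) read_bed(cfg$tracks[[t]]$peaks))
  blacklist <- if (!is.null(cfg$blacklist)) read_bed(cfg$blacklist) else NULL
  regions <- build_union_regions(acc, peaks$CTCF, blacklist,
                                 anchor_mode = cfg$anchor_mode)
  inform(sprintf("candidate regions after union + blacklist: %d", nrow(regions)))
  tick("regions")

  me1 <- read_coverage_track(cfg$tracks$H3K4me1$bigwig)
  me3 <- read_coverage_track(cfg$tracks$H3K4me3$bigwig)
  covmat <- compute_coverage_matrix(regions[, c("chrom", "start", "end")],
                                    me1, me3)
  write.table(covmat, file.path(cfg$out_dir, "coverage_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  metaplot_order <- order_by_mark_difference(covmat)
  tick("coverage")

  aln <- lapply(setNames(TRACKS, TRACKS),
                function(t) read_alignments(cfg$tracks[[t]]$bam))
  sig <- compute_signal_matrix(regions[, c("chrom", "start", "end")],
                               peaks, aln, auc_mode = cfg$auc_mode,
                               workers = cfg$workers)
  write_signal_matrix(sig, file.path(cfg$out_dir, "signal_matrix.tsv"))
  tick("signal")

  ann <- classify_regions(sig, activity_threshold = cfg$activity_threshold,
                          hybrid_scope = cfg$hybrid_scope,
                          tie_priority = cfg$tie_priority)
  ann$provenance <- regions$provenance
  dist <- class_distribution(ann)
  write.table(dist, file.path(cfg$out_dir, "class_distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  inform(paste(sprintf("%s: %d (%.1f%%)", dist$label, dist$n, dist$percentage),
               collapse = ", "))
  tick("classify")

  if (!is.null(cfg$genes)) {
    genes <- read_gene_annotation(cfg$genes)
    tss <- build_tss_registry(genes)
    if (nrow(tss) > 0) {
      ann$log_dist_tss <- log_distance_to_tss(
        ann[, c("chrom", "start", "end")], tss)
    } else {
      warn("no TSS after biotype filtering; skipping TSS distances")
    }
  }
  annotation_bed <- file.path(cfg$out_dir, "annotation.bed")
  write_annotation_bed(ann, annotation_bed)

  if (!is.null(cfg$variants)) {
    v <- read_variants(cfg$variants, cfg$variant_convention)
    hits <- intersect_variants(v, ann)
    write.table(hits$per_variant,
                file.path(cfg$out_dir, "variant_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(hits$per_label,
                file.path(cfg$out_dir, "variant_label_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(cfg$compute_metaplots)) {
    ordered <- regions[metaplot_order, c("chrom", "start", "end")]
    for (t in TRACKS) {
      track <- read_coverage_track(cfg$tracks[[t]]$bigwig)
      mp <- compute_metaplot(ordered, track, flank = cfg$metaplot_flank,
                             bin_width = cfg$metaplot_bin)
      write.table(unclass(mp), file.path(cfg$out_dir,
                                         sprintf("metaplot_%s.tsv", t)),
                  sep = "\t", quote = FALSE)
    }
  }
  tick("downstream")

  inputs <- c(cfg$accessibility_peaks,
              unlist(lapply(cfg$tracks[TRACKS],
                            function(tr) c(tr$bam, tr$bigwig, tr$peaks))),
              cfg$blacklist, cfg$genes, cfg$variants)
  manifest <- list(
    package_version = as.character(packageVersion("creclass")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_md5 = as.list(tools::md5sum(inputs)),
    n_regions = nrow(ann),
    stage_seconds = as.list(stage_time)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  attr(ann, "paths") <- list(annotation = annotation_bed, out_dir = cfg$out_dir)
  invisible(ann)
}

#' Read variant positions from BED or a 1-based table
#'
#' @param path BED3+ file (0-based) or TSV with columns chrom, pos, id
#'   (1-based when `convention = "1based"`).
#' @param convention `"bed"` or `"1based"`.
#' @return Tibble with `chrom`, `pos` (0-based), `id`.
#' @export
read_variants <- function(path, convention = c("bed", "1based")) {
  convention <- match.arg(convention)
  if (convention == "bed") {
    b <- read_bed(path)
    tibble(chrom = b$chrom, pos = b$start,
           id = if ("name" %in% names(b)) b$name else
             paste0("var", seq_len(nrow(b))))
  } else {
    x <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "numeric", "character"),
                    col.names = c("chrom", "pos", "id"))
    tibble(chrom = x$chrom, pos = x$pos - 1, id = x$id)
  }
}
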
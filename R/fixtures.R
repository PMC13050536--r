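#' Default regulatory archetype table
#'
#' One row per planted class with its relative track intensities (t1..t4 =
#' H3K4me1, H3K4me3, H3K27ac, CTCF). Each profile is validated against the
#' rule engine at dataset construction: the noise-free profile must classify
#' to its own label.
#'
#' @param count Instances to plant per archetype.
#' @param width Planted region width in bp.
#' @return Tibble with `label`, `I_<track>` intensity columns, `width`,
#'   `count`.
#' @export
cre_archetypes <- function(count = 10, width = 600) {
  tibble(
    label = c("Promoter", "Enhancer", "CTCF",
              "Promoter/CTCF", "Enhancer/CTCF", "Not assigned"),
    I_H3K4me1 = c(1, 10, 0, 0, 8, 0),
    I_H3K4me3 = c(10, 1, 0, 8, 0, 0),
    I_H3K27ac = c(6, 6, 2, 5, 5, 0),
    I_CTCF    = c(0, 0, 10, 9, 9, 0),
    width = width,
    count = count
  )
}

#' Generate a fully synthetic toy dataset with planted regulatory archetypes
#'
#' Builds a single-chromosome toy genome and plants non-overlapping regions of
#' each archetype. For every track with nonzero intensity at a region,
#' fixed-length single-end reads are placed uniformly inside it, with count
#' drawn Poisson around `intensity * reads_per_unit` (floored at 1 so a
#' planted mark is never silent). Peaks for a track are emitted exactly at the
#' planted regions where its intensity is positive, plus `n_decoy_peaks`
#' decoys in empty genome. Uniform background reads are added at
#' `noise_level` times each track's planted read count. At `noise_level = 0`
#' and no decoys, the classifier recovers every planted label exactly.
#'
#' @param archetypes Archetype tibble, see [cre_archetypes()].
#' @param genome_length Toy chromosome length in bp.
#' @param chrom Chromosome name.
#' @param noise_level Background read fraction in `[0, 1]`.
#' @param reads_per_unit Mean planted reads per intensity unit.
#' @param read_length Read length in bp.
#' @param n_decoy_peaks Per-track decoy peaks planted in empty genome.
#' @param n_genes,n_variants Gene records and variant positions to simulate.
#' @param seed Integer seed; the dataset is a pure function of the arguments.
#' @return A `cre_dataset` list: `genome`, `regions` (truth tibble with
#'   `label`), per-track `reads` and `peaks`, `accessibility_peaks`, `genes`,
#'   `variants`.
#' @export
simulate_dataset <- function(archetypes = cre_archetypes(),
                             genome_length = 2e5, chrom = "chrS",
                             noise_level = 0, reads_per_unit = 20,
                             read_length = 50, n_decoy_peaks = 0,
                             n_genes = 8, n_variants = 40, seed = 1) {
  stopifnot(noise_level >= 0, noise_level <= 1)
  arch <- as_tibble(archetypes)
  int_cols <- paste0("I_", TRACKS)
  # self-consistency: each noise-free profile must classify to its own label
  for (i in seq_len(nrow(arch))) {
    s <- as.numeric(arch[i, int_cols])
    r <- rank_row(s)
    got <- assign_hybrid_label(s, r, assign_primary_label(s, r))
    if (got != arch$label[i]) {
      abort(sprintf("archetype '%s' mis-specified: profile classifies as '%s'",
                    arch$label[i], got))
    }
  }
  set.seed(seed)
  plan <- arch[rep(seq_len(nrow(arch)), arch$count), ]
  n <- nrow(plan)
  if (n > 0) {
    plan <- plan[sample.int(n), ]                 # interleave classes
    gap_budget <- genome_length - sum(plan$width) - 2 * read_length * (n + 1)
    if (gap_budget < n + 1) {
      abort("genome too small for the requested planted regions")
    }
    gaps <- as.numeric(stats::rmultinom(1, size = gap_budget,
                                        prob = rep(1, n + 1)))
    # keep at least one read length of clear space between consecutive regions
    starts <- cumsum(c(2 * read_length + gaps[1],
                       if (n > 1) plan$width[-n] + 2 * read_length + gaps[2:n]))
    regions <- tibble(chrom = chrom, start = starts,
                      end = starts + plan$width, label = plan$label)
  } else {
    regions <- tibble(chrom = character(), start = numeric(),
                      end = numeric(), label = character())
  }

  sim_reads <- function(region_start, region_end, count) {
    lo <- region_start
    hi <- region_end - read_length
    pos <- if (hi <= lo) rep(lo, count) else
      lo + floor(runif(count) * (hi - lo + 1))
    tibble(chrom = chrom, start = pos, end = pos + read_length)
  }
  reads <- list(); peaks <- list()
  for (t in TRACKS) {
    intensity <- plan[[paste0("I_", t)]]
    planted <- which(intensity > 0)
    rd <- dplyr::bind_rows(
      tibble(chrom = character(), start = numeric(), end = numeric()),
      purrr::map_dfr(planted, function(i) {
        cnt <- max(1L, rpois(1, intensity[i] * reads_per_unit))
        sim_reads(regions$start[i], regions$end[i], cnt)
      }))
    # every track keeps positive genome-wide coverage so the per-million
    # normalization is defined even when no archetype uses the track; such a
    # track also has no peaks, so ambient reads cannot alter any signal
    n_bg <- rpois(1, noise_level * nrow(rd)) + if (nrow(rd) == 0) 10L else 0L
    if (n_bg > 0) {
      pos <- floor(runif(n_bg) * (genome_length - read_length))
      rd <- dplyr::bind_rows(rd, tibble(chrom = chrom, start = pos,
                                        end = pos + read_length))
    }
    pk <- regions[planted, c("chrom", "start", "end")]
    if (n_decoy_peaks > 0) {
      dstart <- floor(runif(n_decoy_peaks) * (genome_length - 200))
      pk <- dplyr::bind_rows(pk, tibble(chrom = chrom, start = dstart,
                                        end = dstart + 200))
    }
    reads[[t]] <- rd
    peaks[[t]] <- pk
  }
  # anchors: accessibility covers every non-pure-CTCF planted region; CTCF
  # peaks (above) cover the rest, so each planted region is anchored
  acc <- regions[regions$label != "CTCF", c("chrom", "start", "end")]
  genes <- sim_genes(n_genes, genome_length, chrom)
  variants <- tibble(chrom = chrom,
                     pos = sort(floor(runif(n_variants) * genome_length)),
                     id = paste0("rs", seq_len(n_variants)))
  structure(list(
    genome = tibble(chrom = chrom, length = genome_length),
    regions = regions, reads = reads, peaks = peaks,
    accessibility_peaks = acc, genes = genes, variants = variants,
    read_length = read_length, noise_level = noise_level, seed = seed
  ), class = "cre_dataset")
}

sim_genes <- function(n_genes, genome_length, chrom) {
  if (n_genes == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), name = character(),
                  biotype = character()))
  }
  gl <- floor(genome_length / n_genes)
  start <- (seq_len(n_genes) - 1) * gl + floor(runif(n_genes) * gl / 4)
  width <- pmax(200, floor(runif(n_genes) * gl / 2))
  biotypes <- rep(c("protein_coding", "lncRNA", "miRNA", "pseudogene"),
                  length.out = n_genes)
  tibble(chrom = chrom, start = start,
         end = pmin(start + width, genome_length),
         strand = rep(c("+", "-"), length.out = n_genes),
         name = paste0("G", seq_len(n_genes)), biotype = biotypes)
}

#' @export
print.cre_dataset <- function(x, ...) {
  cat(sprintf("<cre_dataset> %s:%d bp, %d planted regions, noise %.2f, seed %d\n",
              x$genome$chrom[1], x$genome$length[1], nrow(x$regions),
              x$noise_level, x$seed))
  print(table(x$regions$label))
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's native formats
#'
#' Emits per track a coordinate-sorted indexed BAM, a bigWig of its read
#' coverage, and a peak BED; plus the accessibility peak BED, a GFF3 gene
#' annotation, a variant BED, and the planted truth table as TSV.
#'
#' @param ds A `cre_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly usable with [cre_config()].
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chrom <- ds$genome$chrom[1]
  len <- ds$genome$length[1]
  paths <- list(tracks = list())
  for (t in TRACKS) {
    rd <- ds$reads[[t]]
    prefix <- file.path(dir, t)
    bam <- write_reads_bam(rd, prefix, chrom, len)
    aln <- alignments_from_reads(rd, setNames(as.integer(len), chrom))
    cov <- coverage_from_alignments(aln)
    bw <- paste0(prefix, ".bw")
    export_coverage_bw(cov, bw)
    bed <- paste0(prefix, "_peaks.bed")
    write_bed(ds$peaks[[t]], bed)
    paths$tracks[[t]] <- list(bam = bam, bigwig = bw, peaks = bed)
  }
  paths$accessibility_peaks <- file.path(dir, "accessibility_peaks.bed")
  write_bed(ds$accessibility_peaks, paths$accessibility_peaks)
  paths$genes <- file.path(dir, "genes.gff3")
  write_gff3(ds$genes, paths$genes)
  paths$variants <- file.path(dir, "variants.bed")
  write_bed(tibble(chrom = ds$variants$chrom, start = ds$variants$pos,
                   end = ds$variants$pos + 1, name = ds$variants$id),
            paths$variants)
  paths$truth <- file.path(dir, "truth.tsv")
  write.table(ds$regions, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# read spans -> SAM text -> sorted indexed BAM
write_reads_bam <- function(reads, prefix, chrom, chrom_length) {
  sam <- paste0(prefix, ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_length))),
             con)
  if (nrow(reads) > 0) {
    w <- reads$end - reads$start
    writeLines(sprintf("r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(reads)), reads$chrom,
                       as.integer(reads$start + 1), as.integer(w)), con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

export_coverage_bw <- function(cov, path) {
  gr <- as(cov, "GRanges")
  GenomeInfoDb::seqlengths(gr) <- vapply(cov, length, 0L)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export.bw(gr, path)
  path
}

write_bed <- function(tbl, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(tbl))
  x <- as.data.frame(tbl[, cols])
  if (nrow(x) > 0) {
    x$start <- format(x$start, scientific = FALSE, trim = TRUE)
    x$end <- format(x$end, scientific = FALSE, trim = TRUE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(sprintf(
      "%s\tcreclass\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;gene_biotype=%s",
      genes$chrom, as.integer(genes$start + 1), as.integer(genes$end),
      genes$strand, genes$name, genes$name, genes$biotype), con)
  }
  path
}
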
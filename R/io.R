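#' Read a BED file into an interval tibble
#'
#' Coordinates are kept in the native BED convention (0-based, half-open).
#' Columns beyond the third are retained: name, score and strand when present,
#' any further fields as `extra1`, `extra2`, ...
#'
#' @param path Path to a tab-separated BED3+ file. Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @return Tibble with `chrom`, `start`, `end` and any extra columns, in file
#'   order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                  path, lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has non-integer coordinates", path, lineno[bad[1]]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d violates 0 <= start < end", path, lineno[bad[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  extra_n <- max(nf) - 3L
  if (extra_n > 0) {
    std <- c("name", "score", "strand")
    for (i in seq_len(extra_n)) {
      col <- if (i <= 3) std[i] else paste0("extra", i - 3L)
      out[[col]] <- vapply(fields, function(f) {
        if (length(f) >= i + 3L) f[[i + 3L]] else NA_character_
      }, "")
    }
  }
  out
}

#' Read gene records from a GFF/GTF annotation
#'
#' Imports `gene`-type features, converts them to 0-based half-open
#' coordinates, and keeps those whose biotype is in `biotypes`. The biotype is
#' taken from the first of the `gene_biotype`, `gene_type` or `biotype`
#' attributes present. Records without strand are skipped with a warning.
#'
#' @param path GFF3 or GTF file.
#' @param biotypes Character vector of biotypes to retain.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `name`, `biotype`.
#' @export
read_gene_annotation <- function(path,
                                 biotypes = c("protein_coding", "miRNA", "lncRNA")) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  md <- S4Vectors::mcols(gr)
  bio_col <- intersect(c("gene_biotype", "gene_type", "biotype"), names(md))
  biotype <- if (length(bio_col) > 0) as.character(md[[bio_col[1]]]) else
    rep(NA_character_, length(gr))
  name_col <- intersect(c("Name", "gene_name", "gene_id", "ID"), names(md))
  name <- if (length(name_col) > 0) as.character(md[[name_col[1]]]) else
    paste0("gene", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  out <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = strand, name = name, biotype = biotype
  )
  stranded <- out$strand %in% c("+", "-")
  if (any(!stranded)) {
    warn(sprintf("%d gene record(s) without strand skipped", sum(!stranded)))
    out <- out[stranded, , drop = FALSE]
  }
  out[out$biotype %in% biotypes, , drop = FALSE]
}

#' Read a bigWig coverage track
#'
#' @param path bigWig file.
#' @return A per-chromosome `RleList` of coverage values.
#' @export
read_coverage_track <- function(path) {
  if (!file.exists(path)) abort(sprintf("bigWig file not found: %s", path))
  rtracklayer::import.bw(path, as = "RleList")
}

#' Open an aligned-read source (BAM)
#'
#' Reads the aligned spans of a coordinate-sorted, indexed BAM file. Each read
#' contributes its full CIGAR-consumed reference span; soft-clipped bases are
#' excluded. Unmapped, duplicate and QC-fail reads are dropped by default.
#'
#' @param path BAM file (index `.bai` alongside or created on the fly).
#' @param include_duplicates Keep reads flagged as duplicates.
#' @param include_qcfail Keep reads flagged as failing quality control.
#' @return An object of class `cre_alignments`: list with `reads` (tibble of
#'   0-based half-open aligned spans), `seqlengths` (named integer vector) and
#'   `path`.
#' @export
read_alignments <- function(path, include_duplicates = FALSE,
                            include_qcfail = FALSE) {
  if (!file.exists(path)) abort(sprintf("BAM file not found: %s", path))
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE,
    isNotPassingQualityControls = if (include_qcfail) NA else FALSE
  )
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag))
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  reads <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1,
    end = as.numeric(GenomicAlignments::end(ga))
  )
  structure(list(reads = reads, seqlengths = hdr, path = path),
            class = "cre_alignments")
}

#' Build an alignment source from an in-memory read table
#'
#' Mainly used by the fixture generator and by oracle-style tests that place
#' reads directly.
#'
#' @param reads Tibble of read spans (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param seqlengths Named vector of chromosome lengths.
#' @return A `cre_alignments` object.
#' @export
alignments_from_reads <- function(reads, seqlengths) {
  reads <- as_intervals(reads, "reads")
  structure(list(reads = reads[, c("chrom", "start", "end")],
                 seqlengths = seqlengths, path = NA_character_),
            class = "cre_alignments")
}

#' @export
print.cre_alignments <- function(x, ...) {
  cat(sprintf("<cre_alignments> %d reads over %d chromosome(s)%s\n",
              nrow(x$reads), length(x$seqlengths),
              if (is.na(x$path)) "" else paste0(" [", x$path, "]")))
  invisible(x)
}

# per-chromosome read coverage as an RleList over the full seqlengths
coverage_from_alignments <- function(aln) {
  gr <- iv_to_gr(aln$reads, seqlengths = aln$seqlengths)
  GenomicRanges::coverage(gr)
}

# sum of coverage values over half-open intervals `tbl`; chromosomes absent
# from `cov` read as 0 with one warning per chromosome
cov_sums <- function(cov, tbl) {
  out <- numeric(nrow(tbl))
  if (nrow(tbl) == 0) return(out)
  for (ch in unique(tbl$chrom)) {
    idx <- which(tbl$chrom == ch)
    if (!ch %in% names(cov)) {
      warn(sprintf("chromosome %s absent from coverage track; reading 0", ch))
      next
    }
    r <- cov[[ch]]
    n <- length(r)
    s <- pmin(pmax(tbl$start[idx] + 1, 1), n + 1)
    e <- pmin(tbl$end[idx], n)
    ok <- s <= e
    if (any(ok)) {
      v <- IRanges::Views(r, start = s[ok], end = e[ok])
      out[idx[ok]] <- IRanges::viewSums(v)
    }
  }
  out
}

#' Write an annotation table as BED6+
#'
#' Columns: chrom, start, end, label, score (max track signal scaled to
#' 0-1000 across the file), strand (`.`), the four normalized signals, the
#' four ranks, the enhancer activity subclass, and `log_dist_tss` when
#' present. A `#`-prefixed header names the columns.
#'
#' @param annotations Annotation tibble from [classify_regions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotations, path) {
  sig_cols <- paste0("A_", TRACKS)
  rank_cols <- paste0("R_", TRACKS)
  cols <- c("chrom", "start", "end", "label", "score", "strand",
            sig_cols, rank_cols, "activity", "log_dist_tss")
  x <- as_tibble(annotations)
  if (nrow(x) > 0) {
    smax <- do.call(pmax, c(unname(as.list(x[sig_cols])), list(0)))
    top <- max(smax)
    x$score <- if (top > 0) as.integer(round(1000 * smax / top)) else 0L
  } else {
    x$score <- integer()
  }
  x$strand <- "."
  if (!"log_dist_tss" %in% names(x)) x$log_dist_tss <- NA_real_
  x <- x[, cols]
  x$label <- as.character(x$label)
  x$start <- format(x$start, scientific = FALSE, trim = TRUE)
  x$end <- format(x$end, scientific = FALSE, trim = TRUE)
  for (cc in sig_cols) x[[cc]] <- sprintf("%.10g", x[[cc]])
  x$log_dist_tss <- ifelse(is.na(x$log_dist_tss), ".",
                           sprintf("%.6f", x$log_dist_tss))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(x) > 0) {
    write.table(x, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a BED6+ annotation file written by [write_annotation_bed()]
#'
#' @param path Annotation BED file.
#' @return Tibble with coordinates, label, signals, ranks, activity and
#'   `log_dist_tss` (NA where absent).
#' @export
read_annotation_bed <- function(path) {
  raw <- read_bed(path)
  sig_cols <- paste0("A_", TRACKS)
  rank_cols <- paste0("R_", TRACKS)
  old <- c("name", "score", "strand", paste0("extra", 1:10))
  new <- c("label", "score", "strand", sig_cols, rank_cols,
           "activity", "log_dist_tss")
  names(raw)[match(old, names(raw))[seq_along(new)]] <- new
  for (cc in c(sig_cols, "score")) raw[[cc]] <- as.numeric(raw[[cc]])
  for (cc in rank_cols) raw[[cc]] <- as.integer(raw[[cc]])
  raw$log_dist_tss <- suppressWarnings(as.numeric(raw$log_dist_tss))
  raw$label <- factor(raw$label, levels = CRE_LABELS)
  raw[, c("chrom", "start", "end", "label", "score", sig_cols, rank_cols,
          "activity", "log_dist_tss")]
}
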
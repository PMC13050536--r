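toy_aln <- function(reads, len = 1000, chrom = "chrT") {
  alignments_from_reads(reads, stats::setNames(as.integer(len), chrom))
}

test_that("auc is the summed per-base coverage restricted to the region", {
  one_read <- tibble::tibble(chrom = "chrT", start = 100, end = 150)
  aln <- toy_aln(one_read)
  region <- tibble::tibble(chrom = "chrT", start = 0, end = 1000)
  expect_equal(auc(region, aln), 50)

  empty_region <- tibble::tibble(chrom = "chrT", start = 500, end = 600)
  expect_equal(auc(empty_region, aln), 0)
  expect_equal(auc(region[0, ], aln), numeric())

  # random placement vs brute-force pileup
  set.seed(5)
  reads <- random_reads(20, 1000)
  aln <- toy_aln(reads)
  r <- tibble::tibble(chrom = "chrT", start = 200, end = 700)
  expect_equal(auc(r, aln), sum(pileup_vector(reads, 1000)[201:700]))

  # additivity over disjoint regions
  r2 <- tibble::tibble(chrom = "chrT", start = c(0, 700), end = c(200, 1000))
  expect_equal(sum(auc(r2, aln)) + auc(r, aln),
               auc(tibble::tibble(chrom = "chrT", start = 0, end = 1000), aln))
})

test_that("genome_auc sums aligned read lengths and scales linearly", {
  reads <- tibble::tibble(chrom = "chrT", start = seq(0, 900, by = 100),
                          end = seq(0, 900, by = 100) + 100)
  aln <- toy_aln(reads)
  expect_equal(genome_auc(aln), 1000)
  expect_equal(genome_auc(toy_aln(dplyr::bind_rows(reads, reads))), 2000)

  mixed <- tibble::tibble(chrom = "chrT", start = c(0, 10, 50),
                          end = c(30, 85, 60))
  expect_equal(genome_auc(toy_aln(mixed)), sum(mixed$end - mixed$start))
  expect_error(genome_auc(toy_aln(mixed[0, ])), "no reads")
})

test_that("signal matrix implements per-million peak-restricted coverage", {
  len <- 2000
  reads <- tibble::tibble(chrom = "chrT", start = c(100, 120, 600),
                          end = c(150, 170, 650))
  aln <- toy_aln(reads, len)
  alns <- stats::setNames(rep(list(aln), 4), cre_tracks())
  region <- tibble::tibble(chrom = "chrT", start = 90, end = 200)

  # region fully inside a peak that holds all of the track coverage
  pk_all <- tibble::tibble(chrom = "chrT", start = 0, end = 2000)
  peaks <- stats::setNames(rep(list(pk_all), 4), cre_tracks())
  sm <- compute_signal_matrix(region, peaks, alns)
  expect_equal(sm$A_H3K4me1, 1e6 * 100 / 150)

  # empty intersection -> exact 0
  peaks$H3K27ac <- tibble::tibble(chrom = "chrT", start = 1800, end = 1900)
  sm <- compute_signal_matrix(region, peaks, alns)
  expect_identical(sm$A_H3K27ac, 0)

  # multi-fragment intersection sums over all fragments
  peaks$CTCF <- tibble::tibble(chrom = "chrT", start = c(90, 160),
                               end = c(110, 200))
  sm <- compute_signal_matrix(region, peaks, alns)
  pv <- pileup_vector(reads, len)
  expect_equal(sm$A_CTCF, 1e6 * (sum(pv[91:110]) + sum(pv[161:200])) / sum(pv))

  expect_error(compute_signal_matrix(region, peaks[-1], alns), "H3K4me1")
})

test_that("signal matrix agrees with the brute-force pileup oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    len <- 5000
    regions <- random_intervals(8, len)
    peaks <- lapply(stats::setNames(cre_tracks(), cre_tracks()),
                    function(t) random_intervals(5, len))
    alns <- lapply(stats::setNames(cre_tracks(), cre_tracks()),
                   function(t) toy_aln(random_reads(200, len), len))
    sm <- compute_signal_matrix(regions, peaks, alns)
    for (t in cre_tracks()) {
      for (i in seq_len(nrow(regions))) {
        expected <- oracle_signal(regions[i, ], peaks[[t]],
                                  alns[[t]]$reads, len)
        expect_equal(sm[[paste0("A_", t)]][i], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("enlarging the peak intersection never decreases the signal", {
  set.seed(9)
  len <- 3000
  aln <- toy_aln(random_reads(150, len), len)
  alns <- stats::setNames(rep(list(aln), 4), cre_tracks())
  region <- tibble::tibble(chrom = "chrT", start = 500, end = 1500)
  grow <- seq(600, 1500, by = 100)
  vals <- vapply(grow, function(e) {
    pk <- tibble::tibble(chrom = "chrT", start = 500, end = e)
    peaks <- stats::setNames(rep(list(pk), 4), cre_tracks())
    compute_signal_matrix(region, peaks, alns)$A_H3K4me1
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("read_count mode counts overlapping reads per million", {
  len <- 1000
  reads <- tibble::tibble(chrom = "chrT", start = c(0, 100, 900),
                          end = c(50, 150, 950))
  aln <- toy_aln(reads, len)
  alns <- stats::setNames(rep(list(aln), 4), cre_tracks())
  pk <- tibble::tibble(chrom = "chrT", start = 0, end = 200)
  peaks <- stats::setNames(rep(list(pk), 4), cre_tracks())
  region <- tibble::tibble(chrom = "chrT", start = 0, end = 500)
  sm <- compute_signal_matrix(region, peaks, alns, auc_mode = "read_count")
  expect_equal(sm$A_CTCF, 1e6 * 2 / 3)
})

test_that("signal matrix TSV round-trips", {
  sig <- tibble::tibble(chrom = "chr1", start = 0, end = 100,
                        A_H3K4me1 = 1.5, A_H3K4me3 = 0, A_H3K27ac = 2,
                        A_CTCF = 0.125)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signal_matrix(sig, f)
  expect_equal(as.data.frame(read_signal_matrix(f)), as.data.frame(sig))
})
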
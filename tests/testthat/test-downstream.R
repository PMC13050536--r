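test_that("TSS registry is strand-aware", {
  genes <- tibble::tibble(chrom = "chr1", start = c(100, 100), end = c(500, 500),
                          strand = c("+", "-"), name = c("F", "R"),
                          biotype = "protein_coding")
  tss <- build_tss_registry(genes)
  expect_equal(tss$pos, c(100, 499))
  expect_equal(nrow(build_tss_registry(genes[0, ])), 0)
  genes$strand[2] <- "."
  expect_warning(tss <- build_tss_registry(genes), "strandless")
  expect_equal(nrow(tss), 1)
})

test_that("log10 TSS distance: overlap 0, gaps hand-computed, monotone", {
  tss <- tibble::tibble(chrom = "chr1", pos = 1000, strand = "+", name = "G")
  lg <- function(start, end) {
    log_distance_to_tss(tibble::tibble(chrom = "chr1", start = start,
                                       end = end), tss)
  }
  expect_equal(lg(900, 1100), 0)            # TSS inside region
  expect_equal(lg(1009, 1200), 1)           # 9 bp away -> log10(10)
  expect_equal(lg(1999, 2100), 3)           # 999 bp away -> log10(1000)
  expect_equal(lg(0, 1), log10(1000 + 1))   # region upstream, d = 1000
  expect_equal(lg(1000, 1001), 0)           # region is exactly the TSS base

  # monotone in the underlying gap
  gaps <- c(1, 5, 50, 500, 5000)
  vals <- vapply(gaps, function(g) lg(1000 + g, 1000 + g + 10), numeric(1))
  expect_true(all(diff(vals) > 0))

  # nearest of several TSSs wins
  tss2 <- tibble::tibble(chrom = "chr1", pos = c(0, 1208), strand = "+",
                         name = c("A", "B"))
  expect_equal(log_distance_to_tss(
    tibble::tibble(chrom = "chr1", start = 1100, end = 1200), tss2), 1)

  expect_error(log_distance_to_tss(
    tibble::tibble(chrom = "chr1", start = 0, end = 10), tss2[0, ]), "empty")
})

test_that("variant intersection: containment is half-open, counts match oracle", {
  ann <- classify_regions(tibble::tibble(
    chrom = "chr1", start = c(100, 150), end = c(200, 400),
    A_H3K4me1 = c(10, 0), A_H3K4me3 = c(1, 8), A_H3K27ac = c(6, 4),
    A_CTCF = c(0, 0)
  ))
  v <- tibble::tibble(chrom = "chr1", pos = c(150, 200, 399, 400, 50),
                      id = paste0("v", 1:5))
  res <- intersect_variants(v, ann)
  # v1 hits both overlapping elements (multi-hit), v2 only the second
  # (half-open: pos 200 is outside [100,200)), v4 and v5 are unannotated
  expect_equal(sum(res$per_variant$id == "v1"), 2)
  expect_true(all(res$per_variant$multi_hit[res$per_variant$id == "v1"]))
  expect_equal(res$per_variant$label[res$per_variant$id == "v2"], "Promoter")
  expect_equal(res$per_label$n_variants[res$per_label$label == "unannotated"], 2)

  # random variants vs random elements against the all-pairs oracle
  set.seed(44)
  els <- random_intervals(50, 1e5)
  sig <- dplyr::mutate(els, A_H3K4me1 = sample(0:9, 50, TRUE),
                       A_H3K4me3 = sample(0:9, 50, TRUE),
                       A_H3K27ac = sample(0:9, 50, TRUE),
                       A_CTCF = sample(0:9, 50, TRUE))
  ann <- classify_regions(sig)
  vs <- tibble::tibble(chrom = "chrT", pos = floor(runif(1000) * 1e5),
                       id = paste0("r", 1:1000))
  res <- intersect_variants(vs, ann)
  # oracle: O(n*m) containment
  lab <- as.character(ann$label)
  pair_count <- stats::setNames(rep(0, length(cre_labels())), cre_labels())
  unann <- 0
  for (i in seq_len(nrow(vs))) {
    inside <- which(vs$pos[i] >= ann$start & vs$pos[i] < ann$end)
    if (length(inside) == 0) unann <- unann + 1
    for (j in inside) pair_count[lab[j]] <- pair_count[lab[j]] + 1
  }
  got <- res$per_variant |> dplyr::filter(!is.na(label)) |> dplyr::count(label)
  for (l in got$label) {
    expect_equal(got$n[got$label == l], unname(pair_count[l]))
  }
  expect_equal(res$per_label$n_variants[res$per_label$label == "unannotated"],
               unann)
  # totals: per-pair rows + unannotated rows cover every variant at least once
  expect_gte(nrow(res$per_variant), nrow(vs))
})

test_that("metaplot bins mean coverage around region centres", {
  len <- 10000
  flat <- IRanges::RleList(chrT = S4Vectors::Rle(1, len))
  regions <- tibble::tibble(chrom = "chrT", start = 4000, end = 5000)
  mp <- compute_metaplot(regions, flat, flank = 2000, bin_width = 10)
  expect_equal(dim(mp), c(1, 400))
  expect_true(all(mp == 1))

  zero <- IRanges::RleList(chrT = S4Vectors::Rle(0, len))
  expect_true(all(compute_metaplot(regions, zero, 2000, 10) == 0))

  # unit spike at the exact centre -> only the centre bin nonzero, mean 0.1
  centre <- floor((4000 + 5000) / 2)
  v <- numeric(len); v[centre + 1] <- 1
  spike <- IRanges::RleList(chrT = S4Vectors::Rle(v))
  mp <- compute_metaplot(regions, spike, 2000, 10)
  expect_equal(sum(mp != 0), 1)
  expect_equal(unname(mp[1, "0"]), 0.1)

  # window truncation at the chromosome edge reads 0
  edge <- tibble::tibble(chrom = "chrT", start = 0, end = 100)
  mp <- compute_metaplot(edge, flat, 2000, 10)
  expect_equal(unname(mp[1, 1]), 0)          # entirely before base 0
  expect_equal(unname(mp[1, 400]), 1)

  # stacked identical regions give identical rows
  stack <- dplyr::bind_rows(regions, regions, regions)
  mp <- compute_metaplot(stack, spike, 2000, 10)
  expect_equal(mp[1, ], mp[2, ])
  expect_equal(mp[2, ], mp[3, ])

  expect_error(compute_metaplot(regions, flat, 2000, 300), "divisible")
})

test_that("class distribution percentages cover all regions and sum to 100", {
  sig <- tibble::tibble(
    chrom = "chr1", start = c(0, 10, 20, 30) * 100,
    end = c(0, 10, 20, 30) * 100 + 50,
    A_H3K4me1 = c(10, 0, 0, 0), A_H3K4me3 = c(1, 8, 0, 0),
    A_H3K27ac = c(6, 4, 2, 0), A_CTCF = c(0, 0, 10, 0)
  )
  d <- class_distribution(classify_regions(sig))
  expect_equal(sort(d$label),
               sort(c("Enhancer", "Promoter", "CTCF", "Not assigned")))
  expect_true(all(d$percentage == 25))
  expect_equal(sum(d$percentage), 100)
  expect_equal(nrow(class_distribution(classify_regions(sig[0, ]))), 0)

  # large random tally matches direct counting
  set.seed(55)
  n <- 1000
  sigr <- tibble::tibble(
    chrom = "chr1", start = seq_len(n) * 100, end = seq_len(n) * 100 + 50,
    A_H3K4me1 = sample(0:5, n, TRUE), A_H3K4me3 = sample(0:5, n, TRUE),
    A_H3K27ac = sample(0:5, n, TRUE), A_CTCF = sample(0:5, n, TRUE)
  )
  ann <- classify_regions(sigr)
  d <- class_distribution(ann)
  tal <- table(as.character(ann$label))
  for (l in d$label) expect_equal(d$n[d$label == l], unname(tal[l]))
  expect_equal(sum(d$percentage), 100)
})
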
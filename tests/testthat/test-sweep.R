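# helper: plant a hard-sweep footprint on a neutral panel by pushing sites
# near the focal position to extreme folded frequencies (the post-fixation
# excess of rare variants), with the distortion probability decaying with
# distance from the focal site as a sweep footprint does
plant_sweep <- function(panel, focal, scale = 10000) {
  mat <- panel$matrix
  n <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    d <- abs(panel$positions[j] - focal)
    if (runif(1) < exp(-d / scale)) {
      col <- integer(n)
      col[sample.int(n, 1)] <- 1L
      mat[, j] <- col
    }
  }
  hap_panel(mat, panel$positions, panel$sequence_length, panel$pop_labels)
}

test_that("CLR is nonnegative and vanishes in the escape limit", {
  p <- simulate_panel(const_model(N = 2e4, mu = 2e-8), 12, 1e5, seed = 6,
                      with_recombination = FALSE)
  scan <- clr_scan(p, grid_interval = 2e4)
  expect_true(all(scan$statistic >= 0))
  # alpha*d >> 1 for every site: p_e ~ 1 -> sweep model equals background
  far <- clr_scan(p, grid = 5e4, alpha_grid = 1e2)
  expect_lt(far$statistic, 1e-6)
})

test_that("CLR localizes a planted sweep", {
  # recombining panels: the panel's own genome-wide spectrum is then a fair
  # background (a single non-recombining genealogy would absorb the very
  # tree-shape fluctuations the scan must detect)
  hits <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    p <- simulate_panel(const_model(N = 2e4, mu = 2e-8, rec = 1e-7), 20, 1e5,
                        seed = 800 + s, with_recombination = TRUE)
    set.seed(1800 + s)
    focal <- 5e4
    sw <- plant_sweep(p, focal)
    bg <- folded_marginal_sfs(p)  # pre-sweep background
    scan <- clr_scan(sw, background = pmax(bg, 0.5), grid_interval = 5e3)
    peak <- scan$position[which.max(scan$statistic)]
    if (abs(peak - focal) <= 1e4) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_seeds)
})

test_that("omega equals its hand-computed toy values", {
  # A,B identical; C,D identical; every cross pair r^2 = 0.25 -> omega = 4
  x <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  y <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L)
  expect_equal(cor(x, y)^2, 0.25)
  m <- cbind(x, x, y, y)
  p <- hap_panel(m, c(9000L, 9500L, 10500L, 11000L), 20000L, rep("Y", 8))
  scan <- omega_scan(p, grid = 10000, minwin = 2000, maxwin = 2000)
  expect_equal(scan$statistic, 4)
  # all pairwise r^2 equal -> omega = 1
  m1 <- cbind(x, x, x, x)
  p1 <- hap_panel(m1, c(9000L, 9500L, 10500L, 11000L), 20000L, rep("Y", 8))
  scan1 <- omega_scan(p1, grid = 10000, minwin = 2000, maxwin = 2000)
  expect_equal(scan1$statistic, 1)
})

test_that("omega is invariant to duplicating every haplotype", {
  p <- simulate_panel(const_model(N = 2e4, mu = 2e-8, rec = 1e-7), 10, 5e4,
                      seed = 44, with_recombination = TRUE)
  dup <- hap_panel(rbind(p$matrix, p$matrix), p$positions,
                   p$sequence_length, rep(p$pop_labels, 2))
  s1 <- omega_scan(p, grid_interval = 1e4, minwin = 5e3, maxwin = 2e4)
  s2 <- omega_scan(dup, grid_interval = 1e4, minwin = 5e3, maxwin = 2e4)
  expect_equal(s1$statistic, s2$statistic)
})

test_that("windows without two flanking SNPs yield missing omega", {
  x <- c(1L, 1L, 0L, 0L)
  p <- hap_panel(cbind(x, x, x), c(100L, 200L, 15000L), 20000L, rep("Y", 4))
  scan <- omega_scan(p, grid = 10000, minwin = 1000, maxwin = 6000)
  expect_true(is.na(scan$statistic))
})

test_that("cutoff calibration is a quantile with sane edge behaviour", {
  vals <- 1:100
  expect_equal(calibrate_cutoff(list(vals), fpr = 0.5), median(vals))
  c1 <- calibrate_cutoff(list(vals), fpr = 0.1)
  c2 <- calibrate_cutoff(list(vals), fpr = 0.01)
  expect_lte(c1, c2)
  expect_warning(calibrate_cutoff(list(1:10), fpr = 1e-4), "widest")
  expect_error(calibrate_cutoff(list()), "empty")
})

test_that("realized false-positive rate matches the nominal rate on nulls", {
  m <- const_model(N = 2e4, mu = 2e-8)
  scans <- lapply(1:40, function(i) {
    p <- simulate_panel(m, 12, 5e4, seed = 2200 + i,
                        with_recombination = FALSE)
    clr_scan(p, grid_interval = 1e4)
  })
  cutoff <- calibrate_cutoff(scans[1:20], fpr = 0.1)
  held_out <- unlist(lapply(scans[21:40], function(s) s$statistic))
  realized <- mean(held_out > cutoff)
  n <- length(held_out)
  expect_lt(abs(realized - 0.1), 3 * sqrt(0.1 * 0.9 / n) + 0.02)
})

test_that("region merging follows the gap rule and is idempotent", {
  scan <- coalsweep:::new_sweep_scan(
    tibble::tibble(position = c(10000, 20000, 50000),
                   statistic = c(5, 6, 7)),
    "clr", 10000, cutoff = 4, fpr = 0.01)
  reg <- merge_regions(scan, max_gap = 10000)
  expect_equal(reg$start, c(10000, 50000))
  expect_equal(reg$end, c(20000, 50000))
  # no significant points
  scan2 <- set_cutoff(scan, 100)
  expect_equal(nrow(merge_regions(scan2)), 0)
  expect_error(merge_regions(coalsweep:::new_sweep_scan(
    tibble::tibble(position = 1, statistic = 1), "clr", 1)), "cutoff")
})

test_that("consensus interval algebra", {
  a <- tibble::tibble(start = c(100, 1000), end = c(300, 2000))
  b <- tibble::tibble(start = 200, end = 400)
  expect_equal(intersect_methods(a, b),
               tibble::tibble(start = 200, end = 300))
  # disjoint
  expect_equal(nrow(intersect_methods(a, tibble::tibble(start = 500,
                                                        end = 600))), 0)
  # idempotence and containment
  expect_equal(intersect_methods(a, a), a)
  cons <- intersect_methods(a, b)
  inside <- function(x, y) all(vapply(seq_len(nrow(x)), function(i) {
    any(x$start[i] >= y$start & x$end[i] <= y$end)
  }, logical(1)))
  expect_true(inside(cons, a))
  expect_true(inside(cons, b))
})

test_that("gene overlap includes 1-bp touches and skips malformed GFF rows", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t150\t250\t.\t+\t.\tID=gene1;Name=g1",
    "chr1\tsrc\tgene\t400\t500\t.\t+\t.\tID=gene2",
    "chr1\tsrc\tgene\t600\t550\t.\t+\t.\tID=bad_coords",
    "chr1\tsrc\tmRNA\t150\t250\t.\t+\t.\tID=rna1",
    "malformed line without tabs"
  ), f)
  regions <- tibble::tibble(chrom = "chr1", start = 200, end = 400)
  genes <- genes_in_regions(regions, f)
  expect_equal(as.character(genes), c("gene1", "gene2"))  # gene2 touches at 400
  expect_equal(attr(genes, "n_skipped"), 2L)
  expect_equal(length(genes_in_regions(regions[0, ], f)), 0)
})

test_that("scan and region writers emit parseable TSV/BED", {
  scan <- coalsweep:::new_sweep_scan(
    tibble::tibble(position = c(1e4, 2e4), statistic = c(1, 2)),
    "omega", 1e4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(scan, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$statistic, c(1, 2))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(tibble::tibble(start = 100, end = 200), f2)
  bed <- readr::read_tsv(f2, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed$X2, 99)  # BED 0-based start
  expect_equal(bed$X3, 200)
})
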
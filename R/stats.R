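# Windowed diversity/differentiation statistics and SFS construction.

# Window tiling over [1, L]: fixed-size sliding windows; a final window is
# appended when the stepped grid would leave the tail of the sequence
# uncovered. Windows never exceed sequence bounds.
tile_windows <- function(L, window_size, step) {
  if (step > window_size || window_size < 1 || step < 1)
    abort("need step <= window_size and both >= 1")
  if (L <= window_size) {
    return(tibble::tibble(start = 1L, end = as.integer(L)))
  }
  starts <- seq(1L, as.integer(L - window_size + 1L), by = as.integer(step))
  last <- as.integer(L - window_size + 1L)
  if (tail(starts, 1) != last) starts <- c(starts, last)
  tibble::tibble(start = starts, end = starts + as.integer(window_size) - 1L)
}

# per-site heterozygosity contributions (unbiased pairwise diversity)
site_pi <- function(mat) {
  n <- nrow(mat)
  p <- colMeans(mat)
  2 * p * (1 - p) * n / (n - 1)
}

new_window_stats <- function(df, statistic) {
  structure(df, class = c("window_stats", class(df)), statistic = statistic)
}

#' Per-site nucleotide diversity contributions
#'
#' The unbiased per-site pairwise diversity
#' \eqn{2 p (1-p)\, n/(n-1)} of every segregating site.
#'
#' @param panel A [hap_panel()] (>= 2 haplotypes).
#' @return A tibble `position`, `pi`.
#' @export
site_diversity <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  if (nrow(panel$matrix) < 2) abort("need >= 2 haplotypes")
  tibble::tibble(position = panel$positions, pi = site_pi(panel$matrix))
}

#' Sliding-window nucleotide diversity
#'
#' Computes per-site pairwise nucleotide diversity
#' \eqn{\pi = \sum_{sites} 2 p (1-p) \, n/(n-1)} in sliding windows,
#' divided by the full window length in bp. The default 200-kb windows with
#' 10-kb steps mirror a typical resequencing-scan configuration.
#'
#' @param panel A [hap_panel()] (needs >= 2 haplotypes).
#' @param window_size,step Window size and step in bp.
#' @return A tibble with columns `start`, `end`, `n_snps`, `pi` (per bp),
#'   carrying class `window_stats` for [autoplot()].
#' @examples
#' p <- hap_panel(matrix(c(0, 1, 0, 1, 1, 0, 0, 1), 4), c(3, 8), 10,
#'                rep("A", 4))
#' nucleotide_diversity(p, window_size = 10, step = 10)
#' @export
nucleotide_diversity <- function(panel, window_size = 200000, step = 10000) {
  stopifnot(inherits(panel, "hap_panel"))
  if (nrow(panel$matrix) < 2) abort("need >= 2 haplotypes")
  win <- tile_windows(panel$sequence_length, window_size, step)
  h <- site_pi(panel$matrix)
  pos <- panel$positions
  win$n_snps <- vapply(seq_len(nrow(win)), function(i) {
    sum(pos >= win$start[i] & pos <= win$end[i])
  }, integer(1))
  win$pi <- vapply(seq_len(nrow(win)), function(i) {
    sum(h[pos >= win$start[i] & pos <= win$end[i]]) / (win$end[i] - win$start[i] + 1)
  }, double(1))
  new_window_stats(win, "pi")
}

#' Sliding-window Watterson's theta
#'
#' \eqn{\theta_W = S / (a_{n-1} L)} per window, with
#' \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i} and `L` the full window length.
#'
#' @inheritParams nucleotide_diversity
#' @return A tibble `start`, `end`, `n_snps`, `theta_w` (per bp).
#' @examples
#' p <- hap_panel(matrix(c(0, 1), 2, 5), c(1, 3, 5, 7, 9), 1000, c("A", "B"))
#' watterson_theta(p, 1000, 1000)$theta_w  # 5 / (1 * 1000)
#' @export
watterson_theta <- function(panel, window_size = 200000, step = 10000) {
  stopifnot(inherits(panel, "hap_panel"))
  n <- nrow(panel$matrix)
  if (n < 2) abort("need >= 2 haplotypes")
  a_n <- sum(1 / seq_len(n - 1))
  win <- tile_windows(panel$sequence_length, window_size, step)
  pos <- panel$positions
  win$n_snps <- vapply(seq_len(nrow(win)), function(i) {
    sum(pos >= win$start[i] & pos <= win$end[i])
  }, integer(1))
  win$theta_w <- win$n_snps / (a_n * (win$end - win$start + 1))
  new_window_stats(win, "theta_w")
}

#' Sliding-window Hudson's FST
#'
#' Hudson's (1992) estimator as a ratio of averages per window:
#' \eqn{F_{ST} = 1 - \bar{\pi}_{within} / \pi_{between}}, where the within
#' term averages the two per-deme pairwise diversities and the between term
#' is the mean pairwise difference across demes
#' (\eqn{p_1(1-p_2) + p_2(1-p_1)} per site). Windows with zero between-deme
#' diversity are flagged `NA`.
#'
#' @inheritParams nucleotide_diversity
#' @param demes Optional two labels selecting/ordering the demes; defaults to
#'   the panel's labels (must be exactly two).
#' @return A tibble `start`, `end`, `n_snps`, `fst`.
#' @examples
#' m <- rbind(matrix(0L, 4, 1), matrix(1L, 4, 1))
#' p <- hap_panel(m, 50, 100, rep(c("A", "B"), each = 4))
#' hudson_fst(p, 100, 100)$fst  # 1: fixed difference
#' @export
hudson_fst <- function(panel, window_size = 200000, step = 10000,
                       demes = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  labs <- unique(panel$pop_labels)
  demes <- demes %||% labs
  if (length(demes) != 2 || !all(demes %in% labs))
    abort("hudson_fst needs exactly 2 demes present in the panel")
  i1 <- panel$pop_labels == demes[1]
  i2 <- panel$pop_labels == demes[2]
  if (sum(i1) < 2 || sum(i2) < 2) abort("need >= 2 haplotypes per deme")
  m1 <- panel$matrix[i1, , drop = FALSE]
  m2 <- panel$matrix[i2, , drop = FALSE]
  hw <- (site_pi_safe(m1) + site_pi_safe(m2)) / 2
  p1 <- colMeans(m1)
  p2 <- colMeans(m2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  win <- tile_windows(panel$sequence_length, window_size, step)
  pos <- panel$positions
  res <- lapply(seq_len(nrow(win)), function(i) {
    j <- pos >= win$start[i] & pos <= win$end[i]
    sb <- sum(hb[j])
    c(n = sum(j), fst = if (sb > 0) 1 - sum(hw[j]) / sb else NA_real_)
  })
  win$n_snps <- vapply(res, function(r) as.integer(r[["n"]]), integer(1))
  win$fst <- vapply(res, function(r) r[["fst"]], double(1))
  new_window_stats(win, "fst")
}

# site_pi tolerating monomorphic-within-deme columns
site_pi_safe <- function(mat) {
  n <- nrow(mat)
  p <- colMeans(mat)
  2 * p * (1 - p) * n / (n - 1)
}

# ---- joint SFS ---------------------------------------------------------------

new_joint_sfs <- function(counts, sample_sizes, folded, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  structure(
    list(counts = counts, sample_sizes = as.integer(sample_sizes),
         folded = folded, mask = mask),
    class = "joint_sfs"
  )
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("<joint_sfs> %s, sample sizes (%s), %s SNPs, %d masked cells\n",
              if (x$folded) "folded" else "unfolded",
              paste(x$sample_sizes, collapse = ", "),
              format(sum(x$counts, na.rm = TRUE)),
              sum(x$mask)))
  invisible(x)
}

# fold an unfolded (n1+1)x(n2+1) count matrix in place: cell (i,j) merges with
# (n1-i, n2-j); the kept cell is the one with the smaller total allele count
# (row-index tie-break for the self-symmetric diagonal). Folded-away cells and
# the monomorphic corners are masked.
fold_joint <- function(counts) {
  n1 <- nrow(counts) - 1L
  n2 <- ncol(counts) - 1L
  out <- matrix(0, n1 + 1, n2 + 1)
  mask <- matrix(TRUE, n1 + 1, n2 + 1)
  for (i in 0:n1) {
    for (j in 0:n2) {
      ii <- n1 - i
      jj <- n2 - j
      tot <- i + j
      tot2 <- ii + jj
      keep <- tot < tot2 || (tot == tot2 && i <= ii)
      if (keep) {
        v <- counts[i + 1, j + 1]
        if (!(ii == i && jj == j)) v <- v + counts[ii + 1, jj + 1]
        out[i + 1, j + 1] <- v
        mask[i + 1, j + 1] <- FALSE
      }
    }
  }
  mask[1, 1] <- TRUE                 # monomorphic configurations stay masked
  out[1, 1] <- 0
  list(counts = out, mask = mask)
}

#' Joint (two-deme) site frequency spectrum of a panel
#'
#' Counts SNPs by their per-deme derived-allele counts into an
#' `(n1+1) x (n2+1)` matrix. With `fold = TRUE` each entry `(i, j)` is merged
#' with its complementary configuration `(n1-i, n2-j)` into the minor
#' configuration; the total SNP count is preserved and monomorphic corners
#' are masked. Genotypes must be complete (simulated panels always are).
#'
#' @param panel A [hap_panel()].
#' @param demes Optional two labels ordering the demes (deme 1 first).
#' @param fold Fold the spectrum? Default `TRUE`.
#' @return A `joint_sfs` object (`counts`, `sample_sizes`, `folded`, `mask`).
#' @examples
#' m <- cbind(c(1L, 1L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 1L))
#' p <- hap_panel(m, c(10, 20), 100, c("Y", "Y", "Y", "N", "N"))
#' joint_folded_sfs(p)
#' @export
joint_folded_sfs <- function(panel, demes = NULL, fold = TRUE) {
  stopifnot(inherits(panel, "hap_panel"))
  if (anyNA(panel$matrix))
    abort("missing genotypes: filter to complete sites first")
  labs <- unique(panel$pop_labels)
  demes <- demes %||% labs
  if (length(demes) != 2) abort("joint SFS needs exactly 2 demes")
  i1 <- panel$pop_labels == demes[1]
  i2 <- panel$pop_labels == demes[2]
  n1 <- sum(i1)
  n2 <- sum(i2)
  c1 <- colSums(panel$matrix[i1, , drop = FALSE])
  c2 <- colSums(panel$matrix[i2, , drop = FALSE])
  counts <- matrix(0, n1 + 1, n2 + 1)
  for (s in seq_along(c1))
    counts[c1[s] + 1, c2[s] + 1] <- counts[c1[s] + 1, c2[s] + 1] + 1
  if (fold) {
    f <- fold_joint(counts)
    sfs <- new_joint_sfs(f$counts, c(n1, n2), TRUE, f$mask)
  } else {
    mask <- matrix(FALSE, n1 + 1, n2 + 1)
    mask[1, 1] <- TRUE
    mask[n1 + 1, n2 + 1] <- TRUE
    sfs <- new_joint_sfs(counts, c(n1, n2), FALSE, mask)
  }
  sfs
}

#' Folded marginal SFS of one deme
#'
#' @param panel A [hap_panel()].
#' @param deme Population label (default: first label = deme 1).
#' @return Named numeric vector of SNP counts for minor-allele classes
#'   `1 .. floor(n/2)`.
#' @export
folded_marginal_sfs <- function(panel, deme = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  deme <- deme %||% panel$pop_labels[1]
  keep <- panel$pop_labels == deme
  n <- sum(keep)
  cc <- colSums(panel$matrix[keep, , drop = FALSE])
  cc <- pmin(cc, n - cc)
  cc <- cc[cc > 0]
  counts <- tabulate(cc, nbins = floor(n / 2))
  setNames(as.numeric(counts), seq_len(floor(n / 2)))
}

#' Private SNP counts per deme
#'
#' A SNP is private to a deme when its (globally) minor allele occurs only in
#' that deme; SNPs whose minor allele segregates in both demes are private to
#' neither.
#'
#' @param panel A [hap_panel()].
#' @return A tibble `population`, `n_private`.
#' @examples
#' m <- cbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 0L))
#' p <- hap_panel(m, c(5, 9), 20, c("Y", "Y", "N", "N"))
#' private_snp_counts(p)
#' @export
private_snp_counts <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  labs <- unique(panel$pop_labels)
  n <- nrow(panel$matrix)
  cc <- colSums(panel$matrix)
  minor_is_1 <- cc <= n - cc
  res <- vapply(labs, function(lab) {
    inside <- panel$pop_labels == lab
    cin <- colSums(panel$matrix[inside, , drop = FALSE])
    minor_in <- ifelse(minor_is_1, cin, sum(inside) - cin)
    minor_tot <- pmin(cc, n - cc)
    sum(minor_in == minor_tot & minor_tot > 0)
  }, double(1))
  tibble::tibble(population = labs, n_private = as.integer(res))
}

#' SNP saturation (subsampling recovery) curve
#'
#' Randomly subsamples haplotypes and records how many of the panel's
#' segregating sites remain polymorphic, emulating the strain-subsampling
#' saturation analysis used to judge whether a sample exhausts a population's
#' common variation.
#'
#' @param panel A [hap_panel()].
#' @param subsample_sizes Haplotype counts to draw (each `<=` panel size).
#' @param replicates Random subsamples per size (default 30).
#' @param seed Integer seed.
#' @return A tibble `subsample_size`, `mean_s`, `sd_s`, with class
#'   `saturation_curve`.
#' @examples
#' m <- matrix(rbinom(40, 1, 0.4), 8)
#' m <- m[, colSums(m) %% 8 != 0, drop = FALSE]
#' p <- hap_panel(m, seq_len(ncol(m)), 50, rep("Y", 8))
#' snp_saturation(p, c(2, 4, 8), seed = 1)
#' @export
snp_saturation <- function(panel, subsample_sizes, replicates = 30, seed = 1) {
  stopifnot(inherits(panel, "hap_panel"))
  n <- nrow(panel$matrix)
  if (any(subsample_sizes > n)) abort("subsample sizes must be <= panel size")
  set.seed(seed)
  res <- purrr::map_dfr(sort(subsample_sizes), function(k) {
    s <- vapply(seq_len(replicates), function(r) {
      idx <- if (k == n) seq_len(n) else sample.int(n, k)
      cs <- colSums(panel$matrix[idx, , drop = FALSE])
      sum(cs > 0 & cs < k)
    }, double(1))
    tibble::tibble(subsample_size = k, mean_s = mean(s), sd_s = sd(s))
  })
  structure(res, class = c("saturation_curve", class(res)))
}

#' Write / read an SFS as plain text
#'
#' One header line (`# n1 n2 folded`) followed by the count matrix.
#'
#' @param sfs A `joint_sfs`.
#' @param path File path.
#' @return `write_sfs()` returns `path` invisibly; `read_sfs()` a
#'   `joint_sfs`.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %s", sfs$sample_sizes[1], sfs$sample_sizes[2],
                     if (sfs$folded) "folded" else "unfolded"), con)
  m <- sfs$counts
  m[sfs$mask] <- NA
  write.table(m, con, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " ")[[1]]
  m <- as.matrix(read.table(path, skip = 1, sep = "\t"))
  dimnames(m) <- NULL
  mask <- is.na(m)
  m[mask] <- 0
  new_joint_sfs(m, as.integer(hdr[2:3]), hdr[4] == "folded", mask)
}

#' @importFrom utils read.table write.table
NULL
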
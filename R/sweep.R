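# Selective-sweep scans: SFS-based composite likelihood ratio (CLR) and the
# LD-based omega statistic, with simulation-calibrated cutoffs.

new_sweep_scan <- function(df, method, grid_interval, cutoff = NA_real_,
                           fpr = NA_real_) {
  structure(df, class = c("sweep_scan", class(df)), method = method,
            grid_interval = grid_interval, cutoff = cutoff, fpr = fpr)
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("<sweep_scan> method = %s, %d grid points%s\n",
              attr(x, "method"), nrow(x),
              if (is.finite(attr(x, "cutoff")))
                sprintf(", cutoff = %.3f (FPR %g)", attr(x, "cutoff"),
                        attr(x, "fpr")) else ""))
  NextMethod()
}

#' Attach a significance cutoff to a scan
#'
#' @param scan A `sweep_scan`.
#' @param cutoff Statistic cutoff.
#' @param fpr Nominal false-positive rate the cutoff corresponds to.
#' @return The scan with cutoff metadata set.
#' @export
set_cutoff <- function(scan, cutoff, fpr = NA_real_) {
  attr(scan, "cutoff") <- cutoff
  attr(scan, "fpr") <- fpr
  scan
}

# ---- CLR (SweepFinder-model) scan -------------------------------------------

# Sweep-transformed sampling distributions. Background: folded minor-allele
# class counts b[k], k = 1..floor(n/2), treated as a symmetric unfolded
# spectrum. For escape probability p_e, B ~ Binomial(n, p_e) lineages escape
# the sweep and the rest descend from a single sweeping lineage; the m = B+1
# pre-sweep ancestors draw their allele counts from the hypergeometrically
# downsampled background, and the sweeping lineage's allele is copied to all
# n - B descendants. Conditioning on polymorphism happens after mixing over B.
# Returns a (floor(n/2) x length(pe_grid)) matrix of folded class
# probabilities.
sweep_spectrum_table <- function(b_folded, n, pe_grid) {
  K <- floor(n / 2)
  stopifnot(length(b_folded) == K)
  # symmetric unfolded spectrum p_i, i = 1..n-1
  p <- numeric(n - 1)
  for (k in seq_len(K)) {
    if (k < n - k) {
      p[k] <- b_folded[k] / 2
      p[n - k] <- b_folded[k] / 2
    } else {
      p[k] <- b_folded[k]
    }
  }
  if (sum(p) <= 0) abort("background spectrum has zero mass")
  p <- p / sum(p)

  # T[[B+1]]: distribution of the observed derived count 0..n given B escapees
  Tmat <- matrix(0, n + 1, n + 1)  # rows: obs 0..n; cols: B 0..n
  for (B in 0:n) {
    if (B == n) {
      Tmat[2:n, n + 1] <- p
      next
    }
    m <- B + 1
    # downsample the n-sample spectrum to m ancestors
    cvec <- 0:m
    psi <- vapply(cvec, function(cc) {
      sum(p * stats::dhyper(cc, 1:(n - 1), n - 1:(n - 1), m))
    }, double(1))
    for (ci in seq_along(cvec)) {
      cc <- cvec[ci]
      w <- psi[ci]
      if (w <= 0) next
      pr_derived <- cc / m
      if (pr_derived > 0) {
        obs <- (cc - 1) + (n - B)
        Tmat[obs + 1, B + 1] <- Tmat[obs + 1, B + 1] + w * pr_derived
      }
      if (pr_derived < 1) {
        obs <- cc
        Tmat[obs + 1, B + 1] <- Tmat[obs + 1, B + 1] + w * (1 - pr_derived)
      }
    }
  }

  # mix over B for each escape probability, condition on polymorphism, fold
  out <- matrix(0, K, length(pe_grid))
  for (g in seq_along(pe_grid)) {
    wB <- stats::dbinom(0:n, n, pe_grid[g])
    q <- as.numeric(Tmat %*% wB)          # obs 0..n
    q[1] <- 0
    q[n + 1] <- 0
    s <- sum(q)
    if (s <= 0) {
      # p_e = 0: conditioning on polymorphism, only the B = 1 term survives
      # in the limit (B = 0 makes every site monomorphic)
      q <- Tmat[, 2]
      q[1] <- 0
      q[n + 1] <- 0
      s <- sum(q)
    }
    q <- q / s
    fq <- numeric(K)
    for (k in seq_len(K)) {
      fq[k] <- if (k < n - k) q[k + 1] + q[n - k + 1] else q[k + 1]
    }
    out[, g] <- fq
  }
  out
}

#' Composite-likelihood-ratio sweep scan
#'
#' At each grid position `x`, compares the composite likelihood of the
#' observed folded site frequencies under (a) the genome-wide background
#' spectrum and (b) a sweep model in which each lineage escapes the sweep
#' with probability \eqn{p_e = 1 - e^{-\alpha d}} (`d` = distance from `x`);
#' non-escaped lineages descend star-like from the single sweeping lineage,
#' which transforms the background spectrum toward extreme frequency
#' classes. \eqn{CLR(x) = 2[\max_\alpha \log CL_{sweep} -
#' \log CL_{background}]}, with \eqn{\alpha} maximized over a positive
#' log-spaced grid; the background itself (the \eqn{p_e \to 1} limit) is
#' part of the maximization, so CLR is nonnegative everywhere.
#'
#' @param panel A [hap_panel()].
#' @param deme Population label to scan (default: first label).
#' @param background Folded marginal background spectrum (named counts as
#'   from [folded_marginal_sfs()], from the same sample size); defaults to
#'   the panel's own genome-wide spectrum.
#' @param grid Grid positions in bp; default: every `grid_interval` across
#'   the sequence.
#' @param grid_interval Grid spacing when `grid` is `NULL` (default 10 kb).
#' @param n_grid Alternative to `grid_interval`: number of evenly spaced
#'   grid points across the sequence (the convention of SweepFinder's `-g`).
#' @param alpha_grid Per-bp sweep intensities to maximize over (default 64
#'   log-spaced values in `[1e-7, 1e-1]`).
#' @param n_pe Resolution of the escape-probability lookup table.
#' @return A `sweep_scan` tibble: `position`, `statistic`, `alpha_hat`.
#' @export
clr_scan <- function(panel, deme = NULL, background = NULL, grid = NULL,
                     grid_interval = 10000, n_grid = NULL,
                     alpha_grid = 10^seq(-7, -1, length.out = 64),
                     n_pe = 256) {
  stopifnot(inherits(panel, "hap_panel"))
  deme <- deme %||% panel$pop_labels[1]
  keep <- panel$pop_labels == deme
  n <- sum(keep)
  mat <- panel$matrix[keep, , drop = FALSE]
  cc <- colSums(mat)
  poly <- cc > 0 & cc < n
  mat <- mat[, poly, drop = FALSE]
  pos <- panel$positions[poly]
  if (!length(pos)) abort("no polymorphic sites in the scanned deme")
  folded <- pmin(colSums(mat), n - colSums(mat))
  K <- floor(n / 2)
  b <- background %||% folded_marginal_sfs(panel, deme)
  if (length(b) != K) abort("background spectrum does not match sample size")
  if (any(b[unique(folded)] <= 0))
    abort("background spectrum has zero-mass classes present in the data")
  if (is.null(grid)) {
    grid <- if (!is.null(n_grid)) {
      round(seq(1, panel$sequence_length, length.out = n_grid))
    } else {
      seq(grid_interval, panel$sequence_length, by = grid_interval)
    }
    if (!length(grid)) grid <- round(panel$sequence_length / 2)
  }
  if (!length(grid)) abort("empty scan grid")

  bprob <- b / sum(b)
  ll_bg <- sum(log(bprob[folded]))

  # lookup table of folded spectra over an escape-probability grid
  pe_grid <- seq(0, 1, length.out = n_pe)
  Ftab <- sweep_spectrum_table(b, n, pe_grid)
  logF <- log(pmax(Ftab, 1e-300))

  stat <- numeric(length(grid))
  ahat <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    d <- abs(pos - grid[gi])
    best <- ll_bg
    besta <- Inf  # background limit
    for (a in alpha_grid) {
      pe <- 1 - exp(-a * d)
      idx <- pmin(n_pe, pmax(1L, as.integer(round(pe * (n_pe - 1))) + 1L))
      ll <- sum(logF[cbind(folded, idx)])
      if (ll > best) {
        best <- ll
        besta <- a
      }
    }
    stat[gi] <- 2 * (best - ll_bg)
    ahat[gi] <- besta
  }
  new_sweep_scan(
    tibble::tibble(position = as.numeric(grid), statistic = stat,
                   alpha_hat = ahat),
    method = "clr",
    grid_interval = if (length(grid) > 1) diff(grid[1:2]) else grid_interval
  )
}

# ---- omega (LD) scan ---------------------------------------------------------

#' Omega-statistic sweep scan
#'
#' At each grid position, SNPs within `maxwin` are split into a left and a
#' right set; \eqn{\omega} is the ratio of the average within-side
#' \eqn{r^2} to the average cross-side \eqn{r^2}:
#' \deqn{\omega = \frac{\left(\binom{l}{2}+\binom{r}{2}\right)^{-1}
#'   \left(\sum_{i<j \in L} r^2_{ij} + \sum_{i<j \in R} r^2_{ij}\right)}
#'   {(lr)^{-1} \sum_{i \in L, j \in R} r^2_{ij}}}
#' maximized over window extents between `minwin` and `maxwin` on each side
#' (leftmost maximizing split on ties). \eqn{r^2} is computed directly from
#' phased haplotypes. Grid points with fewer than 2 SNPs on either side get
#' `NA`.
#'
#' @param panel A [hap_panel()].
#' @param deme Population label to scan (default: first label).
#' @param grid Grid positions (default: every `grid_interval`).
#' @param grid_interval Grid spacing in bp (default 10 kb).
#' @param minwin,maxwin Minimum / maximum window extent on each side of the
#'   grid point (defaults 10 kb / 100 kb).
#' @return A `sweep_scan` tibble: `position`, `statistic`.
#' @export
omega_scan <- function(panel, deme = NULL, grid = NULL, grid_interval = 10000,
                       minwin = 10000, maxwin = 100000) {
  stopifnot(inherits(panel, "hap_panel"))
  if (minwin > maxwin) abort("minwin must be <= maxwin")
  deme <- deme %||% panel$pop_labels[1]
  keep <- panel$pop_labels == deme
  n <- sum(keep)
  mat <- panel$matrix[keep, , drop = FALSE]
  cc <- colSums(mat)
  poly <- cc > 0 & cc < n
  mat <- mat[, poly, drop = FALSE]
  pos <- panel$positions[poly]
  if (is.null(grid)) {
    grid <- seq(grid_interval, panel$sequence_length, by = grid_interval)
    if (!length(grid)) grid <- round(panel$sequence_length / 2)
  }
  stat <- rep(NA_real_, length(grid))
  for (gi in seq_along(grid)) {
    x <- grid[gi]
    sel <- which(pos >= x - maxwin & pos <= x + maxwin)
    if (length(sel) < 4) next
    p <- pos[sel]
    left_all <- which(p <= x)
    right_all <- which(p > x)
    if (length(left_all) < 2 || length(right_all) < 2) next
    r2 <- suppressWarnings(cor(mat[, sel, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    # candidate left boundaries: suffixes of the left side that contain at
    # least the sites within minwin; ditto (mirrored) on the right
    la_max <- if (any(p[left_all] >= x - minwin)) {
      min(left_all[p[left_all] >= x - minwin])
    } else {
      max(left_all)
    }
    la_candidates <- left_all[left_all <= la_max]
    rb_min <- if (any(p[right_all] <= x + minwin)) {
      max(right_all[p[right_all] <= x + minwin])
    } else {
      min(right_all)
    }
    rb_candidates <- right_all[right_all >= rb_min]
    nl_end <- max(left_all)
    r_start <- min(right_all)
    # prefix/suffix sums so every candidate split costs O(1):
    # sL[a] = sum of r2 over pairs within the left suffix a..nl_end
    sL <- numeric(nl_end)
    acc <- 0
    for (a in (nl_end - 1):1) {
      acc <- acc + sum(r2[a, (a + 1):nl_end])
      sL[a] <- acc
      if (a == 1) break
    }
    last_r <- max(right_all)
    sR <- numeric(last_r)
    acc <- 0
    for (b2 in (r_start + 1):last_r) {
      acc <- acc + sum(r2[b2, r_start:(b2 - 1)])
      sR[b2] <- acc
    }
    # cross sums: C[a, b] = sum over r2[a..nl_end, r_start..b]
    M <- r2[seq_len(nl_end), r_start:last_r, drop = FALSE]
    P <- if (ncol(M) == 1) M else t(apply(M, 1, cumsum))  # prefix over cols
    Csuf <- matrix(apply(P, 2, function(col) rev(cumsum(rev(col)))),
                   nrow = nrow(P))                        # suffix over rows
    best <- -Inf
    for (a in la_candidates) {
      nl <- nl_end - a + 1
      if (nl < 2) next
      for (b2 in rb_candidates) {
        nr <- b2 - r_start + 1
        if (nr < 2) next
        within <- (sL[a] + sR[b2]) / (choose(nl, 2) + choose(nr, 2))
        cross <- Csuf[a, b2 - r_start + 1] / (nl * nr)
        w <- if (cross > 0) within / cross else if (within > 0) Inf else NA_real_
        if (!is.na(w) && w > best) best <- w
      }
    }
    stat[gi] <- if (best == -Inf) NA_real_ else best
  }
  new_sweep_scan(
    tibble::tibble(position = as.numeric(grid), statistic = stat),
    method = "omega",
    grid_interval = if (length(grid) > 1) diff(grid[1:2]) else grid_interval
  )
}

#' Calibrate a sweep-statistic cutoff from null scans
#'
#' Pools the statistic values of scans of neutral (null) datasets — computed
#' with the same scan parameters as the real data — and returns the
#' `1 - fpr` quantile. With fewer than `1/fpr` values available the widest
#' available quantile is used, with a warning.
#'
#' @param null_scans A list of `sweep_scan` objects (or numeric vectors).
#' @param fpr Nominal per-grid-point false positive rate (default 1e-4, i.e.
#'   0.01\%).
#' @return The cutoff (scalar).
#' @export
calibrate_cutoff <- function(null_scans, fpr = 1e-4) {
  if (!length(null_scans)) abort("empty null set")
  vals <- unlist(lapply(null_scans, function(s) {
    if (is.numeric(s)) s else s$statistic
  }))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) abort("no finite null statistics")
  if (length(vals) < 1 / fpr)
    warn(sprintf(paste("only %d null values for FPR %g;",
                       "using the widest available quantile"),
                 length(vals), fpr))
  unname(quantile(vals, probs = 1 - fpr, type = 7))
}

#' Merge significant grid points into sweep regions
#'
#' Grid points with statistic above the scan's cutoff that lie within
#' `max_gap` bp of each other are merged into one region spanning them
#' (1-based inclusive).
#'
#' @param scan A `sweep_scan` with a cutoff set (see [set_cutoff()]).
#' @param max_gap Maximum gap between neighbouring significant points
#'   (default: the scan's grid interval).
#' @return A tibble `start`, `end`, `n_points`, `max_statistic`.
#' @export
merge_regions <- function(scan, max_gap = NULL) {
  cutoff <- attr(scan, "cutoff")
  if (!is.finite(cutoff)) abort("scan has no cutoff: calibrate first")
  max_gap <- max_gap %||% attr(scan, "grid_interval")
  sig <- scan[is.finite(scan$statistic) & scan$statistic > cutoff, ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          n_points = integer(), max_statistic = numeric()))
  }
  sig <- sig[order(sig$position), ]
  grp <- cumsum(c(1, diff(sig$position) > max_gap))
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(position = sig$position,
                                   statistic = sig$statistic, grp = grp),
                    .data$grp),
    start = min(.data$position), end = max(.data$position),
    n_points = dplyr::n(), max_statistic = max(.data$statistic),
    .groups = "drop"
  )[, c("start", "end", "n_points", "max_statistic")]
}

#' Intersect sweep regions from two methods
#'
#' Interval intersection of two internally non-overlapping sorted region
#' sets; the output (the two-method consensus) is sorted and
#' non-overlapping.
#'
#' @param regions_a,regions_b Tibbles with `start`, `end` (1-based
#'   inclusive).
#' @return A tibble `start`, `end`.
#' @examples
#' a <- tibble::tibble(start = 100, end = 300)
#' b <- tibble::tibble(start = 200, end = 400)
#' intersect_methods(a, b)
#' @export
intersect_methods <- function(regions_a, regions_b) {
  a <- dplyr::arrange(tibble::as_tibble(regions_a), .data$start)
  b <- dplyr::arrange(tibble::as_tibble(regions_b), .data$start)
  out_s <- numeric(0)
  out_e <- numeric(0)
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (s <= e) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
    }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  tibble::tibble(start = out_s, end = out_e)
}

#' Genes overlapping sweep regions
#'
#' Reports genes whose span overlaps any region by at least 1 bp
#' (closed-interval overlap), deduplicated and sorted. The GFF3 is parsed
#' leniently: malformed rows are skipped and counted (attribute
#' `n_skipped`).
#'
#' @param regions A tibble `start`, `end` (optionally `chrom`).
#' @param gff Path to a GFF3 file, or a tibble as returned by
#'   [read_gff_genes()].
#' @return Sorted character vector of gene IDs with attribute `n_skipped`.
#' @export
genes_in_regions <- function(regions, gff) {
  genes <- if (is.character(gff)) read_gff_genes(gff) else tibble::as_tibble(gff)
  regions <- tibble::as_tibble(regions)
  n_skipped <- attr(genes, "n_skipped") %||% 0L
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(structure(character(), n_skipped = n_skipped))
  }
  has_chrom <- "chrom" %in% names(regions) && "chrom" %in% names(genes)
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    r <- regions
    if (has_chrom) r <- r[r$chrom == genes$chrom[i], , drop = FALSE]
    any(genes$start[i] <= r$end & genes$end[i] >= r$start)
  }, logical(1))
  structure(sort(unique(genes$gene_id[hit])), n_skipped = n_skipped)
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 path.
#' @return A tibble `chrom`, `start`, `end`, `gene_id` (gene features only),
#'   with attribute `n_skipped` counting malformed rows.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 9 &&
      !is.na(suppressWarnings(as.integer(f[4]))) &&
      !is.na(suppressWarnings(as.integer(f[5]))) &&
      as.integer(f[4]) <= as.integer(f[5])
  }, logical(1))
  n_skipped <- sum(!ok)
  fields <- fields[ok]
  is_gene <- vapply(fields, function(f) f[3] == "gene", logical(1))
  fields <- fields[is_gene]
  out <- tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = vapply(fields, function(f) as.integer(f[4]), integer(1)),
    end = vapply(fields, function(f) as.integer(f[5]), integer(1)),
    gene_id = vapply(fields, function(f) {
      m <- regmatches(f[9], regexpr("ID=[^;]+", f[9]))
      if (length(m)) sub("^ID=", "", m) else f[9]
    }, character(1))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write scan / regions outputs as TSV or BED
#'
#' @param scan A `sweep_scan`.
#' @param regions A regions tibble.
#' @param path Output path.
#' @param chrom Contig name for BED output.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  readr::write_tsv(tibble::as_tibble(scan), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
write_regions_bed <- function(regions, path, chrom = "sim1") {
  df <- tibble::tibble(chrom = chrom, start = as.integer(regions$start) - 1L,
                       end = as.integer(regions$end))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
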
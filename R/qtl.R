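# F2 cross simulation and QTL mapping: Haley-Knott interval mapping,
# permutation LOD thresholds, variance explained, haplotype association and
# candidate-variant filtering.

#' Build a genetic map
#'
#' Default: a 5-chromosome map proportioned like the *A. thaliana* genome at
#' 3.6 cM/Mb (~429 cM total) carrying 32 roughly evenly spaced markers —
#' the sparse whole-genome marker panel of a typical F2 flowering-time
#' mapping design.
#'
#' @param n_markers Markers per chromosome; a vector (one entry per
#'   chromosome) or a total to be allocated proportionally to length.
#' @param chr_lengths Named chromosome lengths in cM.
#' @return A tibble `chr`, `marker`, `pos` (cM), class `genetic_map`.
#' @examples
#' genetic_map()
#' @export
genetic_map <- function(n_markers = 32,
                        chr_lengths = c(chr1 = 109.5, chr2 = 70.9,
                                        chr3 = 84.5, chr4 = 66.9,
                                        chr5 = 97.1)) {
  if (any(chr_lengths <= 0)) abort("chromosome lengths must be > 0")
  nc <- length(chr_lengths)
  if (length(n_markers) == 1) {
    alloc <- pmax(1, round(n_markers * chr_lengths / sum(chr_lengths)))
    # adjust rounding drift onto the largest chromosomes
    while (sum(alloc) != n_markers) {
      i <- if (sum(alloc) > n_markers) which.max(alloc) else which.max(chr_lengths - alloc)
      alloc[i] <- alloc[i] + sign(n_markers - sum(alloc))
    }
  } else {
    stopifnot(length(n_markers) == nc)
    alloc <- n_markers
  }
  out <- purrr::map_dfr(seq_len(nc), function(i) {
    k <- alloc[i]
    pos <- if (k == 1) chr_lengths[i] / 2 else
      seq(0, chr_lengths[i], length.out = k)
    tibble::tibble(
      chr = names(chr_lengths)[i] %||% paste0("chr", i),
      marker = sprintf("%s_m%02d", names(chr_lengths)[i] %||% paste0("chr", i),
                       seq_len(k)),
      pos = pos
    )
  })
  structure(out, class = c("genetic_map", class(out)),
            chr_lengths = chr_lengths)
}

#' Define the true QTL architecture for simulation
#'
#' @param qtls A tibble `chr`, `pos` (cM), `additive`, `dominance`. Additive
#'   effect `a` means genotype values `-a, d, +a` for `AA, AB, BB`.
#' @param residual_sd Residual standard deviation (> 0).
#' @param mean Grand mean of the phenotype.
#' @return A list of class `qtl_model`.
#' @export
qtl_model <- function(qtls, residual_sd, mean = 0) {
  qtls <- tibble::as_tibble(qtls)
  stopifnot(all(c("chr", "pos", "additive") %in% names(qtls)))
  if (!"dominance" %in% names(qtls)) qtls$dominance <- 0
  if (residual_sd <= 0) abort("residual_sd must be > 0")
  structure(list(qtls = qtls, residual_sd = residual_sd, mean = mean),
            class = "qtl_model")
}

#' Two-QTL flowering-time truth matching parental lines
#'
#' Builds an additive two-QTL architecture (chromosomes 2 and 5) whose
#' drop-one percentages of variance explained equal `pve` at equilibrium F2
#' genotype frequencies, and whose homozygote span matches the difference
#' between the parental means: with additive effects \eqn{a_i} the parents
#' differ by \eqn{2(a_1 + a_2)}. Defaults reproduce a cross between an
#' early- and a late-flowering accession (parental means 50.33 and 24.87
#' days) with PVEs of 60.9\% and 21.6\%.
#'
#' @param pve True fractions of phenotypic variance for the two QTLs.
#' @param parental_means Late and early parental phenotype means (days).
#' @param chrs,positions Chromosome and cM position of each QTL.
#' @return A `qtl_model`.
#' @examples
#' flowering_qtl_model()
#' @export
flowering_qtl_model <- function(pve = c(0.609, 0.216),
                                parental_means = c(50.33, 24.87),
                                chrs = c("chr2", "chr5"),
                                positions = c(35, 50)) {
  if (sum(pve) >= 1) abort("pve must sum to < 1")
  rel <- sqrt(2 * pve)               # additive effects up to a common scale
  scale <- abs(diff(parental_means)) / (2 * sum(rel))
  a <- rel * scale
  v_qtl <- sum(a^2 / 2)
  v_tot <- v_qtl / sum(pve)
  qtl_model(
    tibble::tibble(chr = chrs, pos = positions, additive = a, dominance = 0),
    residual_sd = sqrt(v_tot - v_qtl),
    mean = mean(parental_means)
  )
}

haldane_c <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

# one gamete: Markov chain of 0/1 alleles along loci with Haldane
# recombination fractions between neighbours
sim_gametes <- function(n, d_cm) {
  L <- length(d_cm) + 1
  g <- matrix(0L, n, L)
  g[, 1] <- rbinom(n, 1, 0.5)
  cs <- haldane_c(d_cm)
  for (j in 2:L) {
    sw <- rbinom(n, 1, cs[j - 1])
    g[, j] <- ifelse(sw == 1, 1L - g[, j - 1], g[, j - 1])
  }
  g
}

#' Simulate an F2 intercross
#'
#' Gametes are generated by a Haldane (no-interference) Markov chain along
#' each chromosome; F2 genotypes are the sum of two independent gametes
#' (0/1/2 = AA/AB/BB). QTL positions are simulated as extra loci and then
#' hidden from the observed marker data. Phenotype = mean + sum of QTL
#' effects + Gaussian noise.
#'
#' @param n Number of F2 individuals.
#' @param map A [genetic_map()].
#' @param truth A [qtl_model()].
#' @param seed Integer seed.
#' @param missing_rate Fraction of marker genotypes set missing (default 0).
#' @return An `f2_cross`: list with `genotypes` (n x markers, 0/1/2, NA =
#'   missing), `phenotypes`, `map`, `truth`.
#' @examples
#' cross <- simulate_f2(50, genetic_map(), flowering_qtl_model(), seed = 1)
#' cross
#' @export
simulate_f2 <- function(n, map, truth, seed = 1, missing_rate = 0) {
  stopifnot(inherits(map, "genetic_map") || is.data.frame(map),
            inherits(truth, "qtl_model"))
  set.seed(seed)
  chrs <- unique(map$chr)
  qt <- truth$qtls
  if (!all(qt$chr %in% chrs)) abort("QTL chromosomes must exist in the map")
  geno <- matrix(NA_integer_, n, nrow(map))
  colnames(geno) <- map$marker
  qtl_geno <- matrix(NA_integer_, n, nrow(qt))
  for (ch in chrs) {
    mk <- which(map$chr == ch)
    qk <- which(qt$chr == ch)
    pos <- c(map$pos[mk], qt$pos[qk])
    ord <- order(pos)
    pos_sorted <- pos[ord]
    if (length(qk) && (min(qt$pos[qk]) < min(map$pos[mk]) - 1e-9 ||
                       max(qt$pos[qk]) > max(map$pos[mk]) + 1e-9))
      abort("QTL positions must lie within the map span")
    d <- diff(pos_sorted)
    gsum <- sim_gametes(n, d) + sim_gametes(n, d)
    back <- order(ord)             # restore original locus order
    gsum <- gsum[, back, drop = FALSE]
    geno[, mk] <- gsum[, seq_along(mk), drop = FALSE]
    if (length(qk))
      qtl_geno[, qk] <- gsum[, length(mk) + seq_along(qk), drop = FALSE]
  }
  y <- rep(truth$mean, n)
  for (q in seq_len(nrow(qt))) {
    y <- y + qt$additive[q] * (qtl_geno[, q] - 1) +
      qt$dominance[q] * (qtl_geno[, q] == 1)
  }
  y <- y + rnorm(n, 0, truth$residual_sd)
  if (missing_rate > 0) {
    drop_idx <- which(runif(length(geno)) < missing_rate)
    geno[drop_idx] <- NA_integer_
  }
  structure(list(genotypes = geno, phenotypes = y,
                 map = tibble::as_tibble(map), truth = truth),
            class = "f2_cross")
}

#' @export
print.f2_cross <- function(x, ...) {
  cat(sprintf("<f2_cross> %d individuals x %d markers on %d chromosomes\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$map$chr))))
  cat(sprintf("  phenotype: mean %.2f, sd %.2f\n", mean(x$phenotypes),
              sd(x$phenotypes)))
  invisible(x)
}

# F2 genotype transition matrix over recombination fraction c
f2_transition <- function(c) {
  matrix(c((1 - c)^2, 2 * c * (1 - c), c^2,
           c * (1 - c), (1 - c)^2 + c^2, c * (1 - c),
           c^2, 2 * c * (1 - c), (1 - c)^2),
         3, 3, byrow = TRUE)
}

# Conditional genotype probabilities at pseudo-positions given flanking
# informative markers (exact for a no-interference F2). Returns a list per
# position of n x 3 probability matrices.
f2_genoprobs <- function(cross, positions, chr) {
  mk <- which(cross$map$chr == chr)
  mpos <- cross$map$pos[mk]
  G <- cross$genotypes[, mk, drop = FALSE]
  n <- nrow(G)
  prior <- c(0.25, 0.5, 0.25)
  lapply(positions, function(p) {
    out <- matrix(0, n, 3)
    left_k <- if (any(mpos <= p + 1e-9)) max(which(mpos <= p + 1e-9)) else NA
    right_k <- if (any(mpos >= p - 1e-9)) min(which(mpos >= p - 1e-9)) else NA
    for (i in seq_len(n)) {
      gl <- if (!is.na(left_k)) {
        lk <- left_k
        while (lk >= 1 && is.na(G[i, lk])) lk <- lk - 1
        if (lk >= 1) c(G[i, lk], mpos[lk]) else NULL
      }
      gr <- if (!is.na(right_k)) {
        rk <- right_k
        while (rk <= length(mk) && is.na(G[i, rk])) rk <- rk + 1
        if (rk <= length(mk)) c(G[i, rk], mpos[rk]) else NULL
      }
      if (!is.null(gl) && !is.null(gr) && gl[2] > gr[2] - 1e-12 &&
          abs(gl[2] - p) < 1e-9) {
        # at an informative marker
        out[i, gl[1] + 1] <- 1
      } else if (!is.null(gl) && !is.null(gr)) {
        tl <- f2_transition(haldane_c(p - gl[2]))[gl[1] + 1, ]
        tr <- f2_transition(haldane_c(gr[2] - p))[, gr[1] + 1]
        pr <- tl * tr
        out[i, ] <- pr / sum(pr)
      } else if (!is.null(gl)) {
        out[i, ] <- f2_transition(haldane_c(p - gl[2]))[gl[1] + 1, ]
      } else if (!is.null(gr)) {
        out[i, ] <- f2_transition(haldane_c(gr[2] - p))[, gr[1] + 1] * prior
        out[i, ] <- out[i, ] / sum(out[i, ])
      } else {
        out[i, ] <- prior
      }
    }
    out
  })
}

scan_positions <- function(map, step) {
  purrr::map_dfr(unique(map$chr), function(ch) {
    mpos <- map$pos[map$chr == ch]
    grid <- if (step > 0) {
      sort(unique(c(mpos, seq(min(mpos), max(mpos), by = step))))
    } else {
      sort(unique(mpos))
    }
    tibble::tibble(chr = ch, pos = grid)
  })
}

#' Haley–Knott interval mapping
#'
#' Regresses the phenotype on conditional expected genotype scores
#' (additive: P(BB) - P(AA); dominance: P(AB)) at pseudo-markers every
#' `step` cM, with conditional probabilities from the flanking informative
#' markers under a Haldane no-interference model. `LOD = (n/2)
#' log10(RSS0/RSS1)`. Missing genotypes are handled naturally through the
#' conditional expectations.
#'
#' @param cross An `f2_cross`.
#' @param step Pseudo-marker spacing in cM (default 1; 0 = markers only).
#' @return A tibble `chr`, `pos`, `lod` of class `lod_curve`.
#' @export
interval_mapping <- function(cross, step = 1) {
  stopifnot(inherits(cross, "f2_cross"))
  y <- cross$phenotypes
  ok <- !is.na(y)
  if (sum(ok) < 10) abort("need >= 10 phenotyped individuals")
  if (sd(y[ok]) == 0) abort("constant phenotype")
  if (any(colSums(!is.na(cross$genotypes)) == 0))
    abort("a marker column is entirely missing")
  y <- y[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  grid <- scan_positions(cross$map, step)
  lod <- numeric(nrow(grid))
  for (ch in unique(grid$chr)) {
    rows <- which(grid$chr == ch)
    probs <- f2_genoprobs(cross, grid$pos[rows], ch)
    for (k in seq_along(rows)) {
      pr <- probs[[k]][ok, , drop = FALSE]
      xa <- pr[, 3] - pr[, 1]
      xd <- pr[, 2]
      X <- cbind(1, xa, xd)
      fit <- stats::lm.fit(X, y)
      rss1 <- sum(fit$residuals^2)
      lod[rows[k]] <- (n / 2) * log10(rss0 / rss1)
    }
  }
  structure(tibble::tibble(chr = grid$chr, pos = grid$pos, lod = lod),
            class = c("lod_curve", "tbl_df", "tbl", "data.frame"),
            n = n, step = step)
}

#' @export
glance.lod_curve <- function(x, ...) {
  i <- which.max(x$lod)
  tibble::tibble(max_lod = x$lod[i], chr = x$chr[i], pos = x$pos[i],
                 n = attr(x, "n"))
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes phenotypes against genotypes `n_perm` times, records each
#' permutation's genome-wide maximum Haley–Knott LOD, and returns the
#' `1 - alpha` quantile — the genome-wide significance threshold of the
#' scan.
#'
#' @param cross An `f2_cross`.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Integer seed.
#' @param step Pseudo-marker spacing (as in [interval_mapping()]).
#' @return The LOD cutoff (scalar) with attribute `max_lods` (the null
#'   distribution).
#' @export
permutation_threshold <- function(cross, n_perm = 1000, alpha = 0.05,
                                  seed = 1, step = 1) {
  stopifnot(inherits(cross, "f2_cross"))
  if (n_perm < 100) abort("n_perm must be >= 100")
  y <- cross$phenotypes
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  grid <- scan_positions(cross$map, step)
  # orthonormal bases of the per-position design matrices
  Qs <- vector("list", nrow(grid))
  idx <- 1L
  for (ch in unique(grid$chr)) {
    rows <- which(grid$chr == ch)
    probs <- f2_genoprobs(cross, grid$pos[rows], ch)
    for (k in seq_along(rows)) {
      pr <- probs[[k]][ok, , drop = FALSE]
      X <- cbind(1, pr[, 3] - pr[, 1], pr[, 2])
      Qs[[rows[k]]] <- qr.Q(qr(X))
      idx <- idx + 1L
    }
  }
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(p) y[sample.int(n)], double(n))
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  max_lod <- rep(-Inf, n_perm)
  tY2 <- colSums(Y^2)
  for (q in Qs) {
    QtY <- crossprod(q, Y)
    rss1 <- tY2 - colSums(QtY^2)
    lod <- (n / 2) * log10(rss0 / rss1)
    max_lod <- pmax(max_lod, lod)
  }
  structure(unname(quantile(max_lod, 1 - alpha, type = 7)),
            max_lods = max_lod)
}

#' Variance explained by QTLs
#'
#' Fits the joint Haley–Knott model with additive + dominance terms for
#' every listed QTL; each QTL's percentage of variance explained (PVE) is
#' the drop-one partition `(RSS_without - RSS_full) / TSS`. For a single
#' QTL the closed form `1 - 10^(-2 LOD / n)` is also reported.
#'
#' @param cross An `f2_cross`.
#' @param qtl_positions A tibble `chr`, `pos` of QTL peak positions.
#' @return A tibble `chr`, `pos`, `lod`, `pve` (percent).
#' @export
variance_explained <- function(cross, qtl_positions) {
  stopifnot(inherits(cross, "f2_cross"))
  qp <- tibble::as_tibble(qtl_positions)
  y <- cross$phenotypes
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  blocks <- lapply(seq_len(nrow(qp)), function(i) {
    pr <- f2_genoprobs(cross, qp$pos[i], qp$chr[i])[[1]][ok, , drop = FALSE]
    cbind(pr[, 3] - pr[, 1], pr[, 2])
  })
  rss_of <- function(bl) {
    X <- cbind(1, do.call(cbind, bl))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  rss_full <- rss_of(blocks)
  pve <- lod <- numeric(nrow(qp))
  for (i in seq_len(nrow(qp))) {
    rss_wo <- if (nrow(qp) == 1) tss else rss_of(blocks[-i])
    pve[i] <- 100 * (rss_wo - rss_full) / tss
    rss_single <- rss_of(blocks[i])
    lod[i] <- (n / 2) * log10(tss / rss_single)
  }
  tibble::tibble(chr = qp$chr, pos = qp$pos, lod = lod, pve = pve)
}

#' Percent variance explained from a single-QTL LOD score
#'
#' @param lod LOD score.
#' @param n Sample size.
#' @return PVE as a fraction: `1 - 10^(-2 lod / n)`.
#' @examples
#' pve_from_lod(5, 100)  # 0.206
#' @export
pve_from_lod <- function(lod, n) 1 - 10^(-2 * lod / n)

#' Phenotype difference between two haplotype groups
#'
#' Two-sided Wilcoxon rank-sum test (default; exact where n permits) or
#' Welch t test between the phenotypes of two haplotype classes, with group
#' summaries.
#'
#' @param phenotypes Numeric phenotype vector.
#' @param haplotype_labels Factor/character with exactly two levels.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, group means,
#'   medians and sizes.
#' @examples
#' haplotype_association(c(1, 2, 3, 10, 11, 12),
#'                       rep(c("early", "late"), each = 3))
#' @export
haplotype_association <- function(phenotypes, haplotype_labels,
                                  method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  labs <- unique(haplotype_labels)
  if (length(labs) != 2) abort("need exactly two haplotype groups")
  g1 <- phenotypes[haplotype_labels == labs[1]]
  g2 <- phenotypes[haplotype_labels == labs[2]]
  if (length(g1) < 2 || length(g2) < 2)
    abort("both groups need at least 2 observations")
  ht <- if (method == "wilcoxon") {
    suppressWarnings(wilcox.test(g1, g2, alternative = "two.sided"))
  } else {
    t.test(g1, g2)
  }
  tibble::tibble(
    method = method,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    mean_1 = mean(g1), mean_2 = mean(g2),
    median_1 = median(g1), median_2 = median(g2),
    n_1 = length(g1), n_2 = length(g2),
    group_1 = as.character(labs[1]), group_2 = as.character(labs[2])
  )
}

#' Filter interval variants to amino-acid-changing candidates
#'
#' Retains variants annotated as nonsynonymous (amino-acid changing) inside
#' a candidate interval and groups them by gene — the fine-mapping step that
#' narrows a QTL interval to the handful of functionally plausible genes.
#'
#' @param variants A tibble with columns `pos`, `gene`, `effect`.
#' @param interval `c(start, end)` in bp, or `NULL` to keep all rows.
#' @param nonsyn_labels Effect labels counted as amino-acid changing.
#' @return A tibble `gene`, `n_variants` (genes with >= 1 candidate).
#' @examples
#' v <- tibble::tibble(pos = c(10, 20, 30), gene = c("g1", "g2", "g2"),
#'                     effect = c("missense", "synonymous", "missense"))
#' candidate_filter(v, interval = c(1, 100))
#' @export
candidate_filter <- function(variants, interval = NULL,
                             nonsyn_labels = c("missense", "nonsynonymous",
                                               "stop_gained", "stop_lost",
                                               "start_lost")) {
  v <- tibble::as_tibble(variants)
  if (!is.null(interval))
    v <- v[v$pos >= interval[1] & v$pos <= interval[2], , drop = FALSE]
  v <- v[tolower(v$effect) %in% nonsyn_labels, , drop = FALSE]
  if (nrow(v) == 0) return(tibble::tibble(gene = character(), n_variants = integer()))
  dplyr::count(v, .data$gene, name = "n_variants")
}

#' Write / read an F2 cross as CSV files
#'
#' Three CSVs sharing a stem: `<stem>_geno.csv` (individuals x markers,
#' 0/1/2, empty = missing), `<stem>_pheno.csv`, `<stem>_map.csv`.
#'
#' @param cross An `f2_cross`.
#' @param stem Path stem.
#' @return `write_cross_csv()` returns `stem` invisibly; `read_cross_csv()`
#'   an `f2_cross` (with a placeholder truth of `NULL`).
#' @export
write_cross_csv <- function(cross, stem) {
  geno <- tibble::as_tibble(cross$genotypes, .name_repair = "minimal")
  readr::write_csv(geno, paste0(stem, "_geno.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(phenotype = cross$phenotypes),
                   paste0(stem, "_pheno.csv"), progress = FALSE)
  readr::write_csv(cross$map, paste0(stem, "_map.csv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_cross_csv
#' @export
read_cross_csv <- function(stem) {
  geno <- as.matrix(readr::read_csv(paste0(stem, "_geno.csv"),
                                    show_col_types = FALSE, progress = FALSE))
  storage.mode(geno) <- "integer"
  pheno <- readr::read_csv(paste0(stem, "_pheno.csv"),
                           show_col_types = FALSE, progress = FALSE)$phenotype
  map <- readr::read_csv(paste0(stem, "_map.csv"), show_col_types = FALSE,
                         progress = FALSE)
  structure(list(genotypes = geno, phenotypes = pheno,
                 map = tibble::as_tibble(map), truth = NULL),
            class = "f2_cross")
}
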
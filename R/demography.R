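# Simulation-based composite-likelihood fitting of demographic models to a
# folded joint SFS, AIC model comparison and parametric bootstrap.

#' Monte-Carlo expected joint SFS under a demographic model
#'
#' Estimates the expected (normalized) joint site frequency spectrum by
#' coalescent simulation: branch lengths are accumulated by joint
#' descendant-count class over `n_sims` genealogies (recombination off — the
#' expected SFS is recombination-invariant) and normalized to cell
#' proportions among polymorphic configurations. Deterministic per seed.
#'
#' @param model A [demographic_model()].
#' @param sample_sizes Haplotypes per deme (length 1 or 2).
#' @param n_sims Number of simulated genealogies.
#' @param seed Integer seed.
#' @param fold Fold the spectrum (default `TRUE`).
#' @return A `joint_sfs` whose `counts` hold cell proportions summing to 1
#'   over unmasked cells.
#' @examples
#' m <- demographic_model(
#'   epochs = data.frame(deme = 1, t_start = 0, size = 1e4), n_demes = 1
#' )
#' e <- expected_sfs(m, 6, n_sims = 500, seed = 1, fold = FALSE)
#' sum(e$counts[!e$mask])
#' @export
expected_sfs <- function(model, sample_sizes, n_sims, seed, fold = TRUE) {
  stopifnot(inherits(model, "demographic_model"))
  if (n_sims < 1) abort("n_sims must be >= 1")
  sample_sizes <- as.integer(sample_sizes)
  n1 <- sample_sizes[1]
  n2 <- if (length(sample_sizes) > 1) sample_sizes[2] else 0L
  if (model$n_demes == 1 && n2 > 0)
    abort("cannot draw a 2-deme sample from a 1-deme model")
  args <- model_cpp_args(model)
  set.seed(seed)
  bl <- .sfs_branch_cpp(n1, n2, as.integer(n_sims),
                        args$t_div, args$d1_t, args$d1_N, args$d2_t, args$d2_N,
                        args$anc_t, args$anc_N, args$mig_t0, args$mig_t1,
                        args$m12, args$m21)
  if (fold) {
    f <- fold_joint(bl)
    counts <- f$counts
    mask <- f$mask
  } else {
    counts <- bl
    mask <- matrix(FALSE, n1 + 1, n2 + 1)
    mask[1, 1] <- TRUE
    mask[n1 + 1, n2 + 1] <- TRUE
    counts[mask] <- 0
  }
  tot <- sum(counts[!mask])
  if (tot > 0) counts[!mask] <- counts[!mask] / tot
  new_joint_sfs(counts, c(n1, n2), fold, mask)
}

#' Draw a multinomial SFS dataset from a model
#'
#' Simulates an observed joint SFS with a fixed number of SNPs: the expected
#' spectrum is estimated by coalescent simulation ([expected_sfs()]) and
#' `n_snps` sites are drawn multinomially from it — the SFS-level equivalent
#' of simulating a large dataset of unlinked SNPs, used for parametric
#' bootstrap and recovery experiments.
#'
#' @inheritParams expected_sfs
#' @param n_snps Number of SNPs to draw.
#' @return A `joint_sfs` of integer counts totalling `n_snps`.
#' @export
simulate_sfs_dataset <- function(model, n_snps, sample_sizes, n_sims = 1e5,
                                 seed = 1, fold = TRUE) {
  e <- expected_sfs(model, sample_sizes, n_sims, seed = derive_seed(seed, 1),
                    fold = fold)
  p <- e$counts[!e$mask]
  set.seed(derive_seed(seed, 2))
  draws <- as.numeric(rmultinom(1, n_snps, p))
  counts <- e$counts
  counts[!e$mask] <- draws
  new_joint_sfs(counts, e$sample_sizes, e$folded, e$mask)
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' Cells of the observed spectrum supported by fewer than `min_support` SNPs
#' are ignored (masked); the expected proportions are renormalized over the
#' retained cells; the composite log-likelihood is
#' \eqn{\sum_{retained} n_i \log p_i} with the expected proportions floored
#' at a small positive constant.
#'
#' @param obs Observed `joint_sfs` (counts).
#' @param expected Expected `joint_sfs` (proportions), same dimensions and
#'   folding.
#' @param min_support Minimum observed SNPs for a cell to enter the
#'   likelihood (default 10).
#' @param p_floor Floor for expected proportions (default 1e-12).
#' @return The composite log-likelihood (scalar).
#' @examples
#' obs <- coalsweep:::new_joint_sfs(matrix(c(0, 30, 70, 0), 2), c(1, 1), FALSE,
#'                                  matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
#' ex <- coalsweep:::new_joint_sfs(matrix(c(0, .5, .5, 0), 2), c(1, 1), FALSE,
#'                                 matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
#' composite_log_likelihood(obs, ex, min_support = 1)  # 100 * log(0.5)
#' @export
composite_log_likelihood <- function(obs, expected, min_support = 10,
                                     p_floor = 1e-12) {
  stopifnot(inherits(obs, "joint_sfs"), inherits(expected, "joint_sfs"))
  if (!identical(dim(obs$counts), dim(expected$counts)) ||
      !identical(obs$folded, expected$folded))
    abort("observed and expected SFS must match in dimensions and folding")
  keep <- !obs$mask & !expected$mask & obs$counts >= min_support
  if (!any(keep)) abort("all SFS cells masked: nothing to fit")
  p <- expected$counts[keep]
  p <- p / sum(p)
  p <- pmax(p, p_floor)
  sum(obs$counts[keep] * log(p))
}

# objective shared by fit_model/bootstrap: composite LL of obs under params
sfs_objective <- function(par_t, free, template, obs, n_sims, crn_seed,
                          min_support, trans) {
  params <- untransform_params(par_t, free, trans)
  model <- try(set_model_params(template, params), silent = TRUE)
  if (inherits(model, "try-error")) return(-1e18)
  e <- try(expected_sfs(model, obs$sample_sizes, n_sims, seed = crn_seed,
                        fold = obs$folded), silent = TRUE)
  if (inherits(e, "try-error")) return(-1e18)
  composite_log_likelihood(obs, e, min_support = min_support)
}

# sizes and migration rates are optimized on log scale, times linear
param_transform <- function(free) {
  ifelse(grepl("^(n|m)", free), "log", "identity")
}
transform_params <- function(params, free, trans) {
  ifelse(trans == "log", log(params), params)
}
untransform_params <- function(par_t, free, trans) {
  setNames(ifelse(trans == "log", exp(par_t), par_t), free)
}

#' Fit a demographic model to an observed SFS by composite likelihood
#'
#' Multi-start derivative-free maximization of the multinomial composite
#' likelihood. Each of `n_runs` independent runs starts at a random point
#' within the bounds and performs `n_cycles` cycles of Nelder–Mead
#' refinement; the number of coalescent simulations per likelihood
#' evaluation escalates geometrically across cycles between
#' `sims_schedule[1]` and `sims_schedule[2]`, and within a cycle all
#' candidate parameter values share the same simulation seeds (common random
#' numbers), which makes the Monte-Carlo likelihood surface smooth enough to
#' optimize. Sizes and migration rates are optimized on log scale, times on
#' linear scale. Fully reproducible per seed.
#'
#' @param obs Observed `joint_sfs` (integer counts).
#' @param template A [demographic_model()] providing the fixed parameters.
#' @param bounds Named list of `c(lower, upper)` per free parameter (names as
#'   in [model_params()]); collapsed bounds (`lower == upper`) pin the
#'   parameter.
#' @param n_runs Independent random starts (default 50).
#' @param sims_schedule Length-2: simulations per likelihood evaluation at
#'   the first and last cycle (default `c(1e5, 1e6)`).
#' @param n_cycles Maximization cycles per run (default 40, the upper end of
#'   the usual 10–40 schedule).
#' @param seed Integer seed.
#' @param min_support Observed-count mask for the likelihood (default 10).
#' @param nm_iter Nelder–Mead iterations per cycle (default 3).
#' @return A `demog_fit` object: `estimate` (named vector), `loglik`, `k`,
#'   per-run diagnostics in `$runs`, `converged` flag. Supports [tidy()] and
#'   [glance()].
#' @export
fit_model <- function(obs, template, bounds, n_runs = 50,
                      sims_schedule = c(1e5, 1e6), n_cycles = 40, seed = 1,
                      min_support = 10, nm_iter = 3) {
  stopifnot(inherits(obs, "joint_sfs"), inherits(template, "demographic_model"))
  free <- names(bounds)
  if (is.null(free) || !length(free)) abort("bounds must be a named list")
  lower <- vapply(bounds, `[`, double(1), 1)
  upper <- vapply(bounds, `[`, double(1), 2)
  if (any(lower > upper)) abort("each bound must satisfy lower <= upper")
  trans <- param_transform(free)
  lo_t <- transform_params(lower, free, trans)
  hi_t <- transform_params(upper, free, trans)
  n_sims_cycle <- if (n_cycles == 1) {
    sims_schedule[1]
  } else {
    round(exp(seq(log(sims_schedule[1]), log(sims_schedule[2]),
                  length.out = n_cycles)))
  }

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, 7000 + r))
    par_t <- lo_t + runif(length(free)) * (hi_t - lo_t)
    best_ll <- -Inf
    improved <- FALSE
    trace <- numeric(0)
    # consecutive cycles with the same simulation count share one
    # Nelder-Mead call carrying the pooled iteration budget (identical
    # refinement, no repeated simplex restarts)
    grp <- cumsum(c(1, diff(n_sims_cycle) != 0))
    for (g in unique(grp)) {
      cys <- which(grp == g)
      crn <- derive_seed(seed, r * 997 + cys[1])  # CRN within the group
      obj <- function(pt) {
        pt <- pmin(pmax(pt, lo_t), hi_t)
        -sfs_objective(pt, free, template, obs, n_sims_cycle[cys[1]], crn,
                       min_support, trans)
      }
      if (all(hi_t == lo_t)) {
        val <- -obj(lo_t)
        par_t <- lo_t
      } else {
        op <- suppressWarnings(
          optim(par_t, obj, method = "Nelder-Mead",
                control = list(maxit = nm_iter * length(cys),
                               warn.1d.NelderMead = FALSE))
        )
        par_t <- pmin(pmax(op$par, lo_t), hi_t)
        val <- -op$value
      }
      trace <- c(trace, val)
      if (val > best_ll + 1e-9) improved <- TRUE
      best_ll <- max(best_ll, val)
    }
    runs[[r]] <- list(par_t = par_t, loglik = trace[n_cycles], trace = trace,
                      improved = improved)
  }
  # final common-seed evaluation so runs are compared on one surface
  crn_final <- derive_seed(seed, 555331)
  finals <- vapply(runs, function(ru) {
    sfs_objective(ru$par_t, free, template, obs,
                  n_sims_cycle[length(n_sims_cycle)], crn_final,
                  min_support, trans)
  }, double(1))
  best <- which.max(finals)
  est <- untransform_params(runs[[best]]$par_t, free, trans)
  run_tbl <- tibble::tibble(
    run = seq_len(n_runs),
    loglik = finals,
    improved = vapply(runs, `[[`, logical(1), "improved")
  )
  for (j in seq_along(free)) {
    run_tbl[[free[j]]] <- vapply(runs, function(ru) {
      untransform_params(ru$par_t, free, trans)[j]
    }, double(1))
  }
  structure(
    list(
      model_id = template$label %||% "model",
      template = template,
      free = free,
      bounds = bounds,
      estimate = est,
      loglik = max(finals),
      k = sum(lower < upper),
      runs = run_tbl,
      traces = lapply(runs, `[[`, "trace"),
      converged = any(run_tbl$improved),
      n_snps = sum(obs$counts[!obs$mask]),
      sample_sizes = obs$sample_sizes,
      min_support = min_support,
      settings = list(n_runs = n_runs, n_cycles = n_cycles,
                      sims_schedule = sims_schedule, seed = seed)
    ),
    class = "demog_fit"
  )
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("<demog_fit> %s: logCL = %.2f (k = %d)%s\n", x$model_id,
              x$loglik, x$k,
              if (!x$converged) " [no run improved: flagged]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_model
#' @param x A `demog_fit`.
#' @param ... Unused.
#' @export
tidy.demog_fit <- function(x, ...) {
  tibble::tibble(term = x$free, estimate = unname(x$estimate))
}

#' @rdname fit_model
#' @export
glance.demog_fit <- function(x, ...) {
  tibble::tibble(model = x$model_id, logLik = x$loglik, k = x$k,
                 AIC = 2 * x$k - 2 * x$loglik, converged = x$converged,
                 n_snps = x$n_snps)
}

#' Compare demographic fits by AIC and Akaike weights
#'
#' \eqn{AIC = 2k - 2\,\log CL_{max}};
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param fits A list of `demog_fit` objects.
#' @return A tibble `model`, `k`, `logLik`, `AIC`, `delta_AIC`, `weight`
#'   (sorted by AIC; the best model's `delta_AIC` is 0 and weights sum to 1).
#' @export
compare_models <- function(fits) {
  if (!length(fits)) abort("need at least one fit")
  df <- dplyr::bind_rows(lapply(fits, glance))
  df <- df[, c("model", "k", "logLik", "AIC")]
  df$delta_AIC <- df$AIC - min(df$AIC)
  w <- exp(-df$delta_AIC / 2)
  df$weight <- w / sum(w)
  df <- dplyr::arrange(df, .data$AIC)
  structure(df, class = c("model_comparison", class(df)))
}

#' Parametric-bootstrap confidence intervals for a demographic fit
#'
#' Simulates `n_boot` SFS datasets at the point estimate (same SNP count as
#' the observed data), refits each with a reduced run/cycle budget, and
#' returns percentile intervals. Refit failures are counted and reported via
#' the `n_failed` attribute; intervals are computed over successes.
#'
#' @param best A `demog_fit`.
#' @param n_boot Bootstrap replicates (default 100).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @param n_runs,n_cycles,n_sims Reduced refit budget.
#' @return A tibble `term`, `estimate`, `ci_low`, `ci_high`, with attributes
#'   `n_failed` and `replicates` (matrix of bootstrap estimates).
#' @export
bootstrap_ci <- function(best, n_boot = 100, level = 0.95, seed = 1,
                         n_runs = 3, n_cycles = 5, n_sims = 2e4) {
  stopifnot(inherits(best, "demog_fit"))
  point <- set_model_params(best$template, best$estimate)
  n_snps <- round(best$n_snps)
  reps <- matrix(NA_real_, n_boot, length(best$free),
                 dimnames = list(NULL, best$free))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    bs <- derive_seed(seed, 31 * b)
    sim <- simulate_sfs_dataset(point, n_snps, best$sample_sizes,
                                n_sims = n_sims, seed = bs)
    fit <- try(fit_model(sim, best$template, best$bounds, n_runs = n_runs,
                         sims_schedule = c(n_sims, n_sims),
                         n_cycles = n_cycles, seed = derive_seed(seed, b),
                         min_support = best$min_support),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, ] <- fit$estimate[best$free]
    }
  }
  a <- (1 - level) / 2
  out <- tibble::tibble(
    term = best$free,
    estimate = unname(best$estimate[best$free]),
    ci_low = apply(reps, 2, quantile, probs = a, na.rm = TRUE),
    ci_high = apply(reps, 2, quantile, probs = 1 - a, na.rm = TRUE)
  )
  attr(out, "n_failed") <- n_failed
  attr(out, "replicates") <- reps
  out
}

#' Convert a fit's time parameters from generations to years
#'
#' Multiplies every time-dimension parameter (`t_div`, epoch start times,
#' migration-window bounds) by the generation time; sizes and rates are
#' returned unchanged.
#'
#' @param fit A `demog_fit`, or a named parameter vector.
#' @param g Years per generation; defaults to the template's
#'   `generation_years`.
#' @return A tibble `term`, `estimate`, `calibrated`, `unit`.
#' @examples
#' years_from_generations(c(t_div = 61409, n_anc = 179724), g = 1)
#' @export
years_from_generations <- function(fit, g = NULL) {
  if (inherits(fit, "demog_fit")) {
    g <- g %||% fit$template$generation_years
    params <- fit$estimate
  } else {
    g <- g %||% 1
    params <- fit
  }
  if (g <= 0) abort("g must be > 0")
  is_time <- grepl("^(t_div$|t[12]_e|tw[0-9]+_)", names(params))
  tibble::tibble(
    term = names(params),
    estimate = unname(params),
    calibrated = unname(ifelse(is_time, params * g, params)),
    unit = ifelse(is_time, "years", "as-is")
  )
}
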
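# Design matrix column for the exponential recoil model at a given tau.
# With interval endpoints (t0, t1) the observed finite-difference velocity is
# the mean of v0*exp(-t/tau) over the frame interval, i.e.
#   v0 * tau * (exp(-t0/tau) - exp(-t1/tau)) / (t1 - t0);
# with pointwise samples it is v0 * exp(-t/tau). v0 enters linearly either
# way, so the fit profiles the residual sum of squares over tau alone.
recoil_basis <- function(tau, t, t0 = NULL, t1 = NULL) {
  if (!is.null(t0) && !is.null(t1) && all(is.finite(t0)) && all(is.finite(t1)) &&
      all(t1 > t0)) {
    tau * (exp(-t0 / tau) - exp(-t1 / tau)) / (t1 - t0)
  } else {
    exp(-t / tau)
  }
}

# lean vector-level fitting core shared by fit_recoil, the bootstrap and the
# permutation null; returns c(v0, tau) with tau = NA when unidentifiable
fit_recoil_core <- function(v, w, t, t0 = NULL, t1 = NULL,
                            tau_bounds = c(0.05, 60)) {
  if (all(v <= 0)) return(c(0, NA_real_))
  interval <- !is.null(t0) && !is.null(t1)
  taus <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = 48))
  e_mat <- if (interval) {
    dt <- t1 - t0
    (exp(-outer(t0, 1 / taus)) - exp(-outer(t1, 1 / taus))) *
      rep(taus, each = length(t0)) / dt
  } else {
    exp(-outer(t, 1 / taus))
  }
  wv <- w * v
  num <- colSums(wv * e_mat)
  den <- colSums(w * e_mat * e_mat)
  v0s <- pmax(0, num / den)
  sse <- sum(w * v^2) - 2 * v0s * num + v0s^2 * den
  i <- which.min(sse)
  sse_at <- function(tau) {
    e <- recoil_basis(tau, t, t0, t1)
    v0 <- max(0, sum(w * v * e) / sum(w * e * e))
    sum(w * (v - v0 * e)^2)
  }
  opt <- optimize(sse_at, c(taus[max(1, i - 1)], taus[min(length(taus), i + 1)]),
                  tol = 1e-10)
  tau_hat <- if (opt$objective <= sse[i]) opt$minimum else taus[i]
  e <- recoil_basis(tau_hat, t, t0, t1)
  v0_hat <- max(0, sum(w * v * e) / sum(w * e * e))
  c(v0_hat, tau_hat)
}

#' Fit the viscoelastic recoil model to orthogonal velocity samples
#'
#' Fits `v_perp(t) = v0 * exp(-t / tau)` — the exponential velocity decay of a
#' simple viscoelastic cortex after ablation — by least squares. The initial
#' outward velocity `v0` is proportional to cortical tension; the relaxation
#' time `tau` is inversely related to cortical stiffness (tau = friction /
#' stiffness; the two are not separately identifiable). No cortical resealing
#' term is included.
#'
#' Because `v0` is linear in the model given `tau`, the fit profiles the
#' (optionally weighted) residual sum of squares over `tau` on a log-spaced
#' grid spanning the admissible range and polishes the best bracket with
#' one-dimensional optimisation — a global, derivative-free scheme equivalent
#' to bounded nonlinear least squares for this model. Bounds: `v0 >= 0`,
#' `tau` in `[0.05, 60]` s (the lower bound guards against degenerate spikes
#' when the recoil decays within one frame). When samples carry frame-interval
#' endpoints (`t0`, `t1`, as produced by [orthogonal_samples()]), the model is
#' averaged over each interval so that finite-difference velocities are fitted
#' without discretisation bias.
#'
#' @param samples Tibble with columns `t`, `v_perp` and optionally `t0`, `t1`.
#' @param weights Optional non-negative sample weights.
#' @param tau_bounds Admissible relaxation-time range, s.
#' @return Object of class `recoil_fit` with elements `v0`, `tau`,
#'   `n_samples`, `ci_v0`, `ci_tau` (NA until bootstrapped), `converged`,
#'   `identifiable`, and the samples used.
#' @examples
#' s <- tibble::tibble(t = seq(0.5, 5.5, 1), v_perp = 1.5 * exp(-seq(0.5, 5.5, 1) / 2))
#' fit_recoil(s)
#' @export
fit_recoil <- function(samples, weights = NULL, tau_bounds = c(0.05, 60)) {
  stopifnot_cols(samples, c("t", "v_perp"), "samples")
  n <- nrow(samples)
  if (n < 3) abort("need at least 3 velocity samples")
  if (length(unique(samples$t)) < 2) abort("need samples at >= 2 distinct times")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0)) abort("`weights` must be n non-negative values")

  t <- samples$t
  v <- samples$v_perp
  t0 <- if ("t0" %in% names(samples)) samples$t0 else NULL
  t1 <- if ("t1" %in% names(samples)) samples$t1 else NULL

  if (all(v <= 0)) {
    fit <- recoil_fit_obj(0, NA_real_, n, converged = FALSE,
                          identifiable = FALSE, samples = samples, weights = w)
    warn("all orthogonal velocities <= 0: v0 = 0, tau unidentifiable")
    return(fit)
  }

  est <- fit_recoil_core(v, w, t, t0, t1, tau_bounds)
  v0_hat <- est[1]
  tau_hat <- est[2]
  at_bound <- tau_hat <= tau_bounds[1] * 1.001 || tau_hat >= tau_bounds[2] * 0.999
  recoil_fit_obj(v0_hat, tau_hat, n, converged = !at_bound,
                 identifiable = v0_hat > 0, samples = samples, weights = w)
}

recoil_fit_obj <- function(v0, tau, n, converged, identifiable, samples,
                           weights, ci_v0 = c(NA_real_, NA_real_),
                           ci_tau = c(NA_real_, NA_real_)) {
  structure(
    list(v0 = v0, tau = tau, n_samples = n, ci_v0 = ci_v0, ci_tau = ci_tau,
         converged = converged, identifiable = identifiable,
         samples = samples, weights = weights),
    class = "recoil_fit"
  )
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat(sprintf("<recoil_fit> v0 = %.4g um/s, tau = %.4g s (n = %d%s)\n",
              x$v0, x$tau, x$n_samples,
              if (!x$converged) ", not converged" else ""))
  if (!any(is.na(x$ci_v0)))
    cat(sprintf("  95%% CI: v0 [%.4g, %.4g], tau [%.4g, %.4g]\n",
                x$ci_v0[1], x$ci_v0[2], x$ci_tau[1], x$ci_tau[2]))
  invisible(x)
}

# pool orthogonal samples across experiments, attaching experiment ids and
# the equal-probability-per-experiment bootstrap weights 1 / (E * n_e)
pool_samples <- function(experiments, flow_correct = NULL) {
  stopifnot(length(experiments) >= 1)
  pooled <- purrr::map_dfr(experiments, function(ex) {
    s <- orthogonal_samples(ex, flow_correct = flow_correct)
    s$experiment_id <- ex$experiment_id
    s$cell <- ex$cell
    s
  })
  if (nrow(pooled) == 0) abort("no velocity samples in the fitting window")
  counts <- table(pooled$experiment_id)
  e_n <- length(counts)
  pooled$weight <- 1 / (e_n * as.numeric(counts[pooled$experiment_id]))
  pooled
}

#' Weighted bootstrap fit of the recoil model across experiments
#'
#' Fits the exponential recoil model to the pooled outward-velocity samples of
#' several ablation experiments of one cell, with bootstrap confidence
#' intervals. Sampling is weighted so that every experiment contributes with
#' equal probability regardless of its number of samples: each sample carries
#' probability `1 / (E * n_e)` (E experiments, `n_e` samples in its
#' experiment). Each of `n_boot` replicates resamples N samples (N = pooled
#' total) with these probabilities and refits; confidence intervals are the
#' 2.5/97.5 percentiles. The point estimate is the weighted fit on all
#' samples. Replicates whose fit fails are redrawn; more than 10% failures is
#' an error.
#'
#' @param experiments List of [ablation_experiment()]s (same cell).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param flow_correct Passed to [orthogonal_samples()].
#' @return Object of class `recoil_boot` (inherits `recoil_fit`) with
#'   percentile CIs and the bootstrap draws in `$boot`.
#' @export
bootstrap_recoil <- function(experiments, n_boot = 1000, seed = NULL,
                             flow_correct = NULL) {
  if (inherits(experiments, "ablation_experiment")) experiments <- list(experiments)
  pooled <- pool_samples(experiments, flow_correct = flow_correct)
  point <- fit_recoil(pooled, weights = pooled$weight)

  v <- pooled$v_perp
  t <- pooled$t
  t0 <- pooled$t0
  t1 <- pooled$t1
  with_seed(seed, {
    n <- nrow(pooled)
    ones <- rep(1, n)
    draws_v0 <- numeric(n_boot)
    draws_tau <- numeric(n_boot)
    failures <- 0L
    max_fail <- ceiling(0.1 * n_boot)
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE, prob = pooled$weight)
      est <- try(fit_recoil_core(v[idx], ones, t[idx], t0[idx], t1[idx]),
                 silent = TRUE)
      if (inherits(est, "try-error") || !all(is.finite(est))) {
        failures <- failures + 1L
        if (failures > max_fail)
          abort(sprintf("more than 10%% of bootstrap replicates failed (%d)", failures))
        next
      }
      draws_v0[b] <- est[1]
      draws_tau[b] <- est[2]
      b <- b + 1L
    }
    out <- point
    out$ci_v0 <- unname(quantile(draws_v0, c(0.025, 0.975)))
    out$ci_tau <- unname(quantile(draws_tau, c(0.025, 0.975)))
    out$boot <- tibble(v0 = draws_v0, tau = draws_tau)
    out$n_boot <- n_boot
    out$n_experiments <- length(experiments)
    out$failures <- failures
    class(out) <- c("recoil_boot", "recoil_fit")
    out
  })
}

#' Permutation contrast of a recoil parameter between two cells
#'
#' Tests whether `v0` (cortical tension proxy) or `tau` (inverse-stiffness
#' proxy) differs between two cells. The observed statistic is the absolute
#' difference of the weighted fits on each cell's pooled samples. The null
#' distribution follows the weighted-bootstrap scheme: each replicate draws a
#' weighted bootstrap dataset from the pooled pair (per-sample probability
#' `1/(E * n_e)` over all experiments of both cells), randomly shuffles the
#' cell labels within that dataset, refits both groups, and records the
#' absolute parameter difference. The p-value is the proportion of null
#' replicates at least as large as the observed difference, with an add-one
#' correction so p is never exactly zero (`add_one = FALSE` recovers the plain
#' proportion).
#'
#' @param experiments_a,experiments_b Lists of [ablation_experiment()]s for
#'   the two cells.
#' @param parameter `"v0"` or `"tau"`.
#' @param n_perm Number of null replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param resample If `TRUE` (default, the weighted-bootstrap null), resample
#'   the dataset before shuffling labels; if `FALSE`, shuffle labels on the
#'   observed samples only (a pure permutation test, comparable to exhaustive
#'   enumeration).
#' @param add_one Apply the add-one correction to the p-value.
#' @param flow_correct Passed to [orthogonal_samples()].
#' @return Object of class `recoil_contrast`: observed difference, p-value,
#'   group fits, and the null draws.
#' @export
permutation_contrast <- function(experiments_a, experiments_b,
                                 parameter = c("v0", "tau"), n_perm = 1000,
                                 seed = NULL, resample = TRUE, add_one = TRUE,
                                 flow_correct = NULL) {
  parameter <- match.arg(parameter)
  if (inherits(experiments_a, "ablation_experiment")) experiments_a <- list(experiments_a)
  if (inherits(experiments_b, "ablation_experiment")) experiments_b <- list(experiments_b)
  pooled <- pool_samples(c(experiments_a, experiments_b),
                         flow_correct = flow_correct)
  cell_a <- experiments_a[[1]]$cell
  cell_b <- experiments_b[[1]]$cell
  ids_a <- vapply(experiments_a, function(e) e$experiment_id, character(1))
  is_a <- pooled$experiment_id %in% ids_a
  if (!any(is_a) || all(is_a)) abort("both cells need samples")

  fit_a <- suppressWarnings(fit_recoil(pooled[is_a, ], weights = pooled$weight[is_a]))
  fit_b <- suppressWarnings(fit_recoil(pooled[!is_a, ], weights = pooled$weight[!is_a]))
  obs <- fit_a[[parameter]] - fit_b[[parameter]]
  if (!is.finite(obs)) abort(sprintf("observed %s difference is undefined", parameter))

  v <- pooled$v_perp
  tt <- pooled$t
  t0 <- pooled$t0
  t1 <- pooled$t1
  lab0 <- is_a
  par_ix <- if (parameter == "v0") 1L else 2L
  with_seed(seed, {
    n <- nrow(pooled)
    ones <- rep(1, n)
    null_draws <- numeric(n_perm)
    failures <- 0L
    max_fail <- ceiling(0.1 * n_perm)
    b <- 1L
    while (b <= n_perm) {
      idx <- if (resample) sample.int(n, n, replace = TRUE, prob = pooled$weight)
             else seq_len(n)
      ia <- sample(lab0[idx])
      d <- if (sum(ia) < 3 || sum(!ia) < 3) NA_real_ else {
        iidx <- idx[ia]; jidx <- idx[!ia]
        da <- try(fit_recoil_core(v[iidx], rep(1, length(iidx)), tt[iidx],
                                  t0[iidx], t1[iidx])[par_ix], silent = TRUE)
        db <- try(fit_recoil_core(v[jidx], rep(1, length(jidx)), tt[jidx],
                                  t0[jidx], t1[jidx])[par_ix], silent = TRUE)
        if (inherits(da, "try-error") || inherits(db, "try-error")) NA_real_
        else da - db
      }
      if (!is.finite(d)) {
        failures <- failures + 1L
        if (failures > max_fail)
          abort(sprintf("more than 10%% of null replicates failed (%d)", failures))
        next
      }
      null_draws[b] <- abs(d)
      b <- b + 1L
    }
    n_ge <- sum(null_draws >= abs(obs))
    p <- if (add_one) (n_ge + 1) / (n_perm + 1) else n_ge / n_perm
    structure(
      list(parameter = parameter, observed = obs, p = p,
           fit_a = fit_a, fit_b = fit_b, cell_a = cell_a, cell_b = cell_b,
           null = null_draws, n_perm = n_perm, resample = resample,
           add_one = add_one, failures = failures),
      class = "recoil_contrast"
    )
  })
}

#' @export
print.recoil_contrast <- function(x, ...) {
  cat(sprintf("<recoil_contrast> %s: %s (%.4g) vs %s (%.4g), |diff| = %.4g, p = %.4g (%d permutations)\n",
              x$parameter, x$cell_a, x$fit_a[[x$parameter]],
              x$cell_b, x$fit_b[[x$parameter]],
              abs(x$observed), x$p, x$n_perm))
  invisible(x)
}

#' Exhaustive permutation contrast (enumeration oracle for small datasets)
#'
#' Enumerates every assignment of group labels that preserves the observed
#' group sizes and computes the exact permutation p-value for the absolute
#' difference of a recoil parameter. Intended for validating the Monte-Carlo
#' permutation test on tiny datasets.
#'
#' @param samples Pooled sample tibble with a `cell` column.
#' @param cell_a Label of the first group.
#' @param parameter `"v0"` or `"tau"`.
#' @return Exact p-value (proportion of labelings with difference >= observed).
#' @export
exhaustive_contrast <- function(samples, cell_a, parameter = c("v0", "tau")) {
  parameter <- match.arg(parameter)
  n <- nrow(samples)
  na <- sum(samples$cell == cell_a)
  if (choose(n, na) > 20000) abort("too many labelings to enumerate")
  fit_param <- function(s) suppressWarnings(fit_recoil(s))[[parameter]]
  obs <- abs(fit_param(samples[samples$cell == cell_a, ]) -
               fit_param(samples[samples$cell != cell_a, ]))
  combs <- utils::combn(n, na)
  diffs <- apply(combs, 2, function(ix) {
    abs(fit_param(samples[ix, ]) - fit_param(samples[-ix, ]))
  })
  mean(diffs >= obs - 1e-12)
}
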
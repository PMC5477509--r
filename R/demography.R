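## Demographic model comparison on folded, projected, singleton-masked
## site-frequency spectra.  Four models of the weedy split from its
## cultivated progenitor: with/without a bottleneck, with/without
## post-bottleneck migration.  Parameters are dimensionless: sizes scaled
## by the ancestral effective size N_a, times by 2 N_a generations,
## migration as M = 2 N_a m.  The expected joint SFS is obtained by
## Monte-Carlo forward simulation of independent neutral sites at desk
## scale (theta-preserving rescaling); the likelihood is the multinomial
## composite log-likelihood over unmasked SFS cells, which is free of the
## mutation-scaled theta multiplier and supports relative model ranking.

MODEL_IDS <- c("BN+MIG", "BN", "NOBN+MIG", "NOBN")

#' A scaled demographic model
#'
#' @param model_id One of `"BN+MIG"`, `"BN"`, `"NOBN+MIG"`, `"NOBN"`
#'   (bottleneck / no bottleneck, with / without migration).
#' @param nu_b Bottleneck size ratio `N_b / N_a` (bottleneck models only).
#' @param nu_w Present weedy size ratio `N_w / N_a`.
#' @param tau_b Bottleneck duration `T_b / (2 N_a)` (bottleneck models).
#' @param tau Time from recovery (or split, for no-bottleneck models) to
#'   the present, `T / (2 N_a)`.
#' @param M Scaled migration rate `2 N_a m` (migration models only).
#' @return List of class `demographic_model`.
#' @export
demographic_model <- function(model_id, nu_w, tau, nu_b = NULL, tau_b = NULL,
                              M = NULL) {
  if (!model_id %in% MODEL_IDS)
    fs_param_error("unknown model id: %s", model_id)
  has_bn <- model_id %in% c("BN+MIG", "BN")
  has_mig <- model_id %in% c("BN+MIG", "NOBN+MIG")
  if (nu_w <= 0 || tau < 0) fs_param_error("need nu_w > 0 and tau >= 0")
  if (has_bn) {
    if (is.null(nu_b) || is.null(tau_b) || nu_b <= 0 || tau_b < 0)
      fs_param_error("%s needs nu_b > 0 and tau_b >= 0", model_id)
  } else {
    nu_b <- NULL; tau_b <- NULL
  }
  M <- if (has_mig) {
    if (is.null(M) || M < 0) fs_param_error("%s needs M >= 0", model_id)
    M
  } else 0
  structure(list(model_id = model_id, nu_w = nu_w, tau = tau,
                 nu_b = nu_b, tau_b = tau_b, M = M),
            class = "demographic_model")
}

## free parameter names per model (optimization order)
model_param_names <- function(model_id) {
  switch(model_id,
         "BN+MIG" = c("nu_b", "nu_w", "tau_b", "tau", "M"),
         "BN" = c("nu_b", "nu_w", "tau_b", "tau"),
         "NOBN+MIG" = c("nu_w", "tau", "M"),
         "NOBN" = c("nu_w", "tau"),
         fs_param_error("unknown model id: %s", model_id))
}

model_from_params <- function(model_id, par) {
  par <- as.list(par)
  demographic_model(model_id, nu_w = par$nu_w, tau = par$tau,
                    nu_b = par$nu_b, tau_b = par$tau_b, M = par$M)
}

#' Does model `a` nest model `b`?
#'
#' `TRUE` when every scenario of `b` is reachable inside `a` (e.g. BN+MIG
#' nests BN at M = 0; BN nests NOBN at tau_b = 0).
#'
#' @param a,b Model ids.
#' @return Logical.
#' @export
model_nests <- function(a, b) {
  nested <- list(
    "BN+MIG" = MODEL_IDS, "BN" = c("BN", "NOBN"),
    "NOBN+MIG" = c("NOBN+MIG", "NOBN"), "NOBN" = "NOBN")
  b %in% nested[[a]]
}

#' Ancestral effective size from diversity
#'
#' `Ne = floor(theta / (4 mu L))` with `theta` the per-site neutral
#' diversity, `mu` the per-site per-generation mutation rate and `L` the
#' generation time in years.
#'
#' @param theta Per-site diversity (e.g. 2.2e-3 for indica cultivars).
#' @param mu Mutation rate per site per generation (e.g. 6.5e-9).
#' @param L Generation time in years (default 1).
#' @return Integer Ne.
#' @export
ne_from_theta <- function(theta, mu, L = 1) {
  if (theta <= 0 || mu <= 0 || L <= 0)
    fs_param_error("theta, mu and L must all be > 0")
  as.integer(floor(theta / (4 * mu * L)))
}

## cache of ancestral equilibrium allele counts, keyed by the simulation
## settings, so common random numbers hold across parameter evaluations
.fs_eq_cache <- new.env(parent = emptyenv())

ancestral_equilibrium <- function(N_a, mu, n_sites, seed) {
  key <- paste(N_a, mu, n_sites, seed, sep = "|")
  if (!is.null(.fs_eq_cache[[key]])) return(.fs_eq_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  x <- wf_burn_in(n_sites, N_a, mu, 8L * N_a)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (length(ls(.fs_eq_cache)) > 32) rm(list = ls(.fs_eq_cache),
                                        envir = .fs_eq_cache)
  .fs_eq_cache[[key]] <- x
  x
}

#' Monte-Carlo expected site-frequency spectrum under a model
#'
#' Simulates `n_replicate_sites` independent neutral sites with the
#' rescaled forward Wright-Fisher engine at reference size `N_anc` diploids
#' (theta-preserving desk scale), samples `n1` cultivated and `n2` weedy
#' alleles per site, accumulates the joint spectrum of sites segregating in
#' the sample, folds, masks singletons, and normalizes to probabilities
#' over the unmasked cells.  Seed-reproducible: the ancestral equilibrium
#' is cached per `(N_anc, theta_site, n_replicate_sites, seed)` and the
#' post-split epochs re-use the seed, so two calls with equal arguments are
#' identical (common random numbers across parameter evaluations).
#'
#' @param model A [demographic_model()].
#' @param n1,n2 Allele-sample sizes for the cultivated and weedy axes.
#' @param n_replicate_sites Number of simulated sites (>= 1e4 recommended).
#' @param seed Integer seed.
#' @param N_anc Desk-scale reference diploid size (default 100).
#' @param theta_site Per-site `4 N mu` at desk scale (default 0.02).
#' @return Folded, masked `sfs` of probabilities (axis 1 = cultivated).
#' @export
expected_sfs <- function(model, n1, n2, n_replicate_sites = 2e4, seed = 1L,
                         N_anc = 100L, theta_site = 0.02) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.null(model$nu_b) && model$nu_b <= 0)
    fs_param_error("degenerate nu_b")
  mu <- theta_site / (4 * N_anc)
  x_anc <- ancestral_equilibrium(N_anc, mu, n_replicate_sites, seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)

  has_bn <- model$model_id %in% c("BN+MIG", "BN")
  N_b <- if (has_bn) max(2L, as.integer(round(model$nu_b * N_anc))) else NULL
  N_w <- max(2L, as.integer(round(model$nu_w * N_anc)))
  T_b <- if (has_bn) as.integer(round(model$tau_b * 2 * N_anc)) else 0L
  T_r <- as.integer(round(model$tau * 2 * N_anc))
  m <- model$M / (2 * N_anc)
  if (m >= 0.5) fs_param_error("migration fraction m = M/(2 N_a) must be < 0.5")

  S <- n_replicate_sites
  ## Smooth common random numbers: every binomial draw is inverse-CDF
  ## coupled to a uniform stream indexed by (epoch, generation), derived
  ## deterministically from the seed.  rbinom's rejection sampler would
  ## desynchronize the stream at any parameter change and decorrelate the
  ## whole trajectory; qbinom on fixed uniforms makes the likelihood
  ## surface a near-continuous function of the parameters, which the
  ## optimizer and across-model comparisons both rely on.
  u_of <- function(tag) {
    set.seed((as.numeric(seed) + as.numeric(tag) * 1000003) %% 2147483629)
    runif(S)
  }
  ## inverse-CDF binomial on a tagged uniform stream; monomorphic sites
  ## (p at the mutation floor/ceiling) take a Bernoulli mutation-arrival
  ## shortcut instead of a full quantile inversion -- double-mutant
  ## arrivals (~(N mu)^2) are beneath Monte-Carlo resolution
  qb <- function(tag, size, prob) {
    u <- u_of(tag)
    out <- integer(S)
    at_floor <- prob <= mu
    at_ceil <- prob >= 1 - mu
    mid <- !(at_floor | at_ceil)
    out[at_floor] <- as.integer(u[at_floor] > (1 - mu)^size)
    out[at_ceil] <- size - as.integer(u[at_ceil] < 1 - (1 - mu)^size)
    if (any(mid)) out[mid] <- qbinom(u[mid], size, prob[mid])
    out
  }
  ## one neutral generation of both populations (frequency-only WF);
  ## epoch-anchored tags keep the recovery phase coupled across tau_b
  step2 <- function(xw, xc, Nw_from, Nw_to, m_now, tag) {
    pw <- xw / (2 * Nw_from); pc <- xc / (2 * N_anc)
    pw <- pw * (1 - mu) + (1 - pw) * mu
    pc <- pc * (1 - mu) + (1 - pc) * mu
    if (m_now > 0) {
      tmp <- (1 - m_now) * pw + m_now * pc
      pc <- (1 - m_now) * pc + m_now * pw
      pw <- tmp
    }
    list(w = qb(tag, 2 * Nw_to, pw), c = qb(tag + 1L, 2 * N_anc, pc))
  }

  ## split: weedy founders drawn from the ancestral gene pool
  p0 <- x_anc / (2 * N_anc)
  start_w <- if (has_bn) N_b else N_w
  xw <- qb(1L, 2 * start_w, p0)
  xc <- x_anc
  if (has_bn) {
    for (g in seq_len(T_b)) {
      r <- step2(xw, xc, N_b, N_b, 0, tag = 10L + 2L * g)
      xw <- r$w; xc <- r$c
    }
  }
  from_N <- start_w
  for (g in seq_len(T_r)) {
    r <- step2(xw, xc, from_N, N_w, m, tag = 4000L + 2L * g)
    xw <- r$w; xc <- r$c
    from_N <- N_w
  }
  N_w_final <- if (T_r > 0) N_w else start_w

  ## binomial sampling kernel in the population frequency (the standard
  ## SFS sampling operator; well-defined for any population size),
  ## inverse-CDF coupled like the trajectory draws
  j1 <- qb(8001L, n1, xc / (2 * N_anc))
  j2 <- qb(8002L, n2, xw / (2 * N_w_final))
  seg <- (j1 + j2) > 0 & (j1 + j2) < (n1 + n2)
  cell <- j1[seg] + (n1 + 1L) * j2[seg] + 1L
  counts <- matrix(tabulate(cell, nbins = (n1 + 1L) * (n2 + 1L)),
                   n1 + 1L, n2 + 1L)
  out <- mask_singletons(fold_sfs(new_sfs(counts, c(n1, n2),
                                          folded = FALSE)))
  ## Dirichlet smoothing of the Monte-Carlo cell estimates: without it,
  ## cells the finite simulation never visits get probability 0 and the
  ## likelihood's log-floor turns Monte-Carlo gaps into huge penalties
  ## that dominate model ranking.  The pseudo-mass is a fixed small
  ## fraction (2%) of the segregating mass, so the distortion it induces
  ## is the same whatever n_replicate_sites is -- a constant per-cell
  ## pseudo-count would bias small simulations against large ones.
  keep <- !out$masked
  alpha <- 0.02 * max(sum(out$counts[keep]), 1) / sum(keep)
  out$counts[keep] <- out$counts[keep] + alpha
  sfs_normalize(out)
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' `sum over unmasked cells of obs * log(max(expected, 1e-12))`.  The
#' observed spectrum carries counts, the expected one probabilities; both
#' must have the same shape, folding state and mask.
#'
#' @param observed `sfs` of counts.
#' @param expected `sfs` of probabilities (e.g. from [expected_sfs()]).
#' @return Log-likelihood (numeric scalar).
#' @export
composite_log_likelihood <- function(observed, expected) {
  if (!identical(dim(as.matrix(observed$counts)),
                 dim(as.matrix(expected$counts))) ||
      !identical(observed$n, expected$n) ||
      !identical(observed$folded, expected$folded) ||
      !identical(observed$masked, expected$masked))
    fs_input_error("observed and expected SFS shape/fold/mask mismatch")
  keep <- !observed$masked
  sum(observed$counts[keep] * log(pmax(expected$counts[keep], 1e-12)))
}

## default log-uniform search bounds per parameter
default_bounds <- function() {
  list(nu_b = c(0.005, 1), nu_w = c(0.01, 5), tau_b = c(0.005, 0.25),
       tau = c(0.005, 0.4), M = c(0.01, 10))
}

#' Fit one demographic model to an observed SFS
#'
#' Each of `n_runs` independent runs screens a batch of random points
#' (log-uniform within `bounds`), then locally maximizes the composite
#' log-likelihood from the best of them with Nelder-Mead in log-parameter
#' space under a fixed evaluation budget.  Every evaluation of every run
#' uses the same inverse-CDF-coupled site-simulation seed (common random
#' numbers), so all runs optimize one deterministic surface and their
#' final values are directly comparable.  Headline parameters are the
#' per-parameter median over the top decile of runs (never fewer than 3)
#' by final log-likelihood.
#'
#' @param observed Folded, masked `sfs` of counts (axis 1 cultivated,
#'   axis 2 weedy), e.g. from [build_sfs()] + [project_sfs()] +
#'   [fold_sfs()] + [mask_singletons()].
#' @param model_id Model to fit.
#' @param n_runs Number of randomized starts (default 20; the study-scale
#'   setting is 200).
#' @param optimizer_budget Maximum likelihood evaluations per run.
#' @param bounds Named list of `c(lo, hi)` per parameter.
#' @param seed Integer seed.
#' @param n_replicate_sites,N_anc,theta_site Passed to [expected_sfs()].
#' @param extra_starts Optional list of named parameter vectors used as
#'   additional (non-random) optimization starts — e.g. a nested
#'   sub-model's optimum embedded in this model's parameter space, which
#'   keeps the nesting inequality (richer model's best likelihood >= its
#'   sub-model's) attainable in practice.
#' @param surface_reps Number of coupled seed replicates averaged per
#'   likelihood evaluation (default 1).  Averaging flattens the
#'   Monte-Carlo noise envelope that maximization would otherwise chase
#'   along weakly identified ridges, at proportional cost.
#' @return List of class `fit_result`: model_id, runs (data.frame), best
#'   (params + ll of the best run), headline (median-of-top-decile params).
#' @export
fit_model <- function(observed, model_id, n_runs = 20L,
                      optimizer_budget = 200L, bounds = default_bounds(),
                      seed = 1L, n_replicate_sites = 2e4, N_anc = 100L,
                      theta_site = 0.02, extra_starts = list(),
                      surface_reps = 1L) {
  if (n_runs < 1) fs_param_error("n_runs must be >= 1")
  pnames <- model_param_names(model_id)
  n1 <- observed$n[1]; n2 <- observed$n[2]
  lo <- log(vapply(bounds[pnames], `[`, numeric(1), 1))
  hi <- log(vapply(bounds[pnames], `[`, numeric(1), 2))
  n_random <- n_runs
  n_runs <- n_runs + length(extra_starts)
  runs <- vector("list", n_runs)
  set.seed(seed)
  ## one site-simulation seed for every evaluation of every run: all runs
  ## (and all models fitted with the same seed) optimize one common,
  ## deterministic likelihood surface, so their final values are directly
  ## comparable -- per-run seeds would make best-run selection a lottery
  ## of Monte-Carlo jitter
  crn_seed <- sample.int(2^30, 1) + 7919L * (seq_len(surface_reps) - 1L)
  start_mat <- matrix(runif(n_random * length(pnames), lo, hi),
                      nrow = n_random, byrow = TRUE)
  if (length(extra_starts) > 0) {
    es <- t(vapply(extra_starts, function(p)
      pmin(pmax(log(unlist(p)[pnames]), lo), hi), numeric(length(pnames))))
    start_mat <- rbind(start_mat, es)
  }
  n_screen <- 10L
  screen_mat <- matrix(runif(n_random * n_screen * length(pnames), lo, hi),
                       ncol = length(pnames), byrow = TRUE)
  for (r in seq_len(n_runs)) {
    nll <- function(logpar) {
      par <- setNames(exp(pmin(pmax(logpar, lo), hi)), pnames)
      mod <- model_from_params(model_id, par)
      ll <- mean(vapply(crn_seed, function(cs) {
        exp_sfs <- expected_sfs(mod, n1, n2, n_replicate_sites, seed = cs,
                                N_anc = N_anc, theta_site = theta_site)
        composite_log_likelihood(observed, exp_sfs)
      }, numeric(1)))
      if (!is.finite(ll)) 1e12 else -ll
    }
    if (r <= n_random) {
      ## screen a handful of random points, then polish the best with a
      ## derivative-free simplex under the evaluation budget
      cand <- rbind(start_mat[r, ],
                    screen_mat[(r - 1L) * n_screen + seq_len(n_screen), ,
                               drop = FALSE])
      cand_val <- apply(cand, 1L, function(x)
        tryCatch(nll(x), error = function(e) Inf))
      best_start <- cand[which.min(cand_val), ]
    } else {
      best_start <- start_mat[r, ]   # warm start: polish as supplied
    }
    fit <- tryCatch(
      optim(best_start, nll, method = "Nelder-Mead",
            control = list(maxit = optimizer_budget)),
      error = function(e) NULL)
    if (is.null(fit)) next
    par <- setNames(exp(pmin(pmax(fit$par, lo), hi)), pnames)
    runs[[r]] <- data.frame(run = r, t(c(start = exp(best_start))),
                            t(par), ll = -fit$value,
                            stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs) || !any(is.finite(runs$ll)))
    fs_degenerate_error("fit_model: all runs failed")
  runs <- runs[order(-runs$ll), , drop = FALSE]
  rownames(runs) <- NULL
  ## headline: per-parameter median over the top decile of runs, but
  ## never fewer than 3 runs -- at desk-scale run counts a single-run
  ## "decile" would chase the Monte-Carlo noise envelope along flat
  ## likelihood ridges; at the study scale (200 runs) this is the decile
  n_top <- min(nrow(runs), max(3L, ceiling(nrow(runs) / 10)))
  top <- runs[seq_len(n_top), , drop = FALSE]
  headline <- vapply(pnames, function(p) median(top[[p]]), numeric(1))
  structure(list(model_id = model_id,
                 runs = runs,
                 best = as.list(runs[1, c(pnames, "ll")]),
                 headline = headline,
                 n_params = length(pnames)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s, %d run(s), best LL %.2f\n", x$model_id,
              nrow(x$runs), x$best$ll))
  cat("headline params:",
      paste(sprintf("%s=%.4g", names(x$headline), x$headline),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit and rank several demographic models
#'
#' Fits each model with [fit_model()] under one shared random seed, so
#' every run of every model optimizes the same common-random-number
#' likelihood surface and the resulting best likelihoods are directly
#' comparable; models are fitted in nesting order and each richer model
#' is additionally warm-started from its fitted sub-models' optima.
#'
#' @param observed Folded, masked `sfs` of counts.
#' @param model_ids Models to compare (default all four).
#' @param n_runs,optimizer_budget,bounds,seed,n_replicate_sites,N_anc,theta_site,surface_reps
#'   Passed to [fit_model()].
#' @return List: `ranking` data.frame (model_id, ll, delta_ll, n_params,
#'   ranked best first) and `fits` (named list of fit_result).
#' @export
compare_models <- function(observed, model_ids = MODEL_IDS, n_runs = 20L,
                           optimizer_budget = 200L, bounds = default_bounds(),
                           seed = 1L, n_replicate_sites = 2e4, N_anc = 100L,
                           theta_site = 0.02, surface_reps = 1L) {
  if (length(model_ids) < 2) fs_param_error("need >= 2 models to compare")
  ## fit in nesting order so each richer model is warm-started from its
  ## fitted sub-models' optima (embedded with the extra parameter at its
  ## smallest bound): this keeps the nesting inequality attainable
  fit_order <- intersect(c("NOBN", "NOBN+MIG", "BN", "BN+MIG"), model_ids)
  fit_order <- c(fit_order, setdiff(model_ids, fit_order))
  lo_of <- function(p) bounds[[p]][1]
  embed_starts <- function(mid, fits) {
    sub <- Filter(function(f) f$model_id != mid &&
                    model_nests(mid, f$model_id), fits)
    lapply(sub, function(f) {
      par <- f$best[model_param_names(f$model_id)]
      if (is.null(par$nu_b)) par$nu_b <- par$nu_w
      if (is.null(par$tau_b)) par$tau_b <- lo_of("tau_b")
      if (is.null(par$M) || par$M == 0) par$M <- lo_of("M")
      par[model_param_names(mid)]
    })
  }
  fits <- list()
  for (mid in fit_order) {
    fits[[mid]] <- fit_model(
      observed, mid, n_runs = n_runs, optimizer_budget = optimizer_budget,
      bounds = bounds, seed = seed, n_replicate_sites = n_replicate_sites,
      N_anc = N_anc, theta_site = theta_site,
      extra_starts = embed_starts(mid, fits), surface_reps = surface_reps)
  }
  fits <- fits[model_ids]
  ## every model was fitted on the same common-random-number surface
  ## (same seed), so the best-fit likelihoods are directly comparable
  ll <- vapply(fits, function(f) f$best$ll, numeric(1))
  ord <- order(-ll)
  ranking <- data.frame(model_id = model_ids[ord], ll = ll[ord],
                        delta_ll = max(ll) - ll[ord],
                        n_params = vapply(fits[ord], `[[`, numeric(1),
                                          "n_params"),
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  list(ranking = ranking, fits = fits)
}

#' Scenario presets for the four demographic models
#'
#' Desk-scale presets (not calibrated estimates): a strong short
#' bottleneck (`nu_b = 0.05`, `tau_b = 0.05`) recovering to
#' `nu_w = 0.8`, split-to-present `tau = 0.1`, migration `M = 2` where the
#' model allows it.
#'
#' @param model_id One of the four model ids.
#' @return A [demographic_model()].
#' @export
preset_model <- function(model_id) {
  switch(model_id,
         "BN+MIG" = demographic_model("BN+MIG", nu_w = 0.8, tau = 0.1,
                                      nu_b = 0.05, tau_b = 0.05, M = 2),
         "BN" = demographic_model("BN", nu_w = 0.8, tau = 0.1,
                                  nu_b = 0.05, tau_b = 0.05),
         "NOBN+MIG" = demographic_model("NOBN+MIG", nu_w = 0.8, tau = 0.15,
                                        M = 2),
         "NOBN" = demographic_model("NOBN", nu_w = 0.8, tau = 0.15),
         fs_param_error("unknown model id: %s", model_id))
}
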
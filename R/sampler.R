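# Reversible-jump MCMC over rate models.  The model space is the set of
# partitions of the named rates into positive-value classes plus a
# structural-zero bin, with one value per class; the model prior is
# uniform over these configurations.  Class values carry either a
# uniform prior or a gamma prior whose mean and shape are hyperparameters
# updated within the chain.

#' Prior on rate-class values
#'
#' @param kind `"uniform"` (default; bounds `lo`, `hi`) or `"gamma"` (a
#'   gamma hyperprior: class values are gamma-distributed with mean and
#'   shape each uniform on `(0, hyper_max]`, resampled by
#'   Metropolis-Hastings within the chain).
#' @param lo,hi uniform bounds, `0 <= lo < hi` (default 0-100, the usual
#'   BayesTraits-style convention for rates on trees of height order 1-10).
#' @param hyper_max upper bound of the hyperparameter ranges (default 10).
#' @return an object of class `rate_prior`.
#' @export
rate_prior <- function(kind = c("uniform", "gamma"), lo = 0, hi = 100,
                       hyper_max = 10) {
  kind <- match.arg(kind)
  stopifnot(lo >= 0, lo < hi, hyper_max > 0)
  structure(list(kind = kind, lo = lo, hi = hi, hyper_max = hyper_max),
            class = "rate_prior")
}

#' MCMC chain settings
#'
#' The `"desk"` profile (default) runs in seconds to minutes on one core;
#' the `"paper"` profile encodes the published cluster-scale
#' BayesTraits settings (ancestral reconstruction: 5.005e7 iterations,
#' 5e4 burn-in, thinning 1000; dependence testing: 5.005e8 iterations,
#' 5e5 burn-in, thinning 1000).
#'
#' @param iterations total iterations.
#' @param burnin burn-in iterations (`burnin < iterations`); the proposal
#'   scale is tuned only during burn-in.
#' @param thin sampling interval (`>= 1`).
#' @param seed optional integer seed.
#' @param target_acceptance target acceptance rate of the rate-value
#'   proposals (default 0.30).
#' @param ratedev initial sliding-window width of the rate-value proposal.
#' @param tune_interval iterations between multiplicative `ratedev`
#'   updates during burn-in.
#' @param profile `NULL`, `"desk"` or `"paper"`; a named profile
#'   overrides `iterations`, `burnin` and `thin`.
#' @param stage for the `"paper"` profile: `"ancestral"` or
#'   `"dependence"`.
#' @return an object of class `chain_settings`.
#' @export
chain_settings <- function(iterations = 1e5, burnin = 1e3, thin = 10,
                           seed = NULL, target_acceptance = 0.30,
                           ratedev = 2, tune_interval = 100,
                           profile = NULL, stage = c("ancestral", "dependence")) {
  stage <- match.arg(stage)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("desk", "paper"))
    if (profile == "desk") {
      iterations <- 1e5; burnin <- 1e3; thin <- 10
    } else if (stage == "ancestral") {
      iterations <- 5.005e7; burnin <- 5e4; thin <- 1000
    } else {
      iterations <- 5.005e8; burnin <- 5e5; thin <- 1000
    }
  }
  stopifnot(burnin < iterations, thin >= 1, target_acceptance > 0,
            target_acceptance < 1, ratedev > 0, tune_interval >= 1)
  structure(list(iterations = as.double(iterations),
                 burnin = as.double(burnin), thin = as.integer(thin),
                 seed = seed, target_acceptance = target_acceptance,
                 ratedev = ratedev, tune_interval = as.integer(tune_interval),
                 profile = profile),
            class = "chain_settings")
}

#' Fit a rate model by reversible-jump MCMC
#'
#' Samples the joint posterior over (rate-class partition incl. the zero
#' bin, class values, tree index) for one of three models: `"binary"`
#' (2-state single character, rates gain/loss), `"independent"` (4-state
#' pair model with 4 free rates) or `"dependent"` (4-state pair model
#' with 8 free rates).  The tree index is a latent variable resampled
#' uniformly over the tree sample, integrating phylogenetic uncertainty;
#' each iteration costs one pruning pass on one tree.
#'
#' @param model `"binary"`, `"independent"` or `"dependent"`.
#' @param trees a `phylo` or `multiPhylo` tree sample.
#' @param tips taxa x states tip partial-likelihood matrix (2 columns for
#'   `"binary"`, 4 for the pair models); see [single_tipdata()],
#'   [pair_tipdata()].
#' @param prior a [rate_prior()].
#' @param settings a [chain_settings()].
#' @param likelihood set `FALSE` to sample from the prior only
#'   (likelihood held constant), used to validate the sampler against
#'   exhaustive enumeration of the model space.
#' @return an object of class `rjmcmc` with components `rates` (samples x
#'   rates), `zero` (0/1 zero-bin flags), `logL`, `tree_index`,
#'   `n_classes`, `acceptance`, `final_ratedev`, plus the inputs.
#' @export
run_rjmcmc <- function(model = c("dependent", "independent", "binary"),
                       trees, tips, prior = rate_prior(),
                       settings = chain_settings(),
                       likelihood = TRUE) {
  model <- match.arg(model)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees <- as_tree_sample(trees)
  rmap <- rate_map_for(model)
  rnames <- rate_names_for(model)
  ns <- nrow(rmap)
  if (ncol(tips) != ns)
    stop("tips have ", ncol(tips), " states but model '", model,
         "' needs ", ns)
  # uniform root prior inside the chain (a stationary prior would change
  # with every Q proposal; use root_prior("stationary") in the fixed-rate
  # likelihood functions instead)
  rootp <- rep(1 / ns, ns)
  ctrees <- lapply(trees, tree_to_c, tips = tips)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  res <- rjmcmc_cpp(ctrees, rmap, length(rnames), unclass(prior), rootp,
                    as.integer(settings$iterations),
                    as.integer(settings$burnin), settings$thin,
                    settings$ratedev, settings$target_acceptance,
                    settings$tune_interval, likelihood)
  colnames(res$rates) <- rnames
  colnames(res$zero) <- rnames
  structure(list(model = model, rates = res$rates, zero = res$zero,
                 logL = as.numeric(res$logL),
                 tree_index = as.integer(res$tree_index),
                 n_classes = as.integer(res$n_classes),
                 hyper_mean = as.numeric(res$hyper_mean),
                 hyper_shape = as.numeric(res$hyper_shape),
                 acceptance = res$acceptance,
                 ratedev = as.numeric(res$ratedev),
                 final_ratedev = res$final_ratedev,
                 prior = prior, settings = settings,
                 n_trees = length(trees),
                 likelihood = likelihood),
            class = "rjmcmc")
}

#' @export
print.rjmcmc <- function(x, ...) {
  cat("rj-MCMC fit (", x$model, " model)\n", sep = "")
  cat("  samples: ", nrow(x$rates), "  (iterations ",
      format(x$settings$iterations, big.mark = ","), ", burn-in ",
      format(x$settings$burnin, big.mark = ","), ", thin ",
      x$settings$thin, ")\n", sep = "")
  cat("  trees: ", x$n_trees, "   prior: ", x$prior$kind, "\n", sep = "")
  cat("  acceptance (rate moves): ", round(x$acceptance, 3),
      "   final ratedev: ", signif(x$final_ratedev, 3), "\n", sep = "")
  cat("  mean logL: ", round(mean(x$logL), 3),
      "   harmonic-mean logL: ", round(harmonic_mean_logL(x), 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.rjmcmc <- function(object, ...) {
  r <- object$rates
  tab <- data.frame(
    rate = colnames(r),
    mean = colMeans(r),
    median = apply(r, 2, median),
    q025 = apply(r, 2, quantile, 0.025),
    q975 = apply(r, 2, quantile, 0.975),
    zero_pct = colMeans(object$zero) * 100,
    ess = apply(r, 2, ess),
    row.names = NULL)
  out <- list(model = object$model, rates = tab,
              logL_hm = harmonic_mean_logL(object),
              mean_classes = mean(object$n_classes),
              acceptance = object$acceptance,
              diagnostics = chain_diagnostics(object))
  class(out) <- "summary.rjmcmc"
  out
}

#' @export
print.summary.rjmcmc <- function(x, ...) {
  cat("rj-MCMC posterior summary (", x$model, " model)\n", sep = "")
  print(x$rates, digits = 4)
  cat("harmonic-mean logL: ", round(x$logL_hm, 3),
      "   mean rate classes: ", round(x$mean_classes, 2), "\n", sep = "")
  if (!x$diagnostics$stationary)
    cat("warning: log-likelihood trace looks non-stationary (Geweke |z| = ",
        round(abs(x$diagnostics$geweke_z), 2), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.rjmcmc <- function(object, ...) colMeans(object$rates)

#' @export
plot.rjmcmc <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$logL, type = "l", xlab = "sample", ylab = "logL",
                 main = "log-likelihood trace", ...)
  graphics::matplot(x$rates, type = "l", lty = 1, xlab = "sample",
                    ylab = "rate", main = "rate traces", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' Multiplicative proposal-scale update
#'
#' `scale * exp(observed - target)`: widens the sliding window when the
#' observed acceptance is above target and narrows it when below.  Applied
#' only during burn-in (the scale is frozen afterwards to preserve
#' detailed balance).
#'
#' @param scale current proposal width.
#' @param observed observed acceptance rate over the last tuning window.
#' @param target target acceptance rate (default 0.30).
#' @export
autotune_ratedev <- function(scale, observed, target = 0.30) {
  stopifnot(length(observed) >= 1)
  scale * exp(mean(observed) - target)
}

#' Harmonic-mean log marginal likelihood
#'
#' `-log(mean(exp(-logL)))`, computed stably in log space.  The harmonic
#' mean of sampled likelihoods converges on the marginal likelihood for
#' long chains, but is noisy; combine several independent runs.
#'
#' @param x an `rjmcmc` fit or a numeric vector of log-likelihoods.
#' @export
harmonic_mean_logL <- function(x) {
  ll <- if (inherits(x, "rjmcmc")) x$logL else as.numeric(x)
  if (length(ll) < 1L) stop("empty sample")
  # log HM = log n - logsumexp(-logL)
  m <- max(-ll)
  log(length(ll)) - (m + log(sum(exp(-ll - m))))
}

# effective sample size from the autocorrelation function, truncated at
# the first non-positive estimate
ess <- function(x) {
  n <- length(x)
  if (n < 4L || var(x) == 0) return(n)
  a <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in a) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Chain diagnostics
#'
#' Effective sample sizes per rate and for the log-likelihood, plus a
#' Geweke-style stationarity flag comparing the first 10% of the trace
#' with the last 50% (|z| < 2 passes).  Flags only, never hard failures.
#'
#' @param x an `rjmcmc` fit (needs at least 10 samples).
#' @return a list with `ess` (named vector), `ess_logL`, `geweke_z`,
#'   `stationary`, and `note`.
#' @export
chain_diagnostics <- function(x) {
  ll <- if (inherits(x, "rjmcmc")) x$logL else as.numeric(x)
  if (length(ll) < 10L) stop("need at least 10 samples for diagnostics")
  note <- character(0)
  if (var(ll) == 0) {
    z <- 0
    note <- "zero-variance trace; ESS reported as sample size"
  } else {
    n <- length(ll)
    a <- ll[seq_len(max(2L, floor(0.1 * n)))]
    b <- ll[seq.int(ceiling(0.5 * n), n)]
    sea2 <- var(a) / ess(a)
    seb2 <- var(b) / ess(b)
    z <- (mean(a) - mean(b)) / sqrt(sea2 + seb2 + 1e-300)
  }
  rate_ess <- if (inherits(x, "rjmcmc")) apply(x$rates, 2, ess) else NULL
  list(ess = rate_ess, ess_logL = ess(ll), geweke_z = z,
       stationary = is.finite(z) && abs(z) < 2, note = note)
}

#' Write an MCMC trace as TSV
#'
#' Columns: sample index, logL, tree index, number of classes, one value
#' column and one zero-bin flag column per rate.  Readable by generic
#' trace viewers.
#'
#' @param x an `rjmcmc` fit.
#' @param path output path.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "rjmcmc"))
  df <- data.frame(sample = seq_len(nrow(x$rates)), logL = x$logL,
                   tree_index = x$tree_index, n_classes = x$n_classes,
                   x$rates,
                   setNames(as.data.frame(x$zero),
                            paste0("zero_", colnames(x$zero))),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
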
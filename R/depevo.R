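# Tests of dependent evolution for character pairs: dependent (8-rate)
# vs independent (4-rate) 4-state models compared by the log Bayes
# factor of harmonic-mean marginal likelihoods across >= 3 runs.

#' Fit one pair model with replicate chains
#'
#' Runs `n_runs` independent rj-MCMC chains (distinct seeds derived from
#' `settings$seed`) of the dependent or independent model on one
#' character pair.  At least three runs are required because the
#' harmonic-mean estimator is unstable; both models of a pair should be
#' fitted with the same trees, prior and settings so the Bayes factor is
#' interpretable.
#'
#' @param model `"dependent"` or `"independent"`.
#' @param trees a tree sample.
#' @param m a character matrix.
#' @param pair length-2 vector of character ids or indices.
#' @param prior a [rate_prior()].
#' @param settings a [chain_settings()].
#' @param n_runs number of replicate chains (`>= 3`).
#' @return list of `rjmcmc` fits, class `pair_fit`, with attributes
#'   `model` and `pair`.
#' @export
fit_pair <- function(model = c("dependent", "independent"), trees, m, pair,
                     prior = rate_prior(), settings = chain_settings(),
                     n_runs = 3) {
  model <- match.arg(model)
  if (n_runs < 3)
    stop("at least 3 replicate runs are required (harmonic-mean stability)")
  if (length(pair) != 2L) stop("pair must have exactly two characters")
  m <- as_character_matrix(m)
  tips <- pair_tipdata(m, pair[1], pair[2])
  base <- if (is.null(settings$seed)) NULL else settings$seed
  fits <- lapply(seq_len(n_runs), function(r) {
    st <- settings
    if (!is.null(base)) st$seed <- (base + 7919L * r) %% .Machine$integer.max
    run_rjmcmc(model, trees, tips, prior, st)
  })
  structure(fits, class = "pair_fit", model = model,
            pair = if (is.character(pair)) pair else colnames(m)[pair])
}

#' Log Bayes factor between dependent and independent fits
#'
#' `2 * (lnHM_dep - lnHM_indep)` where `lnHM` is the median across runs
#' of the per-run harmonic-mean log marginal likelihoods.  Values above 2
#' are read as evidence for dependent evolution.
#'
#' @param dep,indep `pair_fit` lists (or plain lists of `rjmcmc` fits)
#'   for the dependent and independent models.
#' @return the log-BF, with attributes `hm_dep`, `hm_indep` (per-run
#'   values) and `spread` (max within-model spread across runs).
#' @export
log_bayes_factor <- function(dep, indep) {
  if (length(dep) == 0L || length(indep) == 0L) stop("empty fit list")
  hm_dep <- vapply(dep, harmonic_mean_logL, numeric(1))
  hm_indep <- vapply(indep, harmonic_mean_logL, numeric(1))
  bf <- 2 * (median(hm_dep) - median(hm_indep))
  spread <- max(diff(range(hm_dep)), diff(range(hm_indep)))
  if (spread > 2)
    warning("harmonic means vary by more than 2 log units across runs; ",
            "consider longer chains")
  structure(bf, hm_dep = hm_dep, hm_indep = hm_indep, spread = spread)
}

#' Dependence decision rule
#'
#' Strictly greater than the threshold (default 2 log units): a log-BF of
#' exactly 2 does not count as dependent.
#'
#' @param log_bf numeric log Bayes factor(s).
#' @param threshold decision threshold (default 2).
#' @export
is_dependent <- function(log_bf, threshold = 2) {
  stopifnot(all(is.finite(log_bf)))
  as.vector(log_bf > threshold)
}

#' Test one character pair for dependent evolution
#'
#' Fits both models with [fit_pair()] and assembles a `dependency_result`.
#'
#' @inheritParams fit_pair
#' @param threshold log-BF decision threshold (default 2).
#' @return an object of class `dependency_result` with per-run harmonic
#'   means, the log-BF, the favoured model, and a stability flag.
#' @export
pair_dependence <- function(trees, m, pair, prior = rate_prior(),
                            settings = chain_settings(), n_runs = 3,
                            threshold = 2) {
  dep <- fit_pair("dependent", trees, m, pair, prior, settings, n_runs)
  indep <- fit_pair("independent", trees, m, pair, prior, settings, n_runs)
  bf <- log_bayes_factor(dep, indep)
  structure(list(pair = attr(dep, "pair"),
                 hm_dep = attr(bf, "hm_dep"),
                 hm_indep = attr(bf, "hm_indep"),
                 log_bf = as.numeric(bf),
                 spread = attr(bf, "spread"),
                 dependent = is_dependent(as.numeric(bf), threshold),
                 favored = if (is_dependent(as.numeric(bf), threshold))
                   "dependent" else "independent",
                 n_runs = n_runs,
                 dep_fits = dep, indep_fits = indep),
            class = "dependency_result")
}

#' @export
print.dependency_result <- function(x, ...) {
  cat("Dependent-evolution test: ", paste(x$pair, collapse = " ~ "), "\n",
      sep = "")
  cat("  lnHM dependent:   ", paste(round(x$hm_dep, 3), collapse = ", "),
      "\n  lnHM independent: ", paste(round(x$hm_indep, 3), collapse = ", "),
      "\n", sep = "")
  cat("  log-BF = ", round(x$log_bf, 3), "  ->  ", x$favored,
      " model favoured (spread ", round(x$spread, 3), ")\n", sep = "")
  invisible(x)
}

#' Scan all character pairs for dependent evolution
#'
#' Runs [pair_dependence()] for every unordered pair of characters (55
#' pairs for 11 characters).  A failed pair is recorded with `NA` values
#' rather than aborting the scan; per-pair JSON caching makes the scan
#' resumable.
#'
#' @inheritParams fit_pair
#' @param threshold log-BF decision threshold.
#' @param cache_dir optional directory for per-pair result caching.
#' @param keep_fits keep the full fits as an attribute (`"fits"`), needed
#'   for downstream Z-score classification.
#' @return a data.frame with one row per pair: `char_i`, `char_j`,
#'   per-run harmonic means (`hm_dep_*`, `hm_indep_*`), `log_bf`,
#'   `dependent`, `spread`, `error`.
#' @export
all_pairs_scan <- function(trees, m, prior = rate_prior(),
                           settings = chain_settings(), n_runs = 3,
                           threshold = 2, cache_dir = NULL,
                           keep_fits = FALSE) {
  m <- as_character_matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 characters")
  prs <- combn(colnames(m), 2)
  rows <- vector("list", ncol(prs))
  fits <- if (keep_fits) vector("list", ncol(prs)) else NULL
  base <- settings$seed
  for (p in seq_len(ncol(prs))) {
    ci <- prs[1, p]; cj <- prs[2, p]
    key <- paste0(ci, "_", cj)
    cache <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".json"))
    if (!is.null(cache) && file.exists(cache)) {
      rows[[p]] <- as.data.frame(jsonlite::fromJSON(cache),
                                 stringsAsFactors = FALSE)
      next
    }
    st <- settings
    if (!is.null(base)) st$seed <- (base + 104729L * p) %% .Machine$integer.max
    res <- tryCatch(pair_dependence(trees, m, c(ci, cj), prior, st,
                                    n_runs, threshold),
                    error = function(e) e)
    if (inherits(res, "error")) {
      row <- data.frame(char_i = ci, char_j = cj,
                        log_bf = NA_real_, dependent = NA, spread = NA_real_,
                        error = conditionMessage(res),
                        stringsAsFactors = FALSE)
    } else {
      row <- data.frame(char_i = ci, char_j = cj,
                        rbind(setNames(res$hm_dep,
                                       paste0("hm_dep_", seq_len(n_runs)))),
                        rbind(setNames(res$hm_indep,
                                       paste0("hm_indep_", seq_len(n_runs)))),
                        log_bf = res$log_bf, dependent = res$dependent,
                        spread = res$spread, error = "",
                        stringsAsFactors = FALSE)
      if (keep_fits) fits[[p]] <- res
    }
    rows[[p]] <- row
    if (!is.null(cache)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(row, cache, auto_unbox = TRUE, digits = NA)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # align columns across cached/failed/fresh rows
    need <- c("char_i", "char_j",
              paste0("hm_dep_", seq_len(n_runs)),
              paste0("hm_indep_", seq_len(n_runs)),
              "log_bf", "dependent", "spread", "error")
    for (cn in setdiff(need, names(r))) r[[cn]] <- NA
    r[need]
  }))
  rownames(out) <- NULL
  if (keep_fits) attr(out, "fits") <- fits
  out
}
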
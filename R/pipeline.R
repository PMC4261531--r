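# Configuration-driven orchestration: reconstruction -> pair scan ->
# contingency network, with a machine-readable manifest and per-pair
# caching so a run is resumable.

#' Run configuration
#'
#' All thresholds are surfaced with the standard protocol values as
#' defaults: log-BF decision threshold 2; Z-score classification
#' threshold 70 with display tiers at 90/95; posterior-probability
#' labels 0.95 (strong) and 0.85 (moderate).  Per-stage priors default
#' to the protocol: uniform for ancestral reconstruction and dependence
#' testing, gamma hyperprior for contingency classification.
#'
#' @param trees,matrix input paths (Newick/NEXUS trees; TSV/NEXUS
#'   matrix), or `NULL` to simulate a fixture study.
#' @param fixture_preset preset for [make_fixture_study()] when no input
#'   paths are given.
#' @param n_taxa,n_char,n_trees fixture dimensions.
#' @param nodes named list of taxon sets for ancestral reconstruction
#'   (`NULL` reconstructs the root clade only).
#' @param profile `"desk"` or `"paper"` chain-settings profile.
#' @param iterations,burnin,thin optional overrides of the profile.
#' @param prior_ancestral,prior_dependence,prior_classification prior
#'   kinds per stage.
#' @param log_bf_threshold,z_threshold,z_moderate,z_strong,pp_strong,pp_moderate
#'   decision thresholds.
#' @param n_runs replicate chains per model fit (`>= 3`).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(trees = NULL, matrix = NULL,
                       fixture_preset = "planted-order",
                       n_taxa = 47, n_char = 11, n_trees = 50,
                       nodes = NULL, profile = "desk",
                       iterations = NULL, burnin = NULL, thin = NULL,
                       prior_ancestral = "uniform",
                       prior_dependence = "uniform",
                       prior_classification = "gamma",
                       log_bf_threshold = 2, z_threshold = 70,
                       z_moderate = 90, z_strong = 95,
                       pp_strong = 0.95, pp_moderate = 0.85,
                       n_runs = 3, seed = 1) {
  stopifnot(z_threshold > 0, z_threshold < 100, pp_strong <= 1,
            pp_moderate <= pp_strong, n_runs >= 3)
  cfg <- list(trees = trees, matrix = matrix,
              fixture_preset = fixture_preset, n_taxa = n_taxa,
              n_char = n_char, n_trees = n_trees, nodes = nodes,
              profile = profile, iterations = iterations, burnin = burnin,
              thin = thin, prior_ancestral = prior_ancestral,
              prior_dependence = prior_dependence,
              prior_classification = prior_classification,
              log_bf_threshold = log_bf_threshold,
              z_threshold = z_threshold, z_moderate = z_moderate,
              z_strong = z_strong, pp_strong = pp_strong,
              pp_moderate = pp_moderate, n_runs = n_runs,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()] (`nodes` as a
#'   mapping from node name to taxon list).
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

cfg_settings <- function(cfg, stage, seed) {
  st <- chain_settings(profile = cfg$profile, stage = stage, seed = seed)
  if (!is.null(cfg$iterations)) st$iterations <- as.double(cfg$iterations)
  if (!is.null(cfg$burnin)) st$burnin <- as.double(cfg$burnin)
  if (!is.null(cfg$thin)) st$thin <- as.integer(cfg$thin)
  st
}

#' Run the full analysis
#'
#' Stages: (1) load or simulate inputs; (2) ancestral-state report at
#' the configured nodes; (3) all-pairs dependence scan; (4) Z-scores and
#' mutual/temporal classification of the dependent pairs (refitted under
#' the classification prior when it differs from the scan prior);
#' (5) contingency network exported as DOT, TSV and JSON; plus a JSON
#' manifest of seeds, settings and stage status.  Stage failures are
#' recorded in the manifest rather than aborting the run.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param resume skip stages whose outputs already exist.
#' @return invisibly, the manifest list.
#' @export
run_full_analysis <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   seeds = list(inputs = config$seed + 101L,
                                ancestral = config$seed + 202L,
                                scan = config$seed + 303L,
                                classify = config$seed + 404L),
                   stages = list(), files = character(0),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
    cat(msg, "\n", sep = "")
    cat(msg, "\n", sep = "", file = file.path(out_dir, "run.log"),
        append = TRUE)
  }
  path_of <- function(f) file.path(out_dir, f)
  stage <- function(name, files, fn) {
    if (resume && all(file.exists(path_of(files)))) {
      log_line("stage ", name, ": outputs exist, skipped (resume)")
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    log_line("stage ", name, ": start")
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      log_line("stage ", name, ": FAILED: ", conditionMessage(res))
      manifest$stages[[name]] <<- paste0("failed: ", conditionMessage(res))
      return(invisible(NULL))
    }
    manifest$stages[[name]] <<- "ok"
    manifest$files <<- c(manifest$files, files)
    log_line("stage ", name, ": done")
    res
  }

  # -- inputs ---------------------------------------------------------------
  truth <- NULL
  if (is.null(config$trees) || is.null(config$matrix)) {
    fx <- make_fixture_study(config$fixture_preset, config$n_taxa,
                             config$n_char, config$n_trees,
                             seed = manifest$seeds$inputs)
    trees <- fx$trees; m <- fx$matrix; truth <- fx$truth
    stage("inputs", c("trees.nwk", "matrix.tsv"), function() {
      write_tree_sample(trees, path_of("trees.nwk"))
      write_character_matrix(m, path_of("matrix.tsv"))
    })
  } else {
    trees <- read_tree_sample(config$trees)
    m <- read_character_matrix(config$matrix)
    manifest$stages$inputs <- "loaded"
  }

  # -- ancestral reconstruction --------------------------------------------
  nodes <- config$nodes
  if (is.null(nodes)) nodes <- list(root = trees[[1]]$tip.label)
  st_anc <- cfg_settings(config, "ancestral", manifest$seeds$ancestral)
  stage("ancestral", "ancestral.tsv", function() {
    rep <- node_series_report(trees, m, nodes,
                              prior = rate_prior(config$prior_ancestral),
                              settings = st_anc,
                              strong = config$pp_strong,
                              moderate = config$pp_moderate)
    write.table(rep, path_of("ancestral.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  # -- dependence scan ------------------------------------------------------
  st_dep <- cfg_settings(config, "dependence", manifest$seeds$scan)
  scan <- stage("depscan", "pair_scan.tsv", function() {
    sc <- all_pairs_scan(trees, m, prior = rate_prior(config$prior_dependence),
                         settings = st_dep, n_runs = config$n_runs,
                         threshold = config$log_bf_threshold,
                         cache_dir = path_of("cache"), keep_fits = TRUE)
    write.table(sc[, setdiff(names(sc), "fits")], path_of("pair_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })

  # -- contingency classification & network --------------------------------
  if (!is.null(scan)) {
    st_cls <- cfg_settings(config, "dependence", manifest$seeds$classify)
    stage("contingency",
          c("z_scores.tsv", "network.dot", "network.tsv", "network.json"),
          function() {
      dep_idx <- which(!is.na(scan$dependent) & scan$dependent)
      cls <- list(); zrows <- list()
      for (i in dep_idx) {
        pr <- c(scan$char_i[i], scan$char_j[i])
        if (identical(config$prior_classification, config$prior_dependence) &&
            !is.null(attr(scan, "fits")[[i]])) {
          fits <- attr(scan, "fits")[[i]]$dep_fits
        } else {
          st_i <- st_cls
          st_i$seed <- (st_cls$seed + 13L * i) %% .Machine$integer.max
          fits <- fit_pair("dependent", trees, m, pr,
                           prior = rate_prior(config$prior_classification),
                           settings = st_i, n_runs = config$n_runs)
        }
        z <- z_scores(fits)
        cls[[length(cls) + 1L]] <-
          classify_pair(z, chars = pr, threshold = config$z_threshold)
        zrows[[length(zrows) + 1L]] <-
          data.frame(char_i = pr[1], char_j = pr[2], rbind(z),
                     stringsAsFactors = FALSE)
      }
      ztab <- if (length(zrows) > 0L) do.call(rbind, zrows) else
        data.frame(char_i = character(0), char_j = character(0))
      write.table(ztab, path_of("z_scores.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      net <- build_network(cls, config$z_moderate, config$z_strong)
      export_network(net, path_of("network.dot"), "dot")
      export_network(net, path_of("network.tsv"), "tsv")
      export_network(net, path_of("network.json"), "json")
      net
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, path_of("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
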
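# Z-scores (zero-bin occupancy of the dependent model's transition
# rates), classification of dependent pairs into mutual vs temporal
# (contingent) dependence, and assembly of the tiered contingency
# network of gain events.

#' Z-scores of a dependent-model posterior
#'
#' For each of the eight transition rates, the percentage of rj-MCMC
#' posterior samples in which the rate sits in the structural-zero bin.
#' A high Z-score means that transition is evolutionarily restricted.
#'
#' @param fit an `rjmcmc` fit of the dependent model, or a `pair_fit`
#'   list of such fits (samples pooled across runs).
#' @return named numeric vector (length 8) of percentages in `[0, 100]`.
#' @export
z_scores <- function(fit) {
  if (inherits(fit, "pair_fit") || (is.list(fit) && !inherits(fit, "rjmcmc"))) {
    zs <- lapply(fit, z_scores)
    return(colMeans(do.call(rbind, zs)))
  }
  stopifnot(inherits(fit, "rjmcmc"))
  if (fit$model != "dependent")
    stop("Z-scores are defined on the 8-rate dependent model, not '",
         fit$model, "'")
  colMeans(fit$zero) * 100
}

#' Classify a dependent pair as temporal, mutual, or unclassified
#'
#' Compares the critical rate pairs (`q12` vs `q34`; `q13` vs `q24`).
#' A gain rate restricted (Z above `threshold`) on the empty background
#' but free on the derived background means that gain is contingent on
#' the other character: `q12` high with `q34` low puts character 1
#' before character 2; `q13` high with `q24` low puts character 2 before
#' character 1.  Both asymmetries at once mean mutual dependence; neither
#' means the pair stays dependent-unclassified.  Loss-rate restrictions
#' are reported but never generate edges (the network's events are
#' gains).
#'
#' @param z named Z-score vector from [z_scores()].
#' @param chars length-2 character ids naming the pair (first = the
#'   background character of `q12`).
#' @param threshold Z-score threshold in percent (default 70).
#' @return a list with `kind` (`"temporal"`, `"mutual"`,
#'   `"dependent-unclassified"`), `from`/`to` (for temporal), `z`
#'   (restricted-rate Z-score backing the edge) and the input scores.
#' @export
classify_pair <- function(z, chars = c("char1", "char2"), threshold = 70) {
  need <- c("q12", "q34", "q13", "q24")
  if (!all(need %in% names(z))) stop("need Z-scores for ", paste(need,
                                                                 collapse = ", "))
  gain2_blocked <- z[["q12"]] > threshold && z[["q34"]] <= threshold
  gain1_blocked <- z[["q13"]] > threshold && z[["q24"]] <= threshold
  if (gain2_blocked && gain1_blocked) {
    list(kind = "mutual", from = chars[1], to = chars[2],
         z = min(z[["q12"]], z[["q13"]]), scores = z)
  } else if (gain2_blocked) {
    list(kind = "temporal", from = chars[1], to = chars[2],
         z = z[["q12"]], scores = z)
  } else if (gain1_blocked) {
    list(kind = "temporal", from = chars[2], to = chars[1],
         z = z[["q13"]], scores = z)
  } else {
    list(kind = "dependent-unclassified", from = NA_character_,
         to = NA_character_, z = NA_real_, scores = z)
  }
}

#' Z-score tier of an edge
#'
#' `"strong"` at Z >= 95, `"moderate"` at Z >= 90, `"weak"` otherwise
#' (edges only exist above the classification threshold, normally 70).
#'
#' @param z Z-score percentage.
#' @param moderate,strong tier boundaries (inclusive).
#' @export
z_tier <- function(z, moderate = 90, strong = 95) {
  ifelse(z >= strong, "strong", ifelse(z >= moderate, "moderate", "weak"))
}

#' Build the contingency network
#'
#' Nodes are gain events (`"<char>:0->1"`), directed edges temporal
#' (contingent) dependencies pointing from the earlier gain to the gain
#' it unlocks, undirected (dotted) edges mutual dependencies.  Layers
#' for display are longest-path depths over the temporal edges (earlier
#' changes at the top).  Cycles are not broken silently: any strongly
#' connected component of size > 1 is reported in `$cycles`.
#'
#' @param classifications list of [classify_pair()] results (entries
#'   with kind `"dependent-unclassified"` are dropped).
#' @param moderate,strong tier boundaries passed to [z_tier()].
#' @return an object of class `contingency_network` with `nodes`
#'   (data.frame `event`, `character`, `layer`), `edges` (data.frame
#'   `from`, `to`, `kind`, `z`, `tier`) and `cycles`.
#' @export
build_network <- function(classifications, moderate = 90, strong = 95) {
  keep <- Filter(function(cl) cl$kind %in% c("temporal", "mutual"),
                 classifications)
  ev <- function(ch) paste0(ch, ":0->1")
  if (length(keep) == 0L) {
    return(structure(list(nodes = data.frame(event = character(0),
                                             character = character(0),
                                             layer = integer(0)),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             kind = character(0),
                                             z = numeric(0),
                                             tier = character(0)),
                          cycles = list()),
                     class = "contingency_network"))
  }
  edges <- do.call(rbind, lapply(keep, function(cl) {
    data.frame(from = ev(cl$from), to = ev(cl$to), kind = cl$kind,
               z = cl$z, tier = z_tier(cl$z, moderate, strong),
               stringsAsFactors = FALSE)
  }))
  if (any(edges$from == edges$to)) stop("self-edge in classifications")
  chars <- unique(c(vapply(keep, `[[`, "", "from"),
                    vapply(keep, `[[`, "", "to")))
  nodes <- data.frame(event = ev(chars), character = chars,
                      layer = 0L, stringsAsFactors = FALSE)

  tedge <- edges[edges$kind == "temporal", , drop = FALSE]
  cycles <- list()
  if (nrow(tedge) > 0L) {
    g <- igraph::graph_from_data_frame(tedge[, c("from", "to")],
                                       directed = TRUE,
                                       vertices = nodes$event)
    comp <- igraph::components(g, mode = "strong")
    big <- which(comp$csize > 1)
    for (b in big)
      cycles[[length(cycles) + 1L]] <-
        names(comp$membership)[comp$membership == b]
    if (length(cycles) == 0L) {
      # longest-path layering over the DAG of temporal edges
      ord <- names(igraph::topo_sort(g))
      depth <- setNames(rep(0L, length(ord)), ord)
      for (v in ord) {
        preds <- tedge$from[tedge$to == v]
        if (length(preds) > 0L)
          depth[v] <- max(depth[preds]) + 1L
      }
      nodes$layer <- as.integer(depth[nodes$event])
    } else {
      warning("contingency network contains a cycle; layering skipped")
    }
  }
  structure(list(nodes = nodes, edges = edges, cycles = cycles),
            class = "contingency_network")
}

#' @export
print.contingency_network <- function(x, ...) {
  cat("Contingency network: ", nrow(x$nodes), " events, ",
      sum(x$edges$kind == "temporal"), " temporal and ",
      sum(x$edges$kind == "mutual"), " mutual edges\n", sep = "")
  if (nrow(x$edges) > 0L) {
    arr <- ifelse(x$edges$kind == "temporal", " -> ", " -- ")
    cat(paste0("  ", x$edges$from, arr, x$edges$to,
               "  [Z=", round(x$edges$z, 1), ", ", x$edges$tier, "]",
               collapse = "\n"), "\n")
  }
  if (length(x$cycles) > 0L)
    cat("warning: ", length(x$cycles), " strongly connected component(s) ",
        "of size > 1\n", sep = "")
  invisible(x)
}

#' Export a contingency network
#'
#' DOT: solid arrows for temporal edges with pen width by tier (weak 1,
#' moderate 2, strong 3), dotted undirected lines (`dir=none`) for
#' mutual edges, nodes ranked by layer.  TSV: the edge list.  JSON: the
#' full network, re-readable by [read_network_json()].
#'
#' @param net a `contingency_network`.
#' @param path output path.
#' @param format `"dot"`, `"tsv"` or `"json"`.
#' @export
export_network <- function(net, path, format = c("dot", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    q <- function(s) paste0('"', s, '"')
    lines <- c("digraph contingency {", "  rankdir=TB;")
    for (ly in sort(unique(net$nodes$layer)))
      lines <- c(lines, paste0("  { rank=same; ",
                               paste(q(net$nodes$event[net$nodes$layer == ly]),
                                     collapse = "; "), "; }"))
    if (nrow(net$edges) > 0L) {
      pw <- c(weak = 1, moderate = 2, strong = 3)[net$edges$tier]
      attr_str <- ifelse(net$edges$kind == "mutual",
                         "dir=none, style=dotted",
                         paste0("penwidth=", pw))
      lines <- c(lines, paste0("  ", q(net$edges$from), " -> ",
                               q(net$edges$to), " [", attr_str, "];"))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a JSON network export
#' @param path path written by [export_network()] with `format = "json"`.
#' @return a `contingency_network`.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(x$edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L)
    nodes <- data.frame(event = character(0), character = character(0),
                        layer = integer(0))
  if (nrow(edges) == 0L)
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), z = numeric(0),
                        tier = character(0))
  nodes$layer <- as.integer(nodes$layer)
  structure(list(nodes = nodes, edges = edges, cycles = list()),
            class = "contingency_network")
}

#' Z-scores and classifications for the dependent pairs of a scan
#'
#' Convenience wrapper: takes an [all_pairs_scan()] result run with
#' `keep_fits = TRUE`, computes pooled Z-scores for every pair flagged
#' dependent, and classifies them.
#'
#' @param scan a scan data.frame with a `"fits"` attribute.
#' @param threshold Z-score threshold (default 70).
#' @return list with `z_table` (data.frame of Z-scores per dependent
#'   pair) and `classifications` (input for [build_network()]).
#' @export
classify_scan <- function(scan, threshold = 70) {
  fits <- attr(scan, "fits")
  if (is.null(fits)) stop("scan must be run with keep_fits = TRUE")
  idx <- which(!is.na(scan$dependent) & scan$dependent)
  cls <- list()
  zrows <- list()
  for (i in idx) {
    res <- fits[[i]]
    if (is.null(res)) next
    z <- z_scores(res$dep_fits)
    cls[[length(cls) + 1L]] <- classify_pair(
      z, chars = c(scan$char_i[i], scan$char_j[i]), threshold = threshold)
    zrows[[length(zrows) + 1L]] <-
      data.frame(char_i = scan$char_i[i], char_j = scan$char_j[i],
                 rbind(z), stringsAsFactors = FALSE)
  }
  z_table <- if (length(zrows) > 0L) do.call(rbind, zrows) else
    data.frame(char_i = character(0), char_j = character(0))
  rownames(z_table) <- NULL
  list(z_table = z_table, classifications = cls)
}
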
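# Synthetic data with the statistical structure the analysis assumes:
# pure-birth trees, jittered tree samples emulating posterior spread, and
# binary characters evolved under independent, dependent, or contingent
# (background-state-gated) CTMCs, with full event logs for auditing.

#' Simulate a pure-birth (Yule) tree
#'
#' Starts from two lineages at the root, draws exponential waiting times
#' with rate `k * birth_rate` while `k` lineages are extant, splits a
#' uniformly chosen lineage at each event, and adds a final
#' `Exp(n * birth_rate)` stretch after the n-th lineage appears, so the
#' expected root-to-tip depth is `sum_{k=2..n} 1/(k * birth_rate)`.  The
#' tree is ultrametric with tips labelled `t1..tn`.
#'
#' @param n_taxa number of tips (`>= 2`).
#' @param birth_rate speciation rate (`> 0`).
#' @param seed optional integer seed.
#' @return an ultrametric `phylo`.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 2 || birth_rate <= 0) stop("need n_taxa >= 2, birth_rate > 0")
  if (!is.null(seed)) set.seed(seed)
  birth <- c(0, 0)
  end <- c(NA_real_, NA_real_)
  kids <- list(NULL, NULL)
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n_taxa) {
    k <- length(active)
    t <- t + rexp(1, k * birth_rate)
    i <- active[sample.int(k, 1)]
    c1 <- length(birth) + 1L
    c2 <- length(birth) + 2L
    birth <- c(birth, t, t)
    end <- c(end, NA_real_, NA_real_)
    kids[[i]] <- c(c1, c2)
    kids <- c(kids, list(NULL, NULL))
    end[i] <- t
    active <- c(setdiff(active, i), c1, c2)
  }
  t_final <- t + rexp(1, n_taxa * birth_rate)
  end[active] <- t_final

  tip_counter <- 0L
  nw <- function(i) {
    len <- end[i] - birth[i]
    if (is.null(kids[[i]])) {
      tip_counter <<- tip_counter + 1L
      paste0("t", tip_counter, ":", format(len, digits = 15))
    } else {
      paste0("(", nw(kids[[i]][1]), ",", nw(kids[[i]][2]), "):",
             format(len, digits = 15))
    }
  }
  txt <- paste0("(", nw(1L), ",", nw(2L), ");")
  parse_newick(txt)
}

#' Jittered copies of a tree, emulating a posterior tree sample
#'
#' Each copy multiplies every branch length by an independent lognormal
#' factor with unit mean (`meanlog = -jitter_sd^2 / 2`), so the expected
#' branch lengths match the source tree.  Optionally a fraction of trees
#' additionally receives one random NNI rearrangement (requires the
#' phangorn package).
#'
#' @param tree a `phylo`.
#' @param m number of copies.
#' @param jitter_sd lognormal sdlog of the branch-length jitter (`>= 0`).
#' @param nni_prob probability that a copy receives one NNI move.
#' @param seed optional integer seed.
#' @return a `multiPhylo` of size `m` over the same taxon set.
#' @export
perturb_tree_sample <- function(tree, m, jitter_sd = 0.1, nni_prob = 0,
                                seed = NULL) {
  stopifnot(jitter_sd >= 0, m >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    tr <- tree
    if (nni_prob > 0 && runif(1) < nni_prob) {
      if (!requireNamespace("phangorn", quietly = TRUE))
        stop("NNI perturbation needs the phangorn package")
      tr <- phangorn::rNNI(tr, 1)
      if (!ape::is.rooted(tr)) tr <- tree  # keep rooted topologies only
    }
    if (jitter_sd > 0) {
      fac <- rlnorm(length(tr$edge.length), -jitter_sd^2 / 2, jitter_sd)
      tr$edge.length <- tr$edge.length * fac
    }
    out[[i]] <- tr
  }
  as_tree_sample(out)
}

# ---------------------------------------------------------------------------
# Character evolution by event simulation
# ---------------------------------------------------------------------------

# Walk the tree from the root, drawing exponential waiting times for the
# next flip of any character.  flip_rates(state) returns the per-character
# toggle rate given the current 0/1 state vector; this covers independent
# characters, the 8-rate pair model (double changes impossible by
# construction) and contingency chains (rates gated on the background).
sim_flip_process <- function(tree, root_state, flip_rates) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tr)
  K <- length(root_state)
  states <- matrix(NA_integer_, ntip + tr$Nnode, K)
  states[ntip + 1L, ] <- root_state
  events <- list()
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
    s <- states[par, ]
    remaining <- tr$edge.length[e]
    repeat {
      r <- flip_rates(s)
      tot <- sum(r)
      if (tot <= 0) break
      wait <- rexp(1, tot)
      if (wait >= remaining) break
      remaining <- remaining - wait
      c_idx <- sample.int(K, 1, prob = r)
      events[[length(events) + 1L]] <- data.frame(
        edge = e, child = chi, char = c_idx, from = s[c_idx],
        to = 1L - s[c_idx],
        time = tr$edge.length[e] - remaining)
      s[c_idx] <- 1L - s[c_idx]
    }
    states[chi, ] <- s
  }
  tipstates <- states[seq_len(ntip), , drop = FALSE]
  rownames(tipstates) <- tr$tip.label
  ev <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(edge = integer(0), child = integer(0), char = integer(0),
               from = integer(0), to = integer(0), time = numeric(0))
  list(tips = tipstates, events = ev)
}

#' Simulate a single binary character on a tree
#'
#' @param tree a rooted `phylo`.
#' @param Q 2x2 generator (e.g. [build_binary_Q()]).
#' @param root_state `0` or `1`.
#' @param seed optional integer seed.
#' @return named character vector of tip states (`"0"`/`"1"`) with the
#'   event log as attribute `"events"`.
#' @export
simulate_character <- function(tree, Q, root_state = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gain <- Q[1, 2]; loss <- Q[2, 1]
  sim <- sim_flip_process(tree, as.integer(root_state),
                          function(s) if (s[1] == 0L) gain else loss)
  out <- setNames(as.character(sim$tips[, 1]), rownames(sim$tips))
  attr(out, "events") <- sim$events
  out
}

#' Simulate a character pair under a 4-state generator
#'
#' The generator must have the double-change transitions zero (as built
#' by [build_dependent_Q()] / [build_independent_Q()]); the pair then
#' evolves as two coupled flip processes whose rates depend on the
#' partner's state.
#'
#' @param tree a rooted `phylo`.
#' @param Q 4x4 generator over states `(0,0),(0,1),(1,0),(1,1)`.
#' @param root_state one of `"00"`, `"01"`, `"10"`, `"11"`.
#' @param seed optional integer seed.
#' @return taxa x 2 character matrix of `"0"`/`"1"` with event log as
#'   attribute `"events"` (char 1 = first character).
#' @export
simulate_pair <- function(tree, Q, root_state = "00", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (Q[1, 4] != 0 || Q[4, 1] != 0 || Q[2, 3] != 0 || Q[3, 2] != 0)
    stop("double-change transitions must be zero")
  rs <- as.integer(strsplit(root_state, "")[[1]])
  flip <- function(s) {
    st <- s[1] * 2L + s[2] + 1L  # 1..4 over 00,01,10,11
    c(if (s[1] == 0L) Q[st, st + 2L] else Q[st, st - 2L],   # flip char 1
      if (s[2] == 0L) Q[st, st + 1L] else Q[st, st - 1L])   # flip char 2
  }
  sim <- sim_flip_process(tree, rs, flip)
  out <- matrix(as.character(sim$tips), nrow(sim$tips), 2,
                dimnames = list(rownames(sim$tips), c("char1", "char2")))
  attr(out, "events") <- sim$events
  out
}

#' Simulate a contingent chain of gains
#'
#' Characters gain state 1 in a planted temporal order: the gain rate of
#' each character after the first is structurally zero until its
#' predecessor in `chain` is in state 1 on that lineage (exactly the
#' background-gated rate structure the dependent model assumes).
#'
#' @param tree a rooted `phylo`.
#' @param n_char number of chained characters.
#' @param gain gain rate once unlocked (default 0.5: roughly 1-2
#'   unlocked gains per root-to-tip path on a unit-rate pure-birth tree,
#'   so chained gains stay late and unsaturated).
#' @param loss loss rate.
#' @param seed optional integer seed.
#' @return taxa x n_char matrix of `"0"`/`"1"` with event log attribute.
#' @export
simulate_contingent_chain <- function(tree, n_char, gain = 0.5, loss = 0.1,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  flip <- function(s) {
    vapply(seq_along(s), function(c) {
      if (s[c] == 1L) loss
      else if (c == 1L || s[c - 1L] == 1L) gain
      else 0
    }, numeric(1))
  }
  sim <- sim_flip_process(tree, rep(0L, n_char), flip)
  out <- matrix(as.character(sim$tips), nrow(sim$tips), n_char,
                dimnames = list(rownames(sim$tips),
                                paste0("chain", seq_len(n_char))))
  attr(out, "events") <- sim$events
  out
}

# ---------------------------------------------------------------------------
# Fixture studies
# ---------------------------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Emulates the shape of the leaf-mimicry data set: `n_taxa` (default 47)
#' taxa, `n_char` (default 11) binary characters, and a jittered
#' pure-birth tree sample standing in for the posterior tree sample.
#' Characters are simulated on the base tree; the jittered sample models
#' the phylogenetic uncertainty the inference integrates over.
#'
#' Presets: `"null"` evolves every character independently (gain = loss
#' = 0.25, a handful of changes per character across the tree);
#' `"planted-pairs"` makes (Ch1, Ch2) and (Ch3, Ch4) dependent pairs
#' with a structural zero (`q12 = 0`: Ch2 can only be gained on the
#' Ch1 = 1 background, `q34 = 2`); `"planted-order"` plants the
#' contingent chain Ch1 -> Ch2 -> Ch3 (gain 0.5 once unlocked, loss
#' 0.1).  Remaining characters are always independent.
#'
#' @param preset `"null"`, `"planted-pairs"` or `"planted-order"`.
#' @param n_taxa,n_char study dimensions.
#' @param n_trees size of the jittered tree sample.
#' @param seed integer seed (mandatory: the fixture is a deterministic
#'   function of `(preset, dimensions, seed)`).
#' @param birth_rate,jitter_sd tree-generator parameters.
#' @return list with `trees` (`multiPhylo`), `matrix` (character
#'   matrix), and `truth` (generators, planted structure, event logs).
#' @export
make_fixture_study <- function(preset = c("null", "planted-pairs",
                                          "planted-order"),
                               n_taxa = 47, n_char = 11, n_trees = 50,
                               seed, birth_rate = 1, jitter_sd = 0.1) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  base_tree <- simulate_yule_tree(n_taxa, birth_rate)
  trees <- perturb_tree_sample(base_tree, n_trees, jitter_sd)
  chars <- paste0("Ch", seq_len(n_char))
  m <- matrix("0", n_taxa, n_char,
              dimnames = list(base_tree$tip.label, chars))
  truth <- list(preset = preset, seed = seed, base_tree = base_tree,
                dependent_pairs = list(), chain = character(0),
                generators = list(), events = list())
  indep_Q <- build_binary_Q(0.25, 0.25)
  done <- character(0)

  if (preset == "planted-pairs") {
    pair_Q <- build_dependent_Q(c(q12 = 0, q34 = 2, q13 = 0.5, q24 = 0.5,
                                  q21 = 0.25, q43 = 0.25,
                                  q31 = 0.25, q42 = 0.25))
    for (pr in list(c("Ch1", "Ch2"), c("Ch3", "Ch4"))) {
      if (!all(pr %in% chars)) next
      sim <- simulate_pair(base_tree, pair_Q, "00")
      m[, pr[1]] <- sim[rownames(m), 1]
      m[, pr[2]] <- sim[rownames(m), 2]
      truth$dependent_pairs[[length(truth$dependent_pairs) + 1L]] <- pr
      truth$generators[[paste(pr, collapse = "_")]] <- pair_Q
      truth$events[[paste(pr, collapse = "_")]] <- attr(sim, "events")
      done <- c(done, pr)
    }
  } else if (preset == "planted-order") {
    k <- min(3L, n_char)
    sim <- simulate_contingent_chain(base_tree, k, gain = 0.5, loss = 0.1)
    for (j in seq_len(k)) m[, chars[j]] <- sim[rownames(m), j]
    truth$chain <- chars[seq_len(k)]
    truth$generators[["chain"]] <- list(gain = 0.5, loss = 0.1)
    truth$events[["chain"]] <- attr(sim, "events")
    done <- chars[seq_len(k)]
  }

  for (ch in setdiff(chars, done)) {
    sim <- simulate_character(base_tree, indep_Q, 0)
    m[, ch] <- sim[rownames(m)]
    truth$generators[[ch]] <- indep_Q
    truth$events[[ch]] <- attr(sim, "events")
  }
  list(trees = trees, matrix = as_character_matrix(m), truth = truth)
}
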
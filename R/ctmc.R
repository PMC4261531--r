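# Continuous-time Markov models for one binary character (2 states) and a
# character pair (4 states), with pruning likelihoods and marginal node
# probabilities.  The pair state space is (0,0),(0,1),(1,0),(1,1) in
# first-character-major order; double transitions ((0,0)<->(1,1) and
# (0,1)<->(1,0)) are structurally zero.

PAIR_STATES <- c("00", "01", "10", "11")
DEP_RATES <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
INDEP_RATES <- c("gain1", "loss1", "gain2", "loss2")
BIN_RATES <- c("gain", "loss")

# off-diagonal cell of Q fed by each named rate (row, col of 4x4)
dep_rate_cells <- function() {
  cbind(row = c(1, 1, 2, 2, 3, 3, 4, 4),
        col = c(2, 3, 1, 4, 1, 4, 2, 3))
}

# rate-index map (0-based rate ids, -1 = structurally zero) for the sampler
rate_map_for <- function(model) {
  switch(model,
    dependent = {
      m <- matrix(-1L, 4, 4)
      cells <- dep_rate_cells()
      for (i in seq_len(8)) m[cells[i, 1], cells[i, 2]] <- i - 1L
      m
    },
    independent = {
      m <- matrix(-1L, 4, 4)
      # gain1 = q13 = q24, loss1 = q31 = q42, gain2 = q12 = q34, loss2 = q21 = q43
      m[1, 3] <- 0L; m[2, 4] <- 0L
      m[3, 1] <- 1L; m[4, 2] <- 1L
      m[1, 2] <- 2L; m[3, 4] <- 2L
      m[2, 1] <- 3L; m[4, 3] <- 3L
      m
    },
    binary = {
      m <- matrix(-1L, 2, 2)
      m[1, 2] <- 0L; m[2, 1] <- 1L
      m
    },
    stop("unknown model: ", model))
}

rate_names_for <- function(model) {
  switch(model, dependent = DEP_RATES, independent = INDEP_RATES,
         binary = BIN_RATES, stop("unknown model: ", model))
}

#' Generator matrix of the dependent (8-rate) pair model
#'
#' Builds the 4-state generator over joint states `(0,0),(0,1),(1,0),(1,1)`
#' from the eight named transition rates; the two double-change
#' transitions are fixed to zero, so each character changes one at a time.
#' `q12` is the gain of character 2 on background character 1 = 0, `q34`
#' the same gain on background 1; `q13`/`q24` are the gains of character 1
#' on backgrounds 0/1 of character 2; `q21,q43,q31,q42` the losses.
#'
#' @param rates named numeric vector with entries
#'   `q12,q13,q21,q24,q31,q34,q42,q43`, all `>= 0`.
#' @return a 4x4 generator matrix with zero row sums.
#' @export
build_dependent_Q <- function(rates) {
  if (is.null(names(rates))) names(rates) <- DEP_RATES
  miss <- setdiff(DEP_RATES, names(rates))
  if (length(miss) > 0L) stop("missing rates: ", paste(miss, collapse = ", "))
  if (any(rates < 0)) stop("negative rate: ",
                           paste(names(rates)[rates < 0], collapse = ", "))
  Q <- matrix(0, 4, 4, dimnames = list(PAIR_STATES, PAIR_STATES))
  cells <- dep_rate_cells()
  for (i in seq_len(8)) Q[cells[i, 1], cells[i, 2]] <- rates[[DEP_RATES[i]]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Generator matrix of the independent (4-rate) pair model
#'
#' The dependent generator with the independence constraints
#' `q12 = q34`, `q13 = q24`, `q21 = q43`, `q31 = q42` imposed, so each
#' character's gain/loss rates ignore the other character's state.
#'
#' @param rates named numeric vector with entries
#'   `gain1, loss1, gain2, loss2`, all `>= 0`.
#' @return a 4x4 generator matrix.
#' @export
build_independent_Q <- function(rates) {
  if (is.null(names(rates))) names(rates) <- INDEP_RATES
  miss <- setdiff(INDEP_RATES, names(rates))
  if (length(miss) > 0L) stop("missing rates: ", paste(miss, collapse = ", "))
  build_dependent_Q(c(
    q12 = rates[["gain2"]], q34 = rates[["gain2"]],
    q13 = rates[["gain1"]], q24 = rates[["gain1"]],
    q21 = rates[["loss2"]], q43 = rates[["loss2"]],
    q31 = rates[["loss1"]], q42 = rates[["loss1"]]))
}

#' Generator matrix of a single binary character
#' @param gain rate of the 0 to 1 transition.
#' @param loss rate of the 1 to 0 transition.
#' @return a 2x2 generator matrix.
#' @export
build_binary_Q <- function(gain, loss) {
  if (gain < 0 || loss < 0) stop("negative rate")
  matrix(c(-gain, loss, gain, -loss), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Transition probabilities exp(Qt)
#'
#' Matrix exponential via the 2-state closed form or eigendecomposition,
#' with a scaling-and-squaring fallback for defective generators.  Tiny
#' negative round-off entries are clipped to zero.
#'
#' @param Q a generator matrix (zero row sums, nonnegative off-diagonals).
#' @param t branch length, `t >= 0`.
#' @return a stochastic matrix of the same dimension.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0")
  P <- trans_mat_cpp(unname(as.matrix(Q)), t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Root state prior
#'
#' @param kind `"uniform"` (default throughout the pipeline) or
#'   `"stationary"` (the stationary distribution of `Q`; falls back to
#'   uniform when `Q` is degenerate, e.g. has absorbing blocks).
#' @param Q generator, required for `"stationary"`.
#' @param nstates number of states, required for `"uniform"` without `Q`.
#' @return a probability vector over states.
#' @export
root_prior <- function(kind = c("uniform", "stationary"), Q = NULL,
                       nstates = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    ns <- if (!is.null(Q)) nrow(Q) else nstates
    if (is.null(ns)) stop("need Q or nstates for a uniform root prior")
    return(rep(1 / ns, ns))
  }
  if (is.null(Q)) stop("stationary root prior needs Q")
  ns <- nrow(Q)
  A <- rbind(t(Q), rep(1, ns))
  pi <- tryCatch(qr.solve(A, c(rep(0, ns), 1)), error = function(e) NULL)
  if (is.null(pi) || any(!is.finite(pi)) || any(pi < -1e-9))
    return(rep(1 / ns, ns))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# ---------------------------------------------------------------------------
# Tip data
# ---------------------------------------------------------------------------

#' Tip partial likelihoods for a single character
#'
#' Observed states become indicator rows; a polymorphic `0/1` cell
#' becomes a row of ones over both states (the standard pruning treatment
#' of ambiguity, giving both resolutions equivalent weight).
#'
#' @param m a character matrix (see [as_character_matrix()]).
#' @param character character id (column name) or index.
#' @return numeric matrix, taxa x 2, rownames = taxa.
#' @export
single_tipdata <- function(m, character) {
  m <- as_character_matrix(m)
  if (is.character(character) && !(character %in% colnames(m)))
    stop("unknown character id: ", character)
  x <- m[, character]
  out <- t(vapply(x, function(v) switch(v,
    "0" = c(1, 0), "1" = c(0, 1), "0/1" = c(1, 1)), numeric(2)))
  rownames(out) <- rownames(m)
  colnames(out) <- c("0", "1")
  out
}

#' Joint tip partial likelihoods for a character pair
#'
#' Indicator rows over the joint states `(0,0),(0,1),(1,0),(1,1)`; a
#' polymorphic cell in either character expands to ones over all joint
#' states consistent with the other character's observation.
#'
#' @param m a character matrix.
#' @param char_i,char_j character ids or indices (first and second member
#'   of the pair; the first indexes the "background" character in `q12`
#'   etc.).
#' @return numeric matrix, taxa x 4.
#' @export
pair_tipdata <- function(m, char_i, char_j) {
  ti <- single_tipdata(m, char_i)
  tj <- single_tipdata(m, char_j)
  out <- cbind(ti[, 1] * tj[, 1], ti[, 1] * tj[, 2],
               ti[, 2] * tj[, 1], ti[, 2] * tj[, 2])
  colnames(out) <- PAIR_STATES
  out
}

# ---------------------------------------------------------------------------
# Likelihood
# ---------------------------------------------------------------------------

# Preprocess a phylo for the C++ pruning: postorder edges, tip rows aligned
# to this tree's tip order.
tree_to_c <- function(tree, tips) {
  tr <- ape::reorder.phylo(tree, "postorder")
  miss <- setdiff(tr$tip.label, rownames(tips))
  if (length(miss) > 0L)
    stop("tip data missing for taxa: ", paste(miss, collapse = ", "))
  tipmat <- tips[tr$tip.label, , drop = FALSE]
  ntip <- ape::Ntip(tr)
  list(edge = tr$edge, len = tr$edge.length, ntip = ntip,
       nnode = ntip + tr$Nnode, root = ntip + 1L,
       tip = unname(as.matrix(tipmat)))
}

#' Pruning log-likelihood of tip data under a CTMC
#'
#' Felsenstein's post-order pruning with per-node rescaling, summed over
#' root states weighted by `root`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tips taxa x states partial-likelihood matrix (rownames = taxa),
#'   e.g. from [single_tipdata()] or [pair_tipdata()].
#' @param Q generator matrix matching the state space of `tips`.
#' @param root root prior probability vector (default uniform).
#' @return the log-likelihood.
#' @export
prune_loglik <- function(tree, tips, Q, root = NULL) {
  if (is.null(root)) root <- rep(1 / ncol(tips), ncol(tips))
  if (ncol(tips) != nrow(Q) || length(root) != nrow(Q))
    stop("state-space dimensions disagree (tips: ", ncol(tips),
         ", Q: ", nrow(Q), ", root: ", length(root), ")")
  if (abs(sum(root) - 1) > 1e-12) stop("root prior does not sum to 1")
  prune_ll_cpp(tree_to_c(tree, tips), unname(as.matrix(Q)), root)
}

#' Brute-force log-likelihood by enumeration (test oracle)
#'
#' Sums the joint probability over every assignment of states to internal
#' nodes.  Exponential in the number of internal nodes, so refuses trees
#' with more than 8 of them; exists purely as an independent cross-check
#' of [prune_loglik()].
#'
#' @inheritParams prune_loglik
#' @export
brute_force_loglik <- function(tree, tips, Q, root = NULL) {
  ns <- ncol(tips)
  if (is.null(root)) root <- rep(1 / ns, ns)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  if (nint > 8L) stop("too many internal nodes (", nint, ") for enumeration")
  tipmat <- tips[tree$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tree$edge)),
              function(i) transition_probabilities(Q, tree$edge.length[i]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  root_node <- ntip + 1L
  total <- 0
  for (g in seq_len(nrow(grid))) {
    states <- grid[g, ]
    pr <- root[states[root_node - ntip]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      sp <- states[par - ntip]
      if (chi <= ntip) {
        pr <- pr * sum(P[[e]][sp, ] * tipmat[chi, ])
      } else {
        pr <- pr * P[[e]][sp, states[chi - ntip]]
      }
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

#' Marginal state probabilities at a node
#'
#' Conditional probability of each state at `node` given the tip data,
#' generator and root prior, computed by clamped pruning (the node's
#' partial likelihood restricted to one state at a time, renormalised by
#' the total likelihood).
#'
#' @inheritParams prune_loglik
#' @param node ape node id (tip index or internal node number).
#' @return probability vector over states (sums to 1).
#' @export
node_state_probs <- function(tree, tips, Q, root = NULL, node) {
  if (is.null(root)) root <- rep(1 / ncol(tips), ncol(tips))
  nn <- ape::Ntip(tree) + tree$Nnode
  if (!(node %in% seq_len(nn))) stop("node not found: ", node)
  p <- as.numeric(node_probs_cpp(tree_to_c(tree, tips),
                                 unname(as.matrix(Q)), root, node))
  names(p) <- colnames(tips)
  p
}
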
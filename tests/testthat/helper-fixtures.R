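# Shared small fixtures built in code.

# deterministic 5-taxon tree with distinct branch lengths
fix_tree5 <- function() {
  parse_newick("(((A:0.4,B:0.6):0.5,C:0.9):0.3,(D:0.7,E:0.2):0.8);")
}

fix_tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")

# indicator tip matrix from a named vector of "0"/"1"/"0/1"
tipmat2 <- function(states) {
  m <- matrix(states, ncol = 1, dimnames = list(names(states), "Ch1"))
  single_tipdata(as_character_matrix(m), "Ch1")
}

# random generator matrices under a fixed seed
random_dep_Q <- function() build_dependent_Q(setNames(runif(8, 0.1, 2),
                                                      rjtraits:::DEP_RATES))

random_binary_Q <- function() build_binary_Q(runif(1, 0.1, 2), runif(1, 0.1, 2))

# small character matrix with a polymorphic cell
fix_matrix3 <- function() {
  as_character_matrix(matrix(c("0", "1", "0/1",
                               "1", "0", "1"), 3, 2,
                             dimnames = list(c("A", "B", "C"),
                                             c("Ch1", "Ch2"))))
}

# brute-force log-likelihood with one node clamped to a state: an
# independent Bayes-rule oracle for node_state_probs
clamp_brute <- function(tree, tips, Q, root, node, state) {
  ns <- ncol(tips)
  ntip <- ape::Ntip(tree)
  if (node <= ntip) {
    mask <- rep(0, ns); mask[state] <- 1
    tips[tree$tip.label[node], ] <- tips[tree$tip.label[node], ] * mask
    return(brute_force_loglik(tree, tips, Q, root))
  }
  # enumerate assignments directly, skipping those where the node differs
  P <- lapply(seq_len(nrow(tree$edge)),
              function(i) transition_probabilities(Q, tree$edge.length[i]))
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  grid <- grid[grid[, node - ntip] == state, , drop = FALSE]
  tipmat <- tips[tree$tip.label, , drop = FALSE]
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    pr <- root[st[1]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      sp <- st[par - ntip]
      pr <- pr * if (chi <= ntip) sum(P[[e]][sp, ] * tipmat[chi, ])
                 else P[[e]][sp, st[chi - ntip]]
    }
    total <- total + pr
  }
  log(total)
}

# count of rate-class models (partitions of n rates with a zero bin),
# split by class count k: sum over zero-set sizes z of C(n,z)*S2(n-z,k)
stirling2 <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  if (k > n) return(0)
  S <- matrix(0, n + 1, k + 1)
  S[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
    }
  }
  S[n + 1, k + 1]
}

model_counts_by_k <- function(n) {
  vapply(0:n, function(k) {
    sum(vapply(0:n, function(z) choose(n, z) * stirling2(n - z, k),
               numeric(1)))
  }, numeric(1))
}
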
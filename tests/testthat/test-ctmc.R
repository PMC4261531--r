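test_that("dependent generator has 8 free rates and structural zeros", {
  Q0 <- build_dependent_Q(setNames(rep(0, 8), rjtraits:::DEP_RATES))
  expect_equal(unname(Q0), matrix(0, 4, 4))

  Q1 <- build_dependent_Q(setNames(rep(1, 8), rjtraits:::DEP_RATES))
  expect_equal(unname(rowSums(Q1)), rep(0, 4))
  expect_equal(Q1["00", "01"], 1)
  # double-change transitions stay exactly zero
  expect_identical(c(Q1["00", "11"], Q1["11", "00"],
                     Q1["01", "10"], Q1["10", "01"]), rep(0, 4))

  set.seed(1)
  for (i in 1:10) {
    Q <- random_dep_Q()
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q - diag(diag(Q)) >= 0))
  }
  expect_error(build_dependent_Q(setNames(c(-1, rep(1, 7)),
                                          rjtraits:::DEP_RATES)), "negative")
})

test_that("independent generator imposes the four rate equalities", {
  r <- c(gain1 = 0.3, loss1 = 0.7, gain2 = 1.1, loss2 = 0.2)
  Q <- build_independent_Q(r)
  expect_equal(Q["00", "01"], Q["10", "11"])  # q12 == q34
  expect_equal(Q["00", "10"], Q["01", "11"])  # q13 == q24
  expect_equal(Q["01", "00"], Q["11", "10"])  # q21 == q43
  expect_equal(Q["10", "00"], Q["11", "01"])  # q31 == q42
  expect_equal(length(unique(Q[Q > 0])), 4)

  # equals the dependent builder with tied arguments
  Qd <- build_dependent_Q(c(q12 = r[["gain2"]], q34 = r[["gain2"]],
                            q13 = r[["gain1"]], q24 = r[["gain1"]],
                            q21 = r[["loss2"]], q43 = r[["loss2"]],
                            q31 = r[["loss1"]], q42 = r[["loss1"]]))
  expect_identical(Q, Qd)

  Qs <- build_independent_Q(c(gain1 = 1, loss1 = 1, gain2 = 1, loss2 = 1))
  expect_equal(unname(Qs), unname(t(Qs)))
})

test_that("transition probabilities match the 2-state closed form", {
  expect_equal(transition_probabilities(build_binary_Q(1, 2), 0),
               diag(2), ignore_attr = TRUE)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.01, 3); b <- runif(1, 0.01, 3); t <- runif(1, 0, 4)
    P <- transition_probabilities(build_binary_Q(a, b), t)
    closed <- (b + a * exp(-(a + b) * t)) / (a + b)
    expect_lt(abs(P[1, 1] - closed), 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  }
  # symmetric rates relax to the uniform distribution
  Pinf <- transition_probabilities(build_binary_Q(1, 1), 100)
  expect_equal(unname(Pinf), matrix(0.5, 2, 2), tolerance = 1e-10)
  expect_error(transition_probabilities(build_binary_Q(1, 1), -1), ">= 0")
})

test_that("Chapman-Kolmogorov holds for 4-state generators", {
  set.seed(3)
  for (i in 1:10) {
    Q <- random_dep_Q()
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    P12 <- transition_probabilities(Q, t1 + t2)
    P1P2 <- transition_probabilities(Q, t1) %*% transition_probabilities(Q, t2)
    expect_lt(max(abs(P12 - P1P2)), 1e-9)
    expect_lt(max(abs(rowSums(P12) - 1)), 1e-10)
    expect_true(all(P12 >= 0))
  }
})

test_that("tip data encodes polymorphism as equal-weight ambiguity", {
  m <- fix_matrix3()
  td <- single_tipdata(m, "Ch1")
  expect_equal(td["A", ], c("0" = 1, "1" = 0))
  expect_equal(td["C", ], c("0" = 1, "1" = 1))

  pt <- pair_tipdata(m, "Ch1", "Ch2")
  expect_equal(unname(pt["A", ]), c(0, 1, 0, 0))   # (0,1)
  expect_equal(unname(pt["C", ]), c(0, 1, 0, 1))   # (0/1, 1)
  m2 <- m; m2["C", "Ch2"] <- "0"
  expect_equal(unname(pair_tipdata(m2, "Ch1", "Ch2")["C", ]),
               c(1, 0, 1, 0))                      # (0/1, 0)
  m2["C", "Ch2"] <- "0/1"
  expect_equal(unname(pair_tipdata(m2, "Ch1", "Ch2")["C", ]),
               c(1, 1, 1, 1))                      # (0/1, 0/1)
  expect_error(pair_tipdata(m, "Ch1", "Ch9"), "Ch9")
})

test_that("pruning equals brute-force enumeration on random instances", {
  # degenerate single-leaf cases
  one <- parse_newick("(A:0);")
  tips <- tipmat2(c(A = "1"))
  expect_equal(prune_loglik(one, tips, build_binary_Q(1, 1)), log(0.5))
  expect_equal(brute_force_loglik(one, tips, build_binary_Q(1, 1)), log(0.5))

  # Q = 0: all mass on the root prior entry for the shared state
  tr <- fix_tree3()
  tips0 <- tipmat2(c(A = "1", B = "1", C = "1"))
  expect_equal(prune_loglik(tr, tips0, build_binary_Q(0, 0),
                            root = c(0.3, 0.7)), log(0.7))

  set.seed(4)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tr <- simulate_yule_tree(n)
    # 2-state
    Q2 <- random_binary_Q()
    states <- sample(c("0", "1", "0/1"), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    t2 <- tipmat2(setNames(states, tr$tip.label))
    expect_lt(abs(prune_loglik(tr, t2, Q2) - brute_force_loglik(tr, t2, Q2)),
              1e-9)
    # 4-state
    Q4 <- random_dep_Q()
    m <- matrix(sample(c("0", "1", "0/1"), 2 * n, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), n, 2,
                dimnames = list(tr$tip.label, c("c1", "c2")))
    t4 <- pair_tipdata(as_character_matrix(m), "c1", "c2")
    expect_lt(abs(prune_loglik(tr, t4, Q4) - brute_force_loglik(tr, t4, Q4)),
              1e-9)
  }
})

test_that("a zero-length internal edge leaves the likelihood unchanged", {
  tr <- parse_newick("(((A:1,B:1):0,C:2):1,D:1);")
  tr2 <- parse_newick("((A:1,B:1,C:2):1,D:1);")  # same after collapsing
  skip_if_not(ape::is.rooted(tr2))
  Q <- build_binary_Q(0.7, 0.4)
  tips <- tipmat2(c(A = "1", B = "0", C = "1", D = "0"))
  expect_equal(prune_loglik(tr, tips, Q), prune_loglik(tr2, tips, Q),
               tolerance = 1e-12)
})

test_that("independent pair likelihood factorizes into the two characters", {
  set.seed(5)
  fx <- make_fixture_study("null", seed = 8, n_trees = 1)
  tr <- fx$trees[[1]]
  m <- fx$matrix
  for (i in 1:5) {
    r <- c(gain1 = runif(1, .1, 2), loss1 = runif(1, .1, 2),
           gain2 = runif(1, .1, 2), loss2 = runif(1, .1, 2))
    Q4 <- build_independent_Q(r)
    pair <- sample(colnames(m), 2)
    joint <- prune_loglik(tr, pair_tipdata(m, pair[1], pair[2]), Q4)
    l1 <- prune_loglik(tr, single_tipdata(m, pair[1]),
                       build_binary_Q(r[["gain1"]], r[["loss1"]]))
    l2 <- prune_loglik(tr, single_tipdata(m, pair[2]),
                       build_binary_Q(r[["gain2"]], r[["loss2"]]))
    expect_lt(abs(joint - (l1 + l2)), 1e-9)
  }
})

test_that("likelihood is invariant to taxon relabeling", {
  set.seed(6)
  tr <- simulate_yule_tree(8)
  Q <- random_binary_Q()
  states <- setNames(sample(c("0", "1"), 8, replace = TRUE), tr$tip.label)
  ll1 <- prune_loglik(tr, tipmat2(states), Q)
  tr2 <- tr
  tr2$tip.label <- paste0("x", seq_len(8))
  states2 <- setNames(states, tr2$tip.label)
  expect_equal(prune_loglik(tr2, tipmat2(states2), Q), ll1)
})

test_that("node probabilities match the clamped brute-force Bayes rule", {
  set.seed(7)
  tr <- simulate_yule_tree(4)
  Q <- random_binary_Q()
  states <- setNames(sample(c("0", "1"), 4, replace = TRUE), tr$tip.label)
  tips <- tipmat2(states)
  root <- c(0.4, 0.6)
  for (node in (ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode)) {
    p <- node_state_probs(tr, tips, Q, root, node)
    expect_lt(abs(sum(p) - 1), 1e-10)
    # oracle: clamped enumeration via brute force with indicator tip rows
    ll_tot <- brute_force_loglik(tr, tips, Q, root)
    clamped <- vapply(1:2, function(s) {
      clamp_brute(tr, tips, Q, root, node, s)
    }, numeric(1))
    expect_equal(unname(p), exp(clamped - ll_tot), tolerance = 1e-9)
  }
  # a leaf with an unambiguous state gets an indicator
  expect_equal(unname(node_state_probs(tr, tips, Q, root, 1)),
               unname(tips[tr$tip.label[1], ]))
})

test_that("symmetric rates and symmetric data give symmetric node probabilities", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tips <- tipmat2(c(A = "0", B = "1", C = "1", D = "0"))
  p <- node_state_probs(tr, tips, build_binary_Q(1, 1), node = 5)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-10)
})
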
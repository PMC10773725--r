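test_that("degenerate two-taxon cases have closed-form likelihoods", {
  mod <- hky_model(2, c(0.1, 0.2, 0.3, 0.4), n_rate_categories = 1)
  two <- ape::read.tree(text = "(a:0,b:0);")
  aln_same <- dna_alignment(rbind(c("A", "G"), c("A", "G")), c("a", "b"))
  expect_equal(site_log_likelihoods(two, aln_same, mod),
               log(c(0.1, 0.3)), tolerance = 1e-12)
  # conflicting states across a zero-length path: impossible, -Inf
  aln_diff <- dna_alignment(rbind("A", "C"), c("a", "b"))
  expect_identical(site_log_likelihoods(two, aln_diff, mod), -Inf)
})

test_that("pattern probabilities sum to one over all site patterns", {
  mod <- hky_model(2.5, c(0.1, 0.2, 0.3, 0.4), gamma_shape = 0.7,
                   n_rate_categories = 4)
  phy <- ape::read.tree(text = "(a:0.11,(b:0.23,c:0.05):0.4,d:0.2);")
  pats <- as.matrix(expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  aln <- dna_alignment(t(pats), c("a", "b", "c", "d"))
  ll <- site_log_likelihoods(phy, aln, mod)
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
})

test_that("kappa=1 with uniform frequencies reproduces the Jukes-Cantor formula", {
  mod <- hky_model(1, rep(0.25, 4), n_rate_categories = 1)
  for (t in c(0.02, 0.4, 2)) {
    two <- ape::read.tree(text = sprintf("(a:%f,b:0);", t))
    aln <- dna_alignment(rbind("G", "G"), c("a", "b"))
    p_same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    expect_equal(site_log_likelihoods(two, aln, mod),
                 log(0.25 * p_same), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to the pruning root and to pattern duplication", {
  mod <- study_model()
  tr <- study_tree(6, "positive", 0.08)
  aln <- simulate_alignment(tr, mod, 200, seed = 11)
  ll <- site_log_likelihoods(tr, aln, mod)
  # reroot: same unrooted tree traversed from a different node
  rr <- ape::unroot(ape::root(tr, outgroup = "t4", resolve.root = TRUE))
  expect_equal(sum(site_log_likelihoods(rr, aln, mod)), sum(ll),
               tolerance = 1e-8)
  # duplicated columns change nothing per site
  aln2 <- dna_alignment(aln$states[, c(1:200, 1:50)], aln$labels)
  expect_equal(site_log_likelihoods(tr, aln2, mod), ll[c(1:200, 1:50)],
               tolerance = 1e-12)
  # one rate category equals the homogeneous model
  mod1 <- hky_model(2, c(0.1, 0.2, 0.3, 0.4), gamma_shape = 37,
                    n_rate_categories = 1)
  mod1b <- hky_model(2, c(0.1, 0.2, 0.3, 0.4), gamma_shape = 1,
                     n_rate_categories = 1)
  expect_equal(site_log_likelihoods(tr, aln, mod1),
               site_log_likelihoods(tr, aln, mod1b), tolerance = 1e-12)
})

test_that("optimized likelihoods agree with phangorn on shared topologies", {
  mod <- study_model()
  tr <- study_tree(6, "positive", 0.1)
  aln <- simulate_alignment(tr, mod, 500, seed = 21)
  cands <- enumerate_topologies(labs6)[c(2, 50, 101)]
  fit <- fit_topologies(aln, cands, mod)
  pd <- as_phyDat(aln)
  for (k in seq_along(cands)) {
    phy <- as_phylo(cands[[k]], rep(0.1, 3), rep(0.1, 6))
    pfit <- phangorn::optim.pml(
      phangorn::pml(phy, pd, bf = c(0.1, 0.2, 0.3, 0.4),
                    Q = c(1, 2, 1, 1, 2, 1), k = 4, shape = 1),
      optEdge = TRUE, control = phangorn::pml.control(trace = 0, eps = 1e-8))
    expect_equal(fit$loglik[k], pfit$logLik, tolerance = 1e-4)
  }
})

test_that("edge-length optimization recovers generating lengths on long alignments", {
  mod <- study_model()
  tr <- study_tree(6, "positive", 0.1)
  aln <- simulate_alignment(tr, mod, 1e5, seed = 31)
  of <- optimize_edge_lengths(as_topology(tr, labs6), aln, mod)
  expect_true(of$converged)
  # compare sorted lengths (edge order differs between representations)
  expect_lt(max(abs(sort(of$tree$edge.length) - sort(tr$edge.length))), 0.01)
})

test_that("optimization respects model nesting and multistart stability", {
  mod <- study_model()
  tr <- study_tree(6, "one_zero", 0.1)
  aln <- simulate_alignment(tr, mod, 400, seed = 41)
  top <- as_topology(tr, labs6)
  full <- optimize_edge_lengths(top, aln, mod)
  contracted <- optimize_edge_lengths(as_topology(tr, labs6, collapse_zero = TRUE),
                                      aln, mod)
  star <- optimize_edge_lengths(topology(labs6), aln, mod)
  expect_gte(full$loglik + 1e-6, contracted$loglik)  # nesting
  expect_gte(contracted$loglik + 1e-6, star$loglik)
  for (s in c(0.02, 0.5)) {
    alt <- optimize_edge_lengths(top, aln, mod, start_length = s)
    expect_equal(alt$loglik, full$loglik, tolerance = 1e-4)
  }
})

test_that("fit_topologies assembles a consistent site log-likelihood matrix", {
  fit <- make_small_fit(seed = 51, n = 300)
  expect_equal(rowSums(fit$values), fit$loglik, tolerance = 1e-9)
  expect_equal(fit$ml_index, which.max(fit$loglik))
  expect_equal(ncol(fit$values), 300)
  # single candidate: it is the ML tree with delta 0
  mod <- study_model()
  aln <- simulate_alignment(study_tree(6, "positive", 0.1), mod, 200, seed = 52)
  one <- fit_topologies(aln, enumerate_topologies(labs6)[5], mod)
  expect_equal(one$ml_index, 1L)
  expect_equal(max(one$loglik) - one$loglik, 0)
  # exact row ties break to the lowest index
  tie <- site_loglik_matrix(matrix(c(-1, -2, -2, -1, -1.5, -1.5), 3, 2,
                                   byrow = TRUE))
  expect_equal(tie$ml_index, 1L)
})

test_that("the ML tree recovers the generating topology on resolved data", {
  mod <- study_model()
  tr <- study_tree(6, "positive", 0.1)
  cands <- enumerate_topologies(labs6)
  truth <- compatible_set(as_topology(tr, labs6, collapse_zero = TRUE),
                          cands, indices = TRUE)
  hits <- 0
  for (seed in 1:5) {
    aln <- simulate_alignment(tr, mod, 1000, seed = 60 + seed)
    fit <- fit_topologies(aln, cands, mod)
    hits <- hits + (fit$ml_index %in% truth)
  }
  expect_gte(hits, 4)
})
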
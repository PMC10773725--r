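# shared fixtures, built in code

labs6 <- paste0("t", 1:6)
labs4 <- paste0("t", 1:4)

study_model <- function(k = 4)
  hky_model(kappa = 2, base_freqs = c(0.1, 0.2, 0.3, 0.4), gamma_shape = 1,
            n_rate_categories = k)

# a small cached 6-taxon fit reused across files (fresh per test file)
make_small_fit <- function(seed = 3, n = 400, tI = 0.1,
                           setting = "positive") {
  mod <- study_model()
  tr <- study_tree(6, setting, tI)
  aln <- simulate_alignment(tr, mod, n, seed = seed)
  cands <- enumerate_topologies(labs6)
  fit_topologies(aln, cands, mod)
}

# a handcrafted site_loglik matrix (no topologies attached)
toy_sitelik <- function(values) site_loglik_matrix(values)

# align a character matrix into phangorn's phyDat (oracle plumbing)
as_phyDat <- function(aln) {
  ch <- matrix(c("A", "C", "G", "T")[aln$states], nrow(aln$states))
  rownames(ch) <- aln$labels
  phangorn::phyDat(ch, type = "DNA")
}

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("%.4f within %.4f of %.4f", value, tol, target))
}
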
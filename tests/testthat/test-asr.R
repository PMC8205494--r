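model <- substitution_model("Dayhoff")

test_that("single-tip and all-gap site likelihoods are analytic", {
  tr <- prepare_tree(ape::read.tree(text = "(A:1,B:1);"))
  g1 <- discrete_gamma_rates(1, 1)
  expect_equal(site_log_likelihood(tr, c(A = "-", B = "-"), model, g1), 0)
  # one observed tip, one missing: likelihood = stationary frequency
  expect_equal(site_log_likelihood(tr, c(A = "K", B = "-"), model, g1),
               log(unname(model$pi["K"])))
})

test_that("pruning equals exhaustive enumeration on small random instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(3:4, 1)
    tr <- random_rooted_tree(n, seed = seed, depth = runif(1, 0.1, 1.5))
    col <- sample(c(aa_alphabet, "-"), n, replace = TRUE,
                  prob = c(rep(1, 20), 3))
    names(col) <- tr$tip.label
    rates <- discrete_gamma_rates(runif(1, 0.3, 2), sample(1:3, 1))
    rho <- runif(1, 0.3, 2)
    expect_equal(site_log_likelihood(tr, col, model, rates, rho),
                 brute_force_loglik(tr, col, model, rates, rho),
                 tolerance = 1e-9)
  }
})

test_that("likelihood respects the pulley principle (virtual re-rooting)", {
  aln <- random_alignment(n = 5, len = 20, seed = 8)
  tr <- random_rooted_tree(5, seed = 8)
  rates <- discrete_gamma_rates(0.9, 3)
  ll1 <- tree_log_likelihood(tr, aln, model, rates, 0.7)$loglik
  # reroot on an internal edge; a reversible model must give the same value
  tr2 <- prepare_tree(ape::root(ape::unroot(tr), outgroup = "t1",
                                resolve.root = TRUE))
  ll2 <- tree_log_likelihood(tr2, aln, model, rates, 0.7)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("likelihood is invariant to (2 * lengths, rho / 2) rescaling", {
  aln <- random_alignment(n = 6, len = 15, seed = 2)
  tr <- random_rooted_tree(6, seed = 3)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  rates <- discrete_gamma_rates(1.2, 2)
  expect_equal(tree_log_likelihood(tr, aln, model, rates, 0.5)$loglik,
               tree_log_likelihood(tr2, aln, model, rates, 0.25)$loglik,
               tolerance = 1e-9)
})

test_that("marginal posteriors match brute-force Bayes on a 4-tip tree", {
  tr <- prepare_tree(ape::read.tree(
    text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.2);"))
  aln <- new_alignment(tibble::tibble(id = c("A", "B", "C", "D"),
                                      seq = c("K", "R", "K", "D")))
  rates <- discrete_gamma_rates(0.8, 2)
  anc <- marginal_reconstruct(tr, aln, model, rates, 1)
  idx <- mbcharge:::tree_index(tr)
  # oracle: enumerate the 20^3 internal assignments x rate categories
  P_by <- function(k) lapply(seq_len(nrow(idx$edge)), function(i) {
    prob_matrix(model, idx$blen[idx$edge[i, 2]] * rates$rates[k])
  })
  tipstate <- c(A = "K", B = "R", C = "K", D = "D")
  post <- matrix(0, 20, 3)
  for (k in 1:2) {
    P <- P_by(k)
    for (r in 1:20) for (u in 1:20) for (v in 1:20) {
      st <- c(rep(NA, 4), r, u, v)
      lik <- model$pi[r]
      for (i in seq_len(nrow(idx$edge))) {
        ch <- idx$edge[i, 2]
        si <- if (ch <= 4) match(tipstate[idx$ids[ch]], aa_alphabet) else st[ch]
        lik <- lik * P[[i]][st[idx$edge[i, 1]], si]
      }
      w <- rates$weights[k] * lik
      post[r, 1] <- post[r, 1] + w
      post[u, 2] <- post[u, 2] + w
      post[v, 3] <- post[v, 3] + w
    }
  }
  post <- sweep(post, 2, colSums(post), "/")
  ids <- idx$ids[5:7]
  for (j in 1:3) {
    expect_equal(unname(anc$posterior[[ids[j]]][, 1]), post[, j],
                 tolerance = 1e-10)
  }
  expect_equal(colSums(anc$posterior[[ids[1]]]), rep(1, 1), tolerance = 1e-9)
})

test_that("zero-length branches pin the root to the shared tip state", {
  tr <- prepare_tree(ape::read.tree(text = "(A:0,B:0);"))
  aln <- new_alignment(tibble::tibble(id = c("A", "B"), seq = c("K", "K")))
  anc <- marginal_reconstruct(tr, aln, model, discrete_gamma_rates(1, 1), 1)
  expect_equal(unname(anc$posterior[["N1"]]["K", 1]), 1, tolerance = 1e-12)
})

test_that("an invariant column on a large tree reconstructs with high confidence", {
  ex <- example_eulipotyphla()
  aln <- new_alignment(tibble::tibble(id = ex$tree$tip.label,
                                      seq = rep("D", 55)))
  anc <- marginal_reconstruct(ex$tree, aln, model,
                              discrete_gamma_rates(1, 1), 0.002)
  expect_true(all(anc$map$residue == "D"))
  expect_true(all(anc$map$prob > 0.99))
})

test_that("fit_scaling recovers simulation parameters and symmetries", {
  tr <- random_rooted_tree(30, seed = 5, depth = 1)
  sc <- scenario(tree = tr, rho = 1.5, alpha = 0.8, seed = 42,
                 charge_purify = 0,
                 shift_branches = tibble::tibble(child_id = character(),
                                                 target_dzmb = numeric()),
                 root_seq = strrep(default_root_sequence(153), 3))
  sim <- simulate_alignment(sc, model)
  fit <- fit_scaling(tr, sim$tips, model, K = 4)
  expect_lt(abs(fit$alpha - 0.8), 0.3)
  expect_lt(abs(fit$rho - 1.5) / 1.5, 0.2)

  const <- new_alignment(tibble::tibble(id = tr$tip.label,
                                        seq = rep(strrep("DKE", 5), 30)))
  expect_warning(fit0 <- fit_scaling(tr, const, model, K = 2), "variable")
  expect_lte(fit0$rho, 1e-6)
})

test_that("alignment/tree tip mismatches are reported", {
  tr <- random_rooted_tree(4, seed = 1)
  aln <- random_alignment(n = 4, len = 5, seed = 1)
  aln$id[1] <- "nope"
  expect_error(tree_log_likelihood(tr, aln, model), "mismatch")
})
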
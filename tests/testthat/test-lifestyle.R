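test_that("single derived tip needs exactly one change", {
  tr <- random_rooted_tree(10, seed = 2)
  trait <- tibble::tibble(tip_id = tr$tip.label,
                          state = as.integer(tr$tip.label == "t4"))
  fit <- fitch_parsimony(tr, trait)
  expect_equal(fit$min_changes, 1)
  org <- count_origins(tr, trait)
  expect_equal(org$origins_min, 1)
  expect_equal(org$origins_max, 1)
})

test_that("parsimony count equals brute-force minimum on random 8-tip trees", {
  for (seed in 1:20) {
    tr <- random_rooted_tree(8, seed = seed)
    set.seed(seed + 1000)
    trait <- tibble::tibble(tip_id = tr$tip.label,
                            state = sample(0:1, 8, replace = TRUE))
    expect_equal(fitch_parsimony(tr, trait)$min_changes,
                 brute_force_fitch(tr, trait))
  }
})

test_that("all-derived tips imply a single origin at the root", {
  tr <- random_rooted_tree(7, seed = 5)
  trait <- tibble::tibble(tip_id = tr$tip.label, state = 1L)
  org <- count_origins(tr, trait)
  expect_equal(org$min_changes, 0)
  expect_equal(org$origins_min, 1)
  expect_equal(org$origins_max, 1)
})

test_that("semi-aquatic and fossorial codings give 5 and 2 origins", {
  ex <- example_eulipotyphla()
  aq <- count_origins(ex$tree, binarize_lifestyle(ex$traits, "semi_aquatic"))
  expect_equal(aq$origins_min, 5)
  expect_equal(aq$origins_max, 5)
  fos <- count_origins(ex$tree, binarize_lifestyle(ex$traits, "fossorial"))
  expect_equal(fos$origins_min, 2)
  expect_equal(fos$origins_max, 2)
})

test_that("equi-parsimonious gain-vs-loss case reports a range", {
  # monophyletic inner clade of non-aquatic tips between two derived tips:
  # one gain + one loss, or two gains
  tr <- prepare_tree(ape::read.tree(
    text = "(o:4,(a:3,((e1:1,e2:1):1,(b:1.5,c:1.5):0.5):1):1);"))
  trait <- tibble::tibble(tip_id = c("o", "a", "e1", "e2", "b", "c"),
                          state = c(0L, 1L, 0L, 0L, 1L, 1L))
  fit <- fitch_parsimony(tr, trait)
  expect_equal(fit$min_changes, 2)
  org <- count_origins(tr, trait)
  expect_equal(org$origins_min, 1)
  expect_equal(org$origins_max, 2)
  sols <- enumerate_mp_solutions(tr, trait)
  expect_true(length(sols) >= 2)
})

test_that("threshold model finds a clustered derived clade", {
  # five derived tips on a long-stemmed clade, six background tips
  tr <- prepare_tree(ape::read.tree(text = paste0(
    "(((d1:2,d2:2):1,((d3:1.5,d4:1.5):0.5,d5:2):1):30,",
    "((o1:10,o2:10):13,((o3:8,o4:8):5,(o5:6,o6:6):7):10):10);")))
  trait <- tibble::tibble(tip_id = tr$tip.label,
                          state = as.integer(grepl("^d", tr$tip.label)))
  suppressWarnings(
    thr <- threshold_asr(tr, trait, "BM",
                         mcmc = list(generations = 3e5, sample_every = 100,
                                     seed = 4)))
  mrca <- node_ids(tr)[ape::getMRCA(tr, paste0("d", 1:5))]
  expect_gt(thr$node_prob$p_derived[thr$node_prob$node_id == mrca], 0.9)
  expect_true(all(thr$node_prob$p_derived >= 0 & thr$node_prob$p_derived <= 1))
  expect_true(is.finite(thr$dic))
})

test_that("star-like balanced data leave the root undecided", {
  set.seed(6)
  tr <- ape::stree(16, type = "balanced")
  tr$edge.length <- ifelse(tr$edge[, 2] <= 16, 1, 0.5)
  tr <- prepare_tree(tr)
  trait <- tibble::tibble(tip_id = tr$tip.label,
                          state = rep(c(0L, 1L), 8))   # one of each per cherry
  suppressWarnings(
    thr <- threshold_asr(tr, trait, "BM",
                         mcmc = list(generations = 4e5, sample_every = 100,
                                     seed = 9)))
  root_p <- thr$node_prob$p_derived[1]
  expect_gt(root_p, 0.3)
  expect_lt(root_p, 0.7)
})

test_that("threshold and correlation chains are seed-reproducible", {
  ex <- example_eulipotyphla()
  b <- binarize_lifestyle(ex$traits, "semi_aquatic")
  ctl <- list(generations = 3e4, sample_every = 100, seed = 123)
  suppressWarnings({
    a1 <- threshold_asr(ex$tree, b, "lambda", mcmc = ctl)
    a2 <- threshold_asr(ex$tree, b, "lambda", mcmc = ctl)
  })
  expect_identical(a1$node_prob, a2$node_prob)
  expect_identical(a1$lambda, a2$lambda)

  z <- stats::setNames(rnorm(55), ex$tree$tip.label)
  suppressWarnings({
    c1 <- threshbayes_correlation(ex$tree, z, b, mcmc = ctl)
    c2 <- threshbayes_correlation(ex$tree, z, b, mcmc = ctl)
  })
  expect_identical(c1$r_samples, c2$r_samples)
})

test_that("liability correlation recovers a strong planted correlation", {
  ex <- example_eulipotyphla()
  tr <- ex$tree
  set.seed(14)
  C <- ape::vcv(tr); C <- C / mean(diag(C)); L <- chol(C)
  z1 <- as.numeric(t(L) %*% rnorm(55))
  z2 <- as.numeric(t(L) %*% rnorm(55))
  liab <- 0.8 * z1 + sqrt(1 - 0.64) * z2
  trait <- tibble::tibble(tip_id = rownames(C), state = as.integer(liab > 0))
  cont <- tibble::tibble(tip_id = rownames(C), value = z1)
  suppressWarnings(
    fit <- threshbayes_correlation(tr, cont, trait,
                                   mcmc = list(generations = 3e5,
                                               sample_every = 150, seed = 5)))
  expect_gt(fit$r_mean, 0.3)
  expect_true(fit$r_hpd[1] <= 0.8 && 0.8 <= fit$r_hpd[2])
  expect_gt(fit$r_hpd[1], 0)     # excludes zero
  expect_error(threshbayes_correlation(
    tr, stats::setNames(rep(1, 55), tr$tip.label), trait), "constant")
})

test_that("PGLS with lambda = 0 reduces to ordinary least squares", {
  set.seed(9)
  tr <- prepare_tree(ape::rcoal(12, tip.label = paste0("t", 1:12)))
  set.seed(10)
  df <- tibble::tibble(tip_id = tr$tip.label, x = rnorm(12),
                       y = rnorm(12))
  fit <- pgls_fit(tr, df, lambda = 0)
  ols <- stats::lm(y ~ x, data = df)
  expect_equal(unname(fit$coefficients),
               unname(stats::coef(ols)[c("(Intercept)", "x")]),
               tolerance = 1e-10)
})

test_that("PGLS matches the closed-form GLS oracle", {
  tr <- prepare_tree(ape::read.tree(
    text = "(((A:1,B:1):1,(C:1.5,D:0.5):0.5):1,(E:2,F:2):1);"))
  set.seed(11)
  df <- tibble::tibble(tip_id = c("A", "B", "C", "D", "E", "F"),
                       x = c(0.1, 0.5, 1.2, 0.8, 2.0, 1.4),
                       y = c(0.35, 0.4, 0.52, 0.44, 0.62, 0.55))
  for (lam in c(1, 0.5)) {
    fit <- pgls_fit(tr, df, lambda = lam)
    C <- ape::vcv(tr)
    V <- lam * C + (1 - lam) * diag(diag(C))
    ord <- match(rownames(C), df$tip_id)
    beta <- gls_oracle(V, df$x[ord], df$y[ord])
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  }
  expect_error(pgls_fit(tr, df[1:2, ]), "at least 3")
})

test_that("PGLS recovers generating coefficients from a clean mobility panel", {
  ex <- example_eulipotyphla()
  z <- stats::setNames(seq(-0.5, 3, length.out = 55), ex$tree$tip.label)
  mob <- simulate_mobility(ex$tree, z, noise_sd = 0)
  fit <- pgls_fit(ex$tree, tibble::tibble(tip_id = mob$tip_id, x = mob$zmb,
                                          y = mob$mobility))
  expect_equal(unname(fit$coefficients["slope"]), 0.1488, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["intercept"]), 0.3075, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("tidy/glance methods return the advertised columns", {
  tr <- random_rooted_tree(12, seed = 9)
  set.seed(10)
  df <- tibble::tibble(tip_id = tr$tip.label, x = rnorm(12),
                       y = rnorm(12) + 0.5)
  fit <- pgls_fit(tr, df)
  expect_named(tidy(fit), c("term", "estimate", "std_error"))
  expect_named(glance(fit), c("r_squared", "sigma2", "p_value", "lambda", "n"))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
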
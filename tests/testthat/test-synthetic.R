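test_that("the bundled example phylogeny matches its description", {
  ex <- example_eulipotyphla()
  expect_equal(length(ex$tree$tip.label), 55)
  expect_true(ape::is.ultrametric(ex$tree, tol = 1e-6))
  expect_true(ape::is.rooted(ex$tree))
  expect_equal(sum(ex$traits$lifestyle == "semi_aquatic"), 7)
  expect_setequal(unique(ex$traits$lifestyle),
                  c("terrestrial", "semi_fossorial", "fossorial", "semi_aquatic"))
})

test_that("the default root sequence is deterministic and myoglobin-like", {
  s1 <- default_root_sequence()
  s2 <- default_root_sequence()
  expect_identical(s1, s2)
  expect_equal(nchar(s1), 153)
  comp <- table(strsplit(s1, "")[[1]])
  n_ionizable <- sum(comp[names(comp) %in% c("D", "E", "K", "R", "H")])
  expect_equal(unname(n_ionizable), 19)
  expect_false("C" %in% names(comp))
})

test_that("identical seeds reproduce the whole study byte-for-byte", {
  sc <- scenario(seed = 55)
  a <- simulate_study(sc)
  b <- simulate_study(sc)
  expect_identical(a$alignment, b$alignment)
  expect_identical(a$truth_log, b$truth_log)
  expect_identical(a$traits, b$traits)
  expect_identical(a$mobility, b$mobility)
})

test_that("planted charge shifts hit their targets and are logged", {
  sc <- scenario(seed = 7)
  sim <- simulate_alignment(sc)
  all_seqs <- dplyr::bind_rows(sim$tips, sim$ancestors)
  seqs <- stats::setNames(all_seqs$seq, all_seqs$id)
  idx <- mbcharge:::tree_index(sc$tree)
  parent_of <- stats::setNames(idx$ids[idx$edge[, 1]], idx$ids[idx$edge[, 2]])
  for (ch in sc$shift_branches$child_id) {
    dz <- attr(net_charge(seqs[[ch]]), "zmb") -
      attr(net_charge(seqs[[parent_of[[ch]]]]), "zmb")
    expect_gte(dz, 2 - 1e-9)
  }
  planted <- sim$truth_log[sim$truth_log$planted, ]
  expect_true(all(planted$child_id %in% sc$shift_branches$child_id))
  expect_gte(nrow(planted), 5)
})

test_that("shifted clades stand above background tips in Z_Mb", {
  hits <- 0
  for (seed in 1:5) {
    sim <- simulate_study(scenario(seed = seed))
    idx <- mbcharge:::tree_index(sim$tree)
    shifted_tips <- unique(unlist(lapply(
      sim$scenario$shift_branches$child_id, function(id) {
        nd <- match(id, idx$ids)
        if (nd <= idx$ntip) return(idx$ids[nd])
        ape::extract.clade(sim$tree, nd)$tip.label
      })))
    z <- stats::setNames(sim$zmb$zmb, sim$zmb$tip_id)
    gap <- mean(z[shifted_tips]) - mean(z[setdiff(names(z), shifted_tips)])
    if (gap > 1.5) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("long-run simulation converges to the model's stationary frequencies", {
  model <- substitution_model("Dayhoff")
  tr <- prepare_tree(ape::read.tree(text = "(A:400,B:400);"))
  sc <- scenario(tree = tr, rho = 1, alpha = 10, seed = 3,
                 root_seq = strrep(default_root_sequence(153), 10),
                 charge_purify = 0,   # the neutral core process
                 shift_branches = tibble::tibble(child_id = character(),
                                                 target_dzmb = numeric()))
  sim <- simulate_alignment(sc, model)
  counts <- table(factor(strsplit(paste(sim$tips$seq, collapse = ""), "")[[1]],
                         levels = aa_alphabet))
  chi <- suppressWarnings(stats::chisq.test(as.numeric(counts),
                                            p = unname(model$pi)))
  expect_gt(chi$p.value, 0.001)
})

test_that("liability labels behave at the correlation limits", {
  ex <- example_eulipotyphla()
  z <- stats::setNames(seq(-1, 3, length.out = 55), ex$tree$tip.label)
  lab1 <- simulate_binary_trait(ex$tree, z, r_true = 1, seed = 1)
  expect_equal(lab1$state, as.integer(z > stats::median(z)))

  set.seed(2)
  cors <- vapply(1:20, function(s) {
    lab <- simulate_binary_trait(ex$tree, z, r_true = 0, seed = s)
    suppressWarnings(stats::cor(z, lab$state))   # NA if a draw is one-state
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.25)
})

test_that("noise-free mobility lies exactly on the generating line", {
  ex <- example_eulipotyphla()
  z <- stats::setNames(runif(55, -1, 3), ex$tree$tip.label)
  mob <- simulate_mobility(ex$tree, z, noise_sd = 0)
  expect_equal(mob$mobility, 0.1488 * mob$zmb + 0.3075, tolerance = 1e-12)
  mob0 <- simulate_mobility(ex$tree, stats::setNames(rep(0, 55), ex$tree$tip.label),
                            noise_sd = 0)
  expect_true(all(mob0$mobility == 0.3075))
})
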
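toy_tree <- function() {
  prepare_tree(ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;"))
}

test_that("node charges agree with direct net_charge at tips and ancestors", {
  tr <- toy_tree()
  aln <- new_alignment(tibble::tibble(
    id = c("A", "B", "C", "D"),
    seq = c("KDSAG", "KDSAG", "KDKAG", "KDKAG")))
  anc <- new_alignment(tibble::tibble(
    id = c("r", "ab", "cd"), seq = c("KDSAG", "KDSAG", "KDKAG")))
  nz <- node_charges(tr, aln, anc)
  expect_equal(nrow(nz), 7)
  expect_equal(nz$zmb[nz$node_id == "A"],
               attr(net_charge("KDSAG"), "zmb"))
  expect_equal(nz$zmb[nz$node_id == "cd"],
               attr(net_charge("KDKAG"), "zmb"))
  # identical alignment: constant charge everywhere
  same <- new_alignment(tibble::tibble(id = c("A", "B", "C", "D"),
                                       seq = rep("KDSAG", 4)))
  anc_same <- new_alignment(tibble::tibble(id = c("r", "ab", "cd"),
                                           seq = rep("KDSAG", 3)))
  nz2 <- node_charges(tr, same, anc_same)
  expect_equal(length(unique(round(nz2$zmb, 10))), 1)
})

test_that("a Ser->Lys branch raises the child by +1.00 at 2 dp", {
  tr <- toy_tree()
  node_seqs <- tibble::tibble(
    id = c("A", "B", "C", "D", "r", "ab", "cd"),
    seq = c("KDKAG", "KDSAG", "KDSAG", "KDSAG",
            "KDSAG", "KDSAG", "KDSAG"))
  subs <- branch_substitutions(tr, node_seqs)
  expect_equal(nrow(subs), 1)
  expect_equal(subs$from_res, "S")
  expect_equal(subs$to_res, "K")
  expect_equal(round_zmb(subs$delta), 1.00)
  nz <- node_charges(tr, new_alignment(node_seqs[1:4, ]),
                     new_alignment(node_seqs[5:7, ]))
  expect_equal(round_zmb(nz$zmb[nz$node_id == "A"] - nz$zmb[nz$node_id == "ab"]),
               1.00)
})

test_that("the desman-stem pattern yields 2 increasing + 1 decreasing", {
  tr <- toy_tree()
  parent <- "QADANG"   # Gln, Asp at sites 26/44-like positions, Asn
  child <- "RAAADG"    # Gln->Arg, Asp->Ala, Asn->Asp
  node_seqs <- tibble::tibble(
    id = c("A", "B", "C", "D", "r", "ab", "cd"),
    seq = c(child, child, parent, parent, parent, child, parent))
  subs <- branch_substitutions(tr, node_seqs)
  br <- subs[subs$child_id == "ab", ]
  expect_equal(sum(br$class == "increasing"), 2)
  expect_equal(sum(br$class == "decreasing"), 1)
  sm <- summarize_branches(subs)
  expect_equal(sm$delta_total[sm$child_id == "ab"],
               substitution_delta("Q", "R") + substitution_delta("D", "A") +
                 substitution_delta("N", "D"))
  # identical parent/child branches contribute nothing
  expect_false("cd" %in% subs$child_id)
})

test_that("gap transitions are reported as indel events with residue charge", {
  tr <- toy_tree()
  node_seqs <- tibble::tibble(
    id = c("A", "B", "C", "D", "r", "ab", "cd"),
    seq = c("K-G", "KDG", "KDG", "KDG", "KDG", "KDG", "KDG"))
  subs <- branch_substitutions(tr, node_seqs)
  del <- subs[subs$child_id == "A", ]
  expect_equal(del$event, "deletion")
  expect_equal(del$delta, -group_charge("acid", 3.90, 6.5))
})

test_that("Z_Mb telescopes along every root-to-tip path", {
  set.seed(21)
  sc <- scenario(seed = 77)
  sim <- simulate_study(sc)
  all_seqs <- dplyr::bind_rows(sim$alignment, sim$ancestors)
  subs <- branch_substitutions(sim$tree, all_seqs)
  nz <- node_charges(sim$tree, sim$alignment, sim$ancestors)
  z <- stats::setNames(nz$zmb, nz$node_id)
  idx <- mbcharge:::tree_index(sim$tree)
  root_id <- idx$ids[idx$root]
  for (tip in sample(sim$tree$tip.label, 8)) {
    path_nodes <- ape::nodepath(sim$tree,
                                from = idx$root,
                                to = match(tip, sim$tree$tip.label))
    ids <- idx$ids[path_nodes]
    dz <- sum(subs$delta[subs$child_id %in% ids])
    expect_equal(z[[tip]], z[[root_id]] + dz, tolerance = 1e-9)
  }
})

test_that("uncertainty ledger partitions node x site space", {
  tr <- toy_tree()
  aln <- new_alignment(tibble::tibble(
    id = c("A", "B", "C", "D"), seq = c("KDE", "KDE", "KNE", "KDD")))
  model <- substitution_model("Dayhoff")
  anc <- marginal_reconstruct(tr, aln, model, discrete_gamma_rates(1, 2), 0.3)
  led <- charge_robustness(anc)
  expect_equal(sum(led$counts$n), led$total)
  expect_equal(sum(led$counts$percent), 100, tolerance = 1e-9)
  expect_equal(led$total, 3 * 3)
})

test_that("hand-built posteriors classify as the ledger rules say", {
  # fabricate a reconstruction object with known posteriors
  mk <- function(p) {
    m <- matrix(0, 20, 1, dimnames = list(aa_alphabet, NULL))
    m[names(p), 1] <- p
    m
  }
  anc <- structure(list(posterior = list(
    n1 = mk(c(K = 0.97, R = 0.03)),       # confident
    n2 = mk(c(D = 0.80, N = 0.20)),       # different-charge alternative
    n3 = mk(c(E = 0.60, D = 0.40))        # same charge (both acidic)
  )), class = "mb_anc")
  led <- charge_robustness(anc)
  counts <- stats::setNames(led$counts$n, led$counts$category)
  expect_equal(unname(counts["confident"]), 1L)
  expect_equal(unname(counts["same_charge_alternative"]), 1L)
  expect_equal(unname(counts["different_charge_alternative"]), 1L)
  expect_equal(led$cases$alt_prob_sum, 0.20)
  expect_equal(led$cases$max_abs_dzmb, abs(substitution_delta("D", "N")))
})
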
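# shared fixtures: random alignments/trees and brute-force oracles that stay
# independent of the pruning/parsimony implementations they check

aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_alignment <- function(n = 4, len = 10, seed = 1, gap_prob = 0) {
  set.seed(seed)
  seqs <- replicate(n, {
    s <- sample(aa_alphabet, len, replace = TRUE)
    if (gap_prob > 0) s[runif(len) < gap_prob] <- "-"
    paste(s, collapse = "")
  })
  new_alignment(tibble::tibble(id = paste0("t", seq_len(n)), seq = seqs))
}

random_rooted_tree <- function(n, seed = 1, depth = 1) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * depth
  prepare_tree(tr)
}

# exhaustive-likelihood oracle: sums over all internal-state assignments and
# rate categories; tractable for <= 4 tips (<= 3 internal nodes)
brute_force_loglik <- function(tr, column, model, rates, rho = 1) {
  tr <- prepare_tree(tr)
  idx <- mbcharge:::tree_index(tr)
  ntip <- idx$ntip
  n_int <- idx$nnode
  stopifnot(n_int <= 3)
  tip_idx <- function(ch) {
    r <- column[[idx$ids[ch]]]
    if (r %in% c("-", "X")) return(NA_integer_)
    match(r, aa_alphabet)
  }
  total <- 0
  for (k in seq_len(rates$K)) {
    P <- lapply(seq_len(nrow(idx$edge)), function(i) {
      prob_matrix(model, idx$blen[idx$edge[i, 2]] * rates$rates[k] * rho)
    })
    grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
    for (g in seq_len(nrow(grid))) {
      st <- c(rep(NA_integer_, ntip), grid[g, ])
      lik <- unname(model$pi[st[idx$root]])
      for (i in seq_len(nrow(idx$edge))) {
        ch <- idx$edge[i, 2]
        si <- if (ch <= ntip) tip_idx(ch) else st[ch]
        if (is.na(si)) next               # missing data: marginalised out
        lik <- lik * P[[i]][st[idx$edge[i, 1]], si]
      }
      total <- total + rates$weights[k] * lik
    }
  }
  log(total)
}

# brute-force minimum-change count: try all 2^n_internal labelings
brute_force_fitch <- function(tr, trait) {
  tr <- prepare_tree(tr)
  idx <- mbcharge:::tree_index(tr)
  states <- stats::setNames(trait$state, trait$tip_id)
  n_int <- idx$nnode
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    lab <- c(states[idx$tree$tip.label],
             as.integer(intToBits(mask))[seq_len(n_int)])
    changes <- sum(lab[idx$edge[, 1]] != lab[idx$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# closed-form GLS estimate (X' V^-1 X)^-1 X' V^-1 y, independent matrix path
gls_oracle <- function(V, x, y) {
  X <- cbind(1, x)
  Vi <- solve(V)
  as.numeric(solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y)
}
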
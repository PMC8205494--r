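# Maximum-likelihood marginal ancestral reconstruction on a fixed rooted
# tree: Felsenstein pruning with per-node rescaling, discrete-gamma rate
# mixing, and an inside-outside (up/down) pass for per-node site posteriors.

# --- tree bookkeeping -------------------------------------------------------

# internal representation: postorder edge list, children per node, branch
# length per node (length of the edge above it); root has none
tree_index <- function(tr) {
  tr <- prepare_tree(tr)
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tr, "postorder")
  blen <- rep(NA_real_, ntip + nnode)
  blen[po$edge[, 2]] <- if (is.null(po$edge.length)) 0 else po$edge.length
  children <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]
    children[[p]] <- c(children[[p]], po$edge[i, 2])
  }
  # postorder over internal nodes (parents appear after all descendants)
  internal_po <- unique(po$edge[, 1])
  list(tree = tr, ntip = ntip, nnode = nnode, root = root,
       edge = po$edge, blen = blen, children = children,
       internal_postorder = internal_po,
       ids = node_ids(tr))
}

# tip conditional likelihoods: list over tips of 20 x S matrices;
# gap/X = all-ones (missing data)
tip_partial_list <- function(aln, idx) {
  m <- aln_matrix(aln)
  if (!setequal(rownames(m), idx$tree$tip.label)) {
    miss <- setdiff(idx$tree$tip.label, rownames(m))
    extra <- setdiff(rownames(m), idx$tree$tip.label)
    abort(paste0("alignment/tree tip mismatch",
                 if (length(miss)) paste0("; missing from alignment: ",
                                          paste(miss, collapse = ", ")) else "",
                 if (length(extra)) paste0("; not in tree: ",
                                           paste(extra, collapse = ", ")) else ""))
  }
  m <- m[idx$tree$tip.label, , drop = FALSE]
  S <- ncol(m)
  lapply(seq_len(idx$ntip), function(i) {
    P <- matrix(0, 20, S, dimnames = list(AA_SYMBOLS, NULL))
    known <- m[i, ] %in% AA_SYMBOLS
    P[cbind(match(m[i, known], AA_SYMBOLS), which(known))] <- 1
    P[, !known] <- 1
    P
  })
}

# one pruning pass at a single rate; returns per-node partials (20 x S),
# per-node cumulative log-scaling (length S), for reuse by the down pass
prune_up <- function(idx, tips, model, rate, rho = 1) {
  n_all <- idx$ntip + idx$nnode
  S <- ncol(tips[[1]])
  partial <- vector("list", n_all)
  logscale <- vector("list", n_all)
  Pmats <- vector("list", n_all)
  for (i in seq_len(idx$ntip)) {
    partial[[i]] <- tips[[i]]
    logscale[[i]] <- numeric(S)
  }
  for (nd in idx$internal_postorder) {
    L <- matrix(1, 20, S)
    ls <- numeric(S)
    for (ch in idx$children[[nd]]) {
      P <- prob_matrix(model, idx$blen[ch] * rate * rho)
      Pmats[[ch]] <- P
      L <- L * (P %*% partial[[ch]])
      ls <- ls + logscale[[ch]]
    }
    cmax <- apply(L, 2, max)
    cmax[cmax == 0] <- 1
    partial[[nd]] <- sweep(L, 2, cmax, "/")
    logscale[[nd]] <- ls + log(cmax)
  }
  list(partial = partial, logscale = logscale, P = Pmats)
}

#' Log-likelihood of an alignment on a tree (pruning, discrete-gamma)
#'
#' Felsenstein pruning under a reversible empirical amino-acid model, with
#' gaps and `X` treated as missing data (all-ones tip partials) and rate
#' variation handled as a K-category discrete-gamma mixture. The root prior
#' is the model's stationary distribution; branch lengths are multiplied by
#' `rho` (a global rescaling from time units to substitutions/site).
#'
#' @param tr Rooted tree (`phylo`).
#' @param aln Amino-acid alignment tibble covering all tips.
#' @param model `mb_submodel` (see [substitution_model()]).
#' @param rates `mb_gamma_rates` (see [discrete_gamma_rates()]).
#' @param rho Global branch-length multiplier (default 1).
#' @return List: `loglik` (total), `site_loglik` (length = sites).
#' @export
tree_log_likelihood <- function(tr, aln, model, rates = discrete_gamma_rates(1, 1),
                                rho = 1) {
  idx <- tree_index(tr)
  tips <- tip_partial_list(aln, idx)
  S <- ncol(tips[[1]])
  site_ll_k <- matrix(NA_real_, rates$K, S)
  for (k in seq_len(rates$K)) {
    up <- prune_up(idx, tips, model, rates$rates[k], rho)
    rootlik <- as.numeric(model$pi %*% up$partial[[idx$root]])
    site_ll_k[k, ] <- log(rootlik) + up$logscale[[idx$root]]
  }
  m <- apply(site_ll_k, 2, max)
  site_ll <- m + log(colSums(rates$weights * exp(sweep(site_ll_k, 2, m, "-"))))
  list(loglik = sum(site_ll), site_loglik = site_ll)
}

#' Log-likelihood of a single site pattern
#'
#' @param tr Rooted tree.
#' @param column Named character vector of tip states (names = tip labels),
#'   or a character vector in `tr$tip.label` order.
#' @inheritParams tree_log_likelihood
#' @return Log-likelihood (scalar).
#' @export
site_log_likelihood <- function(tr, column, model,
                                rates = discrete_gamma_rates(1, 1), rho = 1) {
  tr <- prepare_tree(tr)
  if (is.null(names(column))) names(column) <- tr$tip.label
  aln <- new_alignment(tibble(id = names(column), seq = unname(column)))
  tree_log_likelihood(tr, aln, model, rates, rho)$site_loglik[1]
}

#' Fit the gamma shape and a global branch-length scaler
#'
#' The input tree is typically a chronogram (branch lengths in Ma); `rho`
#' converts it to expected substitutions per site, assumed clock-like, and
#' `alpha` is the discrete-gamma shape. Both are fitted by bounded
#' quasi-Newton maximisation of the pruning log-likelihood on the log scale
#' (alpha in [0.05, 50], rho in [1e-8, 10], tolerance 1e-6 in log-likelihood).
#'
#' @param tr Rooted tree with at least one positive branch length.
#' @param aln Alignment tibble.
#' @param model `mb_submodel`.
#' @param K Gamma categories (default 4).
#' @param init Optional named start values `c(alpha=, rho=)`.
#' @return List: `alpha`, `rho`, `loglik`, `rates` (`mb_gamma_rates`),
#'   `convergence`.
#' @export
fit_scaling <- function(tr, aln, model, K = 4, init = NULL) {
  idx <- tree_index(tr)
  if (all(idx$blen[!is.na(idx$blen)] <= 0)) abort("tree has no positive branch length")
  m <- aln_matrix(aln)
  variable <- any(apply(m, 2, function(col) {
    obs <- col[col %in% AA_SYMBOLS]
    length(unique(obs)) > 1
  }))
  if (!variable) {
    warn("alignment has no variable sites; rho is driven to its lower bound")
  }
  # guess rho from mean pairwise difference over tree depth
  depth <- mean(ape::node.depth.edgelength(idx$tree)[seq_len(idx$ntip)])
  pdiff <- mean(utils::combn(nrow(m), 2, function(ij) {
    a <- m[ij[1], ]; b <- m[ij[2], ]
    ok <- a %in% AA_SYMBOLS & b %in% AA_SYMBOLS
    if (!any(ok)) 0 else mean(a[ok] != b[ok])
  }))
  rho0 <- max(pdiff / max(2 * depth, 1e-6), 1e-6)
  start <- log(c(alpha = 1, rho = rho0))
  if (!is.null(init)) start <- log(c(alpha = init[["alpha"]], rho = init[["rho"]]))
  nll <- function(par) {
    a <- exp(par[1]); r <- exp(par[2])
    -tree_log_likelihood(idx$tree, aln, model, discrete_gamma_rates(a, K), r)$loglik
  }
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = log(c(0.05, 1e-8)), upper = log(c(50, 10)),
                      control = list(factr = 1e-6 / .Machine$double.eps))
  alpha <- exp(opt$par[1]); rho <- exp(opt$par[2])
  list(alpha = unname(alpha), rho = unname(rho), loglik = -opt$value,
       rates = discrete_gamma_rates(alpha, K), convergence = opt$convergence)
}

#' Marginal ancestral state posteriors at every internal node
#'
#' Inside-outside (up/down) pass: for each internal node and site, the
#' posterior over the 20 residues given all tip data, under the fitted model.
#' Rate categories are mixed per site by their posterior weight. The MAP
#' residue and its probability are tabulated per node and site.
#'
#' @inheritParams tree_log_likelihood
#' @return Object of class `mb_anc`: list with `posterior` (list over
#'   internal node ids of 20 x S matrices), `map` (tibble `node_id`, `site`,
#'   `residue`, `prob`), `loglik`, `tree`, plus the model/rate/rho config.
#' @export
marginal_reconstruct <- function(tr, aln, model,
                                 rates = discrete_gamma_rates(1, 1), rho = 1) {
  idx <- tree_index(tr)
  tips <- tip_partial_list(aln, idx)
  S <- ncol(tips[[1]])
  n_all <- idx$ntip + idx$nnode
  K <- rates$K

  site_ll_k <- matrix(NA_real_, K, S)
  post_k <- vector("list", K)      # [[k]][[node]] = unnormalised 20 x S
  for (k in seq_len(K)) {
    up <- prune_up(idx, tips, model, rates$rates[k], rho)
    rootlik <- as.numeric(model$pi %*% up$partial[[idx$root]])
    site_ll_k[k, ] <- log(rootlik) + up$logscale[[idx$root]]
    # down pass: outside[nd] = message from the rest of the tree
    outside <- vector("list", n_all)
    outside[[idx$root]] <- matrix(model$pi, 20, S)
    preorder <- rev(idx$internal_postorder)
    for (nd in preorder) {
      kids <- idx$children[[nd]]
      for (ch in kids) {
        if (ch <= idx$ntip) next
        sib_prod <- matrix(1, 20, S)
        for (sb in setdiff(kids, ch)) {
          sib_prod <- sib_prod * (up$P[[sb]] %*% up$partial[[sb]])
        }
        o <- t(up$P[[ch]]) %*% (outside[[nd]] * sib_prod)
        cmax <- apply(o, 2, max); cmax[cmax == 0] <- 1
        outside[[ch]] <- sweep(o, 2, cmax, "/")
      }
    }
    post_k[[k]] <- lapply((idx$ntip + 1L):n_all, function(nd) {
      p <- up$partial[[nd]] * outside[[nd]]
      sweep(p, 2, colSums(p), "/")          # normalised within category
    })
  }
  # per-site category posterior weights
  m <- apply(site_ll_k, 2, max)
  wk <- exp(sweep(site_ll_k, 2, m, "-")) * rates$weights
  wk <- sweep(wk, 2, colSums(wk), "/")       # K x S
  internal_ids <- idx$ids[(idx$ntip + 1L):n_all]
  posterior <- lapply(seq_len(idx$nnode), function(j) {
    p <- matrix(0, 20, S, dimnames = list(AA_SYMBOLS, NULL))
    for (k in seq_len(K)) p <- p + sweep(post_k[[k]][[j]], 2, wk[k, ], "*")
    p
  })
  names(posterior) <- internal_ids
  map <- purrr::map_dfr(internal_ids, function(id) {
    p <- posterior[[id]]
    i <- apply(p, 2, which.max)
    tibble(node_id = id, site = seq_len(S),
           residue = AA_SYMBOLS[i], prob = p[cbind(i, seq_len(S))])
  })
  site_ll <- m + log(colSums(rates$weights * exp(sweep(site_ll_k, 2, m, "-"))))
  out <- list(posterior = posterior, map = map, loglik = sum(site_ll),
              site_loglik = site_ll, tree = idx$tree, model = model,
              rates = rates, rho = rho)
  class(out) <- "mb_anc"
  out
}

#' @export
print.mb_anc <- function(x, ...) {
  cat(sprintf("Marginal ancestral reconstruction: %d internal nodes x %d sites, lnL = %.2f\n",
              length(x$posterior), max(x$map$site), x$loglik))
  invisible(x)
}

#' Tidy the MAP ancestral states
#' @param x An `mb_anc`.
#' @param ... Unused.
#' @return Tibble `node_id`, `site`, `residue`, `prob`.
#' @export
tidy.mb_anc <- function(x, ...) x$map

#' One-row model summary of a reconstruction
#' @param x An `mb_anc`.
#' @param ... Unused.
#' @return Tibble with `loglik`, `alpha`, `K`, `rho`, `n_nodes`, `n_sites`.
#' @export
glance.mb_anc <- function(x, ...) {
  tibble(loglik = x$loglik, alpha = x$rates$alpha, K = x$rates$K,
         rho = x$rho, n_nodes = length(x$posterior), n_sites = max(x$map$site))
}

# --- gap (indel) reconstruction --------------------------------------------

#' Parsimony reconstruction of gap presence/absence
#'
#' Columns where any tip carries `-` are treated as a binary
#' presence/absence character and reconstructed by Fitch parsimony, with
#' ambiguous nodes resolved toward "present" (a residue), matching the view
#' that deletions are derived. The result feeds ancestral sequence assembly:
#' an "absent" node gets `-` at that column.
#'
#' @param tr Rooted tree.
#' @param aln Tip alignment.
#' @param gap_columns Optional integer sites; default: all columns with a gap.
#' @return Tibble `node_id`, `site`, `present` (logical), covering tips and
#'   internal nodes for each gap column.
#' @export
reconstruct_gaps <- function(tr, aln, gap_columns = NULL) {
  idx <- tree_index(tr)
  m <- aln_matrix(aln)[idx$tree$tip.label, , drop = FALSE]
  if (is.null(gap_columns)) gap_columns <- which(apply(m == "-", 2, any))
  purrr::map_dfr(gap_columns, function(s) {
    states <- stats::setNames(as.integer(m[, s] != "-"), rownames(m)) # 1 = present
    fit <- fitch_parsimony(idx$tree, tibble(tip_id = names(states), state = states))
    res <- fitch_resolve(idx, fit$state_sets, prefer = 1L)
    tibble(node_id = idx$ids, site = s, present = res == 1L)
  })
}

# resolve Fitch state sets to a single state per node via a preorder pass;
# `prefer` breaks ties (at the root and wherever the parent state is absent
# from the child's set)
fitch_resolve <- function(idx, state_sets, prefer = 1L) {
  n_all <- idx$ntip + idx$nnode
  state <- integer(n_all)
  pick <- function(set) if (prefer %in% set) prefer else set[1]
  state[idx$root] <- pick(state_sets[[idx$root]])
  for (nd in rev(idx$internal_postorder)) {
    for (ch in idx$children[[nd]]) {
      ss <- state_sets[[ch]]
      state[ch] <- if (state[nd] %in% ss) state[nd] else pick(ss)
    }
  }
  state
}

#' Assemble MAP ancestral sequences (with gap states)
#'
#' Combines the per-site MAP residues of a marginal reconstruction with the
#' parsimony gap reconstruction into one sequence per internal node.
#'
#' @param anc An `mb_anc` from [marginal_reconstruct()].
#' @param aln The tip alignment (for gap columns).
#' @return Alignment tibble of internal-node sequences (`id` = node id).
#' @export
ancestral_sequences <- function(anc, aln) {
  S <- max(anc$map$site)
  mat <- anc$map |>
    dplyr::arrange(.data$node_id, .data$site)
  ids <- unique(mat$node_id)
  seqs <- vapply(ids, function(id) {
    paste(mat$residue[mat$node_id == id], collapse = "")
  }, character(1))
  gaps <- reconstruct_gaps(anc$tree, aln)
  if (nrow(gaps) > 0) {
    gl <- gaps[!gaps$present & gaps$node_id %in% ids, ]
    if (nrow(gl) > 0) {
      for (i in seq_len(nrow(gl))) {
        id <- gl$node_id[i]
        substr(seqs[id], gl$site[i], gl$site[i]) <- "-"
      }
    }
  }
  new_alignment(tibble(id = ids, seq = unname(seqs)))
}
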
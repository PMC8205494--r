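# Ancestral-lifestyle and trait-correlation inference: minimum-change
# parsimony with origin counting, Bayesian threshold-model ancestral states,
# liability-correlation MCMC, and lambda-fixed phylogenetic GLS.

# --- parsimony --------------------------------------------------------------

#' Minimum-change (Fitch) parsimony for a binary tip character
#'
#' Computes the minimal number of state changes on a rooted tree with equal
#' transition costs, by dynamic programming over per-node state costs (exact
#' on polytomies as well). State sets contain, per node, the states
#' attainable in at least one minimum-change reconstruction.
#'
#' @param tr Rooted tree (`phylo`).
#' @param trait Tibble `tip_id`, `state` (0/1) covering every tip.
#' @return List: `min_changes`, `state_sets` (list over node ids),
#'   `cost` (2-column matrix of subtree costs for states 0/1), `idx`
#'   (internal tree index).
#' @export
fitch_parsimony <- function(tr, trait) {
  idx <- tree_index(tr)
  states <- stats::setNames(trait$state, trait$tip_id)
  miss <- setdiff(idx$tree$tip.label, names(states))
  if (length(miss) > 0) {
    abort(paste0("missing tip state(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(states %in% c(0, 1))) abort("states must be 0/1")
  n_all <- idx$ntip + idx$nnode
  cost <- matrix(Inf, n_all, 2)
  for (i in seq_len(idx$ntip)) {
    s <- states[[idx$tree$tip.label[i]]]
    cost[i, s + 1] <- 0
  }
  for (nd in idx$internal_postorder) {
    for (s in 0:1) {
      tot <- 0
      for (ch in idx$children[[nd]]) {
        tot <- tot + min(cost[ch, s + 1], cost[ch, 2 - s] + 1)
      }
      cost[nd, s + 1] <- tot
    }
  }
  min_changes <- min(cost[idx$root, ])
  # states reachable in some MP reconstruction (top-down feasibility)
  feas <- matrix(FALSE, n_all, 2)
  feas[idx$root, ] <- cost[idx$root, ] == min_changes
  for (nd in rev(idx$internal_postorder)) {
    for (ch in idx$children[[nd]]) {
      for (sp in 0:1) {
        if (!feas[nd, sp + 1]) next
        best <- min(cost[ch, 1] + (sp != 0), cost[ch, 2] + (sp != 1))
        for (s in 0:1) {
          if (cost[ch, s + 1] + (sp != s) == best) feas[ch, s + 1] <- TRUE
        }
      }
    }
  }
  state_sets <- lapply(seq_len(n_all), function(v) which(feas[v, ]) - 1L)
  names(state_sets) <- idx$ids
  list(min_changes = min_changes, state_sets = state_sets,
       cost = cost, idx = idx)
}

#' Count independent origins of the derived state under parsimony
#'
#' Among all minimum-change reconstructions, counts 0 -> 1 transitions (a
#' derived root counts as one origin). When equally parsimonious
#' reconstructions disagree, the range is reported — e.g. a single origin
#' with a secondary loss versus two independent origins.
#'
#' @param tr Rooted tree.
#' @param trait Tibble `tip_id`, `state` (0/1).
#' @return Tibble: `min_changes`, `origins_min`, `origins_max`.
#' @export
count_origins <- function(tr, trait) {
  fit <- fitch_parsimony(tr, trait)
  idx <- fit$idx
  n_all <- idx$ntip + idx$nnode
  # lexicographic DP: among min-change labelings of the subtree rooted in
  # state s, the min and max number of 0->1 edges inside the subtree
  omin <- matrix(0, n_all, 2); omax <- matrix(0, n_all, 2)
  for (nd in idx$internal_postorder) {
    for (s in 0:1) {
      lo <- 0; hi <- 0
      for (ch in idx$children[[nd]]) {
        opts_lo <- c(); opts_hi <- c()
        best <- min(fit$cost[ch, 1] + (s != 0), fit$cost[ch, 2] + (s != 1))
        for (cs in 0:1) {
          if (fit$cost[ch, cs + 1] + (s != cs) == best) {
            gain <- as.integer(s == 0 && cs == 1)
            opts_lo <- c(opts_lo, omin[ch, cs + 1] + gain)
            opts_hi <- c(opts_hi, omax[ch, cs + 1] + gain)
          }
        }
        lo <- lo + min(opts_lo); hi <- hi + max(opts_hi)
      }
      omin[nd, s + 1] <- lo; omax[nd, s + 1] <- hi
    }
  }
  roots <- which(fit$cost[idx$root, ] == fit$min_changes) - 1L
  lo <- min(omin[idx$root, roots + 1] + roots)
  hi <- max(omax[idx$root, roots + 1] + roots)
  tibble(min_changes = fit$min_changes, origins_min = lo, origins_max = hi)
}

#' Enumerate all minimum-change reconstructions (small trees)
#'
#' @param tr Rooted tree.
#' @param trait Tibble `tip_id`, `state`.
#' @param max_solutions Safety cap (default 10000).
#' @return List of named integer vectors (internal node id -> state).
#' @export
enumerate_mp_solutions <- function(tr, trait, max_solutions = 10000) {
  fit <- fitch_parsimony(tr, trait)
  idx <- fit$idx
  sols <- list()
  assign_node <- function(order_pos, current) {
    if (length(sols) >= max_solutions) return()
    if (order_pos > length(order)) {
      sols[[length(sols) + 1]] <<- current
      return()
    }
    nd <- order[order_pos]
    if (nd == idx$root) {
      for (s in 0:1) {
        if (fit$cost[nd, s + 1] == fit$min_changes) {
          cur <- current; cur[idx$ids[nd]] <- s
          assign_node(order_pos + 1, cur)
        }
      }
    } else {
      parent <- parent_of[nd]
      sp <- current[[idx$ids[parent]]]
      best <- min(fit$cost[nd, 1] + (sp != 0), fit$cost[nd, 2] + (sp != 1))
      for (s in 0:1) {
        if (fit$cost[nd, s + 1] + (sp != s) == best) {
          cur <- current; cur[idx$ids[nd]] <- s
          assign_node(order_pos + 1, cur)
        }
      }
    }
  }
  parent_of <- integer(idx$ntip + idx$nnode)
  parent_of[idx$edge[, 2]] <- idx$edge[, 1]
  order <- rev(idx$internal_postorder)   # preorder over internal nodes
  assign_node(1, stats::setNames(integer(0), character(0)))
  sols
}

# --- threshold-model machinery ---------------------------------------------

# per-node branch variances under the Pagel-lambda transform of a tree:
# internal branches scaled by lambda, tip branches extended so each tip's
# root-to-tip variance is unchanged
lambda_branch_vars <- function(idx, lambda) {
  v <- idx$blen
  if (lambda < 1) {
    depth <- ape::node.depth.edgelength(idx$tree)
    ntip <- idx$ntip
    v <- v * lambda
    v[seq_len(ntip)] <- v[seq_len(ntip)] + (1 - lambda) * depth[seq_len(ntip)]
  }
  v
}

# truncated-normal draw on (0, Inf) (side = 1) or (-Inf, 0) (side = 0)
rtnorm_sign <- function(mu, sd, side) {
  lo <- stats::pnorm(0, mu, sd)
  u <- if (side == 1) lo + stats::runif(1) * (1 - lo) else stats::runif(1) * lo
  u <- min(max(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mu, sd)
}

mcmc_defaults <- function(mcmc, n_units) {
  def <- list(generations = 1e6, sample_every = 500, burn_in = 0.2, seed = 1)
  for (nm in names(mcmc)) def[[nm]] <- mcmc[[nm]]
  if (def$burn_in >= 1) abort("burn_in must be a fraction < 1")
  # a generation is one elementary parameter update; convert to full sweeps
  sweeps <- max(20L, ceiling(def$generations / n_units))
  thin <- max(1L, round(def$sample_every / n_units))
  burn <- ceiling(sweeps * def$burn_in)
  c(def, list(sweeps = sweeps, thin = thin, burn = burn))
}

#' Bayesian threshold-model ancestral states for a binary trait
#'
#' The binary character is modelled as the sign of an unobserved continuous
#' liability evolving on the tree by Brownian motion (unit rate; the sign is
#' scale-invariant so the rate is not identifiable) or by a Pagel-lambda
#' transform of it. Node liabilities are sampled by Gibbs draws from their
#' tree-structured Gaussian full conditionals — truncated at tips to match
#' the observed state — and lambda (when selected) by Metropolis on [0, 1].
#' Posterior probabilities of the derived state per internal node and a DIC
#' (deviance from the truncated-Gaussian tip likelihood) are returned.
#'
#' @param tr Rooted tree; ultrametric recommended (warning otherwise).
#' @param trait Tibble `tip_id`, `state` (0/1).
#' @param liability_model `"BM"` or `"lambda"`.
#' @param mcmc List overriding `generations` (elementary updates, default
#'   1e6), `sample_every` (default 500), `burn_in` (fraction, default 0.2),
#'   `seed`.
#' @return Object of class `mb_threshold_asr`: `node_prob` tibble
#'   (`node_id`, `p_derived`), `dic`, `lambda` samples (lambda model),
#'   `samples` (liability means), `ess_min`, config.
#' @export
threshold_asr <- function(tr, trait, liability_model = c("BM", "lambda"),
                          mcmc = list()) {
  liability_model <- match.arg(liability_model)
  idx <- tree_index(tr)
  if (!ape::is.ultrametric(idx$tree, tol = 1e-6)) {
    warn("tree is not ultrametric; threshold-model liabilities assume a time tree")
  }
  states <- stats::setNames(trait$state, trait$tip_id)
  miss <- setdiff(idx$tree$tip.label, names(states))
  if (length(miss) > 0) abort(paste0("missing tip state(s): ", paste(miss, collapse = ", ")))
  n_all <- idx$ntip + idx$nnode
  ctl <- mcmc_defaults(mcmc, n_units = n_all + (liability_model == "lambda"))
  set.seed(ctl$seed)

  parent_of <- integer(n_all); parent_of[idx$edge[, 2]] <- idx$edge[, 1]
  tipstate <- states[idx$tree$tip.label]
  eps <- 1e-8 * max(idx$blen, na.rm = TRUE)
  lambda <- 1
  v <- pmax(lambda_branch_vars(idx, lambda), eps)
  # init liabilities: +-1 at tips by state, 0 internal
  l <- numeric(n_all)
  l[seq_len(idx$ntip)] <- ifelse(tipstate == 1, 1, -1)

  bm_loglik <- function(l, v) {
    d <- l[idx$edge[, 2]] - l[idx$edge[, 1]]
    vv <- v[idx$edge[, 2]]
    -0.5 * sum(d^2 / vv + log(2 * pi * vv))
  }
  tip_deviance <- function(l, v) {
    # probability of each observed tip state given its parent's liability
    mu <- l[parent_of[seq_len(idx$ntip)]]
    sd <- sqrt(v[seq_len(idx$ntip)])
    p1 <- stats::pnorm(0, mu, sd, lower.tail = FALSE)
    p <- ifelse(tipstate == 1, p1, 1 - p1)
    -2 * sum(log(pmax(p, 1e-300)))
  }

  n_keep <- floor((ctl$sweeps - ctl$burn) / ctl$thin)
  p_pos <- numeric(n_all); lbar <- numeric(n_all); kept <- 0
  lambda_samples <- numeric(0)
  dev_samples <- numeric(0)
  root_trace <- numeric(0)
  for (it in seq_len(ctl$sweeps)) {
    for (nd in seq_len(n_all)) {
      prec <- 0; wsum <- 0
      if (nd != idx$root) {
        prec <- prec + 1 / v[nd]
        wsum <- wsum + l[parent_of[nd]] / v[nd]
      }
      for (ch in idx$children[[nd]]) {
        prec <- prec + 1 / v[ch]
        wsum <- wsum + l[ch] / v[ch]
      }
      mu <- wsum / prec; sd <- sqrt(1 / prec)
      if (nd <= idx$ntip) {
        l[nd] <- rtnorm_sign(mu, sd, tipstate[nd])
      } else {
        l[nd] <- stats::rnorm(1, mu, sd)
      }
    }
    if (liability_model == "lambda") {
      prop <- lambda + stats::rnorm(1, 0, 0.1)
      if (prop >= 0 && prop <= 1) {
        vp <- pmax(lambda_branch_vars(idx, prop), eps)
        if (log(stats::runif(1)) < bm_loglik(l, vp) - bm_loglik(l, v)) {
          lambda <- prop; v <- vp
        }
      }
    }
    if (it > ctl$burn && (it - ctl$burn) %% ctl$thin == 0) {
      kept <- kept + 1
      p_pos <- p_pos + (l > 0)
      lbar <- lbar + l
      lambda_samples <- c(lambda_samples, lambda)
      dev_samples <- c(dev_samples, tip_deviance(l, v))
      root_trace <- c(root_trace, l[idx$root])
    }
  }
  p_pos <- p_pos / kept; lbar <- lbar / kept
  v_fin <- if (liability_model == "lambda") {
    pmax(lambda_branch_vars(idx, mean(lambda_samples)), eps)
  } else v
  dic <- 2 * mean(dev_samples) - tip_deviance(lbar, v_fin)
  ess <- ess_of(root_trace)
  if (ess < 100) warn(sprintf("low effective sample size (%.0f) for the root liability", ess))
  out <- list(
    node_prob = tibble(node_id = idx$ids[(idx$ntip + 1L):n_all],
                       p_derived = p_pos[(idx$ntip + 1L):n_all]),
    tip_prob = tibble(node_id = idx$ids[seq_len(idx$ntip)],
                      p_derived = p_pos[seq_len(idx$ntip)]),
    dic = dic, liability_model = liability_model,
    lambda = if (liability_model == "lambda") lambda_samples else NULL,
    liability_mean = tibble(node_id = idx$ids, liability = lbar),
    ess = ess, n_samples = kept, mcmc = ctl)
  class(out) <- "mb_threshold_asr"
  out
}

#' @export
print.mb_threshold_asr <- function(x, ...) {
  cat(sprintf("Threshold-model ancestral states (%s liability): %d nodes, DIC = %.1f\n",
              x$liability_model, nrow(x$node_prob), x$dic))
  invisible(x)
}

#' Tidy per-node derived-state posterior probabilities
#' @param x An `mb_threshold_asr`.
#' @param ... Unused.
#' @return Tibble `node_id`, `p_derived`.
#' @export
tidy.mb_threshold_asr <- function(x, ...) x$node_prob

#' @export
glance.mb_threshold_asr <- function(x, ...) {
  tibble(dic = x$dic, liability_model = x$liability_model,
         lambda = if (is.null(x$lambda)) NA_real_ else mean(x$lambda),
         n_samples = x$n_samples, ess = x$ess)
}

# crude autocorrelation-based effective sample size
ess_of <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

# shortest interval containing `prob` of the samples
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, floor(prob * n))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Liability-model correlation between a continuous trait and a binary trait
#'
#' Bivariate Brownian model on the tree: the continuous trait (here Z_Mb)
#' and the binary trait's latent liability evolve as correlated Brownian
#' motions; the observed state is the sign of the tip liability. The MCMC
#' samples the Brownian rate of the continuous trait, the correlation r, the
#' two root means (random-walk Metropolis, proposal scales tuned during
#' burn-in) and the tip liabilities (exact Gibbs draws from their truncated
#' Gaussian conditionals). The liability rate is fixed at 1 for
#' identifiability. Priors: flat on the root means, log-uniform-equivalent
#' weakly informative on the rate, uniform on r in (-1, 1).
#'
#' @param tr Rooted tree.
#' @param continuous Tibble `tip_id`, `value` (e.g. Z_Mb per tip), or a
#'   named numeric vector.
#' @param trait Tibble `tip_id`, `state` (0/1).
#' @param mcmc List overriding `generations` (default 1e6 elementary
#'   updates), `sample_every` (500), `burn_in` (0.2), `seed`.
#' @return Object of class `mb_threshbayes`: `r_samples`, `r_mean`,
#'   `r_hpd`, `ess`, full parameter samples, config.
#' @export
threshbayes_correlation <- function(tr, continuous, trait, mcmc = list()) {
  idx <- tree_index(tr)
  if (is.numeric(continuous)) {
    continuous <- tibble(tip_id = names(continuous), value = unname(continuous))
  }
  x <- stats::setNames(continuous$value, continuous$tip_id)[idx$tree$tip.label]
  s <- stats::setNames(trait$state, trait$tip_id)[idx$tree$tip.label]
  if (anyNA(x) || anyNA(s)) abort("both traits must cover every tip")
  if (stats::sd(x) == 0) abort("continuous trait is constant")
  n <- idx$ntip
  ctl <- mcmc_defaults(mcmc, n_units = n + 4)
  set.seed(ctl$seed)

  C <- ape::vcv(idx$tree)
  Ci <- solve(C)
  logdetC <- determinant(C, logarithm = TRUE)$modulus[1]

  # parameters: a1, a2 (root means), s1 (sd scale of continuous), r
  a1 <- mean(x); a2 <- 0; s1 <- stats::sd(x); r <- 0
  l <- ifelse(s == 1, 0.5, -0.5) * sqrt(diag(C))

  u <- as.numeric(Ci %*% (l - a2))   # Ci (l - a2)
  w <- as.numeric(Ci %*% (x - a1))   # Ci (x - a1)

  loglik <- function(a1, a2, s1, r, u, w) {
    R <- matrix(c(s1^2, r * s1, r * s1, 1), 2)
    M11 <- sum((x - a1) * w); M12 <- sum((x - a1) * u); M22 <- sum((l - a2) * u)
    Rdet <- s1^2 * (1 - r^2)
    Rinv <- matrix(c(1, -r * s1, -r * s1, s1^2), 2) / Rdet
    -0.5 * (n * log(Rdet) + 2 * logdetC +
              Rinv[1, 1] * M11 + 2 * Rinv[1, 2] * M12 + Rinv[2, 2] * M22) -
      n * log(2 * pi)
  }

  sds <- c(a1 = stats::sd(x) / 4, a2 = 0.5, ls1 = 0.2, zr = 0.3)
  acc <- c(0, 0, 0, 0); try_n <- c(0, 0, 0, 0)
  cur_ll <- loglik(a1, a2, s1, r, u, w)

  keep_r <- numeric(0); keep_s1 <- numeric(0); keep_a <- NULL
  for (it in seq_len(ctl$sweeps)) {
    # Gibbs: tip liabilities, one at a time (conditional of a kronecker MVN)
    Rdet <- s1^2 * (1 - r^2)
    k21 <- -r * s1 / Rdet      # Rinv[2,1]
    k22 <- s1^2 / Rdet         # Rinv[2,2]
    for (i in seq_len(n)) {
      prec <- k22 * Ci[i, i]
      lin <- k21 * w[i] + k22 * u[i] - prec * (l[i] - a2)
      mu <- a2 - lin / prec
      sd_i <- sqrt(1 / prec)
      newl <- rtnorm_sign(mu, sd_i, s[i])
      dl <- newl - l[i]
      if (dl != 0) { u <- u + Ci[, i] * dl; l[i] <- newl }
    }
    cur_ll <- loglik(a1, a2, s1, r, u, w)
    # Metropolis: a1, a2, log s1, atanh r
    for (j in 1:4) {
      p_a1 <- a1; p_a2 <- a2; p_s1 <- s1; p_r <- r
      if (j == 1) p_a1 <- a1 + stats::rnorm(1, 0, sds[1])
      if (j == 2) p_a2 <- a2 + stats::rnorm(1, 0, sds[2])
      if (j == 3) p_s1 <- exp(log(s1) + stats::rnorm(1, 0, sds[3]))
      if (j == 4) {
        p_r <- tanh(atanh(r) + stats::rnorm(1, 0, sds[4]))
        if (abs(p_r) > 0.9999) next
      }
      p_u <- if (j == 2) u + as.numeric(Ci %*% rep(a2 - p_a2, n)) else u
      p_w <- if (j == 1) w + as.numeric(Ci %*% rep(a1 - p_a1, n)) else w
      # Jacobians: log for s1 (prior ~ 1/s1 cancels), atanh for r makes the
      # implied prior on r uniform-equivalent after the 1 - r^2 factor
      lj <- 0
      if (j == 3) lj <- log(p_s1) - log(s1)
      if (j == 4) lj <- log(1 - p_r^2) - log(1 - r^2)
      p_ll <- loglik(p_a1, p_a2, p_s1, p_r, p_u, p_w)
      try_n[j] <- try_n[j] + 1
      if (log(stats::runif(1)) < p_ll - cur_ll + lj) {
        a1 <- p_a1; a2 <- p_a2; s1 <- p_s1; r <- p_r
        u <- p_u; w <- p_w; cur_ll <- p_ll
        acc[j] <- acc[j] + 1
      }
    }
    if (it <= ctl$burn && it %% 50 == 0) {
      rate <- ifelse(try_n > 0, acc / try_n, 0.3)
      sds <- sds * ifelse(rate > 0.4, 1.3, ifelse(rate < 0.2, 0.75, 1))
      acc[] <- 0; try_n[] <- 0
    }
    if (it > ctl$burn && (it - ctl$burn) %% ctl$thin == 0) {
      keep_r <- c(keep_r, r); keep_s1 <- c(keep_s1, s1)
      keep_a <- rbind(keep_a, c(a1, a2))
    }
  }
  ess <- ess_of(keep_r)
  if (ess < 100) warn(sprintf("low effective sample size (%.0f) for r", ess))
  out <- list(r_samples = keep_r, r_mean = mean(keep_r),
              r_hpd = hpd_interval(keep_r, 0.95),
              sigma_samples = keep_s1, mean_samples = keep_a,
              ess = ess, n_samples = length(keep_r), mcmc = ctl)
  class(out) <- "mb_threshbayes"
  out
}

#' @export
print.mb_threshbayes <- function(x, ...) {
  cat(sprintf("Liability correlation: r = %.3f (95%% HPD %.3f to %.3f, ESS %.0f)\n",
              x$r_mean, x$r_hpd[1], x$r_hpd[2], x$ess))
  invisible(x)
}

#' Tidy the correlation posterior
#' @param x An `mb_threshbayes`.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `hpd_lower`, `hpd_upper`,
#'   `ess`.
#' @export
tidy.mb_threshbayes <- function(x, ...) {
  tibble(term = "correlation", estimate = x$r_mean,
         hpd_lower = unname(x$r_hpd[1]), hpd_upper = unname(x$r_hpd[2]),
         ess = x$ess)
}

#' @export
glance.mb_threshbayes <- function(x, ...) {
  tibble(r_mean = x$r_mean, hpd_lower = unname(x$r_hpd[1]),
         hpd_upper = unname(x$r_hpd[2]), ess = x$ess,
         n_samples = x$n_samples)
}

#' Posterior density plot for the liability correlation
#' @param object An `mb_threshbayes`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_threshbayes <- function(object, ...) {
  df <- tibble(r = object$r_samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_density(fill = "#74add1", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$r_hpd, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$r_mean) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "correlation r", y = "posterior density") +
    ggplot2::theme_minimal()
}

# --- PGLS -------------------------------------------------------------------

#' Phylogenetic generalised least squares with fixed lambda
#'
#' GLS regression of y on x with residual covariance proportional to the
#' Pagel-lambda transform of the tree's shared-path-length matrix C:
#' off-diagonals scaled by lambda (fixed, not estimated; default 1, pure
#' Brownian). With lambda = 0 the fit reduces to ordinary least squares.
#'
#' @param tr Rooted tree with branch lengths.
#' @param data Tibble with columns `tip_id`, `x`, `y` (tips may be a subset
#'   of the tree; the tree is pruned).
#' @param lambda Fixed Pagel's lambda in [0, 1] (default 1).
#' @return Object of class `mb_pgls`: coefficients, their SEs, `r_squared`
#'   (GLS definition), `sigma2`, two-sided `p_value` for the slope, `lambda`,
#'   `n`.
#' @export
pgls_fit <- function(tr, data, lambda = 1) {
  stopifnot(all(c("tip_id", "x", "y") %in% names(data)))
  if (nrow(data) < 3) abort("need at least 3 tips for PGLS")
  tr <- prepare_tree(tr)
  drop <- setdiff(tr$tip.label, data$tip_id)
  if (length(drop) > 0) tr <- prepare_tree(ape::drop.tip(tr, drop))
  miss <- setdiff(data$tip_id, tr$tip.label)
  if (length(miss) > 0) abort(paste0("tips not in tree: ", paste(miss, collapse = ", ")))
  C <- ape::vcv(tr)
  ord <- match(rownames(C), data$tip_id)
  x <- data$x[ord]; y <- data$y[ord]
  V <- lambda * C + (1 - lambda) * diag(diag(C), nrow(C))
  Vi <- tryCatch(solve(V), error = function(e) abort("singular phylogenetic covariance"))
  X <- cbind(intercept = 1, slope = x)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid <- y - X %*% beta
  n <- length(y); p <- 2
  sigma2 <- as.numeric(t(resid) %*% Vi %*% resid) / (n - p)
  covb <- sigma2 * solve(XtVi %*% X)
  se <- sqrt(diag(covb))
  tstat <- beta[2] / se[2]
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  # GLS R^2 against the GLS intercept-only model
  one <- matrix(1, n, 1)
  mu0 <- as.numeric(solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% y))
  ss_tot <- as.numeric(t(y - mu0) %*% Vi %*% (y - mu0))
  ss_res <- as.numeric(t(resid) %*% Vi %*% resid)
  out <- list(coefficients = stats::setNames(as.numeric(beta), c("intercept", "slope")),
              se = stats::setNames(se, c("intercept", "slope")),
              r_squared = 1 - ss_res / ss_tot, sigma2 = sigma2,
              p_value = pval, lambda = lambda, n = n,
              fitted = as.numeric(X %*% beta), residuals = as.numeric(resid),
              data = tibble(tip_id = rownames(C), x = x, y = y))
  class(out) <- "mb_pgls"
  out
}

#' @export
print.mb_pgls <- function(x, ...) {
  cat(sprintf("PGLS (lambda = %.2f, n = %d): y = %.4f x + %.4f, R2 = %.3f, p = %.3g\n",
              x$lambda, x$n, x$coefficients["slope"], x$coefficients["intercept"],
              x$r_squared, x$p_value))
  invisible(x)
}

#' Tidy PGLS coefficients
#' @param x An `mb_pgls`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std_error`.
#' @export
tidy.mb_pgls <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients), std_error = unname(x$se))
}

#' @export
glance.mb_pgls <- function(x, ...) {
  tibble(r_squared = x$r_squared, sigma2 = x$sigma2, p_value = x$p_value,
         lambda = x$lambda, n = x$n)
}

#' Scatter + fitted-line plot for a PGLS fit
#' @param object An `mb_pgls`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_pgls <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$coefficients["intercept"],
                         slope = object$coefficients["slope"]) +
    ggplot2::labs(x = "net surface charge (e)", y = "relative mobility",
                  subtitle = sprintf("y = %.4f x + %.4f, R2 = %.3f",
                                     object$coefficients["slope"],
                                     object$coefficients["intercept"],
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
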
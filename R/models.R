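#' Empirical amino-acid substitution model
#'
#' Builds a reversible 20-state rate matrix Q = S diag(pi) from an empirical
#' exchangeability matrix S and stationary frequencies pi, with rows summing
#' to zero and scaled so the expected number of substitutions per site per
#' unit branch length is 1. The bundled empirical tables (Dayhoff by default;
#' JTT, LG, WAG also available) are taken from phangorn's model library;
#' alternatively a plain-text exchangeability file can be supplied.
#'
#' @param name Model name (default `"Dayhoff"`).
#' @param exchangeabilities Optional 20x20 symmetric matrix (rows/cols in the
#'   standard order `r AA_SYMBOLS`) overriding the named model.
#' @param frequencies Optional length-20 stationary frequencies summing to 1.
#' @return An object of class `mb_submodel`: list with `name`, `S`, `pi`,
#'   `Q`, and the eigensystem used for fast transition probabilities.
#' @export
substitution_model <- function(name = "Dayhoff", exchangeabilities = NULL,
                               frequencies = NULL) {
  if (is.null(exchangeabilities) || is.null(frequencies)) {
    got <- phangorn_model(name)
    if (is.null(exchangeabilities)) {
      S <- matrix(0, 20, 20)
      S[lower.tri(S)] <- got$Q
      S <- S + t(S)
      exchangeabilities <- S
    }
    if (is.null(frequencies)) frequencies <- unname(got$bf)
  }
  S <- unname(as.matrix(exchangeabilities))
  pi <- as.numeric(frequencies)
  stopifnot(nrow(S) == 20, ncol(S) == 20, length(pi) == 20)
  if (max(abs(S - t(S))) > 1e-8) abort("exchangeability matrix must be symmetric")
  if (any(pi <= 0)) abort("stationary frequencies must be positive")
  pi <- pi / sum(pi)
  dimnames(S) <- list(AA_SYMBOLS, AA_SYMBOLS)
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # expected rate; normalise to 1
  Q <- Q / mu
  # reversible Q: symmetrise with sqrt(pi) and eigendecompose once
  d <- sqrt(pi)
  A <- diag(d) %*% Q %*% diag(1 / d)
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  out <- list(name = name, S = S, pi = stats::setNames(pi, AA_SYMBOLS), Q = Q,
              eigenvalues = es$values,
              U1 = diag(1 / d) %*% es$vectors,    # P(t) = U1 diag(e^{lambda t}) U2
              U2 = t(es$vectors) %*% diag(d))
  class(out) <- "mb_submodel"
  out
}

# phangorn's model library stores exchangeabilities as the 190-element lower
# triangle (standard residue order) and assigns Q/bf into the caller's frame
phangorn_model <- function(name) {
  getter <- get("getModelAA", asNamespace("phangorn"))
  Q <- NULL; bf <- NULL
  getter(name, bf = TRUE, Q = TRUE)
  list(Q = Q, bf = bf)
}

#' @export
print.mb_submodel <- function(x, ...) {
  cat(sprintf("Reversible amino-acid model '%s' (20 states, mean rate 1)\n", x$name))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model An `mb_submodel`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 20x20 stochastic matrix.
#' @export
prob_matrix <- function(model, t) {
  if (t < 0) abort("branch length must be non-negative")
  P <- model$U1 %*% (exp(model$eigenvalues * t) * model$U2)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate categories
#'
#' Among-site rate heterogeneity is approximated by K equal-probability
#' categories of a gamma(alpha, alpha) distribution (mean 1). Category rates
#' are the conditional means of the distribution within each quantile band,
#' computed in closed form via the incomplete-gamma identity
#' \eqn{E[X; X<q] = P(q; alpha+1, alpha)} for gamma(alpha, alpha), so the
#' weighted mean rate is exactly 1.
#'
#' @param alpha Shape parameter (> 0).
#' @param K Number of categories (>= 1).
#' @return Object of class `mb_gamma_rates`: list with `alpha`, `K`,
#'   `rates`, `weights`.
#' @export
discrete_gamma_rates <- function(alpha, K = 4) {
  if (alpha <= 0) abort("alpha must be positive")
  K <- as.integer(K)
  if (K < 1) abort("K must be >= 1")
  if (K == 1) {
    out <- list(alpha = alpha, K = 1L, rates = 1, weights = 1)
  } else {
    q <- stats::qgamma(seq_len(K - 1) / K, shape = alpha, rate = alpha)
    cum <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
    rates <- K * diff(cum)
    out <- list(alpha = alpha, K = K, rates = rates, weights = rep(1 / K, K))
  }
  class(out) <- "mb_gamma_rates"
  out
}

#' @export
print.mb_gamma_rates <- function(x, ...) {
  cat(sprintf("Discrete-gamma rates: alpha = %.4g, K = %d\n", x$alpha, x$K))
  cat("  rates:", paste(sprintf("%.4f", x$rates), collapse = " "), "\n")
  invisible(x)
}
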
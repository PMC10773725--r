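# ---- substitution model ---------------------------------------------------

#' HKY+Gamma substitution model
#'
#' Defines an HKY85 rate matrix with transition/transversion rate ratio
#' `kappa` and stationary base frequencies `base_freqs` (order A, C, G, T),
#' scaled so that one unit of edge length equals one expected substitution
#' per site at the stationary distribution. Rate variation across sites uses
#' the discrete gamma approximation with `n_rate_categories` equal-weight
#' categories whose rates are the within-bin means of a Gamma(shape =
#' `gamma_shape`, mean 1) distribution, so the category rates average
#' exactly 1. With `n_rate_categories = 1` the model is rate-homogeneous
#' and `gamma_shape` is ignored.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Numeric length-4 vector of frequencies (A, C, G, T),
#'   all positive, summing to 1.
#' @param gamma_shape Gamma shape parameter alpha (> 0) for rates across
#'   sites.
#' @param n_rate_categories Number of discrete gamma categories (>= 1).
#' @return An object of class `"subst_model"` carrying the scaled rate
#'   matrix, its eigendecomposition, and the category rates.
#' @examples
#' m <- hky_model(kappa = 2, base_freqs = c(0.1, 0.2, 0.3, 0.4),
#'                gamma_shape = 1, n_rate_categories = 4)
#' rowSums(transition_matrix(m, 0.3))  # each row sums to 1
#' @export
hky_model <- function(kappa = 2, base_freqs = rep(0.25, 4),
                      gamma_shape = 1, n_rate_categories = 4) {
  stopifnot(kappa > 0, length(base_freqs) == 4, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8, n_rate_categories >= 1)
  pi <- base_freqs / sum(base_freqs)
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  transitions <- rbind(c(1L, 3L), c(2L, 4L))  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- any((transitions[, 1] == min(i, j)) & (transitions[, 2] == max(i, j)))
    Q[i, j] <- pi[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))           # mean rate at stationarity
  Q <- Q / mu
  # reversible => similar to a symmetric matrix; eigendecompose that
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  U <- diag(1 / sp) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(sp)
  rates <- if (n_rate_categories == 1L) 1 else
    discrete_gamma_rates(gamma_shape, n_rate_categories)
  structure(list(kappa = kappa, pi = pi, gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 Q = Q, U = U, Uinv = Uinv, lambda = e$values, rates = rates),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> HKY kappa=%g, pi=(%s)", x$kappa,
              paste(signif(x$pi, 3), collapse = ", ")))
  if (x$n_rate_categories > 1L)
    cat(sprintf(" + Gamma(alpha=%g), %d categories", x$gamma_shape,
                x$n_rate_categories))
  cat("\n")
  invisible(x)
}

#' Discrete gamma category rates (equal-weight bins, bin-mean variant)
#'
#' @param alpha Gamma shape (> 0); the rate distribution is Gamma(alpha,
#'   alpha) so its mean is 1.
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean exactly 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean of Gamma(alpha, alpha) over [q_i, q_{i+1}], times k (bin prob 1/k)
  upper <- pgamma(q[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(q[-(k + 1)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

#' Transition probability matrix P(t)
#'
#' @param model A `"subst_model"`.
#' @param t Edge length (expected substitutions/site, >= 0).
#' @param rate Relative site rate multiplier.
#' @return 4x4 stochastic matrix, rows = ancestral state (A,C,G,T).
#' @export
transition_matrix <- function(model, t, rate = 1) {
  P <- model$U %*% diag(exp(model$lambda * t * rate)) %*% model$Uinv
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}

model_for_engine <- function(model) {
  list(U = model$U, Uinv = model$Uinv, lambda = model$lambda,
       pi = model$pi, rates = model$rates)
}
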
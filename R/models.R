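#' Reversible nucleotide substitution models
#'
#' Constructs a time-reversible substitution model from one of the standard
#' nested families, with optional discrete-gamma rate variation and a
#' proportion of invariant sites. The rate matrix is scaled so that one unit
#' of branch length equals one expected substitution per site at equilibrium
#' (the gamma category rates are rescaled by `1/(1 - pinv)` so the mean rate
#' of the full mixture is 1).
#'
#' Family parameters:
#' * `JC69` - none (equal rates, equal frequencies)
#' * `K80` - `kappa` (transition/transversion), equal frequencies
#' * `HKY85` - `kappa`, free frequencies
#' * `TN93` - `kappa1` (A<->G), `kappa2` (C<->T), free frequencies
#' * `GTR` - `rates`, six exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (GT is the reference and is normalized to 1)
#'
#' @param family model family name.
#' @param bf base frequencies (A, C, G, T); ignored (forced equal) for
#'   JC69/K80.
#' @param kappa,kappa1,kappa2,rates family-specific rate parameters.
#' @param alpha gamma shape (> 0); only used when `ncat > 1`.
#' @param ncat number of discrete gamma categories (1 = no rate variation).
#' @param pinv proportion of invariant sites in `[0, 1)`.
#' @return object of class `subst_model` carrying the scaled rate matrix `Q`,
#'   its eigen-decomposition, the category rates and all parameters.
#' @examples
#' m <- subst_model("HKY85", bf = c(.3, .2, .2, .3), kappa = 4,
#'                  alpha = 0.5, ncat = 4, pinv = 0.1)
#' m$Q
#' @export
subst_model <- function(family = c("JC69", "K80", "HKY85", "TN93", "GTR"),
                        bf = rep(0.25, 4), kappa = 2, kappa1 = 2, kappa2 = 2,
                        rates = rep(1, 6), alpha = 1, ncat = 1L, pinv = 0) {
  family <- match.arg(family)
  if (family %in% c("JC69", "K80")) bf <- rep(0.25, 4)
  stopifnot(length(bf) == 4, all(bf > 0), alpha > 0, ncat >= 1,
            pinv >= 0, pinv < 1)
  bf <- bf / sum(bf)
  ex <- switch(family,
    JC69  = rep(1, 6),
    K80   = c(1, kappa, 1, 1, kappa, 1),
    HKY85 = c(1, kappa, 1, 1, kappa, 1),
    TN93  = c(1, kappa1, 1, 1, kappa2, 1),
    GTR   = rates / rates[6])
  if (any(ex <= 0)) stop("rate parameters must be positive")
  params <- switch(family,
    JC69 = list(), K80 = list(kappa = kappa), HKY85 = list(kappa = kappa),
    TN93 = list(kappa1 = kappa1, kappa2 = kappa2), GTR = list(rates = ex))
  Q <- build_q(ex, bf)
  gr <- if (ncat == 1L) 1 else discrete_gamma_rates(alpha, ncat)
  gr <- gr / (1 - pinv)
  structure(list(family = family, bf = bf, params = params,
                 alpha = alpha, ncat = as.integer(ncat), pinv = pinv,
                 Q = Q, eig = rev_eigen(Q, bf), rates = gr),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(x$family,
      if (x$ncat > 1) sprintf("+G%d(alpha=%.3g)", x$ncat, x$alpha) else "",
      if (x$pinv > 0) sprintf("+I(%.3g)", x$pinv) else "", "\n", sep = "")
  if (length(x$params)) {
    p <- unlist(x$params)
    cat(" ", paste(names(p), signif(p, 4), sep = "=", collapse = " "), "\n")
  }
  cat("  bf:", paste(signif(x$bf, 4), collapse = " "), "\n")
  invisible(x)
}

# Q from exchangeabilities (AC AG AT CG CT GT) and frequencies; mean rate 1
build_q <- function(ex, bf) {
  s <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  s[1, 2] <- ex[1]; s[1, 3] <- ex[2]; s[1, 4] <- ex[3]
  s[2, 3] <- ex[4]; s[2, 4] <- ex[5]; s[3, 4] <- ex[6]
  s <- s + t(s)
  Q <- s * rep(bf, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q / mu
}

# eigen-decomposition of a reversible Q via symmetrization:
# B = D^(1/2) Q D^(-1/2) symmetric; Q = (D^(-1/2) V) L (V' D^(1/2))
rev_eigen <- function(Q, bf) {
  d <- sqrt(bf)
  B <- (Q * d) / rep(d, each = 4)   # B_ij = d_i Q_ij / d_j, symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / d, Uinv = t(e$vectors) * rep(d, each = 4),
       lambda = e$values)
}

# Yang (1994) equal-probability discrete gamma: category mean rates
discrete_gamma_rates <- function(alpha, ncat) {
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha,
                     rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- ncat * diff(p)
  r / mean(r) * 1  # exact mean 1 up to rounding
}

# transition probability matrix, mostly for simulation and tests
pmatrix <- function(model, t) {
  e <- model$eig
  P <- e$U %*% (exp(e$lambda * t) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
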
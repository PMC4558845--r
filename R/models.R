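## Substitution models: the empirical WAG amino-acid model (exchangeabilities
## read from a PAML-layout rate file, generator scaled to one expected
## substitution per site) and the Kimura two-parameter nucleotide model.
## Transition probabilities come from the symmetric eigendecomposition of
## pi^{1/2} Q pi^{-1/2}, which a reversible generator guarantees has a real
## spectrum and makes repeated P(t) evaluations cheap.

#' Read a PAML-layout amino-acid rate file
#'
#' Lower-triangle exchangeabilities (19 rows) followed by the 20 equilibrium
#' frequencies, amino acids in PAML order `ARNDCQEGHILKMFPSTWYV`.
#'
#' @param path rate file.
#' @return list with `exchangeabilities` (symmetric 20x20) and `freqs`.
#' @export
read_paml_matrix <- function(path) {
  nums <- scan(path, quiet = TRUE)
  if (length(nums) < 210L) stop("expected 190 exchangeabilities + 20 frequencies")
  ex <- nums[1:190]
  freqs <- nums[191:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) { S[i, j] <- S[j, i] <- ex[k]; k <- k + 1L }
  freqs <- freqs / sum(freqs)
  names(freqs) <- AA_LETTERS
  list(exchangeabilities = S, freqs = freqs)
}

#' Construct a reversible amino-acid model
#'
#' Builds the generator Q with off-diagonals S_ij * pi_j, scaled so the
#' expected number of substitutions per site per unit time is 1, and caches
#' its spectral decomposition.
#'
#' @param exchangeabilities symmetric non-negative 20x20 matrix.
#' @param freqs equilibrium frequencies (sum 1).
#' @param gamma_shape optional discrete-Gamma shape alpha (> 0).
#' @param n_categories Gamma categories (>= 1).
#' @return object of class `"aa_model"`.
#' @export
aa_model <- function(exchangeabilities, freqs, gamma_shape = NULL,
                     n_categories = 1L) {
  stopifnot(all(dim(exchangeabilities) == c(20L, 20L)),
            isTRUE(all.equal(exchangeabilities, t(exchangeabilities))),
            all(exchangeabilities >= 0), length(freqs) == 20L,
            abs(sum(freqs) - 1) < 1e-8, all(freqs > 0))
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be > 0")
  Q <- exchangeabilities * rep(freqs, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))          # expected rate under pi
  Q <- Q / mu
  sp <- sqrt(freqs)
  B <- Q * (sp %o% (1 / sp))           # pi^{1/2} Q pi^{-1/2}, symmetric
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- eig$vectors / sp                # rows scaled: diag(1/sp) %*% V
  Uinv <- t(eig$vectors) * rep(sp, each = 20L)
  rates <- if (is.null(gamma_shape) || n_categories == 1L) 1
           else discrete_gamma_rates(gamma_shape, n_categories)
  structure(list(Q = Q, freqs = freqs, eigenvalues = eig$values,
                 U = U, Uinv = Uinv, gamma_shape = gamma_shape,
                 n_categories = length(rates), category_rates = rates),
            class = "aa_model")
}

#' The WAG model
#'
#' Loads the bundled published WAG constants.
#'
#' @inheritParams aa_model
#' @export
wag_model <- function(gamma_shape = NULL, n_categories = 1L) {
  p <- read_paml_matrix(system.file("extdata", "wag.dat", package = "cytonuc",
                                    mustWork = TRUE))
  aa_model(p$exchangeabilities, p$freqs, gamma_shape, n_categories)
}

#' @export
print.aa_model <- function(x, ...) {
  cat("reversible amino-acid model (20 states, unit expected rate)\n")
  if (!is.null(x$gamma_shape))
    cat(sprintf("  discrete-Gamma: alpha = %g, %d categories\n",
                x$gamma_shape, x$n_categories))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model an [aa_model()].
#' @param t branch length (expected substitutions/site), finite and >= 0.
#' @return 20x20 row-stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  P <- model$U %*% (exp(model$eigenvalues * t) * model$Uinv)
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Discrete-Gamma rate categories
#'
#' Mean-of-quantile discretization: k equiprobable categories whose rates are
#' the conditional means of a Gamma(alpha, alpha) between consecutive
#' quantiles, hence averaging exactly 1.
#'
#' @param alpha shape (> 0).
#' @param k number of categories (>= 1).
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X | a < X < b] for Gamma(alpha, alpha) via the alpha+1 cdf identity
  cum <- stats::pgamma(bounds, shape = alpha + 1, rate = alpha)
  r <- k * diff(cum)
  r / mean(r) * 1  # guards rounding; mean(r) is 1 up to floating error
}

#' Kimura two-parameter model
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @return object of class `"k80_model"`.
#' @export
k80_model <- function(kappa = 2.0) {
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(kappa = kappa), class = "k80_model")
}

#' K80 closed-form substitution probabilities
#'
#' With the generator scaled to one expected substitution/site, returns the
#' probability that a site shows a transition (`p_transition`) or either
#' transversion (`p_transversion`, total over both types) after time `t`.
#'
#' @param model a [k80_model()].
#' @param t time (>= 0).
#' @export
k80_probs <- function(model, t) {
  if (any(t < 0)) stop("t must be >= 0")
  kap <- model$kappa
  beta <- 1 / (kap + 2)    # transversion rate; alpha + 2 beta = 1
  alpha <- kap * beta
  Ptr <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  Qtv <- 0.5 - 0.5 * exp(-4 * beta * t)
  list(p_transition = Ptr, p_transversion = Qtv)
}

## residue -> integer codes; NA for gap/ambiguity (missing data)
.aa_index <- function(ch) match(ch, AA_LETTERS)
.nt_index <- function(ch) match(ch, c("A", "C", "G", "T"))

## encode an msa as an integer matrix (rows = sequences)
.encode_msa <- function(x, alphabet = attr(x, "alphabet")) {
  m <- unclass(x)
  idx <- if (alphabet == "AA") .aa_index(m) else .nt_index(m)
  matrix(idx, nrow = nrow(m), dimnames = dimnames(m))
}
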
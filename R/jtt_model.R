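#' The JTT amino-acid substitution model
#'
#' Builds the time-reversible rate matrix of the Jones-Taylor-Thornton
#' (1992) empirical model from the packaged exchangeabilities and
#' equilibrium frequencies. The generator Q is scaled so that the expected
#' number of substitutions per site per unit time is one
#' (`-sum(pi_i * Q_ii) = 1`), so branch lengths and distances are in
#' substitutions per site.
#'
#' @return An object of class `aa_model`: list with `name`, `alphabet`,
#'   `Q` (20 x 20 generator), `pi` (equilibrium frequencies) and a cached
#'   spectral decomposition used to compute transition matrices.
#' @export
jtt_model <- function() {
  path <- system.file("extdata", "jtt92_model.txt", package = "magnetochrome")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  s <- matrix(0, 20, 20, dimnames = list(AA_MODEL_ORDER, AA_MODEL_ORDER))
  for (i in 2:20) {
    s[i, seq_len(i - 1)] <- vals[[i - 1]]
  }
  s <- s + t(s)
  freqs <- vals[[20]]
  pi <- freqs / sum(freqs)
  names(pi) <- AA_MODEL_ORDER
  Q <- s * rep(pi, each = 20)        # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # reversibility makes D^(1/2) Q D^(-1/2) symmetric: stable eigen solve
  dh <- sqrt(pi)
  B <- Q * (dh %o% (1 / dh))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(
    list(
      name = "JTT", alphabet = AA_MODEL_ORDER, Q = Q, pi = pi,
      eig_values = eig$values,
      eig_left = eig$vectors * (1 / dh),         # rows scaled: D^-1/2 U
      eig_right = t(eig$vectors * dh)            # U^T D^1/2
    ),
    class = "aa_model"
  )
}

#' @export
print.aa_model <- function(x, ...) {
  cat("<aa_model> ", x$name, " (20 states, mean rate 1 substitution/site)\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model An `aa_model`.
#' @param t Branch length in substitutions per site (>= 0).
#' @return A 20 x 20 stochastic matrix.
#' @export
probability_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}
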
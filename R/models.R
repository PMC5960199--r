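# Le & Gascuel (2008) amino acid replacement matrix: lower-triangle
# exchangeabilities in column-major pair order (2,1), (3,1), ..., (20,1),
# (3,2), ... over ARNDCQEGHILKMFPSTWYV, and stationary frequencies, as
# published.
LG_EXCH <- c(
  0.425093, 0.276818, 0.395144, 2.489084, 0.969894, 1.038545, 2.066040,
  0.358858, 0.149830, 0.395337, 0.536518, 1.124035, 0.253701, 1.177651,
  4.727182, 2.139501, 0.180717, 0.218959, 2.547870, 0.751878, 0.123954,
  0.534551, 2.807908, 0.363970, 0.390192, 2.426601, 0.126991, 0.301848,
  6.326067, 0.484133, 0.052722, 0.332533, 0.858151, 0.578987, 0.593607,
  0.314440, 0.170887, 5.076149, 0.528768, 1.695752, 0.541712, 1.437645,
  4.509238, 0.191503, 0.068427, 2.145078, 0.371004, 0.089525, 0.161787,
  4.008358, 2.000679, 0.045376, 0.612025, 0.083688, 0.062556, 0.523386,
  5.243870, 0.844926, 0.927114, 0.010690, 0.015076, 0.282959, 0.025548,
  0.017416, 0.394456, 1.240275, 0.425860, 0.029890, 0.135107, 0.037967,
  0.084808, 0.003499, 0.569265, 0.640543, 0.320627, 0.594007, 0.013266,
  0.893680, 1.105251, 0.075382, 2.784478, 1.143480, 0.670128, 1.165532,
  1.959291, 4.128591, 0.267959, 4.813505, 0.072854, 0.582457, 3.234294,
  1.672569, 0.035855, 0.624294, 1.223828, 1.080136, 0.236199, 0.257336,
  0.210332, 0.348847, 0.423881, 0.044265, 0.069673, 1.807177, 0.173735,
  0.018811, 0.419409, 0.611973, 0.604545, 0.077852, 0.120037, 0.245034,
  0.311484, 0.008705, 0.044261, 0.296636, 0.139538, 0.089586, 0.196961,
  1.739990, 0.129836, 0.268491, 0.054679, 0.076701, 0.108882, 0.366317,
  0.697264, 0.442472, 0.682139, 0.508851, 0.990012, 0.584262, 0.597054,
  5.306834, 0.119013, 4.145067, 0.159069, 4.273607, 1.112727, 0.078281,
  0.064105, 1.033739, 0.111660, 0.232523, 10.649107, 0.137500, 6.312358,
  2.592692, 0.249060, 0.182287, 0.302936, 0.619632, 0.299648, 1.702745,
  0.656604, 0.023918, 0.390322, 0.748683, 1.136863, 0.049906, 0.131932,
  0.185202, 1.798853, 0.099849, 0.346960, 2.020366, 0.696175, 0.481306,
  1.898718, 0.094464, 0.361819, 0.165001, 2.457121, 7.803902, 0.654683,
  1.338132, 0.571468, 0.095131, 0.089613, 0.296501, 6.472279, 0.248862,
  0.400547, 0.098369, 0.140825, 0.245841, 2.188158, 3.151815, 0.189510,
  0.249313)

LG_FREQS <- c(
  0.079066, 0.055941, 0.041977, 0.053052, 0.012937, 0.040767, 0.071586,
  0.057337, 0.022355, 0.062157, 0.099081, 0.064600, 0.022951, 0.042302,
  0.044040, 0.061197, 0.053287, 0.012066, 0.034155, 0.069147)

#' Substitution models
#'
#' A `substitution_model` bundles symmetric exchangeabilities, stationary
#' frequencies, and discrete-gamma rate heterogeneity. The rate matrix Q is
#' rescaled so that one unit of branch length equals one expected
#' substitution per site; discrete-gamma category rates (equal-probability
#' categories, mean-of-category rates) always average one.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param exchangeabilities symmetric k x k non-negative matrix (diagonal
#'   ignored), or the lower-triangle vector in column-major pair order
#'   (2,1), (3,1), ..., (3,2), ...
#' @param frequencies stationary frequencies (length k, summing to 1).
#' @param gamma_shape shape of the gamma rate distribution (`Inf` for rate
#'   homogeneity).
#' @param n_categories number of discrete gamma categories (>= 1).
#' @param name model name tag.
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(alphabet, exchangeabilities, frequencies,
                               gamma_shape = Inf, n_categories = 4L,
                               name = "custom") {
  k <- length(alphabet_states(alphabet))
  if (!is.matrix(exchangeabilities)) {
    if (length(exchangeabilities) != k * (k - 1L) / 2L) {
      stop("need ", k * (k - 1L) / 2L, " lower-triangle exchangeabilities")
    }
    S <- matrix(0, k, k)
    S[lower.tri(S)] <- exchangeabilities  # column-major: (2,1), (3,1), ...
    S <- S + t(S)
  } else {
    S <- exchangeabilities
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    diag(S) <- 0
  }
  if (any(S < 0)) stop("exchangeabilities must be non-negative")
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != k) stop("need ", k, " frequencies")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  # published frequency tables are printed rounded; renormalized below
  if (abs(sum(frequencies) - 1) > 1e-5) stop("frequencies must sum to 1")
  frequencies <- frequencies / sum(frequencies)
  if (!is.numeric(gamma_shape) || gamma_shape <= 0) {
    stop("gamma_shape must be positive (use Inf for no rate heterogeneity)")
  }
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")

  Q <- S * rep(frequencies, each = k)   # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(frequencies * diag(Q))     # expected rate; rescale to 1
  Q <- Q / mu

  # reversible Q: symmetrize with D = diag(sqrt(pi)) for a stable eigen basis
  sp <- sqrt(frequencies)
  A <- Q * (sp / rep(sp, each = k))     # A_ij = Q_ij * sp_i / sp_j
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)

  rates <- if (is.finite(gamma_shape) && n_categories > 1L) {
    phangorn::discrete.gamma(gamma_shape, n_categories)
  } else {
    rep(1, n_categories)
  }

  structure(list(
    alphabet = alphabet, name = name, k = k,
    exchangeabilities = S, frequencies = frequencies, Q = Q,
    gamma_shape = gamma_shape, n_categories = n_categories,
    category_rates = rates,
    eig_values = eig$values, eig_vectors = eig$vectors, sqrt_freq = sp
  ), class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  g <- if (is.finite(x$gamma_shape)) {
    sprintf("+G%d(alpha=%.3g)", x$n_categories, x$gamma_shape)
  } else ""
  cat(sprintf("<substitution_model> %s%s on %s (k=%d)\n",
              x$name, g, x$alphabet, x$k))
  invisible(x)
}

#' @rdname substitution_model
#' @param rates six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @export
model_gtr <- function(rates = rep(1, 6), frequencies = rep(0.25, 4),
                      gamma_shape = Inf, n_categories = 4L) {
  if (length(rates) != 6L) stop("GTR needs 6 exchangeabilities")
  S <- matrix(0, 4, 4)
  S[1, 2] <- rates[1]; S[1, 3] <- rates[2]; S[1, 4] <- rates[3]
  S[2, 3] <- rates[4]; S[2, 4] <- rates[5]; S[3, 4] <- rates[6]
  substitution_model("nucleotide", S + t(S), frequencies, gamma_shape,
                     n_categories, name = "GTR")
}

#' @rdname substitution_model
#' @details `model_lg()` uses the published LG exchangeabilities; pass
#'   `frequencies` for "+F" empirical frequencies (default: LG frequencies).
#' @export
model_lg <- function(gamma_shape = Inf, n_categories = 4L, frequencies = NULL) {
  substitution_model("amino_acid", LG_EXCH, frequencies %||% LG_FREQS,
                     gamma_shape, n_categories, name = "LG")
}

#' @rdname substitution_model
#' @export
model_jc <- function(alphabet = "nucleotide", gamma_shape = Inf,
                     n_categories = 1L) {
  k <- length(alphabet_states(alphabet))
  substitution_model(alphabet, rep(1, k * (k - 1L) / 2L), rep(1 / k, k),
                     gamma_shape, n_categories, name = "JC")
}

#' Transition probability matrix
#'
#' P(t) = exp(Q * rate * t), computed from the model's precomputed spectral
#' decomposition. Rows sum to 1; for a reversible model detailed balance
#' pi_i P_ij(t) = pi_j P_ji(t) holds.
#'
#' @param model a `substitution_model`.
#' @param t branch length (expected substitutions per site), >= 0.
#' @param category_rate rate multiplier (a discrete-gamma category rate).
#' @return k x k stochastic matrix.
#' @export
transition_matrix <- function(model, t, category_rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  e <- exp(model$eig_values * (t * category_rate))
  U <- model$eig_vectors
  P <- U %*% (e * t(U))
  P <- P * (rep(model$sqrt_freq, each = model$k) / model$sqrt_freq)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Parse a model configuration string
#'
#' Accepts strings such as `"GTR+G4"`, `"LG+G4"`, `"JC"`, `"LG"`; the digit
#' after `G` is the discrete-gamma category count.
#' @param string model string.
#' @param gamma_shape gamma shape used when the string requests `+G`.
#' @param frequencies optional frequency override.
#' @return a `substitution_model`.
#' @export
parse_model <- function(string, gamma_shape = 1, frequencies = NULL) {
  m <- regmatches(string, regexec("^([A-Za-z]+)(\\+G(\\d+)?)?$", string))[[1L]]
  if (!length(m)) stop("cannot parse model string: ", string)
  base <- toupper(m[2L])
  ncat <- if (nzchar(m[3L])) max(1L, as.integer(if (nzchar(m[4L])) m[4L] else 4L)) else 1L
  shape <- if (nzchar(m[3L])) gamma_shape else Inf
  switch(base,
         GTR = model_gtr(frequencies = frequencies %||% rep(0.25, 4),
                         gamma_shape = shape, n_categories = ncat),
         LG = model_lg(gamma_shape = shape, n_categories = ncat,
                       frequencies = frequencies),
         JC = model_jc(gamma_shape = shape, n_categories = ncat),
         stop("unknown model: ", base))
}
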
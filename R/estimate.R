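#' Estimate per-partition substitution models from a supermatrix
#'
#' Model parameters are fitted once per partition on the full supermatrix
#' and then held fixed across all quartets of an FcLM run; per-quartet
#' re-estimation would be unstable on sparse partitions. For each
#' partition:
#'
#' * stationary frequencies are the observed residue frequencies of the
#'   partition (floored at 1e-6 and renormalized);
#' * the gamma shape (and, for nucleotide data, the five free GTR
#'   exchangeabilities relative to GT = 1) are optimized by maximum
#'   likelihood on a fixed random sample of quartets, summing quartet
#'   log-likelihoods with branch lengths re-optimized at each candidate
#'   parameter point;
#' * amino acid partitions use the published LG exchangeabilities, with
#'   empirical ("+F") frequencies.
#'
#' @param supermatrix a `phylo_alignment`.
#' @param scheme a `partition_scheme`.
#' @param n_quartets_fit number of quartets sampled for parameter fitting.
#' @param n_categories discrete-gamma categories for the fitted models.
#' @param estimate_rates if `FALSE` (nucleotide), keep equal
#'   exchangeabilities and fit only the gamma shape.
#' @param seed RNG seed for the quartet sample.
#' @return named list of `substitution_model`s, one per partition.
#' @export
estimate_partition_models <- function(supermatrix, scheme,
                                      n_quartets_fit = 5L,
                                      n_categories = 4L,
                                      estimate_rates = TRUE,
                                      seed = NULL) {
  alphabet <- supermatrix$alphabet
  states <- alphabet_states(alphabet)
  k <- length(states)
  taxa <- taxa_labels(supermatrix)
  if (length(taxa) < 4L) stop("need at least 4 taxa to fit models")
  quartet_taxa <- with_seed(seed, {
    lapply(seq_len(n_quartets_fit), function(i) sample(taxa, 4L))
  })

  lapply(stats::setNames(names(scheme$partitions), names(scheme$partitions)),
         function(nm) {
    cols <- scheme$partitions[[nm]]
    sub <- slice_alignment(supermatrix, columns = cols)
    obs <- sub$matrix[!missing_mask(sub)]
    counts <- as.numeric(table(factor(obs, levels = states)))
    freqs <- pmax(counts / max(1, sum(counts)), 1e-6)
    freqs <- freqs / sum(freqs)

    qparts <- lapply(quartet_taxa, function(qt) {
      quartet_patterns(encode_alignment(slice_alignment(sub, qt)))
    })
    qparts <- Filter(function(p) p$n_sites_used > 0L, qparts)

    build <- function(par) {
      shape <- exp(par[1L])
      if (alphabet == "amino_acid") {
        model_lg(gamma_shape = shape, n_categories = n_categories,
                 frequencies = freqs)
      } else if (length(par) > 1L) {
        model_gtr(rates = c(exp(par[2:6]), 1), frequencies = freqs,
                  gamma_shape = shape, n_categories = n_categories)
      } else {
        model_gtr(rates = rep(1, 6), frequencies = freqs,
                  gamma_shape = shape, n_categories = n_categories)
      }
    }
    if (!length(qparts)) return(build(0))

    # star-like fixed branch lengths: parameter fit only, branches are
    # re-optimized per quartet downstream
    bl <- c(rep(0.1, 4L), 1e-6)
    objective <- function(par) {
      model <- build(par)
      -sum(vapply(qparts, function(p) {
        quartet_loglik_single(p, model, "T1", bl)
      }, numeric(1L)))
    }
    par0 <- if (alphabet == "nucleotide" && estimate_rates) {
      rep(0, 6L)
    } else {
      0
    }
    fit <- if (length(par0) == 1L) {
      stats::optim(par0, objective, method = "Brent",
                   lower = log(0.05), upper = log(50))
    } else {
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = c(log(0.05), rep(log(1e-3), 5L)),
                   upper = c(log(50), rep(log(1e3), 5L)),
                   control = list(maxit = 200L))
    }
    build(fit$par)
  })
}
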
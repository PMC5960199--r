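#' Permutation null matrices for confounding-signal tests
#'
#' Three randomization schemes that progressively destroy structure while
#' controlling what is preserved:
#'
#' * **Scheme I** permutes the observed residues of each partition across
#'   that partition's non-missing cells (across taxa and sites). It
#'   destroys phylogenetic signal but preserves the per-partition residue
#'   multiset and the missing-data mask exactly.
#' * **Scheme II** replaces every non-missing cell with an i.i.d. draw
#'   from a frequency vector (the published LG frequencies, the
#'   partition's empirical frequencies, or uniform). It additionally
#'   destroys among-taxon compositional heterogeneity; the mask is still
#'   preserved exactly.
#' * **Scheme III** applies scheme II and then permutes the
#'   missing/non-missing indicator uniformly across each partition's
#'   cells, destroying the missing-data structure while conserving the
#'   per-partition count of missing cells.
#'
#' Columns not covered by the partition scheme are left untouched.
#'
#' @param aln a `phylo_alignment`.
#' @param scheme a `partition_scheme` over `aln`'s columns.
#' @param frequency_source `"empirical"` (per-partition observed
#'   frequencies), `"LG"` (amino acid matrices only), or `"uniform"`.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return a `phylo_alignment` of the same dimensions.
#' @name permutation_schemes
NULL

#' @rdname permutation_schemes
#' @export
permute_scheme_I <- function(aln, scheme, seed = NULL) {
  m <- aln$matrix
  miss <- missing_mask(aln)
  with_seed(seed, {
    for (cols in scheme$partitions) {
      cells <- which(!miss[, cols, drop = FALSE])
      if (length(cells) > 1L) {
        sub <- m[, cols, drop = FALSE]
        sub[cells] <- sub[cells][sample.int(length(cells))]
        m[, cols] <- sub
      }
    }
  })
  phylo_alignment(m, aln$alphabet)
}

freq_vector <- function(source, aln, cols, miss) {
  states <- alphabet_states(aln$alphabet)
  switch(source,
         LG = {
           if (aln$alphabet != "amino_acid") {
             stop("LG frequencies are defined for amino acid matrices only")
           }
           LG_FREQS / sum(LG_FREQS)
         },
         uniform = rep(1 / length(states), length(states)),
         empirical = {
           obs <- aln$matrix[, cols, drop = FALSE][!miss[, cols, drop = FALSE]]
           counts <- table(factor(obs, levels = states))
           if (sum(counts) == 0L) return(rep(1 / length(states), length(states)))
           as.numeric(counts) / sum(counts)
         },
         stop("unknown frequency source: ", source))
}

#' @rdname permutation_schemes
#' @export
permute_scheme_II <- function(aln, scheme,
                              frequency_source = c("empirical", "LG", "uniform"),
                              seed = NULL) {
  frequency_source <- match.arg(frequency_source)
  states <- alphabet_states(aln$alphabet)
  m <- aln$matrix
  miss <- missing_mask(aln)
  with_seed(seed, {
    for (cols in scheme$partitions) {
      cells <- which(!miss[, cols, drop = FALSE])
      if (length(cells)) {
        f <- freq_vector(frequency_source, aln, cols, miss)
        sub <- m[, cols, drop = FALSE]
        sub[cells] <- sample(states, length(cells), replace = TRUE, prob = f)
        m[, cols] <- sub
      }
    }
  })
  phylo_alignment(m, aln$alphabet)
}

#' @rdname permutation_schemes
#' @details Scheme III fills newly observed cells with the values drawn for
#'   the scheme-II stage (the draws are relocated, not redrawn), so a
#'   partition without missing cells reduces exactly to the scheme-II
#'   output under the same seed. Newly missing cells are written as `'-'`.
#' @export
permute_scheme_III <- function(aln, scheme,
                               frequency_source = c("empirical", "LG", "uniform"),
                               seed = NULL) {
  frequency_source <- match.arg(frequency_source)
  states <- alphabet_states(aln$alphabet)
  m <- aln$matrix
  miss <- missing_mask(aln)
  with_seed(seed, {
    for (cols in scheme$partitions) {
      sub <- m[, cols, drop = FALSE]
      submiss <- miss[, cols, drop = FALSE]
      n_cells <- length(sub)
      n_miss <- sum(submiss)
      n_obs <- n_cells - n_miss
      if (n_obs > 0L) {
        f <- freq_vector(frequency_source, aln, cols, miss)
        vals <- sample(states, n_obs, replace = TRUE, prob = f)
      } else {
        vals <- character()
      }
      if (n_miss > 0L && n_miss < n_cells) {
        new_missing <- sample.int(n_cells, n_miss)
        out <- character(n_cells)
        out[new_missing] <- "-"
        out[-new_missing] <- vals
        sub[] <- out
      } else if (n_miss == 0L) {
        sub[] <- vals
      }
      m[, cols] <- sub
    }
  })
  phylo_alignment(m, aln$alphabet)
}

#' Dispatch one of the three permutation schemes
#'
#' @inheritParams permutation_schemes
#' @param which `"I"`, `"II"` or `"III"`.
#' @return a `phylo_alignment`.
#' @export
permute_matrix <- function(aln, scheme, which = c("I", "II", "III"),
                           frequency_source = "empirical", seed = NULL) {
  which <- match.arg(which)
  switch(which,
         I = permute_scheme_I(aln, scheme, seed = seed),
         II = permute_scheme_II(aln, scheme, frequency_source, seed = seed),
         III = permute_scheme_III(aln, scheme, frequency_source, seed = seed))
}
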
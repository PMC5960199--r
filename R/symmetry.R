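#' Pairwise divergence counts
#'
#' The k x k table of joint states for two aligned sequences, restricted to
#' columns where neither member is missing. This is the contingency table
#' Bowker's matched-pairs test of symmetry consumes: asymmetry of this
#' table is evidence against globally stationary, reversible, homogeneous
#' (SRH) evolution of the pair.
#'
#' @param aln a `phylo_alignment`.
#' @param taxon_a,taxon_b taxon labels present in `aln`.
#' @return a `pair_divergence` object: `counts` (k x k integer matrix with
#'   state dimnames), `taxa`, and `n_effective` (number of jointly observed
#'   columns).
#' @export
divergence_counts <- function(aln, taxon_a, taxon_b) {
  for (tx in c(taxon_a, taxon_b)) {
    if (!tx %in% taxa_labels(aln)) stop("unknown taxon: ", tx)
  }
  states <- alphabet_states(aln$alphabet)
  k <- length(states)
  codes <- encode_alignment(slice_alignment(aln, c(taxon_a, taxon_b)))
  ok <- !is.na(codes[1L, ]) & !is.na(codes[2L, ])
  a <- codes[1L, ok]
  b <- codes[2L, ok]
  counts <- matrix(tabulate((a - 1L) * k + b, nbins = k * k),
                   nrow = k, byrow = TRUE, dimnames = list(states, states))
  structure(list(counts = counts, taxa = c(taxon_a, taxon_b),
                 n_effective = sum(ok)),
            class = "pair_divergence")
}

#' Bowker's matched-pairs test of symmetry
#'
#' B = sum over unordered state pairs \{i, j\} with n_ij + n_ji > 0 of
#' (n_ij - n_ji)^2 / (n_ij + n_ji), referred to the upper tail of a
#' chi-square distribution with one degree of freedom per contributing
#' pair. B = 0 (no off-diagonal disagreement, df = 0) is defined to give
#' p = 1: no evidence against symmetry.
#'
#' @param m a `pair_divergence`, or a plain square count matrix.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
bowker_test <- function(m) {
  counts <- if (inherits(m, "pair_divergence")) m$counts else m
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop("counts must be a square matrix")
  }
  nij <- counts[upper.tri(counts)]
  nji <- t(counts)[upper.tri(counts)]
  tot <- nij + nji
  use <- tot > 0
  stat <- sum((nij[use] - nji[use])^2 / tot[use])
  df <- sum(use)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' All-pairs Bowker symmetry screen
#'
#' Applies [bowker_test()] to every unordered taxon pair of an alignment,
#' in input taxon order. Pairs sharing no jointly observed column carry
#' `class = "no_overlap"` and no p-value.
#'
#' @param aln a `phylo_alignment` with at least 2 taxa.
#' @param alpha significance level for the pass/fail classification
#'   (pass means p > alpha, the "white cell" of the diagnostic heat map).
#' @return a tibble of class `symmetry_pairs` with columns `taxon_a`,
#'   `taxon_b`, `n_effective`, `statistic`, `df`, `p_value`, `class`
#'   (`"pass"`, `"fail"` or `"no_overlap"`).
#' @export
pairwise_symmetry <- function(aln, alpha = 0.05) {
  if (n_taxa(aln) < 2L) stop("need at least 2 taxa")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  taxa <- taxa_labels(aln)
  states <- alphabet_states(aln$alphabet)
  k <- length(states)
  codes <- encode_alignment(aln)
  pairs <- utils::combn(length(taxa), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
    n_eff <- sum(ok)
    if (n_eff == 0L) {
      return(tibble::tibble(taxon_a = taxa[i], taxon_b = taxa[j],
                            n_effective = 0L, statistic = NA_real_,
                            df = NA_integer_, p_value = NA_real_,
                            class = "no_overlap"))
    }
    counts <- matrix(tabulate((codes[i, ok] - 1L) * k + codes[j, ok],
                              nbins = k * k), nrow = k, byrow = TRUE)
    bt <- bowker_test(counts)
    tibble::tibble(taxon_a = taxa[i], taxon_b = taxa[j], n_effective = n_eff,
                   statistic = bt$statistic, df = bt$df, p_value = bt$p_value,
                   class = if (bt$p_value > alpha) "pass" else "fail")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "taxa") <- taxa
  attr(out, "alpha") <- alpha
  class(out) <- c("symmetry_pairs", class(out))
  out
}

#' Square p-value matrix from a pairwise symmetry screen
#'
#' @param pairs a `symmetry_pairs` tibble.
#' @return symmetric taxa x taxa numeric matrix of p-values; the diagonal is
#'   `NA` (undefined) and no-overlap pairs are `NaN`.
#' @export
symmetry_matrix <- function(pairs) {
  taxa <- attr(pairs, "taxa")
  m <- matrix(NA_real_, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  p <- ifelse(pairs$class == "no_overlap", NaN, pairs$p_value)
  m[cbind(pairs$taxon_a, pairs$taxon_b)] <- p
  m[cbind(pairs$taxon_b, pairs$taxon_a)] <- p
  m
}

#' Reclassify a symmetry screen at a different significance level
#'
#' @param pairs a `symmetry_pairs` tibble.
#' @param alpha significance level in (0, 1); `pass` means p > alpha
#'   (strict), matching the heat-map convention that white cells are
#'   p-values above the threshold.
#' @return the tibble with its `class` column recomputed.
#' @export
classify_symmetry <- function(pairs, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  pairs$class <- dplyr::case_when(
    pairs$class == "no_overlap" ~ "no_overlap",
    pairs$p_value > alpha ~ "pass",
    TRUE ~ "fail"
  )
  attr(pairs, "alpha") <- alpha
  pairs
}

#' @export
tidy.symmetry_pairs <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.symmetry_pairs <- function(x, ...) {
  tested <- x$class != "no_overlap"
  tibble::tibble(
    n_pairs = nrow(x),
    n_tested = sum(tested),
    n_no_overlap = sum(!tested),
    n_fail = sum(x$class == "fail"),
    rejection_rate = if (any(tested)) mean(x$class[tested] == "fail") else NA_real_,
    alpha = attr(x, "alpha")
  )
}

#' Heat-map plot of a pairwise symmetry screen
#'
#' White cells are pairs with p-value above the significance level (no
#' detected SRH violation); filled cells are failures; grey cells had no
#' jointly observed column. Taxa appear in input order.
#'
#' @param object a `symmetry_pairs` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.symmetry_pairs <- function(object, ...) {
  taxa <- attr(object, "taxa")
  both <- dplyr::bind_rows(
    object,
    dplyr::rename(object, taxon_a = "taxon_b", taxon_b = "taxon_a")
  )
  both$taxon_a <- factor(both$taxon_a, levels = taxa)
  both$taxon_b <- factor(both$taxon_b, levels = rev(taxa))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                     fill = .data$class)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(pass = "white", fail = "#b2182b",
                                          no_overlap = "grey60")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Bowker matched-pairs symmetry screen") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
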
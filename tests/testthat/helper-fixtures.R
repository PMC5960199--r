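# Build a phylo_alignment from per-taxon strings.
mk_aln <- function(seqs, alphabet = "nucleotide",
                   taxa = paste0("t", seq_along(seqs))) {
  n <- nchar(seqs[1L])
  m <- matrix("", length(seqs), n, dimnames = list(taxa, NULL))
  if (n > 0L) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- taxa
  }
  phylo_alignment(m, alphabet)
}

# Independent oracle for the quartet likelihood: explicit enumeration over
# all k^2 internal-node state pairs, site by site, no pruning and no
# pattern compression. The x/y double loop is the enumeration; only the
# per-site products are vectorized.
brute_quartet_loglik <- function(qaln, topology, model, bl) {
  perm <- QUARTET_TOPOLOGIES[[topology]]
  codes <- encode_alignment(qaln)
  usable <- colSums(is.na(codes)) == 0L
  codes <- codes[perm, usable, drop = FALSE]
  bla <- c(bl[perm], bl[5L])
  k <- model$k
  n <- ncol(codes)
  lik <- numeric(n)
  for (r in model$category_rates) {
    Pa <- transition_matrix(model, bla[1L], r)
    Pb <- transition_matrix(model, bla[2L], r)
    Pc <- transition_matrix(model, bla[3L], r)
    Pd <- transition_matrix(model, bla[4L], r)
    Pi <- transition_matrix(model, bla[5L], r)
    for (x in seq_len(k)) {
      for (y in seq_len(k)) {
        lik <- lik + model$frequencies[x] * Pi[x, y] *
          Pa[x, codes[1L, ]] * Pb[x, codes[2L, ]] *
          Pc[y, codes[3L, ]] * Pd[y, codes[4L, ]]
      }
    }
  }
  sum(log(lik / model$n_categories))
}

random_gtr <- function(gamma = TRUE) {
  f <- stats::runif(4, 0.5, 2)
  model_gtr(rates = stats::runif(6, 0.2, 3), frequencies = f / sum(f),
            gamma_shape = if (gamma) stats::runif(1, 0.3, 2) else Inf,
            n_categories = if (gamma) 4L else 1L)
}

random_quartet_aln <- function(n_sites, alphabet = "nucleotide") {
  states <- alphabet_states(alphabet)
  m <- matrix(sample(states, 4L * n_sites, replace = TRUE), nrow = 4L,
              dimnames = list(paste0("t", 1:4), NULL))
  phylo_alignment(m, alphabet)
}

# Small random gene records for supermatrix algebra properties.
random_gene_set <- function(n_genes = 3L, n_taxa = 8L) {
  tips <- paste0("t", sprintf("%02d", seq_len(n_taxa)))
  nwk <- paste0("(", paste0(tips, ":0.15", collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  config <- simulation_config(tree, n_genes = n_genes,
                              gene_length_range = c(12L, 30L),
                              occupancy = 0.8, mask_fraction = 0.15,
                              domains_per_gene = 1,
                              domain_length_range = c(4L, 8L),
                              seed = sample.int(1e6, 1L))
  simulate_gene_records(config)
}
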
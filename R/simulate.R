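#' Simulate sequences down a tree
#'
#' Standard continuous-time Markov chain simulation: root states are drawn
#' from the root model's stationary frequencies, then evolved edge by edge
#' with per-edge transition matrices. Per-site rate heterogeneity uses the
#' model's discrete-gamma categories (each site is assigned one category
#' uniformly). Lineage-heterogeneous composition — the violation the
#' Bowker screen targets — is induced by `frequency_overrides`: every
#' lineage whose tip set lies within an override's taxon set evolves under
#' a rate matrix rebuilt from the override frequencies (same
#' exchangeabilities), making the process non-stationary across the tree.
#'
#' @param tree an ape `phylo` with branch lengths.
#' @param model a `substitution_model`.
#' @param n_sites number of columns to simulate.
#' @param frequency_overrides optional list of
#'   `list(taxa = <tips>, frequencies = <simplex vector>)`.
#' @param seed RNG seed.
#' @return a `phylo_alignment` over the tree's tip labels.
#' @export
simulate_sequences <- function(tree, model, n_sites,
                               frequency_overrides = NULL, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  states <- alphabet_states(model$alphabet)
  k <- model$k
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  override_model <- function(freqs) {
    substitution_model(model$alphabet, model$exchangeabilities, freqs,
                       gamma_shape = model$gamma_shape,
                       n_categories = model$n_categories,
                       name = paste0(model$name, "-override"))
  }
  models <- c(list(model), lapply(frequency_overrides %||% list(),
                                  function(o) override_model(o$frequencies)))

  # model index per node: an override applies to every node whose tip
  # descendants all fall inside the override's taxon set
  node_model <- rep(1L, nnode)
  if (length(frequency_overrides)) {
    desc <- phangorn::Descendants(tree, seq_len(nnode), type = "tips")
    for (oi in seq_along(frequency_overrides)) {
      o <- frequency_overrides[[oi]]
      inside <- vapply(desc, function(d) {
        all(tree$tip.label[d] %in% o$taxa)
      }, logical(1L))
      node_model[inside] <- oi + 1L
    }
  }

  with_seed(seed, {
    cat_rates <- model$category_rates
    site_cat <- sample.int(length(cat_rates), n_sites, replace = TRUE)
    node_states <- matrix(NA_integer_, nnode, n_sites)
    node_states[root, ] <- sample.int(k, n_sites, replace = TRUE,
                                      prob = model$frequencies)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1L]
      child <- ord$edge[e, 2L]
      t_e <- ord$edge.length[e]
      m_e <- models[[node_model[child]]]
      for (ci in seq_along(cat_rates)) {
        P <- transition_matrix(m_e, t_e, cat_rates[ci])
        for (s in seq_len(k)) {
          idx <- which(node_states[parent, ] == s & site_cat == ci)
          if (length(idx)) {
            node_states[child, idx] <- sample.int(k, length(idx),
                                                  replace = TRUE, prob = P[s, ])
          }
        }
      }
    }
    m <- matrix(states[node_states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(tree$tip.label, NULL))
    phylo_alignment(m, model$alphabet)
  })
}

#' Four-cluster tree with labelled groups
#'
#' Builds a rooted tree of four clusters arranged as
#' `((G1, G2), (G3, G4))` — generating quartet topology T1 in the group
#' order — where each cluster is a star of tips on a common stem. The
#' unrooted internal branch separating the cluster pairs has total length
#' `internal_length`.
#'
#' @param group_sizes integer vector of 4 cluster sizes.
#' @param internal_length internal (quartet-defining) branch length.
#' @param stem_length cluster stem branch length.
#' @param tip_length terminal branch length.
#' @param group_names names for the four groups.
#' @return list with `tree` (ape `phylo`) and `groups` (a `taxon_groups`
#'   with purpose `"fclm_hypothesis"`).
#' @export
four_cluster_tree <- function(group_sizes, internal_length = 0.3,
                              stem_length = 0.1, tip_length = 0.1,
                              group_names = paste0("G", 1:4)) {
  stopifnot(length(group_sizes) == 4L, all(group_sizes >= 1L))
  tips <- lapply(1:4, function(g) {
    sprintf("%s_t%02d", group_names[g], seq_len(group_sizes[g]))
  })
  clade <- function(labels) {
    # single-tip groups sit directly on the stem edge
    if (length(labels) == 1L) {
      labels
    } else {
      sprintf("(%s)", paste(sprintf("%s:%g", labels, tip_length),
                            collapse = ","))
    }
  }
  nwk <- sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g);",
                 clade(tips[[1L]]), stem_length, clade(tips[[2L]]),
                 stem_length, internal_length / 2,
                 clade(tips[[3L]]), stem_length, clade(tips[[4L]]),
                 stem_length, internal_length / 2)
  tree <- ape::read.tree(text = nwk)
  groups <- taxon_groups(stats::setNames(tips, group_names),
                         purpose = "fclm_hypothesis")
  list(tree = tree, groups = groups)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_gene_records()] needs to emit study-shaped
#' inputs: a tree, per-track substitution models, gene count and length
#' distribution, domain layout, mask fraction, occupancy (block-structured
#' missingness: whole gene x taxon dropout), and lineage frequency
#' overrides. Defaults mirror a scaled-down target-enrichment
#' supermatrix: LG+G4 amino acids, GTR+G4 nucleotides, a ~0.9 gene
#' occupancy, ~20% of columns masked as ambiguously aligned, and one or
#' two annotated domains per gene.
#'
#' @param tree ape `phylo` with branch lengths.
#' @param n_genes number of genes.
#' @param gene_length_range range (aa columns) genes are drawn from,
#'   uniformly.
#' @param aa_model,nt_model `substitution_model`s for the two tracks
#'   (simulated independently on the same tree; the 3:1 nucleotide/amino
#'   acid column correspondence is bookkeeping, not a codon model).
#' @param occupancy probability a (taxon, gene) pair carries data.
#' @param mask_fraction expected fraction of aa columns masked per gene.
#' @param domains_per_gene expected number of domains per gene (Poisson,
#'   capped so domains fit).
#' @param domain_length_range domain length range (aa columns).
#' @param frequency_overrides see [simulate_sequences()].
#' @param seed RNG seed; fixed seed gives byte-identical gene records.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(tree, n_genes = 10L,
                              gene_length_range = c(60L, 120L),
                              aa_model = model_lg(gamma_shape = 1,
                                                  n_categories = 4L),
                              nt_model = model_gtr(
                                rates = c(1.5, 4, 1, 1.2, 4.5, 1),
                                frequencies = c(0.3, 0.2, 0.2, 0.3),
                                gamma_shape = 1, n_categories = 4L),
                              occupancy = 0.9, mask_fraction = 0.2,
                              domains_per_gene = 1.5,
                              domain_length_range = c(15L, 40L),
                              frequency_overrides = NULL, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1,
            mask_fraction >= 0, mask_fraction < 1)
  structure(list(tree = tree, n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 aa_model = aa_model, nt_model = nt_model,
                 occupancy = occupancy, mask_fraction = mask_fraction,
                 domains_per_gene = domains_per_gene,
                 domain_length_range = domain_length_range,
                 frequency_overrides = frequency_overrides,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate gene records
#'
#' @param config a [simulation_config()].
#' @return named list of `gene_record`s (plus attribute `"tree"`).
#' @export
simulate_gene_records <- function(config) {
  taxa <- config$tree$tip.label
  genes <- with_seed(config$seed, {
    lapply(seq_len(config$n_genes), function(gi) {
      len <- sample(seq(config$gene_length_range[1L],
                        config$gene_length_range[2L]), 1L)
      aa <- simulate_sequences(config$tree, config$aa_model, len,
                               frequency_overrides = config$frequency_overrides)
      nt <- simulate_sequences(config$tree, config$nt_model, 3L * len,
                               frequency_overrides = config$frequency_overrides)
      # block-structured missingness: whole gene x taxon dropout
      absent <- taxa[stats::runif(length(taxa)) > config$occupancy]
      if (length(absent)) {
        aa$matrix[absent, ] <- "-"
        nt$matrix[absent, ] <- "-"
      }
      mask <- which(stats::runif(len) < config$mask_fraction)
      n_dom <- min(stats::rpois(1L, config$domains_per_gene),
                   len %/% config$domain_length_range[2L])
      domains <- NULL
      if (n_dom > 0L) {
        dlen <- sample(seq(config$domain_length_range[1L],
                           config$domain_length_range[2L]),
                       n_dom, replace = TRUE)
        gap <- (len - sum(dlen)) %/% (n_dom + 1L)
        starts <- cumsum(c(gap + 1L, utils::head(dlen, -1L) + gap))
        domains <- tibble::tibble(
          domain_id = sprintf("PF%03d", sample.int(25L, n_dom)),
          start = as.integer(starts),
          end = as.integer(starts + dlen - 1L))
      }
      gene_record(sprintf("gene%03d", gi), aa, nt, mask = mask,
                  domains = domains)
    })
  })
  names(genes) <- vapply(genes, `[[`, character(1L), "gene_id")
  attr(genes, "tree") <- config$tree
  genes
}

#' Write a ready-to-run input fixture
#'
#' Emits the exact formats the pipeline consumes: per-gene FASTA pairs,
#' mask files (one 0-based aa column index per line), a domain annotation
#' TSV (`gene_id`, `domain_id`, `start`, `end`; 0-based half-open), the
#' hypothesis groups JSON and the true tree in Newick. Sizes: `tiny`
#' (8 taxa, 3 genes), `small` (24 taxa, 20 genes), `paper_shaped`
#' (183 taxa, 195 short genes, with four-cluster hypothesis group sizes
#' 2 / 5 / 42 / 134 mirroring a published apoid-wasp/bee study design).
#'
#' @param size `"tiny"`, `"small"` or `"paper_shaped"`.
#' @param dir output directory (created).
#' @param seed RNG seed.
#' @param internal_length internal branch of the four-cluster tree.
#' @return invisibly, a list with `dir`, `genes`, `tree`, `groups`.
#' @export
make_fixture <- function(size = c("tiny", "small", "paper_shaped"), dir,
                         seed = 1L, internal_length = 0.3) {
  size <- match.arg(size)
  layout <- switch(size,
    tiny = list(sizes = c(2L, 2L, 2L, 2L), n_genes = 3L, len = c(40L, 90L)),
    small = list(sizes = c(4L, 6L, 8L, 6L), n_genes = 20L, len = c(60L, 120L)),
    paper_shaped = list(sizes = c(2L, 5L, 42L, 134L), n_genes = 195L,
                        len = c(40L, 80L)))
  fct <- four_cluster_tree(layout$sizes, internal_length = internal_length)
  config <- simulation_config(fct$tree, n_genes = layout$n_genes,
                              gene_length_range = layout$len, seed = seed)
  genes <- simulate_gene_records(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dom_rows <- list()
  for (g in genes) {
    write_alignment(g$aa, file.path(dir, paste0(g$gene_id, "_aa.fasta")))
    write_alignment(g$nt, file.path(dir, paste0(g$gene_id, "_nt.fasta")))
    writeLines(as.character(g$mask - 1L),
               file.path(dir, paste0(g$gene_id, ".mask")))
    if (nrow(g$domains)) {
      dom_rows[[g$gene_id]] <- tibble::tibble(
        gene_id = g$gene_id, domain_id = g$domains$domain_id,
        start = g$domains$start - 1L, end = g$domains$end)
    }
  }
  doms <- if (length(dom_rows)) dplyr::bind_rows(dom_rows) else {
    tibble::tibble(gene_id = character(), domain_id = character(),
                   start = integer(), end = integer())
  }
  utils::write.table(doms, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_taxon_groups(fct$groups, file.path(dir, "groups.json"))
  write_newick(fct$tree, file.path(dir, "tree.nwk"))
  invisible(list(dir = dir, genes = genes, tree = fct$tree,
                 groups = fct$groups))
}

#' Read a fixture directory back into gene records
#'
#' Inverse of [make_fixture()]: reads FASTA pairs, 0-based mask files and
#' the 0-based half-open domain TSV into `gene_record`s.
#'
#' @param dir fixture directory.
#' @return named list of `gene_record`s.
#' @export
read_gene_records <- function(dir) {
  aa_files <- sort(list.files(dir, pattern = "_aa\\.fasta$", full.names = TRUE))
  if (!length(aa_files)) stop("no *_aa.fasta files in ", dir)
  dom_path <- file.path(dir, "domains.tsv")
  doms <- if (file.exists(dom_path)) {
    utils::read.table(dom_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), domain_id = character(),
               start = integer(), end = integer())
  }
  genes <- lapply(aa_files, function(fp) {
    gene_id <- sub("_aa\\.fasta$", "", basename(fp))
    aa <- read_alignment(fp, "amino_acid")
    nt <- read_alignment(file.path(dir, paste0(gene_id, "_nt.fasta")),
                         "nucleotide")
    mask_path <- file.path(dir, paste0(gene_id, ".mask"))
    mask <- if (file.exists(mask_path)) {
      as.integer(readLines(mask_path, warn = FALSE)) + 1L
    } else {
      integer()
    }
    d <- doms[doms$gene_id == gene_id, , drop = FALSE]
    domains <- if (nrow(d)) {
      tibble::tibble(domain_id = d$domain_id, start = d$start + 1L,
                     end = d$end)
    } else NULL
    gene_record(gene_id, aa, nt, mask = mask, domains = domains)
  })
  stats::setNames(genes, vapply(genes, `[[`, character(1L), "gene_id"))
}
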
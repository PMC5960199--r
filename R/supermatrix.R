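#' Gene record
#'
#' One single-copy gene with its amino acid alignment, the codon-aligned
#' nucleotide alignment (exactly 3x the amino acid length), the set of
#' ambiguously aligned amino acid columns to mask, and protein-domain
#' annotations as amino acid column ranges.
#'
#' @param gene_id gene identifier.
#' @param aa amino acid `phylo_alignment`.
#' @param nt nucleotide `phylo_alignment`, 3x the aa column count, same
#'   taxa.
#' @param mask integer vector of 1-based aa columns flagged ambiguous.
#' @param domains tibble/data.frame with columns `domain_id`, `start`,
#'   `end` (1-based inclusive aa columns); ranges must not overlap.
#' @return an object of class `gene_record`.
#' @export
gene_record <- function(gene_id, aa, nt, mask = integer(),
                        domains = NULL) {
  stopifnot(inherits(aa, "phylo_alignment"), inherits(nt, "phylo_alignment"))
  if (aa$alphabet != "amino_acid" || nt$alphabet != "nucleotide") {
    stop("gene_record needs an amino acid and a nucleotide alignment")
  }
  if (n_sites(nt) != 3L * n_sites(aa)) {
    stop(sprintf("gene %s: nt length %d is not 3x aa length %d",
                 gene_id, n_sites(nt), n_sites(aa)))
  }
  if (!setequal(taxa_labels(aa), taxa_labels(nt))) {
    stop("gene ", gene_id, ": aa and nt alignments list different taxa")
  }
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1L || max(mask) > n_sites(aa))) {
    stop("gene ", gene_id, ": mask column outside alignment")
  }
  if (is.null(domains)) {
    domains <- tibble::tibble(domain_id = character(), start = integer(),
                              end = integer())
  }
  domains <- tibble::as_tibble(domains)
  if (nrow(domains)) {
    if (any(domains$start < 1L) || any(domains$end > n_sites(aa)) ||
        any(domains$end < domains$start)) {
      stop("gene ", gene_id, ": domain range out of bounds")
    }
    d <- domains[order(domains$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      i <- which(d$start[-1L] <= d$end[-nrow(d)])[1L]
      stop(sprintf("gene %s: overlapping domain ranges %s [%d,%d] and %s [%d,%d]",
                   gene_id, d$domain_id[i], d$start[i], d$end[i],
                   d$domain_id[i + 1L], d$start[i + 1L], d$end[i + 1L]))
    }
  }
  structure(list(gene_id = gene_id, aa = aa, nt = nt, mask = mask,
                 domains = domains), class = "gene_record")
}

# aa columns -> the three nt columns of each codon
codon_columns <- function(aa_cols) {
  as.vector(rbind(3L * aa_cols - 2L, 3L * aa_cols - 1L, 3L * aa_cols))
}

# Row-union an alignment list onto a common taxon set, missing-filled.
union_alignment <- function(alns, alphabet) {
  taxa <- sort(unique(unlist(lapply(alns, taxa_labels))))
  mats <- lapply(alns, function(a) {
    m <- matrix("-", length(taxa), n_sites(a), dimnames = list(taxa, NULL))
    m[taxa_labels(a), ] <- a$matrix
    m
  })
  phylo_alignment(do.call(cbind, mats), alphabet)
}

#' Build protein-domain data blocks from masked gene alignments
#'
#' Masked amino acid columns are removed (with their codons on the
#' nucleotide level). Remaining columns inside a domain annotation are
#' pooled across genes into one block per domain; columns outside any
#' domain form one residual block per gene. Every block records its
#' provenance and carries codon-frame-consistent nucleotide columns
#' (frame offset 0, whole codons by construction).
#'
#' @param genes list of `gene_record`s.
#' @return a named list of `data_block`s, each a list with `name`,
#'   `domain_id` (or `NA`), `provenance` (tibble gene_id / aa_col), `aa`
#'   and `nt` alignments (taxon union, missing-filled).
#' @export
build_blocks <- function(genes) {
  pieces <- list()  # per (block name): list of per-gene contributions
  for (g in genes) {
    keep <- setdiff(seq_len(n_sites(g$aa)), g$mask)
    if (!length(keep)) next
    in_domain <- rep(NA_character_, n_sites(g$aa))
    for (i in seq_len(nrow(g$domains))) {
      in_domain[g$domains$start[i]:g$domains$end[i]] <- g$domains$domain_id[i]
    }
    assignment <- in_domain[keep]
    for (dom in unique(assignment)) {
      cols <- keep[is.na(assignment) == is.na(dom) &
                     (is.na(dom) | assignment %in% dom)]
      name <- if (is.na(dom)) paste0("gene:", g$gene_id) else paste0("domain:", dom)
      pieces[[name]] <- c(pieces[[name]], list(list(
        gene_id = g$gene_id, aa_cols = cols,
        aa = slice_alignment(g$aa, columns = cols),
        nt = slice_alignment(g$nt, columns = codon_columns(cols)),
        domain_id = if (is.na(dom)) NA_character_ else dom
      )))
    }
  }
  blocks <- lapply(names(pieces), function(nm) {
    contrib <- pieces[[nm]]
    prov <- dplyr::bind_rows(lapply(contrib, function(p) {
      tibble::tibble(gene_id = p$gene_id, aa_col = p$aa_cols)
    }))
    structure(list(
      name = nm,
      domain_id = contrib[[1L]]$domain_id,
      provenance = prov,
      aa = union_alignment(lapply(contrib, `[[`, "aa"), "amino_acid"),
      nt = union_alignment(lapply(contrib, `[[`, "nt"), "nucleotide"),
      frame_offset = 0L
    ), class = "data_block")
  })
  stats::setNames(blocks, vapply(blocks, `[[`, character(1L), "name"))
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block> %s: %d aa / %d nt columns, %d taxa\n",
              x$name, n_sites(x$aa), n_sites(x$nt), n_taxa(x$aa)))
  invisible(x)
}

# taxa of a block with at least one non-missing aa character
block_taxa_with_data <- function(block) {
  has <- rowSums(!missing_mask(block$aa)) > 0L
  taxa_labels(block$aa)[has]
}

# a column is parsimony-informative if >= 2 states each occur >= 2 times
parsimony_informative_columns <- function(aln) {
  codes <- encode_alignment(aln)
  vapply(seq_len(ncol(codes)), function(j) {
    tab <- tabulate(codes[, j], nbins = length(alphabet_states(aln$alphabet)))
    sum(tab >= 2L) >= 2L
  }, logical(1L))
}

#' Drop blocks without phylogenetic information content
#'
#' A block is removed when fewer than 4 taxa carry data in it (no quartet
#' can be formed) or when it has no parsimony-informative amino acid
#' column. This is a stated proxy for information content, not a MARE
#' score; removal reasons are recorded so results cannot be confused with
#' MARE output.
#'
#' @param blocks named list of `data_block`s.
#' @return the kept blocks, with a `"report"` attribute tibble
#'   (`block`, `kept`, `reason`).
#' @export
empty_block_report <- function() {
  tibble::tibble(block = character(), n_aa_columns = integer(),
                 n_taxa_with_data = integer(),
                 kept = logical(), reason = character())
}

drop_uninformative_blocks <- function(blocks) {
  if (!length(blocks)) {
    attr(blocks, "report") <- empty_block_report()
    return(blocks)
  }
  report <- dplyr::bind_rows(lapply(blocks, function(b) {
    n_with_data <- length(block_taxa_with_data(b))
    informative <- any(parsimony_informative_columns(b$aa))
    reason <- if (n_with_data < 4L) {
      "fewer than 4 taxa with data"
    } else if (!informative) {
      "no parsimony-informative column"
    } else {
      NA_character_
    }
    tibble::tibble(block = b$name, n_aa_columns = n_sites(b$aa),
                   n_taxa_with_data = n_with_data,
                   kept = is.na(reason), reason = reason)
  }))
  kept <- blocks[report$block[report$kept]]
  attr(kept, "report") <- report
  kept
}

#' Keep blocks with sequence information from every required group
#'
#' A block passes when, for every group of the rule, at least one member
#' taxon has at least one non-missing character in the block; a taxon that
#' is present but fully gapped does not count as a representative.
#'
#' @param blocks named list of `data_block`s.
#' @param rule a `taxon_groups` with purpose `"block_filter"`.
#' @return the kept blocks, with a `"report"` attribute tibble.
#' @export
filter_required_groups <- function(blocks, rule) {
  if (!inherits(rule, "taxon_groups") || rule$purpose != "block_filter") {
    stop("rule must be a taxon_groups with purpose 'block_filter'")
  }
  if (!length(blocks)) {
    attr(blocks, "report") <-
      empty_block_report()[, c("block", "kept", "reason")]
    return(blocks)
  }
  report <- dplyr::bind_rows(lapply(blocks, function(b) {
    with_data <- block_taxa_with_data(b)
    missing_groups <- names(rule$groups)[
      !vapply(rule$groups, function(g) any(g %in% with_data), logical(1L))]
    tibble::tibble(block = b$name, kept = !length(missing_groups),
                   reason = if (length(missing_groups)) {
                     paste("no representative of:",
                           paste(missing_groups, collapse = ", "))
                   } else NA_character_)
  }))
  kept <- blocks[report$block[report$kept]]
  attr(kept, "report") <- report
  kept
}

#' Concatenate data blocks into a supermatrix
#'
#' Blocks are laid out in lexicographic name order; taxa are the sorted
#' union over blocks, with absent stretches missing-filled. Coordinates of
#' every block in the supermatrix are returned (1-based inclusive).
#'
#' @param blocks named list of `data_block`s.
#' @param level `"aa"` or `"nt"`.
#' @return list with `alignment` (the supermatrix `phylo_alignment`) and
#'   `blocks` (tibble `name`, `start`, `end`, `domain_id`).
#' @export
concatenate_blocks <- function(blocks, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (!length(blocks)) stop("no blocks to concatenate")
  blocks <- blocks[order(names(blocks))]
  alns <- lapply(blocks, `[[`, level)
  alphabet <- alns[[1L]]$alphabet
  if (!all(vapply(alns, function(a) a$alphabet == alphabet, logical(1L)))) {
    stop("blocks mix alphabets")
  }
  lens <- vapply(alns, n_sites, integer(1L))
  ends <- cumsum(lens)
  coords <- tibble::tibble(
    name = names(blocks),
    start = unname(ends - lens + 1L),
    end = unname(ends),
    domain_id = unname(vapply(blocks, function(b) b$domain_id %||% NA_character_,
                              character(1L)))
  )
  list(alignment = union_alignment(alns, alphabet), blocks = coords)
}

#' Emit a codon-position partition scheme
#'
#' `NT123` produces three partitions per block (codon positions 1, 2, 3);
#' `NT12` produces two per block and excludes all third-position columns
#' from the scheme's column universe.
#'
#' @param block_coords tibble with `name`, `start`, `end` over a
#'   nucleotide supermatrix, as returned by [concatenate_blocks()]; blocks
#'   must be in-frame (lengths divisible by 3).
#' @param mode `"NT123"` or `"NT12"`.
#' @return a `partition_scheme` with model hint `"GTR"`.
#' @export
emit_codon_scheme <- function(block_coords, mode = c("NT123", "NT12")) {
  mode <- match.arg(mode)
  if (any((block_coords$end - block_coords$start + 1L) %% 3L != 0L)) {
    stop("block length not divisible by 3; frame metadata inconsistent")
  }
  n_pos <- if (mode == "NT123") 3L else 2L
  parts <- list()
  for (i in seq_len(nrow(block_coords))) {
    for (pos in seq_len(n_pos)) {
      nm <- sprintf("%s_pos%d", block_coords$name[i], pos)
      parts[[nm]] <- seq.int(block_coords$start[i] + pos - 1L,
                             block_coords$end[i], by = 3L)
    }
  }
  partition_scheme(parts, model_hint = "GTR", mode = mode)
}

#' MCMC sample-count bookkeeping
#'
#' Retained posterior sample count across independent runs: each run
#' yields `n_generations / sample_every` samples (generation 0 excluded),
#' the first `floor(burnin_fraction x samples)` of which are discarded.
#'
#' @param n_runs number of independent runs.
#' @param n_generations generations per run; must be divisible by
#'   `sample_every`.
#' @param sample_every sampling interval in generations.
#' @param burnin_fraction fraction in `[0, 1)` discarded as burn-in.
#' @return total retained sample count over all runs.
#' @export
mcmc_sample_budget <- function(n_runs, n_generations, sample_every,
                               burnin_fraction) {
  if (n_runs < 1L || n_generations < 1L || sample_every < 1L) {
    stop("runs, generations and sampling interval must be positive")
  }
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  if (n_generations %% sample_every != 0) {
    stop("n_generations must be divisible by sample_every")
  }
  per_run <- n_generations %/% sample_every
  retained <- per_run - floor(burnin_fraction * per_run)
  n_runs * retained
}
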
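#' Alignment container
#'
#' A `phylo_alignment` is a plain character matrix (taxa in rows, columns in
#' sites) with an explicit alphabet and missing-data convention. `'-'` and
#' `'?'` are always missing; `'N'` (nucleotide) and `'X'` (amino acid) are
#' also treated as missing so that ambiguity-masked cells contribute no
#' signal to counts or likelihoods. Characters are stored upper-case.
#'
#' @param x character matrix with unique, non-empty rownames (taxon labels).
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return an object of class `phylo_alignment`.
#' @export
phylo_alignment <- function(x, alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(x) || !is.character(x)) {
    stop("`x` must be a character matrix (taxa x sites)")
  }
  taxa <- rownames(x)
  if (is.null(taxa) || anyNA(taxa) || any(!nzchar(taxa))) {
    stop("alignment rows must carry non-empty taxon labels")
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  }
  if (any(grepl("\\s", taxa))) {
    stop("taxon labels must not contain whitespace: '",
         taxa[grepl("\\s", taxa)][1L], "'")
  }
  x[] <- toupper(x)
  legal <- c(alphabet_states(alphabet), missing_symbols(alphabet))
  bad <- !(x %in% legal)
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(x))
    stop(sprintf("illegal character '%s' for %s alphabet at taxon '%s', column %d",
                 x[idx], alphabet, taxa[rc[1L]], rc[2L]))
  }
  structure(list(matrix = x, alphabet = alphabet),
            class = "phylo_alignment")
}

#' @export
print.phylo_alignment <- function(x, ...) {
  cat(sprintf("<phylo_alignment> %d taxa x %d sites (%s)\n",
              n_taxa(x), n_sites(x), x$alphabet))
  invisible(x)
}

#' Canonical residue states of an alphabet
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return character vector of states (4 nucleotides or 20 amino acids in
#'   the standard one-letter order used by the LG matrix).
#' @export
alphabet_states <- function(alphabet) {
  switch(alphabet,
         nucleotide = c("A", "C", "G", "T"),
         amino_acid = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
         stop("unknown alphabet: ", alphabet))
}

#' Missing-data symbols of an alphabet
#' @inheritParams alphabet_states
#' @return character vector of symbols treated as missing.
#' @export
missing_symbols <- function(alphabet) {
  switch(alphabet,
         nucleotide = c("-", "?", "N"),
         amino_acid = c("-", "?", "X"),
         stop("unknown alphabet: ", alphabet))
}

#' @rdname phylo_alignment
#' @param aln a `phylo_alignment`.
#' @export
n_taxa <- function(aln) nrow(aln$matrix)

#' @rdname phylo_alignment
#' @export
n_sites <- function(aln) ncol(aln$matrix)

#' @rdname phylo_alignment
#' @export
taxa_labels <- function(aln) rownames(aln$matrix)

#' Logical mask of missing cells
#' @param aln a `phylo_alignment`.
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(aln) {
  m <- aln$matrix %in% missing_symbols(aln$alphabet)
  dim(m) <- dim(aln$matrix)
  dimnames(m) <- dimnames(aln$matrix)
  m
}

#' Integer encoding of an alignment
#'
#' States are coded 1..k in the order of [alphabet_states()]; missing cells
#' are `NA`.
#' @param aln a `phylo_alignment`.
#' @return integer matrix with the alignment's dimnames.
#' @keywords internal
encode_alignment <- function(aln) {
  states <- alphabet_states(aln$alphabet)
  m <- match(aln$matrix, states)
  dim(m) <- dim(aln$matrix)
  dimnames(m) <- dimnames(aln$matrix)
  m
}

#' Slice an alignment
#' @param aln a `phylo_alignment`.
#' @param taxa character vector of taxon labels (default all).
#' @param columns integer vector of column indices (default all).
#' @return a `phylo_alignment` restricted to the requested rows/columns.
#' @export
slice_alignment <- function(aln, taxa = taxa_labels(aln), columns = seq_len(n_sites(aln))) {
  missing_taxa <- setdiff(taxa, taxa_labels(aln))
  if (length(missing_taxa)) {
    stop("unknown taxon: ", paste(missing_taxa, collapse = ", "))
  }
  m <- aln$matrix[taxa, columns, drop = FALSE]
  phylo_alignment(m, aln$alphabet)
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' @param path file path.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param format `"fasta"` or `"phylip"` (relaxed, sequential).
#' @return a `phylo_alignment`.
#' @export
read_alignment <- function(path, alphabet = c("nucleotide", "amino_acid"),
                           format = c("fasta", "phylip")) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    labels <- names(set)
    seqs <- as.character(set)
  } else {
    parsed <- read_relaxed_phylip(path)
    labels <- parsed$labels
    seqs <- parsed$seqs
  }
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("alignment contains an empty taxon label")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate taxon label: ", labels[duplicated(labels)][1L])
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  mat <- matrix("", nrow = length(seqs), ncol = lens[1L],
                dimnames = list(labels, NULL))
  if (lens[1L] > 0L) {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- labels
  }
  phylo_alignment(mat, alphabet)
}

# Relaxed sequential PHYLIP: header "ntaxa nsites", then one
# whitespace-separated "label sequence" record per line.
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed PHYLIP header: ", lines[1L])
  body <- lines[-1L]
  if (length(body) != hdr[1L]) {
    stop(sprintf("PHYLIP header declares %d taxa but %d records found",
                 hdr[1L], length(body)))
  }
  parts <- strsplit(trimws(body), "\\s+")
  labels <- vapply(parts, `[`, character(1L), 1L)
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1L))
  if (any(nchar(seqs) != hdr[2L])) {
    stop("PHYLIP record length disagrees with header site count")
  }
  list(labels = labels, seqs = seqs)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' `write_alignment()` followed by [read_alignment()] is the identity on
#' (taxa, matrix).
#' @param aln a `phylo_alignment`.
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  if (n_sites(aln) == 0L) seqs <- rep("", n_taxa(aln))
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", taxa_labels(aln)), seqs))
    writeLines(out, path)
  } else {
    out <- c(sprintf("%d %d", n_taxa(aln), n_sites(aln)),
             paste(taxa_labels(aln), seqs))
    writeLines(out, path)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around ape preserving branch lengths to 10 significant
#' digits on the write side.
#' @param path file path.
#' @return `read_newick()` returns an ape `phylo`; `write_newick()` its path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an ape `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
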
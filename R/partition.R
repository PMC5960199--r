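#' Partition scheme
#'
#' A named collection of pairwise-disjoint column sets over a supermatrix,
#' each with a model hint. Column indices are 1-based; emitted partition
#' files use the RAxML dialect `"MODEL, name = start-end[, ...]"` with
#' 1-based inclusive ranges and an optional `"\3"` codon-stride suffix.
#'
#' @param partitions named list of sorted integer column vectors.
#' @param model_hint character vector of model names, one per partition
#'   (recycled if length 1).
#' @param mode `"AA"`, `"NT123"` or `"NT12"`.
#' @return an object of class `partition_scheme`.
#' @export
partition_scheme <- function(partitions, model_hint = "GTR",
                             mode = c("AA", "NT123", "NT12")) {
  mode <- match.arg(mode)
  if (!length(partitions) || is.null(names(partitions)) ||
      any(!nzchar(names(partitions)))) {
    stop("partitions must be a non-empty named list")
  }
  if (anyDuplicated(names(partitions))) stop("duplicate partition names")
  partitions <- lapply(partitions, function(p) sort(unique(as.integer(p))))
  all_cols <- unlist(partitions, use.names = FALSE)
  if (anyDuplicated(all_cols)) {
    dup <- all_cols[duplicated(all_cols)][1L]
    owners <- names(partitions)[vapply(partitions, function(p) dup %in% p, logical(1L))]
    stop(sprintf("overlapping partitions: column %d appears in %s",
                 dup, paste(owners, collapse = " and ")))
  }
  if (any(all_cols < 1L)) stop("column indices must be >= 1")
  model_hint <- rep_len(as.character(model_hint), length(partitions))
  names(model_hint) <- names(partitions)
  structure(list(partitions = partitions, model_hint = model_hint, mode = mode),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("<partition_scheme> %s, %d partitions, %d columns\n",
              x$mode, length(x$partitions),
              length(unlist(x$partitions, use.names = FALSE))))
  invisible(x)
}

#' Columns covered by a scheme
#' @param scheme a `partition_scheme`.
#' @return sorted integer vector of all covered columns.
#' @export
scheme_columns <- function(scheme) {
  sort(unlist(scheme$partitions, use.names = FALSE))
}

#' One partition covering a whole alignment
#' @param aln a `phylo_alignment`.
#' @param name partition name.
#' @param model_hint model name for the single partition.
#' @return a `partition_scheme` with a single partition spanning `aln`.
#' @export
single_partition <- function(aln, name = "all", model_hint = "GTR") {
  mode <- if (aln$alphabet == "amino_acid") "AA" else "NT123"
  partition_scheme(stats::setNames(list(seq_len(n_sites(aln))), name),
                   model_hint = model_hint, mode = mode)
}

#' Read a RAxML-style partition file
#'
#' Dialect: one partition per line, `"MODEL, name = start-end[, start-end...]"`,
#' ranges 1-based inclusive, optional `"\3"` suffix meaning every third
#' column starting at `start`.
#'
#' @param path file path.
#' @param mode passed to [partition_scheme()].
#' @return a `partition_scheme`.
#' @export
read_partition_file <- function(path, mode = c("AA", "NT123", "NT12")) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- list()
  hints <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^\\s*([^,]+?)\\s*,\\s*([^=]+?)\\s*=\\s*(.+?)\\s*$", ln))[[1L]]
    if (length(m) != 4L) stop(sprintf("malformed partition line %d: '%s'", i, ln))
    model <- m[2L]; name <- m[3L]; spec <- m[4L]
    cols <- integer()
    for (rng in strsplit(spec, ",")[[1L]]) {
      rng <- trimws(rng)
      rm <- regmatches(rng, regexec("^(\\d+)\\s*-\\s*(\\d+)(\\\\3)?$", rng))[[1L]]
      if (length(rm) == 0L) {
        sm <- regmatches(rng, regexec("^(\\d+)$", rng))[[1L]]
        if (length(sm) == 0L) stop(sprintf("malformed range '%s' on line %d", rng, i))
        cols <- c(cols, as.integer(sm[2L]))
        next
      }
      a <- as.integer(rm[2L]); b <- as.integer(rm[3L])
      if (b < a) stop(sprintf("inverted range '%s' on line %d", rng, i))
      step <- if (nzchar(rm[4L])) 3L else 1L
      cols <- c(cols, seq.int(a, b, by = step))
    }
    parts[[name]] <- cols
    hints[name] <- model
  }
  partition_scheme(parts, model_hint = hints, mode = mode)
}

#' Write a RAxML-style partition file
#'
#' Runs of consecutive columns are emitted as `start-end`; runs with a
#' constant stride of 3 as `start-end\3`. Reading the emitted file with
#' [read_partition_file()] recovers the identical column sets.
#'
#' @param scheme a `partition_scheme`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_partition_file <- function(scheme, path) {
  fmt_cols <- function(cols) {
    runs <- character()
    i <- 1L
    n <- length(cols)
    while (i <= n) {
      # greedily take a stride-1 run, else a stride-3 run, else a singleton
      for (step in c(1L, 3L)) {
        j <- i
        while (j < n && cols[j + 1L] - cols[j] == step) j <- j + 1L
        if (j > i) break
      }
      if (j == i) {
        runs <- c(runs, sprintf("%d", cols[i]))
      } else if (step == 1L) {
        runs <- c(runs, sprintf("%d-%d", cols[i], cols[j]))
      } else {
        runs <- c(runs, sprintf("%d-%d\\3", cols[i], cols[j]))
      }
      i <- j + 1L
    }
    paste(runs, collapse = ", ")
  }
  lines <- vapply(names(scheme$partitions), function(nm) {
    sprintf("%s, %s = %s", scheme$model_hint[[nm]], nm,
            fmt_cols(scheme$partitions[[nm]]))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Taxon group configuration
#'
#' An ordered, pairwise-disjoint set of named taxon groups. With purpose
#' `"fclm_hypothesis"` exactly four non-empty groups are required (the four
#' clusters of a likelihood-mapping hypothesis); with `"block_filter"` any
#' number of non-empty groups is allowed (the required-groups rule for data
#' blocks).
#'
#' @param groups named list of character vectors of taxon labels.
#' @param purpose `"fclm_hypothesis"` or `"block_filter"`.
#' @return an object of class `taxon_groups`.
#' @export
taxon_groups <- function(groups, purpose = c("fclm_hypothesis", "block_filter")) {
  purpose <- match.arg(purpose)
  if (!length(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a non-empty named list")
  }
  groups <- lapply(groups, as.character)
  if (any(!lengths(groups))) {
    stop("empty group: ", names(groups)[!lengths(groups)][1L])
  }
  all_taxa <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_taxa)) {
    dup <- unique(all_taxa[duplicated(all_taxa)])
    stop("groups overlap; shared taxa: ", paste(dup, collapse = ", "))
  }
  if (purpose == "fclm_hypothesis" && length(groups) != 4L) {
    stop("an FcLM hypothesis requires exactly 4 groups, got ", length(groups))
  }
  structure(list(groups = groups, purpose = purpose), class = "taxon_groups")
}

#' @export
print.taxon_groups <- function(x, ...) {
  cat(sprintf("<taxon_groups> purpose=%s: %s\n", x$purpose,
              paste(sprintf("%s(%d)", names(x$groups), lengths(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write taxon group configurations (JSON)
#'
#' Format: `{"groups": {"name": ["taxonA", ...], ...}, "purpose": "..."}`.
#' @param path file path.
#' @return `read_taxon_groups()` returns a `taxon_groups`.
#' @export
read_taxon_groups <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$groups)) stop("taxon group config missing 'groups' field: ", path)
  groups <- lapply(doc$groups, as.character)
  taxon_groups(groups, purpose = doc$purpose %||% "fclm_hypothesis")
}

#' @rdname read_taxon_groups
#' @param groups a `taxon_groups`.
#' @export
write_taxon_groups <- function(groups, path) {
  jsonlite::write_json(list(groups = groups$groups, purpose = groups$purpose),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Check that all grouped taxa occur in an alignment
#' @param groups a `taxon_groups`.
#' @param aln a `phylo_alignment`.
#' @return invisibly `TRUE`; errors naming absent taxa otherwise.
#' @export
validate_groups_in_alignment <- function(groups, aln) {
  absent <- setdiff(unlist(groups$groups, use.names = FALSE), taxa_labels(aln))
  if (length(absent)) {
    stop("taxa listed in groups but absent from alignment: ",
         paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}
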
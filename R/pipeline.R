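#' Run the full diagnostics pipeline
#'
#' Chains every stage on a fixture-style input directory: read gene
#' records, build domain data blocks, drop uninformative blocks, apply the
#' required-groups rule (when a block-filter config is given), concatenate
#' the amino acid supermatrix, emit codon partition schemes for the
#' nucleotide supermatrix, screen taxon pairs with Bowker's test, run FcLM
#' on the original matrix and on permutation schemes I-III, and compute
#' permutation-corrected support. Per-stage reports and a run manifest are
#' written under `out_dir`; rerunning with identical inputs and seed
#' reproduces the outputs.
#'
#' @param input_dir fixture directory (see [make_fixture()]); must contain
#'   `groups.json` (the FcLM hypothesis) unless `groups` is supplied.
#' @param out_dir output directory (created).
#' @param groups optional `taxon_groups` hypothesis (overrides
#'   `groups.json`).
#' @param block_filter optional `taxon_groups` with purpose
#'   `"block_filter"` for the required-groups rule.
#' @param level `"aa"` or `"nt"`: which supermatrix feeds the symmetry
#'   screen and FcLM.
#' @param max_quartets per-FcLM-run quartet cap.
#' @param alpha significance level of the symmetry screen.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @param schemes which permutation schemes to run (subset of I/II/III).
#' @return invisibly, a list with the supermatrix, block coordinates,
#'   symmetry tibble, FcLM reports, corrected-support tibbles, and the
#'   manifest.
#' @export
run_pipeline <- function(input_dir, out_dir, groups = NULL,
                         block_filter = NULL, level = c("aa", "nt"),
                         max_quartets = 50L, alpha = 0.05, seed = 1L,
                         schemes = c("I", "II", "III")) {
  level <- match.arg(level)
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(groups)) {
    gp <- file.path(input_dir, "groups.json")
    if (!file.exists(gp)) stop("config missing groups: no `groups` argument ",
                               "and no groups.json in ", input_dir)
    groups <- read_taxon_groups(gp)
  }

  genes <- stage("read_genes", read_gene_records(input_dir))
  blocks <- stage("build_blocks", build_blocks(genes))
  blocks <- stage("drop_uninformative", drop_uninformative_blocks(blocks))
  info_report <- attr(blocks, "report")
  group_report <- NULL
  if (!is.null(block_filter)) {
    blocks <- stage("required_groups", filter_required_groups(blocks, block_filter))
    group_report <- attr(blocks, "report")
  }
  concat <- stage("concatenate", concatenate_blocks(blocks, level = level))
  supermatrix <- concat$alignment
  scheme <- if (level == "nt") {
    emit_codon_scheme(concat$blocks, "NT123")
  } else {
    partition_scheme(
      stats::setNames(
        mapply(seq.int, concat$blocks$start, concat$blocks$end,
               SIMPLIFY = FALSE),
        concat$blocks$name),
      model_hint = "LG", mode = "AA")
  }

  write_alignment(supermatrix, file.path(out_dir, "supermatrix.fasta"))
  write_partition_file(scheme, file.path(out_dir, "partitions.txt"))
  utils::write.table(info_report, file.path(out_dir, "block_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sym <- stage("symmetry", pairwise_symmetry(supermatrix, alpha = alpha))
  utils::write.table(tidy(sym), file.path(out_dir, "symmetry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  models <- stage("fit_models",
                  estimate_partition_models(supermatrix, scheme,
                                            seed = seed))
  fclm_orig <- stage("fclm_original",
                     run_fclm(supermatrix, groups, scheme = scheme,
                              models = models, max_quartets = max_quartets,
                              seed = seed, matrix_label = "original"))
  reports <- list(original = fclm_orig)
  corrections <- list()
  # permuted amino acid matrices are analyzed under LG across all
  # partitions; the permutation destroys any per-partition structure
  perm_models <- if (level == "aa") {
    model_lg(gamma_shape = 1, n_categories = 4L)
  } else {
    models
  }
  for (sc in schemes) {
    lab <- paste0("scheme_", sc)
    perm <- stage(paste0("permute_", sc),
                  permute_matrix(supermatrix, scheme, which = sc,
                                 frequency_source =
                                   if (level == "aa") "LG" else "empirical",
                                 seed = seed + match(sc, c("I", "II", "III"))))
    rep_sc <- stage(paste0("fclm_", lab),
                    run_fclm(perm, groups, scheme = scheme,
                             models = perm_models,
                             max_quartets = max_quartets, seed = seed,
                             matrix_label = lab))
    reports[[lab]] <- rep_sc
    corrections[[lab]] <- corrected_support(fclm_orig, rep_sc)
  }

  for (nm in names(reports)) {
    jsonlite::write_json(glance(reports[[nm]]),
                         file.path(out_dir, paste0("fclm_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  input_files <- sort(list.files(input_dir, full.names = TRUE))
  manifest <- list(
    tool = "quartetdiag",
    version = as.character(utils::packageVersion("quartetdiag")),
    subcommand = "pipeline",
    config = list(level = level, max_quartets = max_quartets, alpha = alpha,
                  schemes = schemes),
    seed = seed,
    input_checksums = as.list(tools::md5sum(input_files)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(supermatrix = supermatrix, blocks = concat$blocks,
                 scheme = scheme, symmetry = sym, fclm = reports,
                 corrected = corrections,
                 block_reports = list(information = info_report,
                                      required_groups = group_report),
                 manifest = manifest))
}
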
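mk_gene <- function(gene_id, aa_seqs, taxa = paste0("t", seq_along(aa_seqs)),
                    mask = integer(), domains = NULL) {
  aa <- mk_aln(aa_seqs, "amino_acid", taxa)
  nt_seqs <- vapply(aa_seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(ch) {
      if (ch %in% c("-", "?", "X")) strrep(ch, 3) else "ACG"
    }, character(1)), collapse = "")
  }, character(1))
  nt <- mk_aln(unname(nt_seqs), "nucleotide", taxa)
  gene_record(gene_id, aa, nt, mask = mask, domains = domains)
}

test_that("gene records validate dimensions, masks and domain overlaps", {
  g <- mk_gene("g1", c("MKLV", "MKLV"))
  expect_s3_class(g, "gene_record")
  aa <- mk_aln(c("MKLV", "MKLV"), "amino_acid")
  nt <- mk_aln(c("ACGACG", "ACGACG"))
  expect_error(gene_record("g2", aa, nt), "not 3x")
  expect_error(mk_gene("g3", c("MKLV", "MKLV"), mask = 9L), "mask")
  expect_error(
    mk_gene("g4", c("MKLVAA", "MKLVAA"),
            domains = data.frame(domain_id = c("D1", "D2"),
                                 start = c(1L, 3L), end = c(4L, 6L))),
    "overlapping domain")
})

test_that("block building pools domains across genes and drops masked codons", {
  g <- mk_gene("g1", c("MKLVAAMKLV", "MKLVAAMKLV"))
  b <- build_blocks(list(g))
  expect_identical(names(b), "gene:g1")
  expect_identical(n_sites(b[[1]]$aa), 10L)
  expect_identical(n_sites(b[[1]]$nt), 30L)

  # full masking leaves nothing
  g2 <- mk_gene("g2", c("MKLV", "MKLV"), mask = 1:4)
  expect_identical(length(build_blocks(list(g2))), 0L)

  # shared domain id pools columns across genes; leftovers stay per gene
  d <- data.frame(domain_id = "PF_A", start = 2L, end = 3L)
  ga <- mk_gene("ga", c("MKLV", "MKLV"), domains = d)
  gb <- mk_gene("gb", c("AMKLVA", "AMKLVA"), taxa = c("t2", "t3"),
                domains = data.frame(domain_id = "PF_A", start = 1L, end = 4L))
  bb <- build_blocks(list(ga, gb))
  expect_setequal(names(bb), c("domain:PF_A", "gene:ga", "gene:gb"))
  expect_identical(n_sites(bb[["domain:PF_A"]]$aa), 6L)  # 2 + 4 pooled
  expect_setequal(taxa_labels(bb[["domain:PF_A"]]$aa), c("t1", "t2", "t3"))
  # taxon absent from a contributing gene is missing-filled there
  expect_true(all(bb[["domain:PF_A"]]$aa$matrix["t1", 3:6] == "-"))

  # masked aa columns take their whole codon with them
  g3 <- mk_gene("g3", c("MKLV", "MKLV"), mask = 2L)
  b3 <- build_blocks(list(g3))
  expect_identical(n_sites(b3[[1]]$aa), 3L)
  expect_identical(n_sites(b3[[1]]$nt), 9L)
})

test_that("uninformative blocks are dropped for taxon count or constancy", {
  few <- build_blocks(list(mk_gene("few", c("MKMK", "MKMK", "MKMK"))))
  kept <- drop_uninformative_blocks(few)
  expect_identical(length(kept), 0L)
  expect_match(attr(kept, "report")$reason, "fewer than 4")

  const <- build_blocks(list(mk_gene("const", rep("MMMM", 5))))
  kept2 <- drop_uninformative_blocks(const)
  expect_identical(length(kept2), 0L)
  expect_match(attr(kept2, "report")$reason, "parsimony")

  # one column with two states twice each is parsimony-informative
  inf <- build_blocks(list(mk_gene("inf", c("M", "M", "K", "K"))))
  expect_identical(length(drop_uninformative_blocks(inf)), 1L)
})

test_that("required-groups rule demands actual sequence information", {
  blocks <- build_blocks(list(
    mk_gene("g1", c("MKLV", "MKLV", "MKLV", "----"),
            taxa = c("out1", "bee1", "wasp1", "wasp2"))))
  rule_ok <- taxon_groups(list(outgroup = "out1", bees = "bee1",
                               wasps = c("wasp1", "wasp2")),
                          purpose = "block_filter")
  expect_identical(length(filter_required_groups(blocks, rule_ok)), 1L)

  # a group whose only member is fully gapped does not count
  rule_gapped <- taxon_groups(list(outgroup = "out1", ghosts = "wasp2"),
                              purpose = "block_filter")
  kept <- filter_required_groups(blocks, rule_gapped)
  expect_identical(length(kept), 0L)
  expect_match(attr(kept, "report")$reason, "ghosts")

  expect_error(filter_required_groups(blocks, rule_ok$groups), "taxon_groups")
})

test_that("concatenation lays out blocks with coordinates and missing fill", {
  ga <- mk_gene("a", c("MKLVMKLVMK", "MKLVMKLVMK"), taxa = c("t1", "t2"))
  gb <- mk_gene("b", rep(strrep("MKLVM", 4), 2), taxa = c("t2", "t3"))
  blocks <- build_blocks(list(ga, gb))
  cc <- concatenate_blocks(blocks, "aa")
  expect_identical(n_sites(cc$alignment), 30L)
  expect_identical(cc$blocks$start, c(1L, 11L))
  expect_identical(cc$blocks$end, c(10L, 30L))
  expect_setequal(taxa_labels(cc$alignment), c("t1", "t2", "t3"))
  expect_true(all(cc$alignment$matrix["t3", 1:10] == "-"))
  expect_true(all(cc$alignment$matrix["t1", 11:30] == "-"))

  # single-block concatenation is the identity on the block alignment
  solo <- concatenate_blocks(blocks[1], "aa")
  expect_identical(solo$alignment$matrix, blocks[[1]]$aa$matrix)

  # slice/concat round trip
  for (i in seq_len(nrow(cc$blocks))) {
    cols <- cc$blocks$start[i]:cc$blocks$end[i]
    sliced <- slice_alignment(cc$alignment,
                              taxa_labels(blocks[[cc$blocks$name[i]]]$aa),
                              cols)
    expect_identical(sliced$matrix, blocks[[cc$blocks$name[i]]]$aa$matrix)
  }
})

test_that("codon schemes stride correctly and NT12 drops third positions", {
  coords <- tibble::tibble(name = "b1", start = 1L, end = 9L,
                           domain_id = NA_character_)
  s123 <- emit_codon_scheme(coords, "NT123")
  expect_identical(s123$partitions$b1_pos1, c(1L, 4L, 7L))
  expect_identical(s123$partitions$b1_pos2, c(2L, 5L, 8L))
  expect_identical(s123$partitions$b1_pos3, c(3L, 6L, 9L))
  s12 <- emit_codon_scheme(coords, "NT12")
  expect_identical(names(s12$partitions), c("b1_pos1", "b1_pos2"))
  expect_identical(length(scheme_columns(s12)),
                   as.integer(2 / 3 * length(scheme_columns(s123))))
  expect_error(emit_codon_scheme(tibble::tibble(name = "x", start = 1L,
                                                end = 8L,
                                                domain_id = NA_character_)),
               "divisible by 3")
})

test_that("filter order does not matter and NT123 tiles the supermatrix", {
  set.seed(81)
  rule <- taxon_groups(list(first = c("t01", "t02"), rest = c("t05", "t06")),
                       purpose = "block_filter")
  for (i in 1:10) {
    genes <- random_gene_set()
    blocks <- build_blocks(genes)
    ab <- filter_required_groups(drop_uninformative_blocks(blocks), rule)
    ba <- drop_uninformative_blocks(filter_required_groups(blocks, rule))
    expect_identical(sort(names(ab)), sort(names(ba)))
    if (!length(ab)) next
    cc <- concatenate_blocks(ab, "nt")
    s123 <- emit_codon_scheme(cc$blocks, "NT123")
    cols <- scheme_columns(s123)
    expect_identical(cols, seq_len(n_sites(cc$alignment)))  # disjoint + complete
  }
})

test_that("MCMC sample bookkeeping matches the run arithmetic", {
  expect_identical(mcmc_sample_budget(3, 3e6, 500, 0.25), 13500)
  expect_identical(mcmc_sample_budget(1, 1000, 100, 0), 10)
  expect_identical(mcmc_sample_budget(2, 1000, 100, 0.5), 10)
  expect_error(mcmc_sample_budget(1, 1000, 300, 0), "divisible")
  expect_error(mcmc_sample_budget(1, 1000, 100, 1), "burnin")
})
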
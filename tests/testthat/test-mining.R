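# In-code annotation builder: genes as (start, end, strand, product, ecs).
make_annotation <- function(..., replicon_len = 100000L) {
  specs <- list(...)
  df <- data.frame(
    gene_id = vapply(seq_along(specs), function(i) {
      specs[[i]]$id %||% sprintf("g%02d", i)
    }, ""),
    replicon_id = "chr",
    start = vapply(specs, function(s) as.integer(s$start), integer(1)),
    end = vapply(specs, function(s) as.integer(s$end), integer(1)),
    strand = vapply(specs, `[[`, "", "strand"),
    product = vapply(specs, function(s) s$product %||% "hypothetical",
                     character(1)),
    stringsAsFactors = FALSE
  )
  df$ec_numbers <- lapply(specs, function(s) s$ecs %||% character(0))
  df$is_tr <- NA
  df$tr_family <- NA_character_
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  structure(list(
    replicons = data.frame(replicon_id = "chr", length = replicon_len,
                           stringsAsFactors = FALSE),
    genes = df, sequences = list()
  ), class = "genome_annotation")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TR detection matches family tokens independent of word order", {
  ann <- make_annotation(
    list(start = 0, end = 100, strand = "+",
         product = "LysR family transcriptional regulator"),
    list(start = 200, end = 300, strand = "+",
         product = "xanthine dehydrogenase subunit A"),
    list(start = 400, end = 500, strand = "+",
         product = "transcriptional regulator, MarR family"),
    list(start = 600, end = 700, strand = "+",
         product = "sigma-54 dependent transcriptional activator")
  )
  ann <- detect_tr_genes(ann)
  expect_equal(ann$genes$is_tr, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(ann$genes$tr_family[c(1, 3, 4)],
               c("LysR", "MarR", "sigma54"))
  expect_true(is.na(ann$genes$tr_family[2]))
})

test_that("operons are maximal same-strand runs bounded by max_gap", {
  # gaps 50 and 60 -> one 3-gene operon
  ann <- detect_tr_genes(make_annotation(
    list(start = 0, end = 300, strand = "+", product = "enzyme kinase"),
    list(start = 350, end = 600, strand = "+", product = "enzyme lyase"),
    list(start = 660, end = 900, strand = "+", product = "enzyme mutase")
  ))
  ops <- infer_operons(ann, max_gap = 150)
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$n_genes, 3L)
  expect_equal(ops$n_catalytic, 3L)

  # 400 bp gap with max_gap 150 -> two single-gene operons
  ann2 <- detect_tr_genes(make_annotation(
    list(start = 0, end = 300, strand = "+", product = "enzyme kinase"),
    list(start = 700, end = 1000, strand = "+", product = "enzyme lyase")
  ))
  expect_equal(nrow(infer_operons(ann2, max_gap = 150)), 2L)

  # interposed opposite-strand gene breaks the run
  ann3 <- detect_tr_genes(make_annotation(
    list(start = 0, end = 300, strand = "+", product = "enzyme kinase"),
    list(start = 320, end = 500, strand = "-", product = "hypothetical"),
    list(start = 520, end = 800, strand = "+", product = "enzyme lyase")
  ))
  ops3 <- infer_operons(ann3, max_gap = 150)
  expect_equal(sum(ops3$strand == "+"), 2L)

  # minus-strand operons list genes in transcription order (descending start)
  ann4 <- detect_tr_genes(make_annotation(
    list(id = "down", start = 0, end = 300, strand = "-",
         product = "enzyme kinase"),
    list(id = "up", start = 350, end = 600, strand = "-",
         product = "enzyme lyase")
  ))
  ops4 <- infer_operons(ann4, max_gap = 150)
  expect_equal(ops4$genes[[1]], c("up", "down"))
})

test_that("TR genes are excluded from operons and their catalytic counts", {
  ann <- detect_tr_genes(make_annotation(
    list(start = 0, end = 300, strand = "+",
         product = "TetR family transcriptional regulator",
         ecs = "1.1.1.1"),
    list(start = 320, end = 600, strand = "+", product = "enzyme kinase"),
    list(start = 620, end = 900, strand = "+", product = "enzyme lyase")
  ))
  ops <- infer_operons(ann, max_gap = 150)
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$n_genes, 2L)
  expect_equal(ops$n_catalytic, 2L)
})

test_that("divergent pairs reproduce the 146-bp head-to-head geometry", {
  # minus-strand TR ending at 1000, plus-strand operon starting at 1146
  ann <- detect_tr_genes(make_annotation(
    list(id = "benM", start = 100, end = 1000, strand = "-",
         product = "LysR family transcriptional regulator"),
    list(id = "benA", start = 1146, end = 2000, strand = "+",
         product = "benzoate 1,2-dioxygenase subunit alpha",
         ecs = "1.14.12.10"),
    list(id = "benB", start = 2050, end = 2600, strand = "+",
         product = "benzoate 1,2-dioxygenase subunit beta",
         ecs = "1.14.12.10")
  ))
  ops <- infer_operons(ann)
  pairs <- find_divergent_candidates(ann, ops)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$tr_gene_id, "benM")
  expect_equal(pairs$intergenic_length, 146L)
  expect_equal(pairs$promoter_start, 1000L)
  expect_equal(pairs$promoter_end, 1146L)
})

test_that("convergent and co-directional arrangements are excluded", {
  # convergent: plus TR then minus operon (3' ends facing)
  conv <- detect_tr_genes(make_annotation(
    list(start = 100, end = 1000, strand = "+",
         product = "LysR family transcriptional regulator"),
    list(start = 1146, end = 2000, strand = "-", product = "enzyme kinase"),
    list(start = 2050, end = 2600, strand = "-", product = "enzyme lyase")
  ))
  expect_equal(nrow(find_divergent_candidates(conv, infer_operons(conv))),
               0L)
  # co-directional
  codir <- detect_tr_genes(make_annotation(
    list(start = 100, end = 1000, strand = "+",
         product = "LysR family transcriptional regulator"),
    list(start = 1400, end = 2000, strand = "+", product = "enzyme kinase"),
    list(start = 2050, end = 2600, strand = "+", product = "enzyme lyase")
  ))
  expect_equal(nrow(find_divergent_candidates(codir,
                                              infer_operons(codir))), 0L)
  # no TR genes at all -> vacuous screen
  notr <- detect_tr_genes(make_annotation(
    list(start = 100, end = 1000, strand = "-", product = "enzyme kinase"),
    list(start = 1146, end = 2000, strand = "+", product = "enzyme lyase")
  ))
  expect_equal(nrow(find_divergent_candidates(notr, infer_operons(notr))),
               0L)
})

test_that("overlapping TR/operon genes and oversized gaps are rejected", {
  overlap <- detect_tr_genes(make_annotation(
    list(start = 100, end = 1200, strand = "-",
         product = "LysR family transcriptional regulator"),
    list(start = 1100, end = 2000, strand = "+", product = "enzyme kinase"),
    list(start = 2050, end = 2600, strand = "+", product = "enzyme lyase")
  ))
  expect_equal(nrow(find_divergent_candidates(overlap,
                                              infer_operons(overlap))), 0L)
  far <- detect_tr_genes(make_annotation(
    list(start = 100, end = 1000, strand = "-",
         product = "LysR family transcriptional regulator"),
    list(start = 1700, end = 2000, strand = "+", product = "enzyme kinase"),
    list(start = 2050, end = 2600, strand = "+", product = "enzyme lyase")
  ))
  expect_equal(nrow(find_divergent_candidates(far, infer_operons(far),
                                              max_intergenic = 500)), 0L)
})

test_that("promoter extraction returns the operon-strand sequence", {
  dir <- withr::local_tempdir()
  gen <- generate_toy_genome(plant_spec(n_systems = 1, n_decoys = 0,
                                        seed = 5), dir)
  ann <- detect_tr_genes(read_annotated_genome(gen$genome))
  ops <- infer_operons(ann)
  pairs <- find_divergent_candidates(ann, ops)
  pr <- extract_promoter_region(pairs[1, ], ann)
  expect_equal(pr$length, pairs$intergenic_length[1])
  # plus-strand operon: sequence is the top strand verbatim
  top <- substr(ann$sequences[[1]], pr$start + 1, pr$end)
  expect_equal(pr$sequence, top)

  # minus-strand operon: reverse complement, checked independently
  minus_pair <- pairs[1, ]
  minus_pair$strand <- "-"
  pr2 <- extract_promoter_region(minus_pair, ann)
  indep_rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", top), "")[[1]]),
                    collapse = "")
  expect_equal(pr2$sequence, indep_rc)

  # out-of-bounds interval is an internal consistency error
  bad <- pairs[1, ]
  bad$promoter_end <- ann$replicons$length + 10
  expect_error(extract_promoter_region(bad, ann), "bounds")
})

test_that("screen output is invariant under input record order", {
  dir <- withr::local_tempdir()
  gen <- generate_toy_genome(plant_spec(n_systems = 3, n_decoys = 3,
                                        seed = 9), dir)
  ann <- detect_tr_genes(read_annotated_genome(gen$genome))
  shuffled <- ann
  set.seed(1)
  perm <- sample(nrow(ann$genes))
  shuffled$genes <- ann$genes[perm, ]
  shuffled$genes <- shuffled$genes[order(shuffled$genes$replicon_id,
                                         shuffled$genes$start), ]
  rownames(shuffled$genes) <- NULL
  p1 <- find_divergent_candidates(ann, infer_operons(ann))
  p2 <- find_divergent_candidates(shuffled, infer_operons(shuffled))
  expect_equal(p1, p2)
})

test_that("returned promoter intervals never overlap a CDS", {
  for (seed in c(2, 13, 77)) {
    dir <- withr::local_tempdir()
    gen <- generate_toy_genome(plant_spec(n_systems = 3, n_decoys = 5,
                                          seed = seed), dir)
    ann <- detect_tr_genes(read_annotated_genome(gen$genome))
    pairs <- find_divergent_candidates(ann, infer_operons(ann))
    expect_gt(nrow(pairs), 0L)
    for (i in seq_len(nrow(pairs))) {
      overlaps <- ann$genes$start < pairs$promoter_end[i] &
        ann$genes$end > pairs$promoter_start[i]
      expect_false(any(overlaps))
    }
  }
})
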
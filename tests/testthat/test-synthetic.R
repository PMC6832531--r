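## The synthetic-data generator: determinism, template guarantees, read
## emission, and self-consistency of the ground truth.

test_that("identical seeds give byte-identical loci and scenario bundles", {
  expect_identical(build_locus("MP17", seed = 1), build_locus("MP17", seed = 1))
  expect_identical(build_locus("SP6", seed = 3), build_locus("SP6", seed = 3))
  a <- simulate_scenario("svVEGF_suite", seed = 5)
  b <- simulate_scenario("svVEGF_suite", seed = 5)
  expect_identical(a$sim$reads, b$sim$reads)
  expect_identical(a$sim$truth, b$sim$truth)
  ## different seeds change the sequence
  expect_false(identical(build_locus("MP17", seed = 1)$genome,
                         build_locus("MP17", seed = 2)$genome))
})

test_that("template guarantees hold: motif placement, exon counts, triad, intron stops", {
  loc <- build_locus("MP17", seed = 1)
  m <- loc$model
  expect_identical(nrow(m$exons), 17L)
  ## the zinc motif matches the reference protein, with all codons in exon 11
  rx <- gsub("X", ".", m$motifs$pattern[1L], fixed = TRUE)
  hit <- regexpr(rx, m$ref_protein)
  expect_gt(hit[1L], 0L)
  cum <- c(0L, cumsum(with(m$exons, end - start)))
  nt_span <- m$cds_start + c((hit[1L] - 1L) * 3L,
                             (hit[1L] - 1L + attr(hit, "match.length")) * 3L)
  expect_true(nt_span[1L] >= cum[11L] && nt_span[2L] <= cum[12L])
  ## CDS is free of internal stops
  expect_false(grepl("\\*", m$ref_protein))
  ## phospholipase template has four exons
  expect_identical(nrow(build_locus("PLA2_4", seed = 2)$model$exons), 4L)
  ## serine-protease triad at the annotated positions
  sp <- build_locus("SP6", seed = 3)$model
  expect_identical(substr(sp$ref_protein, 57, 57), "H")
  expect_identical(substr(sp$ref_protein, 102, 102), "D")
  expect_identical(substr(sp$ref_protein, 195, 195), "S")
  ## every intron carries a stop in all three frames within its first 60 nt
  seqs <- loc$genome[[m$scaffold]]
  de <- m$exons[m$exons$in_original, ]
  for (i in seq_len(nrow(de) - 1L)) {
    intr <- substr(seqs, de$end[i] + 1L, de$start[i + 1L])
    head60 <- substr(intr, 1L, 60L)
    for (frame in 0:2) {
      codons <- substring(head60, seq(1L + frame, 58L, 3L),
                          seq(3L + frame, 60L, 3L))
      expect_true(any(codons %in% c("TAA", "TAG", "TGA")))
    }
  }
  ## at least two polyA signals, hexamer present at each annotated position
  expect_gte(length(m$polya_signals), 2L)
  for (p in m$polya_signals) {
    expect_identical(substr(seqs, p + 1L, p + 6L), "AATAAA")
  }
})

test_that("unknown templates and scenarios are rejected", {
  expect_error(build_locus("MP99", seed = 1), "unknown")
  expect_error(simulate_scenario("nope"), "unknown")
})

test_that("emitted reads splice the planned blocks and carry tails", {
  loc <- build_locus("MP17", seed = 4, gene_id = "g", scaffold = "s")
  models <- list(g = loc$model)
  plans <- list(
    read_plan("orig", list(event_spec("NONE")), gene_id = "g", support = 3L),
    read_plan("skip15", list(event_spec("EXON_SKIP", exons = 15L)),
              gene_id = "g", support = 1L)
  )
  sim <- emit_reads(models, loc$genome, plans, seed = 4)
  ## support 3 -> three identical full-length reads
  expect_identical(length(sim$reads), 4L)
  expect_identical(sim$reads[["orig_r1"]], sim$reads[["orig_r2"]])
  expect_identical(sim$reads[["orig_r1"]], sim$reads[["orig_r3"]])
  expect_true(endsWith(sim$reads[["orig_r1"]], strrep("A", 30L)))
  ## skip chain omits exon 15's interval exactly
  de <- loc$model$exons[loc$model$exons$in_original, ]
  e15 <- de[de$index == 15L, ]
  b <- sim$chains[["skip15_r1"]]$blocks
  expect_false(any(b[, 1L] < e15$end & b[, 2L] > e15$start))
  expect_identical(nrow(b), 16L)
  ## original read equals the model transcript + tail
  tx <- venomsplice:::model_transcript_seq(loc$model, loc$genome[["s"]])
  expect_identical(sim$reads[["orig_r1"]], paste0(tx, strrep("A", 30L)))
  ## one truth row per read
  expect_identical(nrow(sim$truth), 4L)
  ## inapplicable plans error with the plan named
  bad <- list(read_plan("bad", list(event_spec("EXON_SKIP", exons = 99L)),
                        gene_id = "g"))
  expect_error(emit_reads(models, loc$genome, bad, seed = 1), "bad")
})

test_that("chimeric reads span both donor genes colinearly", {
  cl <- build_cluster(c("SP6", "SP6"), seed = 6, gene_ids = c("gA", "gB"),
                      scaffold = "s")
  plan <- read_plan("chim", chimera = chimera_spec(list(
    list(gene_id = "gA", exons = 1:5), list(gene_id = "gB", exons = 6L))),
    support = 1L)
  sim <- emit_reads(cl$models, cl$genome, list(plan), seed = 6)
  b <- sim$chains[["chim_r1"]]$blocks
  expect_identical(nrow(b), 6L)
  deA <- cl$models$gA$exons; deB <- cl$models$gB$exons
  expect_true(all(b[1:5, 1L] == deA$start[1:5]))
  expect_identical(unname(b[6L, 1L]), deB$start[6L])
  expect_true(all(diff(b[, 1L]) > 0L))  # colinear
  ## a single-gene "cluster" admits no chimeras
  expect_error(chimera_spec(list(list(gene_id = "gA", exons = 1:6))),
               "two distinct genes")
})

test_that("two clusters on two scaffolds group separately", {
  c1 <- build_cluster(rep("SP6", 3L), seed = 7, scaffold = "sX")
  c2 <- build_cluster(rep("SP6", 2L), seed = 8,
                      gene_ids = c("p1", "p2"), scaffold = "sY")
  models <- c(c1$models, c2$models)
  cls <- infer_clusters(models)
  expect_length(cls, 2L)
  expect_setequal(vapply(cls, function(x) x$scaffold, character(1)),
                  c("sX", "sY"))
})

test_that("the ground-truth protein is reproduced by an independent translation scan", {
  for (name in c("svMP05_suite", "svVEGF_suite", "svSP_clusters")) {
    sc <- get_scenario(name)
    tr <- sc$sim$truth
    for (i in which(tr$status == "full_length")) {
      rid <- tr$read_id[i]
      ch <- sc$sim$chains[[rid]]
      seqs <- sc$sim$reads[[rid]]
      ## locate the start independently: canonical position if present else
      ## first ATG
      m <- sc$models[[strsplit(tr$gene_id[i], "+", fixed = TRUE)[[1L]][1L]]]
      ob <- venomsplice:::oriented_blocks(ch)
      g0 <- venomsplice:::.t2g(venomsplice:::oriented_exons(m), m$cds_start)
      t0 <- venomsplice:::.g2t(ob, g0)
      start <- if (!is.na(t0) && substr(seqs, t0 + 1L, t0 + 3L) == "ATG") t0
               else regexpr("ATG", seqs, fixed = TRUE)[1L] - 1L
      expect_identical(oracle_translate(seqs, start), tr$protein[i],
                       label = paste("truth protein for", rid))
    }
  }
})

test_that("every injected event class appears in at least one scenario", {
  evs <- unlist(lapply(c("svMP05_suite", "svMP08_suite", "svVEGF_suite",
                         "svSP_clusters"), function(n) {
    sc <- get_scenario(n)
    c(sc$sim$truth$events, if (any(sc$sim$truth$chimeric)) "CHIMERA")
  }))
  for (kind in c("EXON_SKIP", "INTRON_RETENTION", "PARTIAL_INTRON_RETENTION",
                 "ALT_DONOR", "ALT_ACCEPTOR", "ALT_FIRST_EXON", "ALT_POLYA",
                 "CHIMERA")) {
    expect_true(any(grepl(kind, evs)), label = paste("class", kind))
  }
})

test_that("simulation bundles write to disk as plain-text artifacts", {
  sc <- get_scenario("svVEGF_suite")
  dir <- withr::local_tempdir()
  write_simulation(sc, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "reads.fasta", "genome.fasta", "alignments.bed", "models.gff3",
    "truth.tsv")))))
  chains <- read_chains_bed12(file.path(dir, "alignments.bed"))
  expect_identical(length(chains), length(sc$sim$chains))
  rt <- read_gene_models(file.path(dir, "models.gff3"),
                         file.path(dir, "genome.fasta"))
  expect_identical(rt$models[[1L]]$ref_protein, sc$models[[1L]]$ref_protein)
})
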
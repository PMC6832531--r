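## ORF re-projection, motif localization, catalytic residues and
## metalloproteinase typing.

test_that("the original transcript reproduces the annotated CDS translation", {
  loc <- build_locus("MP17", seed = 51, gene_id = "g", scaffold = "s")
  m <- loc$model
  sim <- emit_reads(list(g = m), loc$genome,
                    list(read_plan("v", list(event_spec("NONE")),
                                   gene_id = "g")), seed = 51)
  orf <- project_orf(sim$reads[[1L]], sim$chains[[1L]], m)
  expect_identical(orf$protein, m$ref_protein)
  expect_true(orf$start$canonical)
  expect_identical(orf$stop$class, "annotated_exon")
  expect_identical(orf$stop$index, 17L)
  expect_false(orf$stop$premature)
  expect_false(orf$frameshift)
})

test_that("intron retention places a premature stop in the retained intron", {
  loc <- build_locus("MP17", seed = 52, gene_id = "g", scaffold = "s")
  m <- loc$model
  sim <- emit_reads(list(g = m), loc$genome,
                    list(read_plan("v", list(event_spec("INTRON_RETENTION",
                                                        intron = 12L)),
                                   gene_id = "g")), seed = 52)
  orf <- project_orf(sim$reads[[1L]], sim$chains[[1L]], m)
  expect_identical(orf$stop$class, "retained_intron")
  expect_identical(orf$stop$index, 12L)
  expect_true(orf$stop$premature)
  expect_lt(nchar(orf$protein), nchar(m$ref_protein))
})

test_that("ORF projection equals the brute-force translation oracle on every simulated read", {
  for (name in c("svMP05_suite", "svMP08_suite", "svVEGF_suite",
                 "svSP_clusters", "family18")) {
    sc <- get_scenario(name)
    tr <- sc$sim$truth
    for (i in which(tr$status == "full_length" & !tr$chimeric)) {
      rid <- tr$read_id[i]
      m <- sc$models[[tr$gene_id[i]]]
      orf <- project_orf(sc$sim$reads[[rid]], sc$sim$chains[[rid]], m)
      expect_identical(orf$protein, tr$protein[i],
                       label = paste("protein of", rid, "in", name))
    }
  }
})

test_that("the zinc motif localizes to exon 11 and vanishes on early truncation", {
  loc <- build_locus("MP17", seed = 53, gene_id = "g", scaffold = "s")
  m <- loc$model
  sim <- emit_reads(list(g = m), loc$genome, list(
    read_plan("orig", list(event_spec("NONE")), gene_id = "g"),
    read_plan("early", list(event_spec("INTRON_RETENTION", intron = 7L)),
              gene_id = "g")), seed = 53)
  orf <- project_orf(sim$reads[["orig_r1"]], sim$chains[["orig_r1"]], m)
  ms <- locate_motifs(orf, m, sim$chains[["orig_r1"]])
  expect_true(ms[[1L]]$found)
  expect_identical(ms[[1L]]$exon, 11L)
  ## derived check: per-codon back-mapping majority agrees
  ob <- venomsplice:::oriented_blocks(sim$chains[["orig_r1"]])
  ea <- venomsplice:::oriented_exons_all(m)
  codx <- vapply(ms[[1L]]$span[1L]:ms[[1L]]$span[2L], function(p) {
    g <- venomsplice:::.t2g(ob, orf$start$tpos + 3L * (p - 1L) + 1L)
    which(ea$iv[, 1L] <= g & g < ea$iv[, 2L])[1L]
  }, integer(1))
  expect_identical(as.integer(names(which.max(table(ea$index[codx])))), 11L)
  ## protein truncated before the motif: not found
  orf2 <- project_orf(sim$reads[["early_r1"]], sim$chains[["early_r1"]], m)
  ms2 <- locate_motifs(orf2, m, sim$chains[["early_r1"]])
  expect_false(ms2[[1L]]$found)
  expect_true(is.na(ms2[[1L]]$exon))
})

test_that("catalytic residues report present, absent and substituted states", {
  loc <- build_locus("SP6", seed = 54, gene_id = "g", scaffold = "s")
  m <- loc$model
  sim <- emit_reads(list(g = m), loc$genome, list(
    read_plan("orig", list(event_spec("NONE")), gene_id = "g"),
    read_plan("short", list(event_spec("INTRON_RETENTION", intron = 4L)),
              gene_id = "g")), seed = 54)
  orf <- project_orf(sim$reads[["orig_r1"]], sim$chains[["orig_r1"]], m)
  st <- check_catalytic(orf, m)
  expect_identical(vapply(st, `[[`, character(1), "state"),
                   rep("present", 3L))
  ## variant stopping in intron 4, upstream of Ser195
  orf2 <- project_orf(sim$reads[["short_r1"]], sim$chains[["short_r1"]], m)
  st2 <- check_catalytic(orf2, m)
  names(st2) <- vapply(st2, `[[`, character(1), "label")
  expect_identical(st2$Ser195$state, "absent")
  ## an expectation not met at an alignable position reads as substituted
  m2 <- m
  probe <- which(strsplit(m$ref_protein, "")[[1L]][1:50] != "W")[1L]
  m2$catalytic <- data.frame(label = "His57", residue = "W", pos = probe)
  st3 <- check_catalytic(orf, m2)
  expect_identical(st3[[1L]]$state, "substituted")
  expect_false(st3[[1L]]$observed == "W")
})

test_that("MP typing follows the stop position through the domain blocks", {
  loc <- build_locus("MP17", seed = 55, gene_id = "g", scaffold = "s")
  m <- loc$model
  plans <- list(
    read_plan("p3", list(event_spec("NONE")), gene_id = "g"),
    read_plan("p2", list(event_spec("INTRON_RETENTION", intron = 14L)),
              gene_id = "g"),
    read_plan("p1", list(event_spec("INTRON_RETENTION", intron = 12L)),
              gene_id = "g"),
    read_plan("nf", list(event_spec("INTRON_RETENTION", intron = 8L)),
              gene_id = "g"))
  sim <- emit_reads(list(g = m), loc$genome, plans, seed = 55)
  types <- vapply(c("p3", "p2", "p1", "nf"), function(lbl) {
    rid <- paste0(lbl, "_r1")
    orf <- project_orf(sim$reads[[rid]], sim$chains[[rid]], m)
    type_mp(orf, m)$type
  }, character(1))
  expect_identical(unname(types), c("P3", "P2", "P1", "non_functional"))
  ## typing refuses non-MP models
  sp <- build_locus("SP6", seed = 56)$model
  orf <- project_orf(sim$reads[["p3_r1"]], sim$chains[["p3_r1"]], m)
  expect_error(type_mp(orf, sp), "not an MP")
})

test_that("moving the stop 5' never increases the MP type", {
  loc <- build_locus("MP17", seed = 57, gene_id = "g", scaffold = "s")
  m <- loc$model
  E <- venomsplice:::oriented_exons(m)
  n <- nrow(E)
  rank <- c(non_functional = 0L, P1 = 1L, P2 = 2L, P3 = 3L)
  ## sweep a synthetic stop position across the gene with full coverage
  prev <- Inf
  for (g in rev(seq(E[1L, 2L], E[n, 2L], by = 60L))) {
    orf <- list(exon_covered = rep(TRUE, n), exon_frame_ok = rep(TRUE, n),
                stop_g_oriented = g)
    ty <- type_mp(orf, m)$type
    expect_lte(rank[[ty]], prev)
    prev <- rank[[ty]]
  }
})

test_that("variants differing only in polyA site translate the same protein", {
  ct <- get_catalog("svMP05_suite")
  v <- ct$variants
  orig <- v[v$is_original, ]
  utr_only <- v[v$events == "ALT_POLYA{2}", ]
  expect_identical(nrow(utr_only), 1L)
  expect_identical(utr_only$protein, orig$protein)
  expect_identical(utr_only$mp_type, "P3")
})
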
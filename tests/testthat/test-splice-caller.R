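## Gene assignment and event calling, checked against hand-built cases, the
## coverage-set oracle, injected truth, and strand mirroring.

## small hand-built models sharing junctions with a 7-block test chain:
## geneA carries 5 of its 6 junctions, geneB only 2
toy_models <- function() {
  mk <- function(id, start, end) {
    ex <- data.frame(index = seq_along(start), sublabel = NA_character_,
                     start = start, end = end, in_original = TRUE)
    gene_model(id, "SP", "s", "+", ex, 10L, 150L,
               polya_signals = max(end) - 20L)
  }
  list(
    geneA = mk("geneA", c(0L, 200L, 400L, 600L, 800L, 1000L),
               c(100L, 300L, 500L, 700L, 900L, 1150L)),
    geneB = mk("geneB", c(700L, 1000L, 1200L),
               c(900L, 1100L, 1350L))
  )
}

toy_chain <- function() {
  exon_chain("mixed", "s", "+",
             venomsplice:::.iv(seq(0L, 1200L, 200L), seq(100L, 1300L, 200L)))
}

test_that("assignment picks the gene sharing the most junctions", {
  ms <- toy_models()
  chain_a <- venomsplice:::original_chain(ms$geneA)
  got <- assign_gene(chain_a, ms)
  expect_identical(got$gene_id, "geneA")
  expect_identical(got$fraction, 1)
  ## chain shares 5/6 junctions with geneA, 2/6 with geneB -> geneA
  got <- assign_gene(toy_chain(), ms)
  expect_identical(got$gene_id, "geneA")
  expect_identical(got$shared, 5L)
  ## a chain matching no junctions is unassigned
  off <- chain_a$blocks + 13L
  ch2 <- exon_chain("off", "s", "+", off)
  expect_true(is.na(assign_gene(ch2, ms)$gene_id))
  ## single-block chains assign by exonic overlap
  ch3 <- exon_chain("mono", "s", "+", venomsplice:::.iv(0L, 90L))
  expect_identical(assign_gene(ch3, ms)$gene_id, "geneA")
})

test_that("perfect-match chains yield zero events", {
  for (tpl in c("MP17", "SP6", "PLA2_4", "VEGF6")) {
    loc <- build_locus(tpl, seed = 31, gene_id = "g", scaffold = "s")
    sim <- emit_reads(list(g = loc$model), loc$genome,
                      list(read_plan("v", list(event_spec("NONE")),
                                     gene_id = "g")), seed = 31)
    expect_length(call_events(sim$chains[[1L]], loc$model), 0L)
  }
})

test_that("described deviations are called as described", {
  loc <- build_locus("MP17", seed = 32, gene_id = "g", scaffold = "s")
  m <- loc$model
  mk <- function(...) {
    sim <- emit_reads(list(g = m), loc$genome,
                      list(read_plan("v", list(...), gene_id = "g")),
                      seed = 32)
    call_events(sim$chains[[1L]], m)
  }
  ## skipping exon 15
  ev <- mk(event_spec("EXON_SKIP", exons = 15L))
  expect_identical(venomsplice:::events_string(ev), "EXON_SKIP{15}")
  ## fusing exons 13-14 across intron 13
  ev <- mk(event_spec("INTRON_RETENTION", intron = 13L))
  expect_identical(venomsplice:::events_string(ev), "INTRON_RETENTION{13}")
  ## ending at the second polyA signal only lengthens the 3'UTR
  ev <- mk(event_spec("ALT_POLYA", signal = 2L))
  expect_identical(venomsplice:::events_string(ev), "ALT_POLYA{2}")
  ## scaffold mismatch errors
  ch <- exon_chain("x", "other_scaffold", "+", venomsplice:::.iv(0L, 10L))
  expect_error(call_events(ch, m), "scaffold")
})

test_that("a block inside an intron flanked by junctions is a novel exon", {
  loc <- build_locus("MP17", seed = 33, gene_id = "g", scaffold = "s")
  m <- loc$model
  ch0 <- venomsplice:::original_chain(m)
  de <- m$exons[m$exons$in_original, ]
  ## insert a 40-nt block in the middle of intron 5
  mid <- (de$end[5L] + de$start[6L]) %/% 2L
  b <- rbind(ch0$blocks, c(mid, mid + 40L))
  ch <- exon_chain("nov", m$scaffold, "+", b)
  ev <- call_events(ch, m)
  expect_identical(venomsplice:::events_string(ev), "NOVEL_EXON{5}")
})

test_that("called events equal the injected events on every scenario read", {
  for (name in c("svMP05_suite", "svMP08_suite", "svVEGF_suite", "family18")) {
    sc <- get_scenario(name)
    tr <- sc$sim$truth
    for (i in which(tr$status == "full_length" & !tr$chimeric)) {
      rid <- tr$read_id[i]
      ev <- call_events(sc$sim$chains[[rid]], sc$models[[tr$gene_id[i]]])
      expect_identical(venomsplice:::events_string(ev), tr$events[i],
                       label = paste("events for", rid, "in", name))
    }
  }
})

test_that("event calling agrees with the coverage-set oracle on random chains", {
  templates <- c("MP17", "MP15", "SP6", "SP8", "VEGF6", "PLA2_4")
  set.seed(99)
  n_checked <- 0L
  for (t in seq_along(templates)) {
    loc <- build_locus(templates[t], seed = 500L + t, gene_id = "g",
                       scaffold = "s")
    m <- loc$model
    for (rep in 1:40) {
      plan <- read_plan("r", random_event_plan(m), gene_id = "g")
      sim <- emit_reads(list(g = m), loc$genome, list(plan), seed = 1)
      ch <- sim$chains[[1L]]
      got <- venomsplice:::events_string(call_events(ch, m))
      want <- oracle_events(ch, m)
      expect_identical(got, want,
                       label = paste("oracle on", templates[t], "rep", rep,
                                     "events", sim$truth$events[1L]))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 240L)
})

test_that("event calling is strand-symmetric", {
  loc <- build_locus("MP17", seed = 41, gene_id = "g", scaffold = "s",
                     sub_exons = TRUE)
  m <- loc$model
  plans <- list(
    read_plan("a", list(event_spec("EXON_SKIP", exons = 15L)), gene_id = "g"),
    read_plan("b", list(event_spec("INTRON_RETENTION", intron = 12L)),
              gene_id = "g"),
    read_plan("c", list(event_spec("PARTIAL_INTRON_RETENTION", intron = 7L,
                                   side = "5p", offset = 30L)), gene_id = "g"),
    read_plan("d", list(event_spec("PARTIAL_INTRON_RETENTION", intron = 7L,
                                   side = "3p", offset = 25L)), gene_id = "g"),
    read_plan("e", list(event_spec("ALT_POLYA", signal = 2L)), gene_id = "g"),
    read_plan("f", list(event_spec("ALT_FIRST_EXON",
                                   first_exons = c("1a", "1b"))),
              gene_id = "g"),
    read_plan("h", list(event_spec("ALT_DONOR", intron = 9L, offset = 7L)),
              gene_id = "g")
  )
  sim <- emit_reads(list(g = m), loc$genome, plans, seed = 41)
  mir <- mirror_scenario(list(g = m), loc$genome, sim$chains)
  for (rid in names(sim$chains)) {
    fwd <- venomsplice:::events_string(call_events(sim$chains[[rid]], m))
    rev <- venomsplice:::events_string(
      call_events(mir$chains[[rid]], mir$models$g))
    expect_identical(rev, fwd, label = paste("mirrored events for", rid))
  }
})
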
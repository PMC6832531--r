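## Canned simulation scenarios reproducing the variant structures described
## for the habu venom-gland families: the hyper-variable 17-exon
## metalloproteinase locus with sub-exons, a 15-exon metalloproteinase
## locus, the 8-structure VEGF suite, two tandem serine-protease clusters
## with trans-spliced chimeras, an 18-family genome with splicing confined
## to three families, and a no-splicing negative control.

#' Scenario names understood by [simulate_scenario()]
#' @return character vector.
#' @export
scenario_names <- function() c("svMP05_suite", "svMP08_suite", "svVEGF_suite",
                               "svSP_clusters", "family18", "family18_noAS",
                               "svMP11_noAS")

#' Generate a canned simulation scenario
#'
#' Each scenario bundles gene models, clusters, a synthetic genome, read
#' plans and the emitted reads/chains/truth table.  Identical seeds give
#' byte-identical bundles.
#'
#' @param name one of [scenario_names()].
#' @param seed integer seed.
#' @return `list(models, clusters, genome, plans, sim)` where `sim` is the
#'   result of [emit_reads()].
#' @export
simulate_scenario <- function(name, seed = 1L) {
  builder <- switch(name,
    svMP05_suite = .scn_mp05,
    svMP08_suite = .scn_mp08,
    svVEGF_suite = .scn_vegf,
    svSP_clusters = .scn_sp_clusters,
    family18 = .scn_family18,
    family18_noAS = function(s) .scn_family18(s, inject = FALSE),
    svMP11_noAS = .scn_mp11,
    stop("unknown scenario: ", name)
  )
  builder(seed)
}

.bundle <- function(models, clusters, genome, plans, seed) {
  sim <- emit_reads(models, genome, plans, seed)
  list(models = models, clusters = clusters, genome = genome, plans = plans,
       sim = sim)
}

.ev <- function(...) event_spec(...)

## 17-exon MP locus expressed as an original plus 17 variants, including
## sub-exon usage, retention-driven P-I/P-II switches and 3'UTR-only pairs
.scn_mp05 <- function(seed) {
  loc <- build_locus("MP17", seed = seed, gene_id = "svMP05",
                     scaffold = "scf_mp05", sub_exons = TRUE)
  models <- list(svMP05 = loc$model)
  g <- "svMP05"
  plans <- list(
    read_plan("svMP05_v1", list(.ev("NONE")), gene_id = g, support = 10L),
    read_plan("svMP05_v2", list(.ev("ALT_FIRST_EXON", first_exons = c("1a", "1b"))),
              gene_id = g, support = 2L),
    read_plan("svMP05_v3", list(.ev("ALT_FIRST_EXON", first_exons = "1b")),
              gene_id = g, support = 1L),
    read_plan("svMP05_v4", list(.ev("ALT_FIRST_EXON", first_exons = "1c")),
              gene_id = g, support = 1L),
    read_plan("svMP05_v5", list(.ev("ALT_FIRST_EXON", first_exons = c("1b", "1c"))),
              gene_id = g, support = 1L),
    read_plan("svMP05_v6", list(.ev("ALT_FIRST_EXON", first_exons = c("1d", "1e"))),
              gene_id = g, support = 1L),
    read_plan("svMP05_v7", list(.ev("ALT_POLYA", signal = 2L)),
              gene_id = g, support = 3L),
    read_plan("svMP05_v8", list(.ev("INTRON_RETENTION", intron = 11L)),
              gene_id = g, support = 2L),
    read_plan("svMP05_v9", list(.ev("INTRON_RETENTION", intron = 14L)),
              gene_id = g, support = 2L),
    read_plan("svMP05_v10", list(.ev("ALT_DONOR", intron = 14L, offset = 21L)),
              gene_id = g, support = 1L),
    read_plan("svMP05_v11", list(.ev("EXON_SKIP", exons = 15L)),
              gene_id = g, support = 1L),
    read_plan("svMP05_v12", list(.ev("INTRON_RETENTION", intron = 12L)),
              gene_id = g, support = 4L),
    read_plan("svMP05_v13", list(.ev("EXON_SKIP", exons = 13L)),
              gene_id = g, support = 1L),
    read_plan("svMP05_v14", list(.ev("INTRON_RETENTION", intron = 12L),
                                 .ev("ALT_POLYA", signal = 2L)),
              gene_id = g, support = 1L),
    read_plan("svMP05_v15", list(.ev("INTRON_RETENTION", intron = 12L),
                                 .ev("EXON_SKIP", exons = 15L)),
              gene_id = g, support = 2L),
    read_plan("svMP05_v16", list(.ev("INTRON_RETENTION", intron = 12L),
                                 .ev("EXON_SKIP", exons = 14L)),
              gene_id = g, support = 1L),
    read_plan("svMP05_v17", list(.ev("PARTIAL_INTRON_RETENTION", intron = 7L,
                                     side = "5p", offset = 30L)),
              gene_id = g, support = 1L),
    read_plan("svMP05_v18", list(.ev("ALT_ACCEPTOR", intron = 2L, offset = 12L)),
              gene_id = g, support = 1L),
    ## non-full-length reads, discarded by the filter
    read_plan("svMP05_trunc5", list(.ev("NONE")), gene_id = g, support = 2L,
              truncation = "no_start"),
    read_plan("svMP05_trunc3", list(.ev("NONE")), gene_id = g, support = 1L,
              truncation = "no_polya")
  )
  .bundle(models, infer_clusters(models), loc$genome, plans, seed)
}

## 15-exon MP locus: original, intron retentions flipping P-II/P-I, a skip
## and a 3'UTR-length variant
.scn_mp08 <- function(seed) {
  loc <- build_locus("MP15", seed = seed + 1L, gene_id = "svMP08",
                     scaffold = "scf_mp08")
  models <- list(svMP08 = loc$model)
  g <- "svMP08"
  plans <- list(
    read_plan("svMP08_v1", list(.ev("NONE")), gene_id = g, support = 4L),
    read_plan("svMP08_v2", list(.ev("ALT_POLYA", signal = 2L)),
              gene_id = g, support = 2L),
    read_plan("svMP08_v3", list(.ev("INTRON_RETENTION", intron = 14L)),
              gene_id = g, support = 2L),
    read_plan("svMP08_v4", list(.ev("INTRON_RETENTION", intron = 13L)),
              gene_id = g, support = 1L),
    read_plan("svMP08_v5", list(.ev("EXON_SKIP", exons = 14L)),
              gene_id = g, support = 1L)
  )
  .bundle(models, infer_clusters(models), loc$genome, plans, seed)
}

## VEGF locus with the eight described structures; the four intron-3
## retention variants differ in exon 5/6 usage but share one protein
.scn_vegf <- function(seed) {
  loc <- build_locus("VEGF6", seed = seed + 2L, gene_id = "svVEGF01",
                     scaffold = "scf_vegf")
  models <- list(svVEGF01 = loc$model)
  g <- "svVEGF01"
  plans <- list(
    read_plan("svVEGF_v1", list(.ev("NONE")), gene_id = g, support = 5L),
    read_plan("svVEGF_v2", list(.ev("INTRON_RETENTION", intron = 5L)),
              gene_id = g, support = 1L),
    read_plan("svVEGF_v3", list(.ev("INTRON_RETENTION", intron = 3L)),
              gene_id = g, support = 2L),
    read_plan("svVEGF_v4", list(.ev("INTRON_RETENTION", intron = 3L),
                                .ev("EXON_SKIP", exons = 5L)),
              gene_id = g, support = 1L),
    read_plan("svVEGF_v5", list(.ev("INTRON_RETENTION", intron = 3L),
                                .ev("ALT_POLYA", signal = 2L)),
              gene_id = g, support = 1L),
    read_plan("svVEGF_v6", list(.ev("INTRON_RETENTION", intron = 3L),
                                .ev("INTRON_RETENTION", intron = 5L)),
              gene_id = g, support = 1L),
    read_plan("svVEGF_v7", list(.ev("INTRON_RETENTION", intron = 1L)),
              gene_id = g, support = 1L),
    read_plan("svVEGF_v8", list(.ev("EXON_SKIP", exons = 2L)),
              gene_id = g, support = 1L)
  )
  .bundle(models, infer_clusters(models), loc$genome, plans, seed)
}

## two tandem serine-protease clusters plus the six described trans-spliced
## chimeric structures (two or three donor genes, colinear)
.scn_sp_clusters <- function(seed) {
  clA <- build_cluster(rep("SP6", 3L), seed = seed + 3L,
                       gene_ids = c("svSP03", "svSP01", "svSP09"),
                       scaffold = "scf_spA")
  clB <- build_cluster(rep("SP6", 3L), seed = seed + 4L,
                       gene_ids = c("svSP04", "svSP05", "svSP08"),
                       scaffold = "scf_spB")
  models <- c(clA$models, clB$models)
  genome <- c(clA$genome, clB$genome)
  clusters <- list(clA$cluster, clB$cluster)
  seg <- function(gene_id, exons) list(gene_id = gene_id, exons = exons)
  plans <- c(
    lapply(names(models), function(g) {
      read_plan(paste0(g, "_v1"), list(.ev("NONE")), gene_id = g, support = 3L)
    }),
    list(
      read_plan("chimera_A1", chimera = chimera_spec(list(
        seg("svSP03", 1:5), seg("svSP01", 6L))), support = 2L),
      read_plan("chimera_A2", chimera = chimera_spec(list(
        seg("svSP01", 1:3), seg("svSP09", 4:6))), support = 2L),
      read_plan("chimera_B1", chimera = chimera_spec(list(
        seg("svSP04", 1:3), seg("svSP05", 4:5), seg("svSP08", 6L))),
        support = 2L),
      read_plan("chimera_B2", chimera = chimera_spec(list(
        seg("svSP04", 1:3), seg("svSP05", 4:5))), support = 2L),
      read_plan("chimera_B3", chimera = chimera_spec(list(
        seg("svSP04", 1:2), seg("svSP05", 3:6))), support = 2L),
      read_plan("chimera_B4", chimera = chimera_spec(list(
        seg("svSP04", 1:3), seg("svSP08", 4:6))), support = 2L)
    )
  )
  .bundle(models, clusters, genome, plans, seed)
}

.FAMILY18 <- c("MP", "SP", "PLA2", "VEGF", "CTLP", "3FTX", "APaseN", "CRISP",
               "Vespryn", "5Nase", "DDPase", "Hyal", "NGF", "LAAO", "PDE",
               "PLB", "BNP", "GPCase")

## one locus per venom family; splice events injected only in MP, SP, VEGF
.scn_family18 <- function(seed, inject = TRUE) {
  models <- list()
  genome <- list()
  plans <- list()
  for (i in seq_along(.FAMILY18)) {
    fam <- .FAMILY18[i]
    template <- switch(fam, MP = "MP17", SP = "SP6", VEGF = "VEGF6", "PLA2_4")
    gid <- paste0("sv", fam, "01")
    loc <- build_locus(template, seed = seed + 10L + i, gene_id = gid,
                       scaffold = paste0("scf_", fam), family = fam)
    models[[gid]] <- loc$model
    genome <- c(genome, loc$genome)
    plans[[length(plans) + 1L]] <-
      read_plan(paste0(gid, "_v1"), list(.ev("NONE")), gene_id = gid,
                support = 2L)
    if (inject && fam %in% c("MP", "SP", "VEGF")) {
      ev <- switch(fam,
        MP = .ev("INTRON_RETENTION", intron = 12L),
        SP = .ev("EXON_SKIP", exons = 2L),
        VEGF = .ev("INTRON_RETENTION", intron = 3L))
      plans[[length(plans) + 1L]] <-
        read_plan(paste0(gid, "_v2"), list(ev), gene_id = gid, support = 1L)
    }
  }
  .bundle(models, infer_clusters(models), genome, plans, seed)
}

## no-splicing negative control: a 17-exon MP-like locus expressed only as
## its original transcript (plus discarded truncated reads)
.scn_mp11 <- function(seed) {
  loc <- build_locus("MP17", seed = seed + 5L, gene_id = "svMP11",
                     scaffold = "scf_mp11")
  models <- list(svMP11 = loc$model)
  plans <- list(
    read_plan("svMP11_v1", list(.ev("NONE")), gene_id = "svMP11", support = 5L),
    read_plan("svMP11_trunc5", list(.ev("NONE")), gene_id = "svMP11",
              support = 2L, truncation = "no_start"),
    read_plan("svMP11_trunc3", list(.ev("NONE")), gene_id = "svMP11",
              support = 1L, truncation = "no_polya"),
    read_plan("svMP11_truncB", list(.ev("NONE")), gene_id = "svMP11",
              support = 1L, truncation = "both")
  )
  .bundle(models, infer_clusters(models), loc$genome, plans, seed)
}
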
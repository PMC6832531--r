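## Gene-model construction, GFF3 round trips, clusters, and the exon
## gain/loss genealogy.

## the 11 metalloproteinase paralogs: six 17-exon, four 15-exon, one 13-exon
MP_EXON_COUNTS <- c(svMP01 = 17L, svMP02 = 17L, svMP03 = 17L, svMP04 = 15L,
                    svMP05 = 17L, svMP06 = 13L, svMP07 = 15L, svMP08 = 15L,
                    svMP09 = 17L, svMP10 = 15L, svMP11 = 17L)

make_mp_family_gff3 <- function() {
  models <- lapply(seq_along(MP_EXON_COUNTS), function(i) {
    tpl <- c("13" = "MP13", "15" = "MP15", "17" = "MP17")[[
      as.character(MP_EXON_COUNTS[i])]]
    build_locus(tpl, seed = 100L + i, gene_id = names(MP_EXON_COUNTS)[i],
                scaffold = paste0("scf_", i))$model
  })
  names(models) <- names(MP_EXON_COUNTS)
  write_gene_models(models, infer_clusters(models))
}

test_that("the metalloproteinase family fixture reads back with the described exon counts", {
  txt <- make_mp_family_gff3()
  got <- read_gene_models(txt)
  expect_length(got$models, 11L)
  counts <- vapply(got$models, function(m) nrow(m$exons), integer(1))
  names(counts) <- vapply(got$models, function(m) m$gene_id, character(1))
  expect_identical(counts[names(MP_EXON_COUNTS)], MP_EXON_COUNTS)
})

test_that("empty GFF3 yields empty model and cluster lists", {
  got <- read_gene_models("##gff-version 3")
  expect_length(got$models, 0L)
  expect_length(got$clusters, 0L)
})

test_that("malformed GFF3 reports the offending line", {
  expect_error(read_gene_models("##gff-version 3\nnot a gff line"),
               "line 2")
})

test_that("overlapping exons are rejected naming the gene", {
  ex <- data.frame(index = 1:2, sublabel = NA_character_,
                   start = c(0L, 50L), end = c(100L, 150L),
                   in_original = TRUE)
  expect_error(
    gene_model("badgene", "MP", "s", "+", ex, 0L, 60L,
               polya_signals = 140L),
    "badgene")
})

test_that("write -> read is the identity on fixtures and random models", {
  templates <- c("MP17", "SP6", "SP8", "VEGF6", "PLA2_4", "MP15", "MP13")
  models <- lapply(seq_len(20L), function(i) {
    build_locus(templates[(i %% length(templates)) + 1L], seed = 300L + i,
                gene_id = paste0("g", i), scaffold = paste0("s", i),
                sub_exons = i %% 5L == 0L)$model
  })
  names(models) <- vapply(models, function(m) m$gene_id, character(1))
  txt <- write_gene_models(models, infer_clusters(models))
  rt <- read_gene_models(txt)
  expect_length(rt$models, length(models))
  for (i in seq_along(models)) {
    a <- models[[i]]; b <- rt$models[[i]]
    a$ref_protein <- NA_character_   # sequence not shipped in GFF3
    expect_equal(a[names(a)], b[names(b)], ignore_attr = TRUE)
  }
  ## byte stability under a second write
  expect_identical(txt, write_gene_models(rt$models, rt$clusters))
  ## sub-exon labels survive
  has_sub <- vapply(rt$models, function(m) any(!is.na(m$exons$sublabel)),
                    logical(1))
  expect_true(any(has_sub))
  sub_m <- rt$models[[which(has_sub)[1L]]]
  expect_true("b" %in% sub_m$exons$sublabel)
})

test_that("cluster inference equals brute-force single-linkage", {
  brute_single_linkage <- function(tab, gap) {
    n <- nrow(tab)
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (grp[i] == grp[j]) next
        if (tab$scaffold[i] != tab$scaffold[j]) next
        d <- max(tab$start[i], tab$start[j]) - min(tab$end[i], tab$end[j])
        if (d <= gap) { grp[grp == grp[j]] <- grp[i]; changed <- TRUE }
      }
      if (!changed) break
    }
    grp
  }
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:8, 1L)
    tab <- data.frame(
      gene_id = paste0("g", seq_len(n)),
      scaffold = sample(c("sA", "sB"), n, replace = TRUE),
      start = sample.int(200000L, n))
    tab$end <- tab$start + sample(2000:8000, n, replace = TRUE)
    gap <- sample(c(1000L, 10000L, 50000L), 1L)
    models <- lapply(seq_len(n), function(i) {
      ex <- data.frame(index = 1L, sublabel = NA_character_,
                       start = tab$start[i], end = tab$end[i],
                       in_original = TRUE)
      gene_model(tab$gene_id[i], "MP", tab$scaffold[i], "+", ex, 0L, 30L,
                 polya_signals = tab$end[i])
    })
    got <- infer_clusters(models, gap = gap)
    grp <- brute_single_linkage(tab, gap)
    expect_identical(length(got), length(unique(grp)))
    ## same partition of gene ids
    part_got <- sort(vapply(got, function(cl) {
      paste(sort(cl$genes), collapse = ",")
    }, character(1)))
    part_brute <- sort(unname(vapply(split(tab$gene_id, grp), function(g) {
      paste(sort(g), collapse = ",")
    }, character(1))))
    expect_identical(part_got, part_brute)
  }
})

test_that("two genes 1 kb apart on one scaffold form one cluster at a 10 kb gap", {
  mk <- function(id, s) {
    ex <- data.frame(index = 1:2, sublabel = NA_character_,
                     start = c(s, s + 2000L), end = c(s + 500L, s + 3000L),
                     in_original = TRUE)
    gene_model(id, "SP", "scf", "+", ex, 0L, 600L, polya_signals = s + 2900L)
  }
  models <- list(a = mk("a", 1000L), b = mk("b", 5000L))  # 1 kb gap
  cl <- infer_clusters(models, gap = 10000L)
  expect_length(cl, 1L)
  expect_identical(cl[[1L]]$genes, c("a", "b"))
})

test_that("two-round deletions take the ancestral 17-exon model to 15 then 13 exons", {
  mp17 <- build_locus("MP17", seed = 7)$model
  step1 <- derive_model(mp17, list(exon_loss(15:16)))
  expect_identical(nrow(step1$exons), 15L)
  expect_false("cys_rich" %in% step1$domain_blocks$name)
  step2 <- derive_model(step1, list(exon_loss(13:14)))
  expect_identical(nrow(step2$exons), 13L)
  expect_false("disintegrin" %in% step2$domain_blocks$name)
  ## equivalent as one event sequence
  direct <- derive_model(mp17, list(exon_loss(15:16), exon_loss(13:14)))
  expect_identical(nrow(direct$exons), 13L)
  ## the ancestral terminal exon is retained (same width, now index 13)
  w17 <- with(mp17$exons[mp17$exons$index == 17L, ], end - start)
  w13 <- with(direct$exons[direct$exons$index == 13L, ], end - start)
  expect_identical(w13, w17)
  ## MP domain block re-indexed but intact
  expect_true(all(c("MP", "signal", "preprosequence") %in%
                    direct$domain_blocks$name))
})

test_that("derive_model with no events is the identity, and invalid losses error", {
  mp17 <- build_locus("MP17", seed = 7)$model
  expect_identical(derive_model(mp17, list()), mp17)
  expect_error(derive_model(mp17, list(exon_loss(25L))), "nonexistent")
  expect_error(derive_model(mp17, list(exon_loss(17L))), "terminal")
})

test_that("a 6-exon serine-protease model gains two 3'UTR exons to reach eight", {
  sp6 <- build_locus("SP6", seed = 8)$model
  sp8 <- derive_model(sp6, list(exon_gain(after = 6L, count = 2L)))
  expect_identical(nrow(sp8$exons), 8L)
  expect_identical(sp8$exons$index, 1:8)
  ## gained exons lie downstream of the CDS: entirely in the 3'UTR
  cum <- c(0L, cumsum(with(sp8$exons, end - start)))
  expect_true(cum[7L] >= sp8$cds_end)
  validate_gene_model(sp8)
})

test_that("exon-count arithmetic holds for random edit sequences", {
  mp17 <- build_locus("MP17", seed = 9)$model
  set.seed(11)
  for (rep in 1:25) {
    m <- mp17
    expected <- 17L
    for (k in 1:3) {
      n <- max(unique(m$exons$index))
      if (runif(1) < 0.5 && n > 4L) {
        len <- sample(1:2, 1L)
        first <- sample(seq_len(n - len), 1L)  # never the terminal exon
        m <- derive_model(m, list(exon_loss(first:(first + len - 1L))))
        expected <- expected - len
      } else {
        cnt <- sample(1:2, 1L)
        m <- derive_model(m, list(exon_gain(after = n, count = cnt)))
        expected <- expected + cnt
      }
      expect_identical(max(m$exons$index), expected)
      expect_identical(length(unique(m$exons$index)), expected)
    }
  }
})
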
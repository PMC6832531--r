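## Deterministic synthetic venom-gland loci and Iso-Seq style reads.
##
## The generator emulates the structural features the isoform pipeline
## relies on: multi-exon gene templates matching the venom families'
## architectures (17/15/13-exon metalloproteinase-like, 6/8-exon serine-
## protease-like, 6-exon VEGF-like, 4-exon phospholipase-A2-like), full-
## length cDNA reads with 30-nt polyA tails whose AATAAA signal sits 20 nt
## upstream of the cleavage site, injected splice events of every class,
## trans-spliced chimeras over tandem clusters, and truncated (non-full-
## length) reads.  Intron sequences carry stop codons in all three frames
## within their first 60 nt, so any intron retention deterministically
## yields a premature stop.  Every read is recorded in a ground-truth table
## whose protein consequence is computed by an independent plain-string ORF
## scan ([scan_orf()]), never asserted.

.BASES <- c("A", "C", "G", "T")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(all = names(gc), aa = as.character(gc),
       coding = names(gc)[gc != "*"])
}

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.scrub <- function(s, pattern, repl) {
  while (grepl(pattern, s, fixed = TRUE)) s <- sub(pattern, repl, s, fixed = TRUE)
  s
}

## random synonymous codon for one amino acid
.codon_for <- function(aa, ct) {
  opts <- ct$coding[ct$aa[match(ct$coding, ct$all)] == aa]
  opts[sample.int(length(opts), 1L)]
}

## intron with guaranteed stops at frame offsets 0, 1, 2 within 60 nt
.intron_seq <- function(len) {
  s <- .rand_dna(len)
  stopifnot(len >= 20L)
  substr(s, 7L, 9L) <- "TAA"    # offset 6, frame 0
  substr(s, 11L, 13L) <- "TAA"  # offset 10, frame 1
  substr(s, 15L, 17L) <- "TAA"  # offset 14, frame 2
  s
}

## ---- locus templates -----------------------------------------------------

#' @keywords internal
.template_spec <- function(template) {
  mp_core <- c(100L, 130L, 85L, 95L, 110L,          # exons 2-6 (prepro)
               130L, 120L, 95L, 110L, 120L, 100L)   # exons 7-12 (MP domain)
  switch(template,
    MP17 = list(
      family = "MP", utr5 = 30L, exon1_coding = 60L,
      coding_mid = c(mp_core, 110L, 100L, 95L, 100L),  # + 13-14 dis, 15-16 cys
      tail_coding = 40L, utr3 = 160L, n_polya = 2L,
      intron_len = c(400L, rep(c(180L, 220L, 150L, 250L), 4L))[1:16],
      domain_blocks = data.frame(
        name = c("signal", "preprosequence", "MP", "disintegrin", "cys_rich"),
        first_exon = c(1L, 2L, 7L, 13L, 15L),
        last_exon = c(1L, 6L, 12L, 14L, 16L)),
      motif = data.frame(name = "zinc_binding", pattern = "HEXGHNLGXXHD",
                         exon = 11L),
      catalytic = NULL, cds_exon = 1L),
    MP15 = list(
      family = "MP", utr5 = 30L, exon1_coding = 60L,
      coding_mid = c(mp_core, 110L, 100L),
      tail_coding = 40L, utr3 = 160L, n_polya = 2L,
      intron_len = c(400L, rep(c(180L, 220L, 150L, 250L), 4L))[1:14],
      domain_blocks = data.frame(
        name = c("signal", "preprosequence", "MP", "disintegrin"),
        first_exon = c(1L, 2L, 7L, 13L), last_exon = c(1L, 6L, 12L, 14L)),
      motif = data.frame(name = "zinc_binding", pattern = "HEXGHNLGXXHD",
                         exon = 11L),
      catalytic = NULL, cds_exon = 1L),
    MP13 = list(
      family = "MP", utr5 = 30L, exon1_coding = 60L,
      coding_mid = mp_core,
      tail_coding = 40L, utr3 = 160L, n_polya = 2L,
      intron_len = c(400L, rep(c(180L, 220L, 150L, 250L), 3L))[1:12],
      domain_blocks = data.frame(
        name = c("signal", "preprosequence", "MP"),
        first_exon = c(1L, 2L, 7L), last_exon = c(1L, 6L, 12L)),
      motif = data.frame(name = "zinc_binding", pattern = "HEXGHNLGXXHD",
                         exon = 11L),
      catalytic = NULL, cds_exon = 1L),
    SP6 = list(
      family = "SP", utr5 = 70L, exon1_len = 60L,   # exon 1 all 5'UTR
      coding_mid = c(140L, 160L, 130L, 137L),       # exons 2-5
      tail_coding = 100L, utr3 = 220L, n_polya = 3L,
      intron_len = c(300L, 210L, 170L, 190L, 230L),
      domain_blocks = data.frame(name = "other", first_exon = 2L,
                                 last_exon = 6L),
      motif = NULL,
      catalytic = data.frame(label = c("His57", "Asp102", "Ser195"),
                             residue = c("H", "D", "S"),
                             pos = c(57L, 102L, 195L)),
      cds_exon = 2L, plant_start_exon = 3L, plant_polya_exon = 5L),
    SP8 = list(
      family = "SP", utr5 = 70L, exon1_len = 60L,
      coding_mid = c(140L, 160L, 130L, 137L),
      tail_coding = 100L, utr3 = 60L, n_polya = 2L,
      utr3_exons = c(120L, 120L),                   # gained exons 7-8, 3'UTR
      intron_len = c(300L, 210L, 170L, 190L, 230L, 150L, 150L),
      domain_blocks = data.frame(name = "other", first_exon = 2L,
                                 last_exon = 6L),
      motif = NULL,
      catalytic = data.frame(label = c("His57", "Asp102", "Ser195"),
                             residue = c("H", "D", "S"),
                             pos = c(57L, 102L, 195L)),
      cds_exon = 2L, plant_start_exon = 3L, plant_polya_exon = 5L),
    VEGF6 = list(
      family = "VEGF", utr5 = 30L, exon1_coding = 60L,
      coding_mid = c(100L, 110L, 120L, 95L),        # exons 2-5
      tail_coding = 60L, utr3 = 160L, n_polya = 2L,
      intron_len = c(250L, 180L, 210L, 160L, 200L),
      domain_blocks = NULL, motif = NULL, catalytic = NULL, cds_exon = 1L),
    PLA2_4 = list(
      family = "PLA2", utr5 = 30L, exon1_coding = 50L,
      coding_mid = c(120L, 110L),                   # exons 2-3
      tail_coding = 50L, utr3 = 140L, n_polya = 2L,
      intron_len = c(220L, 180L, 190L),
      domain_blocks = NULL, motif = NULL, catalytic = NULL, cds_exon = 1L),
    stop("unknown locus template: ", template)
  )
}

#' Locus templates available to [build_locus()]
#' @return character vector of template names.
#' @export
locus_templates <- function() c("MP17", "MP15", "MP13", "SP6", "SP8",
                                "VEGF6", "PLA2_4")

## core builder: writes a locus starting at `offset` on a scaffold; returns
## the model, the sequence segment [offset, seg_end) and seg_end.
.build_locus_at <- function(template, gene_id, scaffold, offset,
                            family = NULL, sub_exons = FALSE) {
  ly <- .template_spec(template)
  ct <- .codon_table()
  family <- family %||% ly$family

  ## exon length layout (transcript order)
  if (!is.null(ly$exon1_len)) {
    exon1_len <- ly$exon1_len
    lead_utr <- ly$utr5                 # 5'UTR spans exon 1 + start of exon 2
  } else {
    exon1_len <- ly$utr5 + ly$exon1_coding
    lead_utr <- ly$utr5
  }
  ## total coding nt (excluding stop); pad tail to a full codon frame
  cds_len <- if (is.null(ly$exon1_len)) {
    ly$exon1_coding + sum(ly$coding_mid) + ly$tail_coding
  } else {
    ## CDS starts inside exon 2 after (lead_utr - exon1_len) UTR nt
    (sum(ly$coding_mid) - (lead_utr - exon1_len)) + ly$tail_coding
  }
  pad <- (3L - cds_len %% 3L) %% 3L
  tail_coding <- ly$tail_coding + pad
  cds_len <- cds_len + pad

  ## exon lengths in transcript order
  exon_len <- c(exon1_len, ly$coding_mid, tail_coding + 3L + ly$utr3)
  if (!is.null(ly$utr3_exons)) exon_len <- c(exon_len, ly$utr3_exons)
  n_ex <- length(exon_len)
  stopifnot(length(ly$intron_len) == n_ex - 1L)

  ## protein design
  n_codon <- cds_len %/% 3L
  codons <- sample(ct$coding, n_codon, replace = TRUE)

  exon_cum <- c(0L, cumsum(exon_len))   # transcript offsets of exon starts
  cds_start <- lead_utr                 # transcript offset of the ATG
  codons[1L] <- "ATG"

  ## place the family motif with all codons inside its expected exon
  motif_tab <- ly$motif
  if (!is.null(motif_tab)) {
    k <- motif_tab$exon[1L]
    pat <- strsplit(motif_tab$pattern[1L], "")[[1L]]
    es <- exon_cum[k] - cds_start; ee <- exon_cum[k + 1L] - cds_start
    j0 <- ceiling((es + 6L) / 3L) + 1L  # first codon safely inside exon k
    stopifnot(3L * (j0 - 1L + length(pat)) <= ee - 6L)
    for (q in seq_along(pat)) {
      aa <- pat[q]
      if (aa == "X") aa <- sample(setdiff(unique(ct$aa), c("*", "X")), 1L)
      codons[j0 + q - 1L] <- .codon_for(aa, ct)
    }
  }
  ## catalytic residues at fixed protein positions
  if (!is.null(ly$catalytic)) {
    for (q in seq_len(nrow(ly$catalytic))) {
      codons[ly$catalytic$pos[q]] <- .codon_for(ly$catalytic$residue[q], ct)
    }
  }
  ## plant a secondary start codon (used after exon-2 skipping)
  if (!is.null(ly$plant_start_exon)) {
    es <- exon_cum[ly$plant_start_exon] - cds_start
    codons[ceiling(es / 3L) + 11L] <- "ATG"
  }
  ## plant an in-frame AATAAA (Asn-Lys) near the 3' end of one exon so that
  ## chimeric reads terminating there carry a usable cleavage signal
  if (!is.null(ly$plant_polya_exon)) {
    ee <- exon_cum[ly$plant_polya_exon + 1L] - cds_start
    j1 <- ee %/% 3L
    codons[j1 - 4L] <- "AAT"; codons[j1 - 3L] <- "AAA"
  }
  cds_nt <- paste0(paste(codons, collapse = ""), "TAA")

  ## UTRs: no spurious ATG upstream of the start, no spurious AATAAA in the
  ## 3'UTR besides the planted signal
  utr5_seq <- .scrub(.rand_dna(lead_utr), "ATG", "ACG")
  utr3_len <- ly$utr3 + sum(ly$utr3_exons %||% integer(0))
  utr3_seq <- .scrub(.rand_dna(utr3_len), "AATAAA", "AATCAA")
  tx <- paste0(utr5_seq, cds_nt, utr3_seq)
  stopifnot(nchar(tx) == sum(exon_len))
  ## default polyA signal: hexamer 20 nt upstream of the terminal cleavage
  L <- nchar(tx)
  substr(tx, L - 19L, L - 14L) <- "AATAAA"

  ## assemble genomic segment
  introns <- vapply(ly$intron_len, .intron_seq, character(1))
  pieces <- character(0)
  exon_rows <- list()
  pos <- offset
  for (i in seq_len(n_ex)) {
    es <- pos
    pieces <- c(pieces, substr(tx, exon_cum[i] + 1L, exon_cum[i + 1L]))
    pos <- pos + exon_len[i]
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(index = i, sublabel = NA_character_, start = es, end = pos,
                 in_original = TRUE, stringsAsFactors = FALSE)
    if (i < n_ex) {
      intr_start <- pos
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
      if (i == 1L && sub_exons) {
        ## annotated optional sub-exons 1b..1e inside intron 1, placed at
        ## fixed fractions of the intron so any template length works
        L1 <- nchar(introns[1L])
        wsub <- max(20L, L1 %/% 8L)
        for (k in 1:4) {
          ss <- intr_start + as.integer(L1 * (0.12 + 0.21 * (k - 1L)))
          exon_rows[[length(exon_rows) + 1L]] <-
            data.frame(index = 1L, sublabel = letters[k + 1L], start = ss,
                       end = ss + wsub, in_original = FALSE,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  gene_end <- pos
  ## downstream region with the additional polyA signals
  down <- .scrub(.rand_dna(300L), "AATAAA", "AATCAA")
  extra_polya <- integer(0)
  for (k in seq_len(ly$n_polya - 1L)) {
    rel <- 80L * k - 20L
    substr(down, rel + 1L, rel + 6L) <- "AATAAA"
    extra_polya <- c(extra_polya, gene_end + rel)
  }
  pieces <- c(pieces, down)
  seg <- paste(pieces, collapse = "")

  ex <- do.call(rbind, exon_rows)
  if (sub_exons) ex$sublabel[ex$index == 1L & ex$in_original] <- "a"
  ex <- ex[order(ex$index, ifelse(is.na(ex$sublabel), "", ex$sublabel)), ,
           drop = FALSE]
  rownames(ex) <- NULL
  polya <- c(gene_end - 20L, extra_polya)
  m <- gene_model(gene_id, family, scaffold, "+", ex,
                  cds_start = cds_start, cds_end = cds_start + nchar(cds_nt),
                  domain_blocks = ly$domain_blocks, motifs = ly$motif,
                  catalytic = ly$catalytic, polya_signals = polya)
  m$ref_protein <- substr(.translate_nt(cds_nt), 1L, n_codon)
  list(model = m, segment = seg, seg_end = offset + nchar(seg))
}

#' Build one synthetic venom locus
#'
#' Generates a random locus realizing a family template: a valid CDS free of
#' internal stops with the family motif placed so that all of its codons lie
#' in the template's expected exon (exon 11 for `MP17`), catalytic-triad
#' residues at their annotated protein positions for serine-protease
#' templates, at least two `AATAAA` signals for alternative-polyadenylation
#' templates, and introns carrying stop codons in all three frames within
#' their first 60 nt.
#'
#' @param template one of [locus_templates()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param gene_id,scaffold identifiers.
#' @param family optional family label override (used for generic loci).
#' @param sub_exons annotate optional sub-exons 1b-1e inside intron 1
#'   (metalloproteinase templates).
#' @return `list(model = <gene_model>, genome = <named list scaffold ->
#'   sequence string>)`.
#' @export
build_locus <- function(template, seed, gene_id = template,
                        scaffold = "scf_1", family = NULL, sub_exons = FALSE) {
  with_seed(seed, {
    flank <- .rand_dna(500L)
    bl <- .build_locus_at(template, gene_id, scaffold, offset = 500L,
                          family = family, sub_exons = sub_exons)
    genome <- stats::setNames(list(paste0(flank, bl$segment)), scaffold)
    list(model = bl$model, genome = genome)
  })
}

#' Build a tandem cluster of synthetic loci
#'
#' Places several template loci on one scaffold, same strand, separated by
#' configurable intergenic gaps, mirroring the tandem serine-protease
#' clusters from which trans-spliced chimeras arise.
#'
#' @param templates character vector of templates (length >= 1).
#' @param seed integer seed.
#' @param gene_ids gene identifiers (defaults to `templates` with suffixes).
#' @param scaffold scaffold name.
#' @param intergenic gap in nt between consecutive loci.
#' @return `list(cluster = <gene_cluster>, models = <named list>, genome =
#'   <named list>)`.
#' @export
build_cluster <- function(templates, seed, gene_ids = NULL,
                          scaffold = "scf_1", intergenic = 2000L) {
  if (is.null(gene_ids)) gene_ids <- paste0(templates, "_", seq_along(templates))
  stopifnot(length(gene_ids) == length(templates))
  with_seed(seed, {
    pieces <- .rand_dna(500L)
    pos <- 500L
    models <- list()
    for (i in seq_along(templates)) {
      bl <- .build_locus_at(templates[i], gene_ids[i], scaffold, offset = pos)
      pieces <- c(pieces, bl$segment)
      pos <- bl$seg_end
      models[[gene_ids[i]]] <- bl$model
      if (i < length(templates)) {
        pieces <- c(pieces, .rand_dna(intergenic))
        pos <- pos + intergenic
      }
    }
    genome <- stats::setNames(list(paste(pieces, collapse = "")), scaffold)
    reg <- range(unlist(lapply(models, function(m) model_region(m))))
    cl <- gene_cluster(paste0(scaffold, "_cluster"), scaffold, reg[1L], reg[2L],
                       names(models))
    list(cluster = cl, models = models, genome = genome)
  })
}

## ---- read plans ----------------------------------------------------------

#' Specify one injected splice event
#'
#' @param kind one of `EXON_SKIP`, `INTRON_RETENTION`,
#'   `PARTIAL_INTRON_RETENTION`, `ALT_DONOR`, `ALT_ACCEPTOR`,
#'   `ALT_FIRST_EXON`, `ALT_POLYA`, `NONE`.
#' @param exons exon indices (for `EXON_SKIP`).
#' @param intron intron index (for retention/site events; intron i separates
#'   exons i and i+1).
#' @param side `"5p"` or `"3p"` for partial retention.
#' @param offset nt offset for partial retention (>= 10) and alternative
#'   donor/acceptor shifts into the exon.
#' @param signal polyA signal index for `ALT_POLYA` (1 = default).
#' @param first_exons exon labels forming the 5' end for `ALT_FIRST_EXON`
#'   (e.g. `c("1a", "1b")`).
#' @return an `event_spec` object.
#' @export
event_spec <- function(kind, exons = NULL, intron = NULL, side = NULL,
                       offset = NULL, signal = NULL, first_exons = NULL) {
  kinds <- c("EXON_SKIP", "INTRON_RETENTION", "PARTIAL_INTRON_RETENTION",
             "ALT_DONOR", "ALT_ACCEPTOR", "ALT_FIRST_EXON", "ALT_POLYA",
             "NONE")
  if (!kind %in% kinds) stop("unknown event kind: ", kind)
  if (kind == "PARTIAL_INTRON_RETENTION" && (is.null(side) || is.null(offset)))
    stop("partial retention needs side and offset")
  if (!is.null(offset) && offset <= 0L) stop("offset must be > 0")
  structure(list(kind = kind, exons = exons, intron = intron, side = side,
                 offset = offset, signal = signal, first_exons = first_exons),
            class = "event_spec")
}

#' Specify a trans-spliced chimera
#'
#' @param segments list of `list(gene_id =, exons =)` entries, ordered 5'->3';
#'   at least two distinct genes, colinear in genomic order.
#' @return a `chimera_spec` object.
#' @export
chimera_spec <- function(segments) {
  if (length(unique(vapply(segments, `[[`, character(1), "gene_id"))) < 2L)
    stop("chimera_spec: at least two distinct genes required")
  structure(list(segments = segments), class = "chimera_spec")
}

#' Plan a set of identical reads for one transcript variant
#'
#' @param label variant label (used in read ids and the truth table).
#' @param events list of [event_spec()]s (ignored when `chimera` given).
#' @param chimera optional [chimera_spec()].
#' @param gene_id target gene (required for non-chimeric plans).
#' @param support number of identical reads to emit (>= 1).
#' @param truncation `"none"` (full-length), `"no_start"`, `"no_polya"` or
#'   `"both"`.
#' @return a `read_plan` object.
#' @export
read_plan <- function(label, events = list(), chimera = NULL, gene_id = NULL,
                      support = 1L, truncation = "none") {
  if (support < 1L) stop("read_plan: support must be >= 1")
  if (is.null(chimera) && is.null(gene_id)) stop("read_plan: gene_id required")
  if (inherits(events, "event_spec")) events <- list(events)
  structure(list(label = label, events = events, chimera = chimera,
                 gene_id = gene_id, support = as.integer(support),
                 truncation = match.arg(truncation,
                                        c("none", "no_start", "no_polya", "both"))),
            class = "read_plan")
}

## compute oriented block matrix + metadata for one plan
.plan_blocks <- function(plan, models) {
  if (!is.null(plan$chimera)) {
    segs <- plan$chimera$segments
    rows <- NULL
    for (sg in segs) {
      m <- models[[sg$gene_id]]
      if (is.null(m)) stop("plan ", plan$label, ": unknown gene ", sg$gene_id)
      de <- default_exons(m)
      de <- de[de$index %in% sg$exons, , drop = FALSE]
      if (nrow(de) != length(sg$exons))
        stop("plan ", plan$label, ": exon range invalid for ", sg$gene_id)
      rows <- rbind(rows, as.matrix(de[, c("start", "end")]))
    }
    m1 <- models[[segs[[1L]]$gene_id]]
    mlast <- models[[segs[[length(segs)]]$gene_id]]
    last_exons <- segs[[length(segs)]]$exons
    if (max(last_exons) == max(default_exons(mlast)$index)) {
      cleave <- polya_sites(mlast)[1L]
    } else {
      de <- default_exons(mlast)
      cleave <- .orient_iv(as.matrix(de[de$index == max(last_exons),
                                        c("start", "end"), drop = FALSE]),
                           mlast$strand)[1L, 2L]
    }
    ob <- .orient_iv(rows, m1$strand)
    ob <- ob[order(ob[, 1L]), , drop = FALSE]
    ob[nrow(ob), 2L] <- cleave
    return(list(blocks = ob, model = m1, scaffold = m1$scaffold,
                strand = m1$strand))
  }

  m <- models[[plan$gene_id]]
  if (is.null(m)) stop("plan ", plan$label, ": unknown gene ", plan$gene_id)
  ea <- oriented_exons_all(m)
  de_iv <- ea$iv[ea$in_original, , drop = FALSE]
  de_idx <- ea$index[ea$in_original]
  n <- nrow(de_iv)
  iv <- de_iv
  keep <- rep(TRUE, n)
  retained <- integer(0)
  cleave <- polya_sites(m)[1L]
  afe <- NULL

  for (ev in plan$events) {
    switch(ev$kind,
      NONE = NULL,
      EXON_SKIP = {
        if (!all(ev$exons %in% de_idx))
          stop("plan ", plan$label, ": EXON_SKIP target missing")
        keep[de_idx %in% ev$exons] <- FALSE
      },
      INTRON_RETENTION = {
        i <- ev$intron
        if (i < 1L || i >= n) stop("plan ", plan$label, ": bad intron ", i)
        retained <- c(retained, i)
      },
      PARTIAL_INTRON_RETENTION = {
        i <- ev$intron
        ilen <- de_iv[i + 1L, 1L] - de_iv[i, 2L]
        if (ev$offset >= ilen) stop("plan ", plan$label, ": offset >= intron")
        if (ev$side == "5p") iv[i, 2L] <- iv[i, 2L] + ev$offset
        else iv[i + 1L, 1L] <- iv[i + 1L, 1L] - ev$offset
      },
      ALT_DONOR = {
        i <- ev$intron
        if (ev$offset >= .iv_width(de_iv[i, , drop = FALSE]))
          stop("plan ", plan$label, ": offset >= exon")
        iv[i, 2L] <- iv[i, 2L] - ev$offset
      },
      ALT_ACCEPTOR = {
        i <- ev$intron
        iv[i + 1L, 1L] <- iv[i + 1L, 1L] + ev$offset
      },
      ALT_FIRST_EXON = {
        pick <- match(ev$first_exons, ea$label)
        if (any(is.na(pick)))
          stop("plan ", plan$label, ": unknown first exon label")
        afe <- pick  # applied after index-based edits
      },
      ALT_POLYA = {
        if (ev$signal > length(polya_sites(m)))
          stop("plan ", plan$label, ": no such polyA signal")
        cleave <- polya_sites(m)[ev$signal]
      },
      stop("plan ", plan$label, ": inapplicable event ", ev$kind)
    )
  }
  if (!is.null(afe)) {
    keep[de_idx == 1L] <- FALSE
    iv <- rbind(ea$iv[afe, , drop = FALSE], iv)
    keep <- c(rep(TRUE, length(afe)), keep)
  }
  iv <- iv[keep, , drop = FALSE]
  ## retained introns become blocks; adjacent blocks are then fused
  for (i in retained) {
    iv <- rbind(iv, c(de_iv[i, 2L], de_iv[i + 1L, 1L]))
  }
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  ## terminal cleavage (possibly beyond the annotated terminal exon)
  iv[nrow(iv), 2L] <- cleave
  ## merge touching/overlapping blocks
  out <- iv[1L, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1L]) {
    if (iv[r, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[r, 2L])
    } else out <- rbind(out, iv[r, , drop = FALSE])
  }
  list(blocks = out, model = m, scaffold = m$scaffold, strand = m$strand)
}

#' Independent brute-force ORF scan of a transcript sequence
#'
#' Plain string scanning, used as the generator's ground truth and as the
#' oracle against the coordinate-based [project_orf()]: take the canonical
#' start when its position is present (and is `ATG`), otherwise the first
#' `ATG` in the sequence; translate codon by codon to the first stop.
#'
#' @param seq transcript sequence (character scalar).
#' @param canonical_tpos 0-based transcript offset of the canonical start,
#'   or `NA` when the read does not contain it.
#' @return `list(start, canonical, protein, stop_tpos)`; `stop_tpos` is the
#'   0-based offset of the stop codon's first base (`NA` for run-through);
#'   `NULL` when no start codon exists.
#' @export
scan_orf <- function(seq, canonical_tpos = NA_integer_) {
  start <- NA_integer_
  canonical <- FALSE
  if (!is.na(canonical_tpos) &&
      substr(seq, canonical_tpos + 1L, canonical_tpos + 3L) == "ATG") {
    start <- canonical_tpos; canonical <- TRUE
  } else {
    hit <- regexpr("ATG", seq, fixed = TRUE)
    if (hit[1L] == -1L) return(NULL)
    start <- hit[1L] - 1L
  }
  prot <- character(0)
  stop_tpos <- NA_integer_
  p <- start
  while (p + 3L <= nchar(seq)) {
    cod <- substr(seq, p + 1L, p + 3L)
    if (cod %in% .stop_codons) { stop_tpos <- p; break }
    prot <- c(prot, cod)
    p <- p + 3L
  }
  protein <- if (length(prot)) .translate_nt(paste(prot, collapse = "")) else ""
  list(start = start, canonical = canonical, protein = protein,
       stop_tpos = stop_tpos)
}

## truth-side MP typing from emitted blocks (simple containment arithmetic)
.truth_mp_type <- function(model, blocks, start_g, stop_g) {
  if (model$family != "MP" || is.na(stop_g)) return(NA_character_)
  ob <- oriented_exons(model)
  idx <- default_exons(model)$index
  db <- model$domain_blocks
  covered <- character(0)
  for (i in seq_len(nrow(db))) {
    if (!db$name[i] %in% c("MP", "disintegrin", "cys_rich")) next
    rng <- which(idx >= db$first_exon[i] & idx <= db$last_exon[i])
    full <- all(vapply(rng, function(r) .iv_covers(blocks, ob[r, 1L], ob[r, 2L]),
                       logical(1)))
    last_end <- ob[max(rng), 2L]
    d <- .iv_overlap_len(blocks, start_g, last_end) -
      .iv_overlap_len(ob, start_g, last_end)
    if (full && stop_g >= last_end && d %% 3L == 0L) {
      covered <- c(covered, db$name[i])
    }
  }
  if (!"MP" %in% covered) return("non_functional")
  if (all(c("disintegrin", "cys_rich") %in% covered)) return("P3")
  if ("disintegrin" %in% covered) return("P2")
  "P1"
}

#' Emit synthetic reads, alignments and the ground-truth table
#'
#' Each read's sequence is the spliced concatenation of its planned genomic
#' blocks, plus a 30-nt polyA tail for full-length plans.  Truncated reads
#' lack the 5' start region and/or the polyA signal and tail according to
#' the plan's truncation mode.  The truth table carries one row per emitted
#' read with the protein consequence computed by [scan_orf()].
#'
#' @param models named list of `gene_model`s.
#' @param genome named list of scaffold sequences.
#' @param plans list of [read_plan()]s.
#' @param seed integer seed (controls nothing but is accepted for interface
#'   symmetry; read construction is fully deterministic given locus and
#'   plans).
#' @return `list(reads = <named character vector>, chains = <list of
#'   exon_chain>, truth = <data.frame>)`.
#' @export
emit_reads <- function(models, genome, plans, seed = 0L) {
  reads <- character(0)
  chains <- list()
  truth <- list()
  for (plan in plans) {
    pb <- .plan_blocks(plan, models)
    m <- pb$model
    scf_seq <- genome[[pb$scaffold]]
    if (is.null(scf_seq)) stop("emit_reads: missing scaffold ", pb$scaffold)
    ob <- pb$blocks
    ## canonical start of the 5'-most gene, oriented
    g0 <- .t2g(oriented_exons(m), m$cds_start)
    full_status <- "full_length"
    if (plan$truncation %in% c("no_start", "both")) {
      cutg <- g0 + 30L
      ob <- ob[ob[, 2L] > cutg, , drop = FALSE]
      ob[1L, 1L] <- max(ob[1L, 1L], cutg)
      full_status <- "missing_start"
    }
    add_tail <- TRUE
    if (plan$truncation %in% c("no_polya", "both")) {
      ob[nrow(ob), 2L] <- ob[nrow(ob), 2L] - 30L
      add_tail <- FALSE
      full_status <- if (full_status == "missing_start") "missing_both"
                     else "missing_polya"
    }
    gb <- .orient_iv(ob, pb$strand)             # back to plus-strand coords
    gb <- gb[order(gb[, 1L]), , drop = FALSE]
    seq0 <- .spliced_seq(scf_seq, gb, pb$strand)
    read_seq <- if (add_tail) paste0(seq0, strrep("A", 30L)) else seq0
    start_tpos <- .g2t(ob, g0)
    orf <- if (full_status %in% c("full_length", "missing_polya")) {
      scan_orf(read_seq, start_tpos)
    } else NULL
    stop_g <- if (!is.null(orf) && !is.na(orf$stop_tpos)) {
      .t2g(ob, orf$stop_tpos)
    } else NA_integer_
    gene_ids <- if (!is.null(plan$chimera)) {
      paste(vapply(plan$chimera$segments, `[[`, character(1), "gene_id"),
            collapse = "+")
    } else plan$gene_id
    ev_str <- if (!is.null(plan$chimera)) "CHIMERA" else {
      ks <- vapply(plan$events, .event_string, character(1))
      ks <- ks[ks != "NONE"]
      if (length(ks)) paste(sort(ks), collapse = ";") else ""
    }
    mp_type <- if (is.null(plan$chimera) && full_status == "full_length") {
      .truth_mp_type(m, ob, g0, stop_g)
    } else NA_character_
    for (j in seq_len(plan$support)) {
      rid <- sprintf("%s_r%d", plan$label, j)
      reads[rid] <- read_seq
      chains[[rid]] <- exon_chain(rid, pb$scaffold, pb$strand, gb)
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = rid, gene_id = gene_ids, variant = plan$label,
        events = ev_str, chimeric = !is.null(plan$chimera),
        status = full_status,
        protein = if (is.null(orf)) NA_character_ else orf$protein,
        mp_type = mp_type, stringsAsFactors = FALSE)
    }
  }
  list(reads = reads, chains = chains,
       truth = do.call(rbind, truth) %||%
         data.frame(read_id = character(0), gene_id = character(0),
                    variant = character(0), events = character(0),
                    chimeric = logical(0), status = character(0),
                    protein = character(0), mp_type = character(0)))
}

.event_string <- function(ev) {
  switch(ev$kind,
    NONE = "NONE",
    EXON_SKIP = paste0("EXON_SKIP{", paste(ev$exons, collapse = ","), "}"),
    INTRON_RETENTION = paste0("INTRON_RETENTION{", ev$intron, "}"),
    PARTIAL_INTRON_RETENTION = paste0("PARTIAL_INTRON_RETENTION{", ev$intron,
                                      ",", ev$side, "}"),
    ALT_DONOR = paste0("ALT_DONOR{", ev$intron, "}"),
    ALT_ACCEPTOR = paste0("ALT_ACCEPTOR{", ev$intron, "}"),
    ALT_FIRST_EXON = paste0("ALT_FIRST_EXON{",
                            paste(ev$first_exons, collapse = ","), "}"),
    ALT_POLYA = paste0("ALT_POLYA{", ev$signal, "}")
  )
}

#' Write a simulation bundle to disk
#'
#' Writes `reads.fasta`, `alignments.bed` (BED12), `models.gff3`,
#' `genome.fasta` and `truth.tsv` under `dir`.
#'
#' @param scenario a bundle from [simulate_scenario()] (or a compatible
#'   list with `models`, `clusters`, `genome`, `sim`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- Biostrings::DNAStringSet(scenario$sim$reads)
  Biostrings::writeXStringSet(rs, file.path(dir, "reads.fasta"))
  gn <- Biostrings::DNAStringSet(unlist(scenario$genome))
  names(gn) <- names(scenario$genome)
  Biostrings::writeXStringSet(gn, file.path(dir, "genome.fasta"))
  write_chains_bed12(scenario$sim$chains, file.path(dir, "alignments.bed"))
  write_gene_models(scenario$models, scenario$clusters,
                    file.path(dir, "models.gff3"))
  utils::write.table(scenario$sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
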
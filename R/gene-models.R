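## Gene models: annotated multi-exon venom genes, tandem clusters, and the
## structural exon gain/loss genealogy connecting paralogs.
##
## Coordinates are 0-based half-open genomic positions on the plus strand of
## a scaffold.  Exon rows are kept in 5'->3' transcription order (descending
## genomic coordinates for minus-strand genes).  Exon indices follow the
## gene's transcription order; sub-exons share an index and differ by a
## letter sublabel (1a, 1b, ...).

#' Construct an annotated gene model
#'
#' A gene model carries the exon table of one venom gene plus the annotation
#' layers the isoform pipeline consumes: domain blocks (e.g. the
#' metalloproteinase/disintegrin/Cys-rich architecture), protein motifs such
#' as the zinc-binding motif `HEXGHNLGXXHD`, catalytic residues (e.g. the
#' serine-protease triad His57/Asp102/Ser195), and annotated `AATAAA`
#' polyadenylation signals.
#'
#' @param gene_id gene identifier.
#' @param family family label (e.g. `"MP"`, `"SP"`, `"VEGF"`, `"PLA2"`).
#' @param scaffold scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `index` (integer, 1-based, in
#'   transcription order), `sublabel` (letter or `NA`; `NA`/`"a"` rows are
#'   part of the original transcript), `start`, `end` (0-based half-open
#'   genomic), `in_original` (logical; used by the original transcript).
#' @param cds_start,cds_end canonical start codon position and stop codon
#'   end (exclusive) in 0-based coordinates of the original transcript.
#' @param domain_blocks data.frame `name`, `first_exon`, `last_exon`
#'   (inclusive exon indices), or `NULL`.
#' @param motifs data.frame `name`, `pattern` (amino acids, `X` = wildcard),
#'   `exon` (expected exon index or `NA`), or `NULL`.
#' @param catalytic data.frame `label`, `residue` (one letter), `pos`
#'   (1-based position in the reference protein), or `NULL`.
#' @param polya_signals integer vector of 0-based plus-strand leftmost
#'   genomic positions of the transcript-sense `AATAAA` hexamer; the first
#'   entry is the default (model) signal.
#' @param ref_protein optional reference protein sequence (computed by
#'   [read_gene_models()]/[build_locus()] when sequence is available).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, family, scaffold, strand, exons,
                       cds_start, cds_end,
                       domain_blocks = NULL, motifs = NULL, catalytic = NULL,
                       polya_signals = integer(0), ref_protein = NA_character_) {
  exons$index <- as.integer(exons$index)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (is.null(exons$sublabel)) exons$sublabel <- NA_character_
  if (is.null(exons$in_original)) {
    exons$in_original <- is.na(exons$sublabel) | exons$sublabel == "a"
  }
  m <- structure(list(
    gene_id = gene_id, family = family, scaffold = scaffold, strand = strand,
    exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    domain_blocks = domain_blocks %||%
      data.frame(name = character(0), first_exon = integer(0), last_exon = integer(0)),
    motifs = motifs %||%
      data.frame(name = character(0), pattern = character(0), exon = integer(0)),
    catalytic = catalytic %||%
      data.frame(label = character(0), residue = character(0), pos = integer(0)),
    polya_signals = as.integer(polya_signals),
    ref_protein = ref_protein
  ), class = "gene_model")
  validate_gene_model(m)
  m
}

#' Validate a gene model's invariants
#'
#' Checks exon ordering/disjointness, CDS coordinates, domain-block exon
#' ranges and the presence of at least one polyA signal.  Errors name the
#' offending `gene_id`.
#'
#' @param m a `gene_model`.
#' @return `m`, invisibly.
#' @export
validate_gene_model <- function(m) {
  ex <- m$exons
  if (nrow(ex) < 1L) stop("gene ", m$gene_id, ": no exons")
  if (!m$strand %in% c("+", "-")) stop("gene ", m$gene_id, ": bad strand")
  if (any(ex$start >= ex$end)) stop("gene ", m$gene_id, ": empty exon interval")
  if (any(ex$start < 0L)) stop("gene ", m$gene_id, ": negative coordinate")
  ov <- .orient_iv(as.matrix(ex[, c("start", "end")]), m$strand)
  if (is.unsorted(ov[, 1L], strictly = TRUE)) {
    stop("gene ", m$gene_id, ": exons not sorted in transcription order")
  }
  if (nrow(ov) > 1L && any(ov[-1L, 1L] < ov[-nrow(ov), 2L])) {
    stop("gene ", m$gene_id, ": overlapping exons")
  }
  if (is.unsorted(ex$index)) stop("gene ", m$gene_id, ": exon indices out of order")
  if (any(ex$index < 1L)) stop("gene ", m$gene_id, ": exon index < 1")
  if (!(m$cds_start < m$cds_end)) stop("gene ", m$gene_id, ": cds_start >= cds_end")
  db <- m$domain_blocks
  if (nrow(db)) {
    idx <- unique(ex$index)
    if (any(!(db$first_exon %in% idx) | !(db$last_exon %in% idx) |
            db$first_exon > db$last_exon)) {
      stop("gene ", m$gene_id, ": domain block exon range invalid")
    }
  }
  if (length(m$polya_signals) < 1L) {
    stop("gene ", m$gene_id, ": at least one polyA signal required")
  }
  invisible(m)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s\n", x$gene_id, x$family,
              x$scaffold, paste0(min(x$exons$start), "-", max(x$exons$end)),
              x$strand))
  cat(sprintf("  %d exons (%d in original transcript), %d domain blocks, %d polyA signal(s)\n",
              nrow(x$exons), sum(x$exons$in_original), nrow(x$domain_blocks),
              length(x$polya_signals)))
  invisible(x)
}

## ---- internal views ------------------------------------------------------

exon_label <- function(index, sublabel) {
  ifelse(is.na(sublabel), as.character(index), paste0(index, sublabel))
}

default_exons <- function(m) m$exons[m$exons$in_original, , drop = FALSE]

## default-exon intervals, transcription order, oriented coordinates
oriented_exons <- function(m) {
  de <- default_exons(m)
  .orient_iv(as.matrix(de[, c("start", "end")]), m$strand)
}

## all annotated exons (incl. sub-exons), oriented, with labels
oriented_exons_all <- function(m) {
  iv <- .orient_iv(as.matrix(m$exons[, c("start", "end")]), m$strand)
  list(iv = iv, index = m$exons$index,
       label = exon_label(m$exons$index, m$exons$sublabel),
       in_original = m$exons$in_original)
}

## oriented hexamer start positions of annotated polyA signals
oriented_polya <- function(m) {
  if (m$strand == "+") m$polya_signals else -(m$polya_signals + 6L)
}

## implied cleavage sites (20 nt downstream of signal start), oriented
polya_sites <- function(m) oriented_polya(m) + 20L

## genomic span of the model (plus-strand coordinates)
model_region <- function(m) c(min(m$exons$start), max(m$exons$end))

## original transcript as an exon chain (genomic plus-strand blocks)
original_chain <- function(m) {
  de <- default_exons(m)
  g <- as.matrix(de[, c("start", "end")])
  g <- g[order(g[, 1L]), , drop = FALSE]
  exon_chain(paste0(m$gene_id, ".original"), m$scaffold, m$strand, g)
}

## spliced original-transcript sequence (transcript orientation)
model_transcript_seq <- function(m, scaffold_seq) {
  de <- default_exons(m)
  g <- as.matrix(de[, c("start", "end")])
  g <- g[order(g[, 1L]), , drop = FALSE]
  .spliced_seq(scaffold_seq, g, m$strand)
}

## reference protein from the annotated CDS
model_ref_protein <- function(m, scaffold_seq) {
  tx <- model_transcript_seq(m, scaffold_seq)
  aa <- .translate_nt(substr(tx, m$cds_start + 1L, m$cds_end))
  sub("\\*$", "", aa)
}

## ---- exon gain / loss genealogy ------------------------------------------

#' Exon edit events for [derive_model()]
#'
#' `exon_loss()` removes a contiguous run of exons (e.g. the Cys-rich-domain
#' exons 15-16, then the disintegrin exons 13-14, in the two-round deletion
#' model of the metalloproteinase family).  `exon_gain()` inserts new exons
#' after a given index (e.g. the two 3'UTR exons gained by one
#' serine-protease paralog, turning 6 exons into 8).
#'
#' @param indices integer vector of contiguous exon indices to remove.
#' @param after exon index after which new exons are inserted.
#' @param count number of exons gained.
#' @param length,gap nucleotide length of each gained exon and the intronic
#'   gap preceding it.
#' @return an `exon_edit` object.
#' @export
exon_loss <- function(indices) {
  indices <- sort(as.integer(indices))
  if (length(indices) == 0L) stop("exon_loss: no indices")
  if (length(indices) > 1L && any(diff(indices) != 1L)) {
    stop("exon_loss: indices must be contiguous")
  }
  structure(list(kind = "loss", indices = indices), class = "exon_edit")
}

#' @rdname exon_loss
#' @export
exon_gain <- function(after, count, length = 120L, gap = 200L) {
  if (count < 1L) stop("exon_gain: count must be >= 1")
  structure(list(kind = "gain", after = as.integer(after),
                 count = as.integer(count), length = as.integer(length),
                 gap = as.integer(gap)), class = "exon_edit")
}

#' Derive a descendant gene model by exon gain/loss
#'
#' Applies a sequence of structural edits to a parent model, re-indexing the
#' surviving exons 1..n in transcription order.  Domain blocks that
#' reference removed exons are dropped; blocks on surviving exons are
#' re-mapped.  The parent's terminal exon is always retained under losses,
#' matching the conservation of the ancestral last exon across all reduced
#' paralogs.  Derived models are structural: CDS coordinates are clamped to
#' the new transcript length and sequence-level re-annotation is left to the
#' caller.
#'
#' @param parent a `gene_model`.
#' @param events list of [exon_loss()]/[exon_gain()] edits, applied in order.
#' @return the derived `gene_model`.
#' @examples
#' \dontrun{
#' mp17 <- build_locus("MP17", seed = 1)$model
#' mp13 <- derive_model(mp17, list(exon_loss(15:16), exon_loss(13:14)))
#' nrow(mp13$exons)  # 13
#' }
#' @export
derive_model <- function(parent, events) {
  m <- parent
  for (ev in events) {
    if (!inherits(ev, "exon_edit")) stop("derive_model: not an exon_edit")
    m <- switch(ev$kind,
                loss = .apply_loss(m, ev),
                gain = .apply_gain(m, ev),
                stop("derive_model: unknown edit kind"))
  }
  validate_gene_model(m)
  m
}

.apply_loss <- function(m, ev) {
  idx <- unique(m$exons$index)
  if (!all(ev$indices %in% idx)) {
    stop("gene ", m$gene_id, ": cannot lose nonexistent exon ",
         paste(setdiff(ev$indices, idx), collapse = ","))
  }
  if (max(idx) %in% ev$indices) {
    stop("gene ", m$gene_id, ": terminal exon is conserved and cannot be lost")
  }
  keep <- !(m$exons$index %in% ev$indices)
  ex <- m$exons[keep, , drop = FALSE]
  old <- unique(ex$index)
  remap <- stats::setNames(seq_along(old), old)
  ex$index <- as.integer(remap[as.character(ex$index)])
  rownames(ex) <- NULL
  db <- m$domain_blocks
  if (nrow(db)) {
    ok <- !(db$first_exon %in% ev$indices) & !(db$last_exon %in% ev$indices) &
      vapply(seq_len(nrow(db)), function(i) {
        !any(seq(db$first_exon[i], db$last_exon[i]) %in% ev$indices)
      }, logical(1))
    db <- db[ok, , drop = FALSE]
    db$first_exon <- as.integer(remap[as.character(db$first_exon)])
    db$last_exon <- as.integer(remap[as.character(db$last_exon)])
    rownames(db) <- NULL
  }
  mo <- m$motifs
  if (nrow(mo)) {
    drop <- !is.na(mo$exon) & mo$exon %in% ev$indices
    mo <- mo[!drop, , drop = FALSE]
    mo$exon <- ifelse(is.na(mo$exon), NA_integer_,
                      as.integer(remap[as.character(mo$exon)]))
    rownames(mo) <- NULL
  }
  m$exons <- ex; m$domain_blocks <- db; m$motifs <- mo
  .clamp_cds(m)
}

.apply_gain <- function(m, ev) {
  idx <- unique(m$exons$index)
  if (!(ev$after %in% idx)) {
    stop("gene ", m$gene_id, ": insertion point exon ", ev$after, " not found")
  }
  ex <- m$exons
  shift <- ex$index > ev$after
  ex$index[shift] <- ex$index[shift] + ev$count
  ## place new exons downstream (transcription sense) of the anchor exon
  anchor <- ex[m$exons$index == ev$after & ex$in_original, , drop = FALSE]
  anchor <- anchor[nrow(anchor), ]
  down <- ex$index > ev$after + ev$count
  new_rows <- vector("list", ev$count)
  if (m$strand == "+") pos <- anchor$end else pos <- anchor$start
  for (k in seq_len(ev$count)) {
    if (m$strand == "+") {
      s <- pos + ev$gap; e <- s + ev$length; pos <- e
    } else {
      e <- pos - ev$gap; s <- e - ev$length; pos <- s
    }
    new_rows[[k]] <- data.frame(index = ev$after + k, sublabel = NA_character_,
                                start = s, end = e, in_original = TRUE)
  }
  if (any(down)) {
    ## shift pre-existing downstream exons out of the way of the insertion
    need <- ev$count * (ev$gap + ev$length)
    if (m$strand == "+") {
      ex$start[down] <- ex$start[down] + need
      ex$end[down] <- ex$end[down] + need
    } else {
      ex$start[down] <- ex$start[down] - need
      ex$end[down] <- ex$end[down] - need
    }
  }
  ex <- rbind(ex, do.call(rbind, new_rows))
  ex <- ex[order(ex$index, ifelse(is.na(ex$sublabel), "", ex$sublabel)), ,
           drop = FALSE]
  rownames(ex) <- NULL
  db <- m$domain_blocks
  if (nrow(db)) {
    db$first_exon <- ifelse(db$first_exon > ev$after, db$first_exon + ev$count,
                            db$first_exon)
    db$last_exon <- ifelse(db$last_exon > ev$after, db$last_exon + ev$count,
                           db$last_exon)
  }
  mo <- m$motifs
  if (nrow(mo)) {
    mo$exon <- ifelse(!is.na(mo$exon) & mo$exon > ev$after, mo$exon + ev$count,
                      mo$exon)
  }
  m$exons <- ex; m$domain_blocks <- db; m$motifs <- mo
  .clamp_cds(m)
}

.clamp_cds <- function(m) {
  len <- sum(.iv_width(as.matrix(default_exons(m)[, c("start", "end")])))
  m$cds_end <- min(m$cds_end, len)
  m$cds_start <- min(m$cds_start, m$cds_end - 3L)
  m
}

## ---- clusters ------------------------------------------------------------

#' Construct a tandem gene cluster
#'
#' @param cluster_id identifier.
#' @param scaffold scaffold name.
#' @param start,end cluster region (0-based half-open).
#' @param genes character vector of member gene ids in tandem genomic order.
#' @return a `gene_cluster` object.
#' @export
gene_cluster <- function(cluster_id, scaffold, start, end, genes) {
  structure(list(cluster_id = cluster_id, scaffold = scaffold,
                 start = as.integer(start), end = as.integer(end),
                 genes = genes), class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s %s:%d-%d [%s]\n", x$cluster_id, x$scaffold,
              x$start, x$end, paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Infer tandem gene clusters by genomic proximity
#'
#' Single-linkage grouping of gene spans on each scaffold: two genes join
#' the same cluster when the gap between their spans is at most `gap`
#' nucleotides.  Member genes are ordered by genomic coordinate.
#'
#' @param models list of `gene_model`s.
#' @param gap maximum intergenic gap (default 50 kb).
#' @return list of `gene_cluster` objects.
#' @export
infer_clusters <- function(models, gap = 50000L) {
  if (length(models) == 0L) return(list())
  tab <- data.frame(
    gene_id = vapply(models, function(m) m$gene_id, character(1)),
    scaffold = vapply(models, function(m) m$scaffold, character(1)),
    start = vapply(models, function(m) model_region(m)[1L], numeric(1)),
    end = vapply(models, function(m) model_region(m)[2L], numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- list(); cid <- 0L
  for (scf in unique(tab$scaffold)) {
    sub <- tab[tab$scaffold == scf, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(sub$start[-1L] - cummax(sub$end)[-nrow(sub)] > gap)))
    for (g in unique(grp)) {
      gg <- sub[grp == g, , drop = FALSE]
      cid <- cid + 1L
      out[[cid]] <- gene_cluster(paste0("cluster_", cid), scf,
                                 min(gg$start), max(gg$end), gg$gene_id)
    }
  }
  out
}
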
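## GFF3 I/O for annotated gene models.
##
## Dialect: standard gene/mRNA/exon/CDS features.  The mRNA feature carries
## the annotation layers as attributes:
##   family=MP
##   domain_blocks=signal:1-1,prepro:2-6,MP:7-12,disintegrin:13-14,cys_rich:15-16
##   motifs=zinc_binding:HEXGHNLGXXHD:11      (name:pattern:exon, exon may be .)
##   catalytic=His57:H:57,Asp102:D:102       (label:residue:protein_pos)
##   polyA=1201,1388                          (1-based genomic hexamer starts)
## Exon features carry exon_label= (e.g. 1a, 1b, 7) and in_original= (1/0).
## CDS features include the stop codon.  Cluster membership is stored as
## gene_group features with a genes= attribute.

.gff3_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  paste(vapply(names(kv), function(k) paste0(k, "=", kv[[k]]), character(1)),
        collapse = ";")
}

#' Write gene models (and clusters) as GFF3
#'
#' @param models list of `gene_model`s.
#' @param clusters optional list of `gene_cluster`s, written as `gene_group`
#'   features.
#' @param file optional output path.
#' @return the GFF3 text as a character scalar (invisibly when `file` is
#'   given).
#' @export
write_gene_models <- function(models, clusters = NULL, file = NULL) {
  lines <- "##gff-version 3"
  for (m in models) {
    validate_gene_model(m)
    reg <- model_region(m)
    rid <- paste0(m$gene_id, ".t1")
    lines <- c(lines, paste(m$scaffold, "venomsplice", "gene", reg[1L] + 1L,
                            reg[2L], ".", m$strand, ".",
                            .gff3_attr(ID = m$gene_id), sep = "\t"))
    db <- m$domain_blocks
    mo <- m$motifs
    ca <- m$catalytic
    attrs <- .gff3_attr(
      ID = rid, Parent = m$gene_id, family = m$family,
      domain_blocks = if (nrow(db)) paste(sprintf("%s:%d-%d", db$name,
                                                  db$first_exon, db$last_exon),
                                          collapse = ","),
      motifs = if (nrow(mo)) paste(sprintf("%s:%s:%s", mo$name, mo$pattern,
                                           ifelse(is.na(mo$exon), ".", mo$exon)),
                                   collapse = ","),
      catalytic = if (nrow(ca)) paste(sprintf("%s:%s:%d", ca$label, ca$residue,
                                              ca$pos), collapse = ","),
      polyA = paste(m$polya_signals + 1L, collapse = ",")
    )
    lines <- c(lines, paste(m$scaffold, "venomsplice", "mRNA", reg[1L] + 1L,
                            reg[2L], ".", m$strand, ".", attrs, sep = "\t"))
    ex <- m$exons
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(m$scaffold, "venomsplice", "exon",
                              ex$start[i] + 1L, ex$end[i], ".", m$strand, ".",
                              .gff3_attr(Parent = rid,
                                         exon_label = exon_label(ex$index[i], ex$sublabel[i]),
                                         in_original = as.integer(ex$in_original[i])),
                              sep = "\t"))
    }
    ## CDS pieces: transcript interval [cds_start, cds_end) over default exons
    ob <- oriented_exons(m)
    cum <- c(0L, cumsum(.iv_width(ob)))
    for (i in seq_len(nrow(ob))) {
      lo <- max(m$cds_start, cum[i]); hi <- min(m$cds_end, cum[i + 1L])
      if (lo >= hi) next
      gs <- ob[i, 1L] + (lo - cum[i]); ge <- ob[i, 1L] + (hi - cum[i])
      g <- sort(.deorient_pos(c(gs, ge), m$strand))  # back to plus-strand
      lines <- c(lines, paste(m$scaffold, "venomsplice", "CDS", g[1L] + 1L,
                              g[2L], ".", m$strand, "0",
                              .gff3_attr(Parent = rid), sep = "\t"))
    }
  }
  for (cl in clusters %||% list()) {
    lines <- c(lines, paste(cl$scaffold, "venomsplice", "gene_group",
                            cl$start + 1L, cl$end, ".", ".", ".",
                            .gff3_attr(ID = cl$cluster_id,
                                       genes = paste(cl$genes, collapse = ",")),
                            sep = "\t"))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    cat(txt, file = file)
    return(invisible(txt))
  }
  txt
}

.gff3_precheck <- function(lines) {
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf != 9L) stop("GFF3 parse error at line ", i, ": expected 9 ",
                       "tab-separated fields, found ", nf)
  }
  invisible(TRUE)
}

#' Read annotated gene models from GFF3
#'
#' Reads gene/mRNA/exon/CDS features in the package's attribute dialect and
#' reconstructs `gene_model` objects.  Clusters come from `gene_group`
#' features when present, otherwise they are inferred from gene proximity
#' with [infer_clusters()].
#'
#' @param gff3_source path to a GFF3 file, or GFF3 text (anything containing
#'   a newline is treated as text).
#' @param fasta_source optional path to the genome FASTA (or a named
#'   character vector / `DNAStringSet` of scaffold sequences); when given,
#'   reference proteins are computed from the annotated CDS.
#' @param cluster_gap gap used by [infer_clusters()] when no `gene_group`
#'   features are present.
#' @return `list(models = <list of gene_model>, clusters = <list of
#'   gene_cluster>)`.
#' @export
read_gene_models <- function(gff3_source, fasta_source = NULL,
                             cluster_gap = 50000L) {
  if (length(gff3_source) == 1L && !grepl("\n", gff3_source) &&
      file.exists(gff3_source)) {
    lines <- readLines(gff3_source)
  } else {
    lines <- strsplit(paste(gff3_source, collapse = "\n"), "\n")[[1L]]
  }
  .gff3_precheck(lines)
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  gr <- rtracklayer::import(tf, format = "gff3")
  if (length(gr) == 0L) return(list(models = list(), clusters = list()))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  seqs <- .load_scaffolds(fasta_source)
  parent1 <- function(i) {
    p <- md$Parent[[i]]
    if (length(p)) p[1L] else NA_character_
  }
  ## comma-separated GFF3 attribute values import as CharacterList
  avals <- function(col, i) {
    x <- md[[col]]
    if (is.null(x)) return(character(0))
    v <- if (methods::is(x, "List")) x[[i]] else x[i]
    v <- as.character(v)
    v[!is.na(v)]
  }

  models <- list()
  mrna_idx <- which(type == "mRNA")
  for (i in mrna_idx) {
    rid <- md$ID[i]
    gid <- parent1(i)
    scf <- as.character(GenomicRanges::seqnames(gr)[i])
    strand <- as.character(GenomicRanges::strand(gr)[i])
    kids <- which(vapply(seq_along(gr), function(j) {
      p <- md$Parent[[j]]; length(p) > 0L && p[1L] == rid
    }, logical(1)))
    exi <- kids[type[kids] == "exon"]
    cdsi <- kids[type[kids] == "CDS"]
    if (length(exi) == 0L) stop("mRNA ", rid, ": no exon features")
    lab <- as.character(md$exon_label[exi])
    idx <- as.integer(sub("[a-z]$", "", lab))
    subl <- ifelse(grepl("[a-z]$", lab), sub("^[0-9]+", "", lab), NA_character_)
    ex <- data.frame(
      index = idx, sublabel = subl,
      start = BiocGenerics::start(gr)[exi] - 1L,
      end = BiocGenerics::end(gr)[exi],
      in_original = as.character(md$in_original[exi]) == "1",
      stringsAsFactors = FALSE
    )
    ord <- if (strand == "+") order(ex$start) else order(-ex$start)
    ex <- ex[ord, , drop = FALSE]
    rownames(ex) <- NULL
    ## CDS genomic span -> transcript coordinates over default exons
    cs <- min(BiocGenerics::start(gr)[cdsi]) - 1L
    ce <- max(BiocGenerics::end(gr)[cdsi])
    de <- ex[ex$in_original, , drop = FALSE]
    ob <- .orient_iv(as.matrix(de[, c("start", "end")]), strand)
    span <- .orient_iv(.iv(cs, ce), strand)
    cds_start <- .g2t(ob, span[1L, 1L])
    cds_end <- .g2t(ob, span[1L, 2L] - 1L) + 1L
    db <- .parse_blocks_attr(avals("domain_blocks", i))
    mo <- .parse_motifs_attr(avals("motifs", i))
    ca <- .parse_catalytic_attr(avals("catalytic", i))
    pa <- as.integer(avals("polyA", i)) - 1L
    m <- gene_model(gid, as.character(md$family[i]), scf, strand, ex,
                    cds_start, cds_end, db, mo, ca, pa)
    if (!is.null(seqs) && m$scaffold %in% names(seqs)) {
      m$ref_protein <- model_ref_protein(m, seqs[[m$scaffold]])
    }
    models[[length(models) + 1L]] <- m
  }

  grp_idx <- which(type == "gene_group")
  if (length(grp_idx)) {
    clusters <- lapply(grp_idx, function(i) {
      gene_cluster(md$ID[i],
                   as.character(GenomicRanges::seqnames(gr)[i]),
                   BiocGenerics::start(gr)[i] - 1L, BiocGenerics::end(gr)[i],
                   avals("genes", i))
    })
  } else {
    clusters <- infer_clusters(models, gap = cluster_gap)
  }
  list(models = models, clusters = clusters)
}

.parse_blocks_attr <- function(x) {
  if (!length(x)) return(NULL)
  parts <- strsplit(x, ":")
  rng <- lapply(parts, function(p) as.integer(strsplit(p[2L], "-")[[1L]]))
  data.frame(name = vapply(parts, `[`, character(1), 1L),
             first_exon = vapply(rng, `[`, integer(1), 1L),
             last_exon = vapply(rng, `[`, integer(1), 2L),
             stringsAsFactors = FALSE)
}

.parse_motifs_attr <- function(x) {
  if (!length(x)) return(NULL)
  parts <- strsplit(x, ":")
  data.frame(name = vapply(parts, `[`, character(1), 1L),
             pattern = vapply(parts, `[`, character(1), 2L),
             exon = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L))),
             stringsAsFactors = FALSE)
}

.parse_catalytic_attr <- function(x) {
  if (!length(x)) return(NULL)
  parts <- strsplit(x, ":")
  data.frame(label = vapply(parts, `[`, character(1), 1L),
             residue = vapply(parts, `[`, character(1), 2L),
             pos = as.integer(vapply(parts, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

## accept a FASTA path, a named character vector, or a DNAStringSet
.load_scaffolds <- function(fasta_source) {
  if (is.null(fasta_source)) return(NULL)
  if (methods::is(fasta_source, "DNAStringSet")) {
    return(stats::setNames(as.list(as.character(fasta_source)),
                           names(fasta_source)))
  }
  if (is.character(fasta_source) && length(fasta_source) == 1L &&
      file.exists(fasta_source)) {
    ss <- Biostrings::readDNAStringSet(fasta_source)
    nm <- sub("\\s.*$", "", names(ss))
    return(stats::setNames(as.list(as.character(ss)), nm))
  }
  if (is.character(fasta_source) && !is.null(names(fasta_source))) {
    return(as.list(fasta_source))
  }
  stop("fasta_source must be a FASTA path, named character vector, or DNAStringSet")
}
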
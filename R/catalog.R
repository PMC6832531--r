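## Variant collapse, trans-spliced chimera detection, and catalog
## summaries: the top of the pipeline.

## polyA-site class of a chain against a model: nearest annotated signal
## within +-tol nt of the terminal end, else the literal end position
.polya_class <- function(chain, model, tol = 8L) {
  b <- oriented_blocks(chain)
  e <- b[nrow(b), 2L]
  sites <- polya_sites(model)
  j <- which.min(abs(sites - e))
  if (abs(sites[j] - e) <= tol) paste0("pA", j) else paste0("end", e)
}

#' Collapse annotated reads into named transcript variants
#'
#' Reads sharing a structural key — the exact junction chain, the polyA-site
#' class, and the start class (canonical versus re-gained start position) —
#' collapse into one variant with summed read support.  Single-nucleotide
#' differences never split variants (allelic variation is below the
#' structural key).  Variants are named `<gene>-v1..vN`: v1 is the original
#' (event-free) variant when present, the rest ordered by support
#' descending, then 5' genomic position, then key.
#'
#' @param records list of per-read annotation records (as built by
#'   [isoform_catalog()]): each carries `chain`, `gene_id`, `events`,
#'   `orf`, `mp_type`.
#' @param models named list of `gene_model`s.
#' @return data.frame with one row per variant.
#' @export
collapse_variants <- function(records, models) {
  if (!length(records)) {
    return(data.frame(gene_id = character(0), name = character(0),
                      key = character(0), support = integer(0),
                      events = character(0), n_events = integer(0),
                      is_original = logical(0), polya_class = character(0),
                      start_class = character(0), stop_class = character(0),
                      premature = logical(0), frameshift = logical(0),
                      protein = character(0), protein_length = integer(0),
                      mp_type = character(0), read_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(records, function(rec) {
    ch <- rec$chain
    jn <- chain_junctions(ch)
    jstr <- if (nrow(jn)) paste(jn[, 1L], jn[, 2L], sep = "-", collapse = ";")
            else "mono"
    m <- models[[rec$gene_id]]
    pac <- .polya_class(ch, m)
    stc <- if (rec$orf$start$canonical) "canonical"
           else paste0("new", rec$orf$start$genomic)
    paste(rec$gene_id, jstr, pac, stc, sep = "|")
  }, character(1))
  rows <- list()
  for (key in unique(keys)) {
    grp <- records[keys == key]
    rec <- grp[[1L]]
    m <- models[[rec$gene_id]]
    ev <- rec$events
    b <- oriented_blocks(rec$chain)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = rec$gene_id, name = NA_character_, key = key,
      support = length(grp),
      events = events_string(ev), n_events = length(ev),
      is_original = length(ev) == 0L,
      polya_class = .polya_class(rec$chain, m),
      start_class = if (rec$orf$start$canonical) "canonical"
                    else paste0("new", rec$orf$start$genomic),
      stop_class = rec$orf$stop$class,
      premature = rec$orf$stop$premature,
      frameshift = rec$orf$frameshift,
      protein = rec$orf$protein,
      protein_length = nchar(rec$orf$protein),
      mp_type = rec$mp_type %||% NA_character_,
      start5 = b[1L, 1L],
      read_ids = paste(vapply(grp, function(g) g$chain$read_id, character(1)),
                       collapse = ","),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  ## deterministic naming per gene
  out <- list()
  for (g in sort(unique(df$gene_id))) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    ord <- order(!sub$is_original, -sub$support, sub$start5, sub$key)
    sub <- sub[ord, , drop = FALSE]
    sub$name <- paste0(g, "-v", seq_len(nrow(sub)))
    out[[g]] <- sub
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$start5 <- NULL
  df
}

#' Detect trans-spliced chimeras over gene clusters
#'
#' Chains spanning more than one gene are segmented at the junctions where
#' consecutive blocks switch donor gene; each segment is labelled with its
#' donor gene and exon range.  A record is kept when there are at least two
#' donors, all donors belong to one cluster, and the segments are colinear
#' (strictly increasing positions along the tandem array; an intervening
#' cluster member may be skipped, as in read-through splicing across a
#' three-gene array).
#'
#' @param chains list of multi-gene `exon_chain`s.
#' @param clusters list of `gene_cluster`s.
#' @param models named list of `gene_model`s.
#' @return data.frame with one row per chimeric structure (reads with the
#'   same structure are collapsed, support summed).
#' @export
detect_chimeras <- function(chains, clusters, models) {
  empty <- data.frame(structure = character(0), cluster_id = character(0),
                      n_donors = integer(0), donors = character(0),
                      support = integer(0), read_ids = character(0),
                      stringsAsFactors = FALSE)
  if (!length(chains)) return(empty)
  recs <- list()
  for (ch in chains) {
    B <- oriented_blocks(ch)
    ## donor gene of each block = gene with maximal default-exon overlap
    donor <- character(nrow(B))
    exon_of <- integer(nrow(B))
    for (r in seq_len(nrow(B))) {
      best_g <- NA_character_; best_ov <- 0L; best_ex <- NA_integer_
      for (gid in names(models)) {
        m <- models[[gid]]
        if (m$scaffold != ch$scaffold || m$strand != ch$strand) next
        E <- oriented_exons(m)
        ov <- vapply(seq_len(nrow(E)), function(k) {
          .iv_overlap_len(B[r, , drop = FALSE], E[k, 1L], E[k, 2L])
        }, integer(1))
        if (sum(ov) > best_ov) {
          best_ov <- sum(ov); best_g <- gid
          best_ex <- default_exons(m)$index[which.max(ov)]
        }
      }
      donor[r] <- best_g; exon_of[r] <- best_ex
    }
    if (anyNA(donor)) next
    if (length(unique(donor)) < 2L) next
    ## segment at donor switches
    seg_id <- cumsum(c(1L, as.integer(donor[-1L] != donor[-length(donor)])))
    segs <- lapply(unique(seg_id), function(s) {
      list(gene_id = donor[seg_id == s][1L],
           exons = range(exon_of[seg_id == s]))
    })
    donors <- vapply(segs, `[[`, character(1), "gene_id")
    if (any(duplicated(donors))) next       # not colinear: gene revisited
    ## all donors in one cluster, strictly increasing cluster positions
    cl_hit <- NULL
    for (cl in clusters) {
      pos <- match(donors, cl$genes)
      if (!anyNA(pos) && all(diff(pos) > 0L)) { cl_hit <- cl; break }
    }
    if (is.null(cl_hit)) next
    struct <- paste(vapply(segs, function(s) {
      sprintf("%s:%d-%d", s$gene_id, s$exons[1L], s$exons[2L])
    }, character(1)), collapse = "|")
    recs[[length(recs) + 1L]] <- list(structure = struct,
                                      cluster_id = cl_hit$cluster_id,
                                      n_donors = length(donors),
                                      read_id = ch$read_id)
  }
  if (!length(recs)) return(empty)
  strct <- vapply(recs, `[[`, character(1), "structure")
  rows <- lapply(unique(strct), function(s) {
    grp <- recs[strct == s]
    data.frame(structure = s, cluster_id = grp[[1L]]$cluster_id,
               n_donors = grp[[1L]]$n_donors,
               donors = paste(unique(vapply(strsplit(s, "|", fixed = TRUE)[[1L]],
                                            function(x) strsplit(x, ":")[[1L]][1L],
                                            character(1))), collapse = ","),
               support = length(grp),
               read_ids = paste(vapply(grp, `[[`, character(1), "read_id"),
                                collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(df$cluster_id, df$structure), , drop = FALSE]
}

#' Run the full isoform-classification pipeline
#'
#' Filters reads to full-length, assigns single-gene chains to gene models,
#' calls splice events, re-projects ORFs (with metalloproteinase typing
#' where applicable), collapses reads into named variants, detects
#' trans-spliced chimeras over clusters, and summarizes per gene and per
#' family.
#'
#' @param reads named character vector of read sequences.
#' @param chains list of `exon_chain`s parallel to `reads`.
#' @param models named list of `gene_model`s.
#' @param clusters list of `gene_cluster`s (default: inferred).
#' @param epsilon junction tolerance passed to [assign_gene()] and
#'   [call_events()].
#' @param min_fraction assignment threshold, see [assign_gene()].
#' @return an object of class `isoform_catalog`.
#' @export
isoform_catalog <- function(reads, chains, models,
                            clusters = infer_clusters(models),
                            epsilon = 0L, min_fraction = 0.5) {
  stopifnot(length(reads) == length(chains))
  flt <- filter_batch(reads, chains, models)
  kept <- flt$kept
  ids <- names(reads)

  records <- list()
  chimeric_chains <- list()
  unassigned <- character(0)
  for (rid in kept) {
    ch <- chains[[match(rid, ids)]]
    spanning <- genes_overlapping(ch, models)
    if (length(spanning) >= 2L) {
      chimeric_chains[[length(chimeric_chains) + 1L]] <- ch
      next
    }
    ar <- assign_gene(ch, models, min_fraction = min_fraction,
                      epsilon = epsilon)
    if (is.na(ar$gene_id)) { unassigned <- c(unassigned, rid); next }
    m <- models[[ar$gene_id]]
    ev <- call_events(ch, m, epsilon = epsilon)
    orf <- project_orf(reads[[rid]], ch, m)
    mp <- if (m$family == "MP" && nrow(m$domain_blocks)) {
      type_mp(orf, m)$type
    } else NA_character_
    motifs <- if (nrow(m$motifs)) locate_motifs(orf, m, ch) else list()
    catal <- if (nrow(m$catalytic) && !is.na(m$ref_protein)) {
      check_catalytic(orf, m)
    } else list()
    records[[rid]] <- list(chain = ch, gene_id = ar$gene_id,
                           assignment = ar, events = ev, orf = orf,
                           mp_type = mp, motifs = motifs, catalytic = catal)
  }

  variants <- collapse_variants(records, models)
  chimeras <- detect_chimeras(chimeric_chains, clusters, models)

  ## conservation: per-gene variant supports must sum to assigned reads
  assigned_per_gene <- table(vapply(records, `[[`, character(1), "gene_id"))
  for (g in names(assigned_per_gene)) {
    s <- sum(variants$support[variants$gene_id == g])
    if (s != assigned_per_gene[[g]]) {
      stop("conservation violated for ", g, ": ", s, " collapsed vs ",
           assigned_per_gene[[g]], " assigned reads")
    }
  }

  structure(list(
    variants = variants, chimeras = chimeras, records = records,
    filter = flt, unassigned = unassigned, models = models,
    clusters = clusters,
    params = list(epsilon = epsilon, min_fraction = min_fraction)
  ), class = "isoform_catalog")
}

#' Summarize an isoform catalog per gene and per family
#'
#' @param catalog an `isoform_catalog`.
#' @return list with `per_gene` (variant counts — inclusive and structural,
#'   i.e. ignoring polyA-site-only differences —, read support, per-event
#'   and per-MP-type counts), `per_family` (alternative-splicing flag: any
#'   member gene with a non-original variant), `n_as_families`,
#'   `chimera_cluster_count`, `n_chimera_structures`, `unassigned_reads`
#'   and the filter counts.
#' @export
catalog_summary <- function(catalog) {
  v <- catalog$variants
  models <- catalog$models
  fam_of <- vapply(models, function(m) m$family, character(1))
  per_gene <- lapply(sort(names(models)), function(g) {
    sub <- v[v$gene_id == g, , drop = FALSE]
    skey <- unique(sub("\\|pA[0-9]+\\|", "|", sub$key))
    ev_kinds <- unlist(lapply(strsplit(sub$events[sub$events != ""], ";"),
                              function(x) sub("\\{.*$", "", x)))
    data.frame(
      gene_id = g, family = fam_of[[g]],
      n_variants = nrow(sub),
      n_variants_structural = length(skey),
      reads = sum(sub$support),
      has_original = any(sub$is_original),
      n_exon_skip = sum(ev_kinds == "EXON_SKIP"),
      n_intron_retention = sum(ev_kinds == "INTRON_RETENTION"),
      n_partial_retention = sum(ev_kinds == "PARTIAL_INTRON_RETENTION"),
      n_alt_site = sum(ev_kinds %in% c("ALT_DONOR", "ALT_ACCEPTOR")),
      n_alt_first_exon = sum(ev_kinds == "ALT_FIRST_EXON"),
      n_alt_polya = sum(ev_kinds == "ALT_POLYA"),
      n_P1 = sum(sub$mp_type == "P1", na.rm = TRUE),
      n_P2 = sum(sub$mp_type == "P2", na.rm = TRUE),
      n_P3 = sum(sub$mp_type == "P3", na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, per_gene)
  fams <- sort(unique(fam_of))
  as_flag <- vapply(fams, function(f) {
    gs <- names(fam_of)[fam_of == f]
    any(per_gene$n_variants[per_gene$gene_id %in% gs] >
          per_gene$has_original[per_gene$gene_id %in% gs])
  }, logical(1))
  per_family <- data.frame(family = fams, alternative_splicing = as_flag,
                           stringsAsFactors = FALSE)
  list(per_gene = per_gene, per_family = per_family,
       n_as_families = sum(as_flag),
       chimera_cluster_count = length(unique(catalog$chimeras$cluster_id)),
       n_chimera_structures = nrow(catalog$chimeras),
       unassigned_reads = length(catalog$unassigned),
       filter_counts = as.list(catalog$filter$counts))
}

#' @export
print.isoform_catalog <- function(x, ...) {
  s <- catalog_summary(x)
  cat("<isoform_catalog>\n")
  cat(sprintf("  reads: %d total, %d full-length, %d discarded, %d unassigned\n",
              length(x$filter$status), length(x$filter$kept),
              length(x$filter$discarded), length(x$unassigned)))
  cat(sprintf("  variants: %d across %d gene(s); chimeras: %d structure(s) in %d cluster(s)\n",
              nrow(x$variants), length(unique(x$variants$gene_id)),
              s$n_chimera_structures, s$chimera_cluster_count))
  cat(sprintf("  families with alternative splicing: %d\n", s$n_as_families))
  invisible(x)
}

#' @export
summary.isoform_catalog <- function(object, ...) {
  s <- catalog_summary(object)
  class(s) <- "summary.isoform_catalog"
  s
}

#' @export
print.summary.isoform_catalog <- function(x, ...) {
  cat("Per-gene variant catalog:\n")
  print(x$per_gene, row.names = FALSE)
  cat("\nPer-family alternative splicing:\n")
  print(x$per_family, row.names = FALSE)
  cat(sprintf("\n%d famil%s with alternative splicing; %d chimeric structure(s) in %d cluster region(s); %d unassigned read(s)\n",
              x$n_as_families, if (x$n_as_families == 1L) "y" else "ies",
              x$n_chimera_structures, x$chimera_cluster_count,
              x$unassigned_reads))
  invisible(x)
}

#' Write catalog reports to disk
#'
#' Writes `variants.tsv`, `chimeras.tsv` and `summary.json` (which also
#' logs the threshold values used) under `dir`.
#'
#' @param catalog an `isoform_catalog`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(catalog$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(catalog$chimeras, file.path(dir, "chimeras.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- catalog_summary(catalog)
  s$params <- catalog$params
  jsonlite::write_json(s, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
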
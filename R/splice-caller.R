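## Gene assignment and splice-event calling: compare a read's exon chain to
## a gene model and classify every deviation.

#' Assign an exon chain to the best-matching gene model
#'
#' Multi-exon chains are assigned to the gene sharing the most exact splice
#' junctions, provided at least one junction matches and at least
#' `min_fraction` of the read's junctions match; single-block chains are
#' assigned by maximal exonic overlap.  Ties are broken by larger exonic
#' overlap, then lexicographic gene id.
#'
#' @param chain an `exon_chain`.
#' @param models named list of `gene_model`s.
#' @param min_fraction minimum fraction of read junctions that must match.
#' @param epsilon junction match tolerance in nt (0 = exact).
#' @return list with `read_id`, `gene_id` (`NA` when unassigned), `shared`
#'   (matching junction count), `fraction` (share of read junctions
#'   matching) and `overlap` (exonic overlap in nt).
#' @export
assign_gene <- function(chain, models, min_fraction = 0.5, epsilon = 0L) {
  jn <- chain_junctions(chain)
  njunc <- nrow(jn)
  best <- list(read_id = chain$read_id, gene_id = NA_character_, shared = 0L,
               fraction = if (njunc) 0 else NA_real_, overlap = 0L)
  for (gid in sort(names(models))) {
    m <- models[[gid]]
    if (m$scaffold != chain$scaffold || m$strand != chain$strand) next
    ea <- oriented_exons_all(m)
    donors <- ea$iv[, 2L]; acceptors <- ea$iv[, 1L]
    shared <- 0L
    if (njunc) {
      for (r in seq_len(njunc)) {
        dok <- any(abs(jn[r, 1L] - donors) <= epsilon)
        aok <- any(abs(jn[r, 2L] - acceptors) <= epsilon)
        if (dok && aok) shared <- shared + 1L
      }
    }
    de <- oriented_exons(m)
    ov <- sum(vapply(seq_len(nrow(de)), function(k) {
      .iv_overlap_len(oriented_blocks(chain), de[k, 1L], de[k, 2L])
    }, integer(1)))
    cand_ok <- if (njunc) {
      shared >= 1L && shared / njunc >= min_fraction
    } else ov > 0L
    if (!cand_ok) next
    better <- if (njunc) {
      shared > best$shared || (shared == best$shared && ov > best$overlap)
    } else ov > best$overlap
    if (is.na(best$gene_id) || better) {
      best <- list(read_id = chain$read_id, gene_id = gid, shared = shared,
                   fraction = if (njunc) shared / njunc else NA_real_,
                   overlap = ov)
    }
  }
  best
}

## gene ids whose default-exon footprint overlaps the chain's blocks
genes_overlapping <- function(chain, models) {
  hits <- character(0)
  for (gid in names(models)) {
    m <- models[[gid]]
    if (m$scaffold != chain$scaffold || m$strand != chain$strand) next
    de <- oriented_exons(m)
    ov <- sum(vapply(seq_len(nrow(de)), function(k) {
      .iv_overlap_len(oriented_blocks(chain), de[k, 1L], de[k, 2L])
    }, integer(1)))
    if (ov > 0L) hits <- c(hits, gid)
  }
  hits
}

.splice_event <- function(kind, exons = NULL, intron = NA_integer_,
                          side = NA_character_, offset = NA_integer_,
                          signal = NA_integer_, labels = NULL) {
  structure(list(kind = kind, exons = exons, intron = intron, side = side,
                 offset = offset, signal = signal, labels = labels),
            class = "splice_event")
}

#' @export
format.splice_event <- function(x, ...) {
  switch(x$kind,
    EXON_SKIP = paste0("EXON_SKIP{", paste(x$exons, collapse = ","), "}"),
    INTRON_RETENTION = paste0("INTRON_RETENTION{", x$intron, "}"),
    PARTIAL_INTRON_RETENTION = paste0("PARTIAL_INTRON_RETENTION{", x$intron,
                                      ",", x$side, "}"),
    ALT_DONOR = paste0("ALT_DONOR{", x$intron, "}"),
    ALT_ACCEPTOR = paste0("ALT_ACCEPTOR{", x$intron, "}"),
    ALT_FIRST_EXON = paste0("ALT_FIRST_EXON{",
                            paste(x$labels, collapse = ","), "}"),
    ALT_POLYA = paste0("ALT_POLYA{", x$signal, "}"),
    NOVEL_EXON = paste0("NOVEL_EXON{", x$intron, "}")
  )
}

#' @export
print.splice_event <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## canonical sorted string form of an event list, for comparison/collapse
events_string <- function(events) {
  if (!length(events)) return("")
  paste(sort(vapply(events, format, character(1))), collapse = ";")
}

#' Call splice events of a chain against its assigned gene model
#'
#' Classifies every deviation of the chain from the model: a default exon
#' absent while spanned by the chain is `EXON_SKIP`; a block running
#' contiguously across an intron is `INTRON_RETENTION`; a junction boundary
#' extending at least `min_partial` nt into an intron without reaching the
#' next exon is `PARTIAL_INTRON_RETENTION` (side recorded, `5p` when the
#' upstream exon extends); a junction boundary shifted into an exon is
#' `ALT_DONOR`/`ALT_ACCEPTOR`; a first block that does not overlap the
#' default first exon, or any use of annotated sub-exons, is
#' `ALT_FIRST_EXON`; a terminal block ending at a non-default annotated
#' polyA site (within `polya_tol` nt) is `ALT_POLYA`; a block overlapping no
#' annotated exon is `NOVEL_EXON`.  A perfect match yields an empty list.
#'
#' @param chain an `exon_chain` assigned to `model`.
#' @param model a `gene_model`.
#' @param epsilon junction tolerance in nt (0 = exact; intron extensions
#'   smaller than `min_partial` are also treated as alignment jitter).
#' @param min_partial minimum intron extension (nt) to call partial
#'   retention.
#' @param polya_tol tolerance (nt) for matching the terminal end to an
#'   annotated polyA site.
#' @return list of `splice_event` objects.
#' @export
call_events <- function(chain, model, epsilon = 0L, min_partial = 10L,
                        polya_tol = 8L) {
  if (chain$scaffold != model$scaffold) {
    stop("call_events: chain scaffold ", chain$scaffold,
         " does not match model scaffold ", model$scaffold)
  }
  E <- oriented_exons(model)           # default exons, transcription order
  idx <- default_exons(model)$index
  n <- nrow(E)
  ea <- oriented_exons_all(model)
  sub_iv <- ea$iv[!ea$in_original, , drop = FALSE]
  sub_lab <- ea$label[!ea$in_original]
  B <- oriented_blocks(chain)
  mB <- nrow(B)
  events <- list()

  ## blocks exactly matching annotated sub-exons
  sub_used <- logical(length(sub_lab))
  is_sub_block <- logical(mB)
  for (r in seq_len(mB)) {
    if (nrow(sub_iv) == 0L) break
    hit <- which(abs(B[r, 1L] - sub_iv[, 1L]) <= epsilon &
                 abs(B[r, 2L] - sub_iv[, 2L]) <= epsilon)
    if (length(hit)) { sub_used[hit[1L]] <- TRUE; is_sub_block[r] <- TRUE }
  }

  ## alternative first exon
  first_overlaps_1a <- .iv_overlap_len(B[1L, , drop = FALSE],
                                       E[1L, 1L], E[1L, 2L]) > 0L
  if (any(sub_used) || !first_overlaps_1a) {
    first_iv <- ea$iv[ea$index == 1L, , drop = FALSE]
    first_lab <- ea$label[ea$index == 1L]
    used <- vapply(seq_len(nrow(first_iv)), function(r) {
      .iv_overlap_len(B, first_iv[r, 1L], first_iv[r, 2L]) > 0L
    }, logical(1))
    events[[length(events) + 1L]] <-
      .splice_event("ALT_FIRST_EXON", labels = first_lab[used])
  }

  Bm <- B[!is_sub_block, , drop = FALSE]   # blocks for model comparison
  span <- c(B[1L, 1L], B[mB, 2L])

  ## exon skipping: default exons with no coverage, inside the chain span
  skipped <- integer(0)
  for (k in seq_len(n)) {
    if (E[k, 2L] <= span[1L] || E[k, 1L] >= span[2L]) next
    if (.iv_overlap_len(Bm, E[k, 1L], E[k, 2L]) == 0L) {
      skipped <- c(skipped, idx[k])
    }
  }
  if (length(skipped)) {
    runs <- split(skipped, cumsum(c(1L, diff(skipped) != 1L)))
    for (rr in runs) {
      events[[length(events) + 1L]] <- .splice_event("EXON_SKIP", exons = rr)
    }
  }

  ## intron analysis
  for (i in seq_len(n - 1L)) {
    d0 <- E[i, 2L]; a0 <- E[i + 1L, 1L]
    if (a0 <= span[1L] || d0 >= span[2L]) next
    ## full retention: one block runs across the whole intron
    retained <- any(Bm[, 1L] < d0 & Bm[, 2L] > a0)
    if (retained) {
      events[[length(events) + 1L]] <-
        .splice_event("INTRON_RETENTION", intron = idx[i])
    }
  }

  ## junction boundary analysis (internal junctions only)
  donors0 <- E[-n, 2L]; acceptors0 <- E[-1L, 1L]
  jn <- if (mB > 1L) .iv(B[-mB, 2L], B[-1L, 1L]) else .iv(integer(0), integer(0))
  for (r in seq_len(nrow(jn))) {
    if (is_sub_block[r] || is_sub_block[r + 1L]) next  # sub-exon junctions
    d <- jn[r, 1L]; a <- jn[r, 2L]
    if (!any(abs(d - donors0) <= epsilon)) {
      ## donor inside an intron (5' partial retention) or inside an exon
      i_in <- which(d > donors0 & d < acceptors0)
      if (length(i_in)) {
        ext <- d - donors0[i_in[1L]]
        ## only when the block is contiguous with the upstream exon; an
        ## intron-interior block is a novel exon, not an extension
        if (ext >= min_partial && B[r, 1L] <= donors0[i_in[1L]]) {
          events[[length(events) + 1L]] <-
            .splice_event("PARTIAL_INTRON_RETENTION", intron = idx[i_in[1L]],
                          side = "5p", offset = ext)
        }
      } else {
        k <- which(d > E[, 1L] & d < E[, 2L])
        if (length(k)) {
          events[[length(events) + 1L]] <-
            .splice_event("ALT_DONOR", intron = idx[k[1L]],
                          offset = E[k[1L], 2L] - d)
        }
      }
    }
    if (!any(abs(a - acceptors0) <= epsilon)) {
      i_in <- which(a > donors0 & a < acceptors0)
      if (length(i_in)) {
        ext <- acceptors0[i_in[1L]] - a
        if (ext >= min_partial && B[r + 1L, 2L] >= acceptors0[i_in[1L]]) {
          events[[length(events) + 1L]] <-
            .splice_event("PARTIAL_INTRON_RETENTION", intron = idx[i_in[1L]],
                          side = "3p", offset = ext)
        }
      } else {
        k <- which(a > E[, 1L] & a < E[, 2L])
        if (length(k)) {
          events[[length(events) + 1L]] <-
            .splice_event("ALT_ACCEPTOR", intron = idx[k[1L] - 1L],
                          offset = a - E[k[1L], 1L])
        }
      }
    }
  }

  ## novel exons: non-sub blocks overlapping no annotated exon, upstream of
  ## the 3' extension region
  for (r in seq_len(mB)) {
    if (is_sub_block[r]) next
    if (B[r, 1L] >= E[n, 2L]) next   # terminal 3'UTR extension (polyA logic)
    ov <- sum(vapply(seq_len(nrow(ea$iv)), function(q) {
      .iv_overlap_len(B[r, , drop = FALSE], ea$iv[q, 1L], ea$iv[q, 2L])
    }, integer(1)))
    ## blocks that bridge into introns overlap exons; a pure intronic block
    ## flanked by junctions is novel
    if (ov == 0L) {
      i_in <- which(B[r, 1L] >= donors0 & B[r, 2L] <= acceptors0)
      events[[length(events) + 1L]] <-
        .splice_event("NOVEL_EXON",
                      intron = if (length(i_in)) idx[i_in[1L]] else NA_integer_)
    }
  }

  ## alternative polyadenylation
  sites <- polya_sites(model)
  e_end <- B[mB, 2L]
  jbest <- which.min(abs(sites - e_end))
  if (abs(sites[jbest] - e_end) <= polya_tol) {
    if (jbest != 1L) {
      events[[length(events) + 1L]] <- .splice_event("ALT_POLYA",
                                                     signal = jbest)
    }
  } else if (abs(e_end - sites[1L]) > polya_tol) {
    events[[length(events) + 1L]] <- .splice_event("ALT_POLYA",
                                                   signal = NA_integer_)
  }
  events
}
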
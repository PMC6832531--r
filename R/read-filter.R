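## Full-length read filter: a read is retained only when it contains both a
## start Met codon and a polyadenylation signal upstream of a polyA tail,
## mirroring the curation rule applied to the venom-gland Iso-Seq data.

#' Classify a read as full-length or short
#'
#' A read is `full_length` when both hold:
#' * start evidence: the model's canonical start codon position is covered
#'   by the chain and reads `ATG`; or, for chains that begin at an annotated
#'   (alternative) first exon without covering the canonical start exon at
#'   all, any `ATG` in the read (alternative-start variants such as
#'   exon-2-skipped serine-protease transcripts keep their full-length
#'   status this way).  Without a model, any `ATG` within the 5' search
#'   window of the first block counts.
#' * polyA evidence: a terminal polyA tail of at least `min_tail` adenines
#'   whose cleavage point has an `AATAAA` hexamer 10-40 nt upstream.
#'
#' @param read_sequence read sequence (character scalar).
#' @param chain the read's `exon_chain` (may be `NULL` with `model = NULL`).
#' @param model assigned `gene_model` or `NULL`.
#' @param min_tail minimum tail length (default 10).
#' @param signal_window polyA signal search window upstream of the cleavage
#'   point, `c(min, max)` distance in nt from hexamer start to cleavage.
#' @param start_window 5' window (nt) searched for an `ATG` when no model is
#'   available.
#' @return list with `status` (`full_length`, `missing_start`,
#'   `missing_polya`, `missing_both`) and evidence fields `start_tpos`,
#'   `canonical_start`, `polya_signal_tpos`, `tail_length`.
#' @export
classify_read <- function(read_sequence, chain = NULL, model = NULL,
                          min_tail = 10L, signal_window = c(10L, 40L),
                          start_window = 100L) {
  if (is.null(read_sequence) || !nzchar(read_sequence)) {
    stop("classify_read: empty read sequence")
  }
  ## ---- start evidence
  start_tpos <- NA_integer_
  canonical <- FALSE
  if (!is.null(model) && !is.null(chain)) {
    ob <- oriented_blocks(chain)
    g0 <- .t2g(oriented_exons(model), model$cds_start)
    t0 <- .g2t(ob, g0)
    if (!is.na(t0) && substr(read_sequence, t0 + 1L, t0 + 3L) == "ATG") {
      start_tpos <- t0; canonical <- TRUE
    } else if (is.na(t0)) {
      ## does the chain lack the canonical start exon entirely while still
      ## beginning at an annotated first exon?
      de <- default_exons(model)
      cum <- c(0L, cumsum(.iv_width(oriented_exons(model))))
      k0 <- findInterval(model$cds_start, cum)
      start_exon <- .orient_iv(as.matrix(de[k0, c("start", "end"), drop = FALSE]),
                               model$strand)
      covers_start_exon <- .iv_overlap_len(ob, start_exon[1L, 1L],
                                           start_exon[1L, 2L]) > 0L
      ea <- oriented_exons_all(model)
      first_iv <- ea$iv[ea$index == 1L, , drop = FALSE]
      at_first <- any(vapply(seq_len(nrow(first_iv)), function(r) {
        .iv_overlap_len(ob[1L, , drop = FALSE], first_iv[r, 1L],
                        first_iv[r, 2L]) > 0L
      }, logical(1)))
      if (!covers_start_exon && at_first) {
        hit <- regexpr("ATG", read_sequence, fixed = TRUE)
        if (hit[1L] != -1L) start_tpos <- hit[1L] - 1L
      }
    }
  } else {
    win <- substr(read_sequence, 1L, start_window)
    hit <- regexpr("ATG", win, fixed = TRUE)
    if (hit[1L] != -1L) start_tpos <- hit[1L] - 1L
  }
  ## ---- polyA evidence
  tail_len <- 0L
  n <- nchar(read_sequence)
  while (tail_len < n &&
         substr(read_sequence, n - tail_len, n - tail_len) == "A") {
    tail_len <- tail_len + 1L
  }
  polya_tpos <- NA_integer_
  if (tail_len >= min_tail) {
    cleave <- n - tail_len  # 0-based cleavage point
    lo <- max(0L, cleave - signal_window[2L])
    hi <- cleave - signal_window[1L]
    if (hi >= lo + 6L) {
      win <- substr(read_sequence, lo + 1L, hi)
      hit <- regexpr("AATAAA", win, fixed = TRUE)
      if (hit[1L] != -1L) polya_tpos <- lo + hit[1L] - 1L
    }
  }
  has_start <- !is.na(start_tpos)
  has_polya <- !is.na(polya_tpos)
  status <- if (has_start && has_polya) "full_length"
    else if (!has_start && !has_polya) "missing_both"
    else if (!has_start) "missing_start"
    else "missing_polya"
  list(status = status, start_tpos = start_tpos, canonical_start = canonical,
       polya_signal_tpos = polya_tpos, tail_length = tail_len)
}

#' Filter a batch of reads into full-length and short
#'
#' Applies [classify_read()] to every read; the model used for the start
#' check is the gene whose region overlaps the chain (5'-most gene for
#' multi-gene chimeric chains).
#'
#' @param reads named character vector of read sequences.
#' @param chains list of `exon_chain`s parallel to `reads`.
#' @param models named list of `gene_model`s.
#' @param ... passed to [classify_read()].
#' @return list with `kept`/`discarded` (read-id vectors), `status` (named
#'   character vector per read) and `counts` (table over the four statuses).
#' @export
filter_batch <- function(reads, chains, models, ...) {
  ids <- names(reads)
  status <- character(0)
  for (i in seq_along(reads)) {
    ch <- chains[[i]]
    m <- .overlapping_model(ch, models)
    status[ids[i]] <- classify_read(reads[[i]], ch, m, ...)$status
  }
  lv <- c("full_length", "missing_start", "missing_polya", "missing_both")
  counts <- table(factor(status, levels = lv))
  list(kept = ids[status == "full_length"],
       discarded = ids[status != "full_length"],
       status = status, counts = counts)
}

## 5'-most model whose span overlaps the chain (NULL when none)
.overlapping_model <- function(chain, models) {
  if (is.null(chain)) return(NULL)
  cand <- list()
  for (m in models) {
    if (m$scaffold != chain$scaffold || m$strand != chain$strand) next
    reg <- model_region(m)
    if (.iv_overlap_len(chain$blocks, reg[1L], reg[2L]) > 0L) {
      cand[[length(cand) + 1L]] <- m
    }
  }
  if (!length(cand)) return(NULL)
  reg5 <- vapply(cand, function(m) {
    r <- model_region(m)
    .orient_pos(if (m$strand == "+") r[1L] else -r[2L], "+")
  }, numeric(1))
  cand[[which.min(reg5)]]
}
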
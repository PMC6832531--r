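## ORF re-projection: translate each variant transcript from its (canonical
## or re-gained) start codon, map the stop codon back through the exon chain
## to genomic space, classify its location against the model's exon/intron
## map, and derive protein-level consequences: motif presence, catalytic
## residue status, and metalloproteinase structural type (P-I/P-II/P-III).

#' Re-project the ORF of a variant transcript
#'
#' Translation starts at the model's canonical start codon when the chain
#' covers it (and it reads `ATG`), otherwise at the first `ATG` of the read
#' (alternative-start variants).  Translation proceeds to the first in-frame
#' stop; the stop codon's transcript position is mapped back through the
#' chain to genomic coordinates and classified against the model as lying in
#' an annotated exon, a downstream (3'UTR) exon, or a retained intron.  When
#' no in-frame stop precedes the transcript end the result is flagged as
#' run-through and the protein is reported to the transcript end.
#'
#' @param transcript_sequence read sequence (may include the polyA tail).
#' @param chain the read's `exon_chain`.
#' @param model the assigned `gene_model`.
#' @return an `orf_result` list: `start` (tpos, genomic position, exon
#'   label, canonical flag), `stop` (tpos, genomic position, `class` one of
#'   `annotated_exon`/`downstream_exon`/`retained_intron`/`run_through`,
#'   `index`, `premature`), `protein`, `frameshift`, plus per-exon coverage
#'   and frame bookkeeping used by [type_mp()].
#' @export
project_orf <- function(transcript_sequence, chain, model) {
  if (!nzchar(transcript_sequence)) stop("project_orf: empty transcript")
  ob <- oriented_blocks(chain)
  W <- sum(.iv_width(ob))
  E <- oriented_exons(model)
  idx <- default_exons(model)$index
  n <- nrow(E)

  g0 <- .t2g(E, model$cds_start)
  t0 <- .g2t(ob, g0)
  if (!is.na(t0) && substr(transcript_sequence, t0 + 1L, t0 + 3L) == "ATG") {
    start_tpos <- t0; canonical <- TRUE
  } else {
    hit <- regexpr("ATG", transcript_sequence, fixed = TRUE)
    if (hit[1L] == -1L) stop("project_orf: no start codon in transcript")
    start_tpos <- hit[1L] - 1L; canonical <- FALSE
  }
  start_g <- if (start_tpos < W) .t2g(ob, start_tpos) else NA_integer_

  ## walk codons to the first stop
  p <- start_tpos
  stop_tpos <- NA_integer_
  nseq <- nchar(transcript_sequence)
  while (p + 3L <= nseq) {
    if (substr(transcript_sequence, p + 1L, p + 3L) %in% .stop_codons) {
      stop_tpos <- p; break
    }
    p <- p + 3L
  }
  run_through <- is.na(stop_tpos)
  prot_end <- if (run_through) nseq else stop_tpos
  prot_nt <- substr(transcript_sequence, start_tpos + 1L, prot_end)
  protein <- sub("\\*.*$", "", .translate_nt(prot_nt))

  ## classify the stop location
  stop_g <- if (!run_through && stop_tpos < W) .t2g(ob, stop_tpos) else NA_integer_
  canon_stop_g <- .t2g(E, model$cds_end - 3L)
  ea <- oriented_exons_all(model)
  donors0 <- E[-n, 2L]; acceptors0 <- E[-1L, 1L]
  ## exon index containing the canonical stop
  k_canon <- which(E[, 1L] <= canon_stop_g & canon_stop_g < E[, 2L])[1L]
  cls <- "run_through"; cls_index <- NA_integer_
  if (!run_through) {
    g <- stop_g
    k <- which(E[, 1L] <= g & g < E[, 2L])
    if (length(k)) {
      cls <- if (idx[k[1L]] <= idx[k_canon]) "annotated_exon" else "downstream_exon"
      cls_index <- idx[k[1L]]
    } else {
      q <- which(!ea$in_original &
                 ea$iv[, 1L] <= g & g < ea$iv[, 2L])
      if (length(q)) {
        cls <- "annotated_exon"; cls_index <- ea$index[q[1L]]
      } else if (g >= E[n, 2L]) {
        cls <- "downstream_exon"; cls_index <- NA_integer_
      } else {
        i <- which(donors0 <= g & g < acceptors0)
        cls <- "retained_intron"
        cls_index <- if (length(i)) idx[i[1L]] else NA_integer_
      }
    }
  }
  premature <- !run_through && !identical(stop_g, canon_stop_g)

  ## frame bookkeeping relative to the model's exonic coordinate system
  delta_at <- function(g) {
    .iv_overlap_len(ob, start_g, g) - .iv_overlap_len(E, start_g, g)
  }
  ref_g <- if (!run_through && !is.na(stop_g)) stop_g else ob[nrow(ob), 2L]
  frameshift <- !is.na(start_g) && (delta_at(ref_g) %% 3L != 0L)
  exon_covered <- vapply(seq_len(n), function(k) {
    .iv_covers(ob, E[k, 1L], E[k, 2L])
  }, logical(1))
  exon_frame_ok <- vapply(seq_len(n), function(k) {
    !is.na(start_g) && delta_at(E[k, 2L]) %% 3L == 0L
  }, logical(1))

  ## exon label at the start
  start_exon <- NA_character_
  if (!is.na(start_g)) {
    q <- which(ea$iv[, 1L] <= start_g & start_g < ea$iv[, 2L])
    if (length(q)) start_exon <- ea$label[q[1L]]
  }

  structure(list(
    read_id = chain$read_id, gene_id = model$gene_id,
    start = list(tpos = start_tpos, genomic = start_g, exon = start_exon,
                 canonical = canonical),
    stop = list(tpos = stop_tpos, genomic = stop_g, class = cls,
                index = cls_index, premature = premature),
    protein = protein, frameshift = frameshift, run_through = run_through,
    exon_covered = exon_covered, exon_frame_ok = exon_frame_ok,
    stop_g_oriented = if (run_through) Inf else stop_g
  ), class = "orf_result")
}

#' @export
print.orf_result <- function(x, ...) {
  cat(sprintf("<orf_result> %s on %s: start %s (%s), stop %s[%s]%s, %d aa%s\n",
              x$read_id, x$gene_id, x$start$tpos,
              if (x$start$canonical) "canonical" else "new",
              x$stop$class, x$stop$index %||% NA,
              if (x$stop$premature) " premature" else "",
              nchar(x$protein),
              if (x$frameshift) ", frameshifted" else ""))
  invisible(x)
}

#' Locate annotated motifs in a re-projected protein
#'
#' Matches each model motif pattern (`X` = any residue) against the ORF's
#' protein and maps the matched codons back through the chain to the exon
#' containing the majority of them.
#'
#' @param orf an `orf_result`.
#' @param model the `gene_model`.
#' @param chain the read's `exon_chain`.
#' @return list of motif status lists: `name`, `found`, `span` (1-based
#'   protein positions), `exon` (majority-codon exon index, `NA` unless
#'   found).
#' @export
locate_motifs <- function(orf, model, chain) {
  ob <- oriented_blocks(chain)
  W <- sum(.iv_width(ob))
  ea <- oriented_exons_all(model)
  out <- list()
  for (r in seq_len(nrow(model$motifs))) {
    pat <- model$motifs$pattern[r]
    rx <- gsub("X", ".", pat, fixed = TRUE)
    hit <- regexpr(rx, orf$protein)
    if (hit[1L] == -1L) {
      out[[r]] <- list(name = model$motifs$name[r], found = FALSE,
                       span = NULL, exon = NA_integer_)
      next
    }
    p1 <- hit[1L]; p2 <- p1 + attr(hit, "match.length") - 1L
    codon_exons <- vapply(p1:p2, function(p) {
      base_t <- orf$start$tpos + 3L * (p - 1L) + 0:2
      exs <- vapply(base_t, function(t) {
        if (t >= W) return(NA_integer_)
        g <- .t2g(ob, t)
        q <- which(ea$iv[, 1L] <= g & g < ea$iv[, 2L])
        if (length(q)) ea$index[q[1L]] else NA_integer_
      }, integer(1))
      tb <- table(exs[!is.na(exs)])
      if (!length(tb)) NA_integer_ else as.integer(names(tb)[which.max(tb)])
    }, integer(1))
    tb <- table(codon_exons[!is.na(codon_exons)])
    out[[r]] <- list(name = model$motifs$name[r], found = TRUE,
                     span = c(p1, p2),
                     exon = if (length(tb)) as.integer(names(tb)[which.max(tb)])
                            else NA_integer_)
  }
  out
}

#' Check catalytic residues of a variant protein
#'
#' The variant protein is aligned to the model's reference protein by
#' shared prefix; a residue is `present` when the observed amino acid at
#' its annotated position matches the expectation, `substituted` when a
#' different residue is observed at an alignable position, and `absent`
#' when the protein ends before the position or a frameshift makes the
#' position unalignable.
#'
#' @param orf an `orf_result`.
#' @param model the `gene_model` (must carry `ref_protein`).
#' @return list of status lists: `label`, `state`
#'   (`present`/`substituted`/`absent`), `observed`.
#' @export
check_catalytic <- function(orf, model) {
  ref <- model$ref_protein
  if (is.na(ref)) stop("check_catalytic: model ", model$gene_id,
                       " has no reference protein (read models with sequence)")
  var <- orf$protein
  ## length of the shared prefix
  L <- 0L
  nmax <- min(nchar(ref), nchar(var))
  while (L < nmax && substr(ref, L + 1L, L + 1L) == substr(var, L + 1L, L + 1L)) {
    L <- L + 1L
  }
  out <- list()
  for (r in seq_len(nrow(model$catalytic))) {
    pos <- model$catalytic$pos[r]
    expd <- model$catalytic$residue[r]
    if (pos <= L) {
      obs <- substr(var, pos, pos)
      state <- if (obs == expd) "present" else "substituted"
    } else if (!orf$frameshift && pos <= nchar(var)) {
      obs <- substr(var, pos, pos)
      state <- if (obs == expd) "present" else "substituted"
    } else {
      obs <- NA_character_; state <- "absent"
    }
    out[[r]] <- list(label = model$catalytic$label[r], state = state,
                     observed = obs)
  }
  out
}

#' Assign the metalloproteinase structural type of a variant
#'
#' A domain block counts as covered when every exon of its range is fully
#' present in the chain, translated in the original frame, and entirely
#' upstream of the stop location.  P-III requires metalloproteinase,
#' disintegrin and Cys-rich domains; P-II the first two; P-I the
#' metalloproteinase domain only.  A variant whose MP domain itself is not
#' fully covered is reported `non_functional` rather than typed.
#'
#' @param orf an `orf_result`.
#' @param model an MP-family `gene_model` with domain blocks.
#' @return list with `type` (`P1`/`P2`/`P3`/`non_functional`) and
#'   `domains_covered`.
#' @export
type_mp <- function(orf, model) {
  if (model$family != "MP") stop("type_mp: model ", model$gene_id,
                                 " is not an MP-family gene")
  E <- oriented_exons(model)
  idx <- default_exons(model)$index
  db <- model$domain_blocks
  covered <- character(0)
  for (i in seq_len(nrow(db))) {
    if (!db$name[i] %in% c("MP", "disintegrin", "cys_rich")) next
    rng <- which(idx >= db$first_exon[i] & idx <= db$last_exon[i])
    if (!length(rng)) next
    full <- all(orf$exon_covered[rng])
    frame_ok <- orf$exon_frame_ok[max(rng)]
    upstream <- orf$stop_g_oriented >= E[max(rng), 2L]
    if (full && frame_ok && upstream) covered <- c(covered, db$name[i])
  }
  type <- if (!"MP" %in% covered) "non_functional"
    else if (all(c("disintegrin", "cys_rich") %in% covered)) "P3"
    else if ("disintegrin" %in% covered) "P2"
    else "P1"
  list(type = type, domains_covered = covered)
}
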
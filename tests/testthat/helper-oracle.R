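## Independent oracles used against the implementation:
##  - oracle_events(): per-base coverage-set reasoning over the gene span,
##    written independently of the interval/junction algebra in call_events()
##  - oracle_translate(): plain regex/substring translation independent of
##    both project_orf() and the generator's scan_orf()
##  - mirror helpers to express a locus on the minus strand

## brute-force splice-event calls from per-base coverage sets
oracle_events <- function(chain, model, min_partial = 10L, polya_tol = 8L) {
  E <- venomsplice:::oriented_exons(model)
  idx <- venomsplice:::default_exons(model)$index
  ea <- venomsplice:::oriented_exons_all(model)
  B <- venomsplice:::oriented_blocks(chain)
  n <- nrow(E)
  origin <- min(E[1L, 1L], B[1L, 1L])
  top <- max(E[n, 2L], B[nrow(B), 2L])
  cov <- rep(FALSE, top - origin)
  for (r in seq_len(nrow(B))) {
    cov[(B[r, 1L] - origin + 1L):(B[r, 2L] - origin)] <- TRUE
  }
  at <- function(g) cov[g - origin + 1L]              # coverage of base g
  covered_in <- function(s, e) if (e <= s) logical(0) else at(s:(e - 1L))
  span <- c(B[1L, 1L], B[nrow(B), 2L])
  out <- character(0)

  ## sub-exon usage / alternative first exon
  subs <- which(!ea$in_original)
  sub_used <- vapply(subs, function(q) {
    all(covered_in(ea$iv[q, 1L], ea$iv[q, 2L]))
  }, logical(1))
  first1a <- any(covered_in(E[1L, 1L], E[1L, 2L]))
  if ((length(sub_used) && any(sub_used)) || !first1a) {
    firsts <- which(ea$index == 1L)
    used <- vapply(firsts, function(q) {
      any(covered_in(ea$iv[q, 1L], ea$iv[q, 2L]))
    }, logical(1))
    out <- c(out, paste0("ALT_FIRST_EXON{",
                         paste(ea$label[firsts[used]], collapse = ","), "}"))
  }

  ## exon skipping (contiguous runs)
  skipped <- idx[vapply(seq_len(n), function(k) {
    E[k, 2L] > span[1L] && E[k, 1L] < span[2L] &&
      !any(covered_in(E[k, 1L], E[k, 2L]))
  }, logical(1))]
  if (length(skipped)) {
    for (rr in split(skipped, cumsum(c(1L, diff(skipped) != 1L)))) {
      out <- c(out, paste0("EXON_SKIP{", paste(rr, collapse = ","), "}"))
    }
  }

  ## introns: full retention, partial retention, novel blocks
  sub_cover <- rep(FALSE, top - origin)
  for (q in subs) {
    sub_cover[(ea$iv[q, 1L] - origin + 1L):(ea$iv[q, 2L] - origin)] <- TRUE
  }
  for (i in seq_len(n - 1L)) {
    d0 <- E[i, 2L]; a0 <- E[i + 1L, 1L]
    if (a0 <= span[1L] || d0 >= span[2L]) next
    ic <- covered_in(d0, a0)
    ic_model <- ic & !sub_cover[(d0 - origin + 1L):(a0 - origin)]
    if (all(ic)) {
      out <- c(out, paste0("INTRON_RETENTION{", idx[i], "}"))
      next
    }
    ext5 <- match(FALSE, ic_model, nomatch = length(ic_model) + 1L) - 1L
    ext3 <- match(FALSE, rev(ic_model), nomatch = length(ic_model) + 1L) - 1L
    if (ext5 >= min_partial && ext5 < length(ic)) {
      out <- c(out, paste0("PARTIAL_INTRON_RETENTION{", idx[i], ",5p}"))
    }
    if (ext3 >= min_partial && ext3 < length(ic)) {
      out <- c(out, paste0("PARTIAL_INTRON_RETENTION{", idx[i], ",3p}"))
    }
    ## interior covered stretch touching neither boundary, outside sub-exons
    inner <- ic_model
    if (ext5 > 0L) inner[seq_len(ext5)] <- FALSE
    if (ext3 > 0L) inner[length(inner) - seq_len(ext3) + 1L] <- FALSE
    if (any(inner)) out <- c(out, paste0("NOVEL_EXON{", idx[i], "}"))
  }

  ## alternative donor/acceptor: uncovered exon suffix/prefix inside span
  for (k in seq_len(n)) {
    exc <- covered_in(E[k, 1L], E[k, 2L])
    if (!any(exc) || all(exc)) next
    gap3 <- match(TRUE, rev(exc), nomatch = 1L) - 1L   # uncovered suffix
    gap5 <- match(TRUE, exc, nomatch = 1L) - 1L        # uncovered prefix
    has_down <- E[k, 2L] < span[2L] && any(covered_in(E[k, 2L], span[2L]))
    has_up <- E[k, 1L] > span[1L] && any(covered_in(span[1L], E[k, 1L]))
    if (gap3 > 0L && has_down) {
      out <- c(out, paste0("ALT_DONOR{", idx[k], "}"))
    }
    if (gap5 > 0L && has_up && k > 1L) {
      out <- c(out, paste0("ALT_ACCEPTOR{", idx[k - 1L], "}"))
    }
  }

  ## alternative polyadenylation
  sites <- venomsplice:::polya_sites(model)
  e_end <- B[nrow(B), 2L]
  j <- which.min(abs(sites - e_end))
  if (abs(sites[j] - e_end) <= polya_tol) {
    if (j != 1L) out <- c(out, paste0("ALT_POLYA{", j, "}"))
  } else if (abs(e_end - sites[1L]) > polya_tol) {
    out <- c(out, "ALT_POLYA{NA}")
  }
  paste(sort(out), collapse = ";")
}

## independent single-frame translation from a fixed start offset
oracle_translate <- function(seq, start_tpos) {
  gc <- Biostrings::GENETIC_CODE
  aa <- character(0)
  p <- start_tpos
  while (p + 3L <= nchar(seq)) {
    cod <- substr(seq, p + 1L, p + 3L)
    r <- gc[[cod]]
    if (r == "*") break
    aa <- c(aa, r)
    p <- p + 3L
  }
  paste(aa, collapse = "")
}

## express a plus-strand locus (model, genome, chains) on the minus strand
mirror_scenario <- function(models, genome, chains) {
  L <- vapply(genome, nchar, integer(1))
  genome2 <- lapply(genome, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  })
  models2 <- lapply(models, function(m) {
    l <- L[[m$scaffold]]
    ex <- m$exons
    tmp <- l - ex$end; ex$end <- l - ex$start; ex$start <- tmp
    m$exons <- ex
    m$strand <- "-"
    m$polya_signals <- l - m$polya_signals - 6L
    venomsplice::validate_gene_model(m)
    m
  })
  chains2 <- lapply(chains, function(ch) {
    l <- L[[ch$scaffold]]
    b <- venomsplice:::.iv(l - ch$blocks[, 2L], l - ch$blocks[, 1L])
    venomsplice::exon_chain(ch$read_id, ch$scaffold, "-", b)
  })
  names(chains2) <- names(chains)
  list(models = models2, genome = genome2, chains = chains2)
}

## resource-claiming sampler of mutually compatible random event plans
random_event_plan <- function(model, n_events = NULL) {
  n <- nrow(venomsplice:::default_exons(model))
  if (is.null(n_events)) n_events <- sample(0:3, 1L)
  claimed <- logical(n)     # claimed exons
  claimed_intron <- logical(n - 1L)
  evs <- list()
  kinds <- c("EXON_SKIP", "INTRON_RETENTION", "PARTIAL_INTRON_RETENTION",
             "ALT_DONOR", "ALT_ACCEPTOR", "ALT_POLYA")
  tries <- 0L
  while (length(evs) < n_events && tries < 30L) {
    tries <- tries + 1L
    kind <- sample(kinds, 1L)
    if (kind == "ALT_POLYA") {
      if (length(model$polya_signals) < 2L || claimed[n]) next
      evs <- c(evs, list(event_spec("ALT_POLYA", signal = 2L)))
      claimed[n] <- TRUE
      next
    }
    i <- sample(seq_len(n - 1L), 1L)
    if (kind == "EXON_SKIP") {
      k <- sample(2:(n - 1L), 1L)
      if (claimed[k] || (k > 1L && claimed_intron[k - 1L]) ||
          (k <= n - 1L && claimed_intron[k])) next
      evs <- c(evs, list(event_spec("EXON_SKIP", exons = k)))
      claimed[k] <- TRUE
      if (k > 1L) claimed_intron[k - 1L] <- TRUE
      if (k <= n - 1L) claimed_intron[k] <- TRUE
    } else {
      if (claimed_intron[i] || claimed[i] || claimed[i + 1L]) next
      E <- venomsplice:::oriented_exons(model)
      intron_len <- E[i + 1L, 1L] - E[i, 2L]
      ev <- switch(kind,
        INTRON_RETENTION = event_spec("INTRON_RETENTION", intron = i),
        PARTIAL_INTRON_RETENTION = event_spec(
          "PARTIAL_INTRON_RETENTION", intron = i,
          side = sample(c("5p", "3p"), 1L),
          offset = sample(10:(intron_len - 5L), 1L)),
        ALT_DONOR = event_spec("ALT_DONOR", intron = i,
                               offset = sample(1:15, 1L)),
        ALT_ACCEPTOR = event_spec("ALT_ACCEPTOR", intron = i,
                                  offset = sample(1:15, 1L)))
      evs <- c(evs, list(ev))
      claimed_intron[i] <- TRUE
      claimed[c(i, i + 1L)] <- TRUE
    }
  }
  if (!length(evs)) evs <- list(event_spec("NONE"))
  evs
}
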
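## Internal helpers: seeded evaluation, interval arithmetic on 0-based
## half-open intervals, and strand orientation.

#' Evaluate code under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## intervals are 2-column integer matrices [start, end), rows sorted
.iv <- function(start, end) {
  m <- cbind(as.integer(start), as.integer(end))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

.iv_width <- function(m) if (nrow(m) == 0L) integer(0) else m[, 2L] - m[, 1L]

## total length of the intersection of interval set `m` with single [s, e)
.iv_overlap_len <- function(m, s, e) {
  if (nrow(m) == 0L) return(0L)
  lo <- pmax(m[, 1L], s)
  hi <- pmin(m[, 2L], e)
  sum(pmax(hi - lo, 0L))
}

## union length of an interval set
.iv_union_len <- function(m) {
  if (nrow(m) == 0L) return(0L)
  m <- m[order(m[, 1L]), , drop = FALSE]
  tot <- 0L; cur_s <- m[1L, 1L]; cur_e <- m[1L, 2L]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] > cur_e) {
      tot <- tot + (cur_e - cur_s); cur_s <- m[i, 1L]; cur_e <- m[i, 2L]
    } else cur_e <- max(cur_e, m[i, 2L])
  }
  tot + (cur_e - cur_s)
}

## is [s, e) fully covered by the union of `m`?
.iv_covers <- function(m, s, e) .iv_overlap_len(m, s, e) == (e - s)

## orient a genomic interval matrix into transcription coordinates:
## '+' keeps coordinates, '-' maps [s, e) -> [-e, -s) so that downstream
## (3') is always numerically larger.  Row order is preserved.
.orient_iv <- function(m, strand) {
  if (strand == "+") return(.iv(m[, 1L], m[, 2L]))
  .iv(-m[, 2L], -m[, 1L])
}

## inverse of .orient_iv for scalar positions
.deorient_pos <- function(p, strand) if (strand == "+") p else -p

.orient_pos <- function(p, strand) if (strand == "+") p else -p

## map oriented genomic position -> transcript offset over oriented,
## 5'->3' sorted blocks; NA when not covered.  `g` is scalar.
.g2t <- function(blocks, g) {
  cum <- c(0L, cumsum(.iv_width(blocks)))
  for (i in seq_len(nrow(blocks))) {
    if (g >= blocks[i, 1L] && g < blocks[i, 2L]) {
      return(unname(as.integer(cum[i] + (g - blocks[i, 1L]))))
    }
  }
  NA_integer_
}

## map transcript offset -> oriented genomic position
.t2g <- function(blocks, t) {
  cum <- c(0L, cumsum(.iv_width(blocks)))
  i <- findInterval(t, cum, rightmost.closed = FALSE)
  if (i < 1L || i > nrow(blocks) || t >= cum[nrow(blocks) + 1L]) return(NA_integer_)
  unname(as.integer(blocks[i, 1L] + (t - cum[i])))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## spliced sequence of oriented blocks given the plus-strand scaffold string
.spliced_seq <- function(scaffold_seq, blocks_genomic, strand) {
  ## blocks_genomic: plus-strand coordinates, rows in genomic order
  parts <- vapply(seq_len(nrow(blocks_genomic)), function(i) {
    substr(scaffold_seq, blocks_genomic[i, 1L] + 1L, blocks_genomic[i, 2L])
  }, character(1))
  s <- paste0(parts, collapse = "")
  if (strand == "-") s <- .revcomp(s)
  s
}

.stop_codons <- c("TAA", "TAG", "TGA")

## translate an in-frame nucleotide string (no ambiguity handling needed for
## synthetic data); returns the AA string including '*' for stops
.translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n)),
                                     no.init.codon = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
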
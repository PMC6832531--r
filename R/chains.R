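## Exon chains: the ordered aligned genomic blocks of one read, the unit
## compared against gene models.  BED12 is the interchange format.

#' Construct an exon chain
#'
#' @param read_id read identifier.
#' @param scaffold scaffold name.
#' @param strand `"+"` or `"-"` (transcription strand of the alignment).
#' @param blocks 2-column matrix of 0-based half-open genomic intervals,
#'   rows in ascending genomic order.
#' @return an object of class `exon_chain`.
#' @export
exon_chain <- function(read_id, scaffold, strand, blocks) {
  blocks <- .iv(blocks[, 1L], blocks[, 2L])
  if (nrow(blocks) < 1L) stop("exon_chain: at least one block required")
  if (any(blocks[, 1L] >= blocks[, 2L])) stop("exon_chain: empty block")
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  if (nrow(blocks) > 1L && any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L])) {
    stop("exon_chain: overlapping blocks in read ", read_id)
  }
  if (!strand %in% c("+", "-")) stop("exon_chain: bad strand")
  structure(list(read_id = read_id, scaffold = scaffold, strand = strand,
                 blocks = blocks), class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat(sprintf("<exon_chain> %s %s(%s) %d block(s), span %d-%d\n", x$read_id,
              x$scaffold, x$strand, nrow(x$blocks), x$blocks[1L, 1L],
              x$blocks[nrow(x$blocks), 2L]))
  invisible(x)
}

## oriented blocks in transcription order (ascending oriented coordinates)
oriented_blocks <- function(chain) {
  b <- .orient_iv(chain$blocks, chain$strand)
  b[order(b[, 1L]), , drop = FALSE]
}

## chain junctions in oriented coordinates: (donor, acceptor) pairs
chain_junctions <- function(chain) {
  b <- oriented_blocks(chain)
  if (nrow(b) < 2L) return(.iv(integer(0), integer(0)))
  .iv(b[-nrow(b), 2L], b[-1L, 1L])
}

#' Write exon chains to BED12
#'
#' @param chains list of `exon_chain` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_chains_bed12 <- function(chains, file) {
  lines <- vapply(chains, function(ch) {
    b <- ch$blocks
    s <- b[1L, 1L]; e <- b[nrow(b), 2L]
    paste(ch$scaffold, s, e, ch$read_id, 0L, ch$strand, s, e, "0,0,0",
          nrow(b),
          paste0(paste(b[, 2L] - b[, 1L], collapse = ","), ","),
          paste0(paste(b[, 1L] - s, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read exon chains from a BED12 file
#'
#' Parsed with `rtracklayer::import`; block structure is taken from the
#' BED12 block columns.
#'
#' @param file BED12 path.
#' @return list of `exon_chain` objects.
#' @export
read_chains_bed12 <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  bl <- rtracklayer::blocks(gr)
  lapply(seq_along(gr), function(i) {
    b <- bl[[i]]
    exon_chain(
      read_id = gr$name[i],
      scaffold = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      blocks = .iv(BiocGenerics::start(b) - 1L, BiocGenerics::end(b))
    )
  })
}
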
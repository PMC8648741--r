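#' Readable size of the hg38 assembly
#'
#' Total ungapped length of the GRCh38 reference assembly, in base pairs.
#' Used as the denominator \eqn{L} of the uniform per-base breakage
#' probability when breakpoint catalogs are mapped to hg38.
#'
#' @format A single integer-valued numeric (2,948,611,470 bp).
#' @export
HG38_READABLE_BP <- 2948611470

#' Define a genome for breakpoint analysis
#'
#' A genome is a set of named chromosomes with lengths plus a readable size
#' \eqn{L}: the number of base pairs a breakpoint can actually fall on.
#' Under the random breakage model every one of the \eqn{L} readable bases
#' is equally likely to carry a breakpoint.  For synthetic genomes with no
#' assembly gaps the readable size is simply the summed chromosome length
#' (the default); for hg38 pass \code{readable_size = HG38_READABLE_BP}.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param readable_size readable genome size \eqn{L} in bp; defaults to
#'   \code{sum(chrom_lengths)}.
#' @return An object of class \code{"bp_genome"}.
#' @examples
#' g <- bp_genome(c(chr1 = 1e7, chr2 = 5e6))
#' g$readable_size
#' @export
bp_genome <- function(chrom_lengths, readable_size = sum(chrom_lengths)) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names")
  if (any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  if (readable_size <= 0)
    stop("readable_size must be positive")
  if (readable_size > sum(chrom_lengths))
    stop("readable_size cannot exceed the summed chromosome length")
  structure(
    list(chrom_lengths = chrom_lengths, readable_size = readable_size),
    class = "bp_genome"
  )
}

#' @export
print.bp_genome <- function(x, ...) {
  cat("Genome:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total,",
      "readable size L =", format(x$readable_size, big.mark = ","), "bp\n")
  invisible(x)
}

.check_chroms <- function(chrom, genome, what = "interval") {
  unknown <- setdiff(unique(as.character(chrom)), names(genome$chrom_lengths))
  if (length(unknown))
    stop(sprintf("%s on unknown chromosome(s): %s", what,
                 paste(unknown, collapse = ", ")))
  invisible(TRUE)
}

.genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome$chrom_lengths),
                        seqlengths = as.integer(genome$chrom_lengths))
}
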
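#' Construct an element interval track
#'
#' A track is one class of genomic DNA elements (e.g. CpG islands,
#' G-quadruplex motifs) as a set of intervals in BED convention: 0-based
#' starts, exclusive ends.
#'
#' @param chrom character vector of chromosome names (or a data.frame with
#'   columns \code{chrom}, \code{start}, \code{end}, in which case
#'   \code{start}/\code{end} are ignored).
#' @param start,end 0-based half-open interval bounds in bp.
#' @param element_class label of the element class.
#' @param merged logical; \code{TRUE} only if the intervals are already
#'   sorted and pairwise non-overlapping.
#' @return A data.frame of class \code{"bp_track"} with columns
#'   \code{chrom}, \code{start}, \code{end} and attributes
#'   \code{element_class} and \code{merged}.
#' @seealso [merge_track()], [cumulative_length()], [read_bed()]
#' @export
bp_track <- function(chrom, start = NULL, end = NULL,
                     element_class = "element", merged = FALSE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop("track data.frame needs columns chrom, start, end")
    df <- df[, c("chrom", "start", "end")]
  } else {
    df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     stringsAsFactors = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (nrow(df)) {
    if (any(is.na(df$start)) || any(is.na(df$end)))
      stop("NA interval bounds")
    if (any(df$start < 0))
      stop("coordinate error: negative start")
    if (any(df$start >= df$end))
      stop("coordinate error: start >= end")
  }
  rownames(df) <- NULL
  structure(df, element_class = element_class, merged = isTRUE(merged),
            class = c("bp_track", "data.frame"))
}

#' @export
print.bp_track <- function(x, ...) {
  cat(sprintf("<bp_track> %s: %d interval(s)%s, %s bp\n",
              element_class(x), nrow(x),
              if (is_merged(x)) " (merged)" else "",
              format(sum(x$end - x$start), big.mark = ",")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @rdname bp_track
#' @param x a \code{bp_track}.
#' @export
element_class <- function(x) attr(x, "element_class")

#' @rdname bp_track
#' @export
is_merged <- function(x) isTRUE(attr(x, "merged"))

## bp_track <-> GRanges (internal; BED half-open to 1-based closed)
.track_gr <- function(track, genome = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end)
  )
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  if (!is.null(genome)) {
    .check_chroms(track$chrom, genome)
    GenomeInfoDb::seqinfo(gr) <- .genome_seqinfo(genome)[
      GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

.gr_track <- function(gr, element_class, merged = FALSE) {
  bp_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ), element_class = element_class, merged = merged)
}

#' Merge overlapping intervals of a track
#'
#' Sorts the intervals and collapses every overlapping or bookended pair so
#' the covered base set is unchanged but intervals are pairwise disjoint.
#' The cumulative length \eqn{L_i} and breakpoint count \eqn{n_i} entering
#' the Hscore are always computed on merged tracks, so elements covering the
#' same bases are not counted twice.
#'
#' @param track a [bp_track()].
#' @return The merged track (\code{merged} attribute set).
#' @examples
#' merge_track(bp_track(c("c1", "c1"), c(0, 5), c(10, 20)))
#' @export
merge_track <- function(track) {
  if (is_merged(track)) return(track)
  if (!nrow(track))
    return(structure(track, merged = TRUE))
  gr <- GenomicRanges::reduce(.track_gr(track))
  gr <- GenomicRanges::sort(gr)
  .gr_track(gr, element_class(track), merged = TRUE)
}

#' Cumulative length of a merged track
#'
#' Sum of merged interval sizes in bp (the \eqn{L_i} of the binomial model).
#' Unmerged tracks are merged first so overlapping bases count once.
#'
#' @param track a [bp_track()].
#' @return Total covered bases (numeric, 0 for an empty track).
#' @export
cumulative_length <- function(track) {
  track <- merge_track(track)
  if (!nrow(track)) return(0)
  sum(track$end - track$start)
}

#' Shift every interval of a track by a multiple of its own length
#'
#' Each interval \eqn{[s, e)} of width \eqn{w = e - s} is moved to
#' \eqn{[s + k w, e + k w)}: \code{k = +1} is the adjacent downstream
#' (rightward) window of the same size, \code{k = -1} the adjacent upstream
#' window, and so on.  Portions falling outside the chromosome are clipped;
#' intervals entirely off-chromosome are dropped (their number is reported
#' as a message).  The result is merged before use.
#'
#' @param track a [bp_track()].
#' @param k signed integer shift multiplier (non-zero).
#' @param genome a [bp_genome()] providing chromosome bounds.
#' @return The shifted, merged track; its \code{element_class} is suffixed
#'   with the offset.
#' @export
shift_track <- function(track, k, genome) {
  if (k == 0) stop("k must be non-zero; offset 0 is the track itself")
  if (k != round(k)) stop("k must be an integer")
  .check_chroms(track$chrom, genome)
  w <- track$end - track$start
  out <- data.frame(chrom = track$chrom,
                    start = track$start + k * w,
                    end = track$end + k * w,
                    stringsAsFactors = FALSE)
  clen <- genome$chrom_lengths[out$chrom]
  out$start <- pmax(out$start, 0)
  out$end <- pmin(out$end, clen)
  keep <- out$start < out$end
  if (any(!keep))
    message(sum(!keep), " interval(s) entirely off-chromosome after shift; dropped")
  out <- out[keep, , drop = FALSE]
  label <- sprintf("%s[%+d]", element_class(track), k)
  merge_track(bp_track(out, element_class = label))
}

#' Split a track into inside-gene and outside-gene sub-tracks
#'
#' An element belongs to the inside-gene sub-track when it overlaps a gene
#' body (TSS to TES) by at least 1 bp; otherwise it is outside.  The split
#' operates on the original (unmerged) elements, so each element is assigned
#' wholly to one side and element counts are conserved.  Genes are merged
#' before the overlap test so the assignment does not depend on overlapping
#' gene models.
#'
#' @param track a [bp_track()] of elements (unmerged).
#' @param genes a [bp_track()] of gene bodies (see [gene_model()]); if it
#'   carries an \code{expressed} column, only expressed genes are used.
#' @return list with components \code{inside} and \code{outside}, both
#'   \code{bp_track}s (element classes suffixed \code{.ingene} /
#'   \code{.outgene}).
#' @export
split_track_by_genes <- function(track, genes) {
  if ("expressed" %in% names(genes))
    genes <- bp_track(genes[as.logical(genes$expressed), , drop = FALSE],
                      element_class = element_class(genes))
  gene_gr <- GenomicRanges::reduce(.track_gr(genes))
  inside <- rep(FALSE, nrow(track))
  if (nrow(track))
    inside <- IRanges::overlapsAny(.track_gr(track), gene_gr)
  list(
    inside = bp_track(track[inside, , drop = FALSE],
                      element_class = paste0(element_class(track), ".ingene")),
    outside = bp_track(track[!inside, , drop = FALSE],
                       element_class = paste0(element_class(track), ".outgene"))
  )
}

#' Construct a gene model track
#'
#' Gene bodies (TSS to TES) as a track with an optional per-gene
#' \code{expressed} flag; gene-context splits only consider genes with
#' expression evidence.
#'
#' @param chrom,start,end as in [bp_track()].
#' @param expressed logical vector (recycled); defaults to all expressed.
#' @return A \code{bp_track} of class \code{"gene"} with an
#'   \code{expressed} column.
#' @export
gene_model <- function(chrom, start, end, expressed = TRUE) {
  tr <- bp_track(chrom, start, end, element_class = "gene")
  tr$expressed <- rep_len(as.logical(expressed), nrow(tr))
  tr
}

#' Read / write BED interval files
#'
#' Minimal BED3(+name) dialect: tab-separated, no header, 0-based half-open
#' coordinates.  With a fourth column, \code{read_bed} can split a
#' multi-class file into one track per name.
#'
#' @param path file path.
#' @param element_class class label for a single-track file; ignored when
#'   \code{split_by_name = TRUE}.
#' @param split_by_name if \code{TRUE} and a 4th column exists, return a
#'   named list of tracks, one per distinct name.
#' @return A \code{bp_track}, or a named list of them.
#' @export
read_bed <- function(path, element_class = NULL, split_by_name = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name")[
                            seq_len(min(4, max(utils::count.fields(path, sep = "\t"))))],
                          fill = TRUE)
  if (split_by_name) {
    if (!"name" %in% names(df)) stop("no name column to split on")
    lapply(split(df, df$name), function(d)
      bp_track(d, element_class = d$name[1]))
  } else {
    if (is.null(element_class))
      element_class <- if ("name" %in% names(df)) df$name[1] else
        sub("\\.bed$", "", basename(path))
    bp_track(df, element_class = element_class)
  }
}

#' @rdname read_bed
#' @param track a [bp_track()] to write.
#' @param name logical; write the element class as a 4th column.
#' @export
write_bed <- function(track, path, name = TRUE) {
  df <- as.data.frame(track)[, c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  if (name) df$name <- element_class(track)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
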
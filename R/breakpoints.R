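#' Construct a breakpoint catalog
#'
#' Breakpoints are single-base positions (0-based) where one side of a
#' structural-variant junction maps; every SV contributes exactly two sides,
#' so a catalog row is one (sample, SV, side) triple.  A catalog may hold
#' one sample or a whole cohort.
#'
#' @param df data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{sv_id}, \code{side} and optionally
#'   \code{partner_chrom}, \code{partner_pos}.
#' @param check_pairing verify that every \code{sv_id} has exactly two sides
#'   (per sample) and fill \code{partner_chrom}/\code{partner_pos} from the
#'   pairing when absent.
#' @return A data.frame of class \code{"bp_catalog"}.
#' @seealso [tbpc()], [classify_sv_sides()], [read_breakpoints()]
#' @export
bp_catalog <- function(df, check_pairing = TRUE) {
  need <- c("sample_id", "chrom", "pos", "sv_id", "side")
  if (!all(need %in% names(df)))
    stop("breakpoint catalog needs columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$sv_id <- as.character(df$sv_id)
  df$side <- as.integer(df$side)
  if (nrow(df)) {
    if (any(is.na(df$pos)) || any(df$pos < 0))
      stop("coordinate error: breakpoint positions must be >= 0")
    if (!all(df$side %in% c(1L, 2L)))
      stop("structural error: side must be 1 or 2")
  }
  if (check_pairing && nrow(df)) {
    key <- paste(df$sample_id, df$sv_id, sep = "\r")
    tab <- table(key)
    if (any(tab != 2))
      stop("structural error: every sv_id must have exactly two sides; offending: ",
           paste(utils::head(sub("\r", "/", names(tab)[tab != 2]), 5),
                 collapse = ", "))
    sides <- split(seq_len(nrow(df)), key)
    if (any(vapply(sides, function(i) sum(df$side[i]) != 3L, logical(1))))
      stop("structural error: each sv_id needs one side 1 and one side 2")
    if (!all(c("partner_chrom", "partner_pos") %in% names(df))) {
      ord <- order(key, df$side)
      partner <- integer(nrow(df))
      partner[ord] <- ord[rep(seq(1, length(ord), 2), each = 2) +
                            rep(c(1, 0), length(ord) / 2)]
      df$partner_chrom <- df$chrom[partner]
      df$partner_pos <- df$pos[partner]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("bp_catalog", "data.frame"))
}

#' @export
print.bp_catalog <- function(x, ...) {
  cat(sprintf("<bp_catalog> %d breakpoint(s), %d sample(s)\n",
              nrow(x), length(unique(x$sample_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Total breakpoint count per sample
#'
#' @param catalog a [bp_catalog()] (one or several samples).
#' @return Named integer vector of per-sample total breakpoint counts
#'   (TBPc).
#' @export
tbpc <- function(catalog) {
  tab <- table(catalog$sample_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Split one sample's catalog list out of a cohort catalog
#' @param catalog a [bp_catalog()].
#' @return Named list of single-sample \code{bp_catalog}s.
#' @export
split_by_sample <- function(catalog) {
  lapply(split(as.data.frame(catalog), catalog$sample_id),
         bp_catalog, check_pairing = FALSE)
}

#' Count breakpoint sides on intra- vs inter-chromosomal SVs
#'
#' A breakpoint is intra-chromosomal when both sides of its SV map to the
#' same chromosome.  Counts are over breakpoint sides, so they sum to the
#' total breakpoint count.
#'
#' @param catalog a [bp_catalog()].
#' @return Named numeric vector \code{c(n_bpsv_intra=, n_bpsv_inter=)}.
#' @export
classify_sv_sides <- function(catalog) {
  if (!nrow(catalog))
    return(c(n_bpsv_intra = 0, n_bpsv_inter = 0))
  if (all(c("partner_chrom", "partner_pos") %in% names(catalog))) {
    intra <- catalog$chrom == catalog$partner_chrom
  } else {
    key <- paste(catalog$sample_id, catalog$sv_id, sep = "\r")
    nchrom <- vapply(split(catalog$chrom, key),
                     function(ch) length(unique(ch)), integer(1))
    if (any(table(key) != 2))
      stop("structural error: every sv_id must have exactly two sides")
    intra <- (nchrom == 1L)[key]
  }
  c(n_bpsv_intra = sum(intra), n_bpsv_inter = sum(!intra))
}

#' Count breakpoints falling in a track
#'
#' Membership is the half-open BED test \code{start <= pos < end} on the
#' merged track: a breakpoint exactly at an interval's \code{end} is
#' outside.  This is the \eqn{n_i} of the binomial model.
#'
#' @param catalog a [bp_catalog()] (one or several samples pooled).
#' @param track a [bp_track()] (merged internally).
#' @param genome a [bp_genome()]; breakpoints on chromosomes absent from
#'   the genome raise an error.
#' @return Number of breakpoints inside the track.
#' @export
count_breakpoints_in_track <- function(catalog, track, genome) {
  .check_chroms(catalog$chrom, genome, what = "breakpoint")
  track <- merge_track(track)
  if (!nrow(track) || !nrow(catalog)) return(0L)
  bp_gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$pos + 1, width = 1))
  sum(IRanges::overlapsAny(bp_gr, .track_gr(track)))
}

## per-sample in-track counts in one overlap pass (internal)
.count_bp_by_sample <- function(catalog, track, genome) {
  .check_chroms(catalog$chrom, genome, what = "breakpoint")
  track <- merge_track(track)
  samples <- sort(unique(catalog$sample_id))
  out <- stats::setNames(integer(length(samples)), samples)
  if (!nrow(track) || !nrow(catalog)) return(out)
  bp_gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$pos + 1, width = 1))
  hit <- IRanges::overlapsAny(bp_gr, .track_gr(track))
  tab <- tapply(hit, catalog$sample_id, sum)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Read / write breakpoint TSV files
#'
#' Tab-separated with header: \code{sample_id, chrom, pos, sv_id, side,
#' partner_chrom, partner_pos}; positions 0-based.
#'
#' @param path file path.
#' @return \code{read_breakpoints}: a [bp_catalog()].
#' @export
read_breakpoints <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  bp_catalog(df)
}

#' @rdname read_breakpoints
#' @param catalog a [bp_catalog()] to write.
#' @export
write_breakpoints <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write clinical survival tables
#'
#' Comma-separated with header: \code{sample_id, time_years, event,
#' treatment} (\code{treatment} in yes/no/NA; optional \code{endpoint}).
#'
#' @param path file path.
#' @return \code{read_clinical}: a data.frame with \code{sample_id},
#'   \code{time_years} (> 0), \code{event} (0/1), \code{treatment}.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_years", "event")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  if (any(df$time_years <= 0)) stop("follow-up times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (!"treatment" %in% names(df)) df$treatment <- NA_character_
  df
}

#' @rdname read_clinical
#' @param clinical data.frame to write.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
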
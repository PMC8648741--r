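#' Element-class membership of the instability indexes
#'
#' TRACe are element classes broken preferentially inside gene bodies
#' (transcription-associated chromosomal instability elements): R-loop
#' forming sequences, G-quadruplexes, CpG islands, cis-regulatory modules,
#' self-aligned self-chain segments and the DNase-hypersensitive site
#' classes.  RACINe are classes broken irrespective of gene context
#' (replication-associated): direct, short-tandem, mirror and inverted
#' repeats, Z-DNA, simple repeats, microsatellites and low-complexity DNA.
#'
#' @param include_dhs_rest keep the residual DHS class in TRACe (default
#'   \code{TRUE}); it can be excluded since it is the one DHS class not
#'   significantly broken on its own.
#' @return Character vector of element-class labels.
#' @export
trace_classes <- function(include_dhs_rest = TRUE) {
  cl <- c("RLFS", "GQ", "CpGi", "CRM", "SCS-S",
          "DHS_prom", "DHS_enh", "DHS_dyadic", "DHS_rest")
  if (!include_dhs_rest) cl <- setdiff(cl, "DHS_rest")
  cl
}

#' @rdname trace_classes
#' @export
racine_classes <- function() {
  c("DR", "STR", "MR", "IR", "Z", "SR", "MS", "LC")
}

#' Define an instability index by its member element classes
#'
#' @param name index label, e.g. \code{"iTRAC"} or \code{"iRACIN"}.
#' @param member_classes element-class labels pooled into the index.
#' @return list of class \code{"index_definition"}.
#' @export
index_definition <- function(name, member_classes) {
  if (!length(member_classes)) stop("an index needs at least one member class")
  structure(list(name = name, member_classes = unique(member_classes)),
            class = "index_definition")
}

#' @rdname index_definition
#' @param include_dhs_rest see [trace_classes()].
#' @export
itrac_definition <- function(include_dhs_rest = TRUE) {
  index_definition("iTRAC", trace_classes(include_dhs_rest))
}

#' @rdname index_definition
#' @export
iracin_definition <- function() {
  index_definition("iRACIN", racine_classes())
}

#' Pool member element tracks into a single index track
#'
#' Concatenates the member tracks, sorts and merges overlapping intervals,
#' yielding the single territory whose per-patient Hscore is the index
#' value.  The pooled cumulative length is at most the sum of the member
#' lengths.
#'
#' @param tracks named list of [bp_track()]s (names or element classes must
#'   cover the definition's members).
#' @param definition an [index_definition()].
#' @return A merged [bp_track()] labelled with the index name.
#' @export
build_index_track <- function(tracks, definition) {
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, element_class, character(1))
  missing <- setdiff(definition$member_classes, names(tracks))
  if (length(missing))
    stop("configuration error: member class(es) absent: ",
         paste(missing, collapse = ", "))
  pooled <- do.call(rbind, lapply(definition$member_classes, function(cl)
    as.data.frame(tracks[[cl]])[, c("chrom", "start", "end")]))
  merge_track(bp_track(pooled, element_class = definition$name))
}

#' Per-patient instability index values
#'
#' One Hscore per sample against the pooled index territory, each sample's
#' \eqn{P_u} using its own total breakpoint count (raw, unadjusted tail:
#' each index is a single test per patient).  Samples without breakpoints
#' are excluded with a warning.
#'
#' @param catalog a cohort [bp_catalog()].
#' @param index_track track from [build_index_track()].
#' @param genome a [bp_genome()].
#' @return data.frame \code{sample_id}, \code{index}, \code{value},
#'   \code{ni}, \code{tbpc}.
#' @export
patient_index_values <- function(catalog, index_track, genome) {
  index_track <- merge_track(index_track)
  counts <- tbpc(catalog)
  if (any(counts == 0)) {
    warning(sum(counts == 0), " sample(s) with no breakpoints excluded")
    counts <- counts[counts > 0]
  }
  Li <- cumulative_length(index_track)
  ni <- .count_bp_by_sample(catalog, index_track, genome)[names(counts)]
  value <- vapply(names(counts), function(s)
    log10_binomial_tail(ni[s], Li,
                        uniform_break_probability(counts[s], genome))$hscore,
    numeric(1))
  data.frame(sample_id = names(counts),
             index = element_class(index_track),
             value = unname(value), ni = unname(ni),
             tbpc = unname(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-patient iTRAC and iRACIN in one table
#'
#' Convenience wrapper: builds both index tracks from the per-class tracks
#' and returns one row per sample with both values.
#'
#' @param catalog a cohort [bp_catalog()].
#' @param tracks named list of element tracks covering both memberships.
#' @param genome a [bp_genome()].
#' @param include_dhs_rest see [trace_classes()].
#' @return data.frame \code{sample_id}, \code{itrac}, \code{iracin}.
#' @export
instability_indexes <- function(catalog, tracks, genome,
                                include_dhs_rest = TRUE) {
  it <- patient_index_values(
    catalog, build_index_track(tracks, itrac_definition(include_dhs_rest)),
    genome)
  ir <- patient_index_values(
    catalog, build_index_track(tracks, iracin_definition()), genome)
  df <- merge(it[, c("sample_id", "value")], ir[, c("sample_id", "value")],
              by = "sample_id", suffixes = c(".itrac", ".iracin"))
  names(df) <- c("sample_id", "itrac", "iracin")
  df
}
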
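#' Uniform per-base breakage probability
#'
#' Under the random breakage model every readable base is equally likely to
#' carry a breakpoint, so the per-base probability is \eqn{P_u = n / L}
#' where \eqn{n} is the total breakpoint count of the set under study
#' (cohort-wide or a single sample) and \eqn{L} the readable genome size.
#'
#' @param n_total total breakpoint count (>= 1).
#' @param genome a [bp_genome()].
#' @return \eqn{P_u}, capped at 1.
#' @examples
#' uniform_break_probability(300, bp_genome(c(c1 = 1e8)))
#' @export
uniform_break_probability <- function(n_total, genome) {
  if (n_total < 1)
    stop("n_total must be >= 1: the Hscore is undefined for empty catalogs")
  min(n_total / genome$readable_size, 1)
}

#' Binomial upper-tail probability and Hscore
#'
#' The number of breakpoints falling in a territory of \eqn{L_i} bp under
#' the random breakage model is \eqn{X \sim Binomial(L_i, P_u)}.  The
#' Hscore is \eqn{-\log_{10} P(X > n_i)} (strict inequality), computed on
#' the log scale via the regularized-incomplete-beta survival function so
#' scores of several hundred remain finite.  When the tail underflows to
#' exactly zero the score is flagged infinite.
#'
#' @param ni observed breakpoint count in the territory (0 <= ni <= Li).
#' @param Li territory size in bp.
#' @param Pu per-base breakage probability.
#' @return list with \code{p_tail}, \code{hscore} and \code{infinite}
#'   (logical flag; \code{hscore} is \code{Inf} when set).
#' @examples
#' log10_binomial_tail(2, 10, 0.05)
#' @export
log10_binomial_tail <- function(ni, Li, Pu) {
  if (ni < 0 || Li < 0 || ni > Li)
    stop("domain error: need 0 <= ni <= Li")
  if (Pu < 0 || Pu > 1) stop("domain error: Pu must be in [0, 1]")
  if (ni == Li) {                       # cannot exceed the number of trials
    return(list(p_tail = 0, hscore = Inf, infinite = TRUE))
  }
  log_p <- stats::pbinom(ni, size = Li, prob = Pu,
                         lower.tail = FALSE, log.p = TRUE)
  if (!is.finite(log_p)) {
    list(p_tail = 0, hscore = Inf, infinite = TRUE)
  } else {
    list(p_tail = exp(log_p), hscore = -log_p / log(10), infinite = FALSE)
  }
}

#' Hscore of a track for a breakpoint set
#'
#' Merges the track, counts breakpoints inside it (\eqn{n_i}), takes its
#' cumulative length (\eqn{L_i}) and evaluates the binomial tail under the
#' random breakage model.  \code{n_total} (the \eqn{n} of \eqn{P_u = n/L})
#' defaults to the number of breakpoints in \code{catalog}: pass the
#' cohort-wide total explicitly if \code{catalog} is a subset.
#'
#' @param catalog a [bp_catalog()] (cohort or single sample).
#' @param track a [bp_track()].
#' @param genome a [bp_genome()].
#' @param n_total total breakpoints defining \eqn{P_u}.
#' @return An object of class \code{"hscore"}: list with
#'   \code{element_class}, \code{ni}, \code{Li}, \code{Pu}, \code{p_tail},
#'   \code{hscore}, \code{infinite}, \code{adjusted} (always \code{FALSE}
#'   here; see [hscore_matrix()]).
#' @export
hscore <- function(catalog, track, genome, n_total = nrow(catalog)) {
  track <- merge_track(track)
  Li <- cumulative_length(track)
  ni <- count_breakpoints_in_track(catalog, track, genome)
  Pu <- uniform_break_probability(n_total, genome)
  tail <- log10_binomial_tail(ni, Li, Pu)
  structure(list(element_class = element_class(track),
                 ni = ni, Li = Li, Pu = Pu,
                 p_tail = tail$p_tail, hscore = tail$hscore,
                 infinite = tail$infinite, adjusted = FALSE),
            class = "hscore")
}

#' @export
print.hscore <- function(x, ...) {
  cat(sprintf(
    "Hscore [%s]: ni = %d, Li = %s bp, Pu = %.4g\n  P(X > ni) = %.4g  ->  Hscore = %s%s\n",
    x$element_class, x$ni, format(x$Li, big.mark = ","), x$Pu, x$p_tail,
    if (x$infinite) "Inf (tail underflow: P = 0)" else sprintf("%.3f", x$hscore),
    if (x$adjusted) " (Holm-adjusted)" else ""))
  invisible(x)
}

#' Per-sample x per-class Hscore matrix
#'
#' Computes one Hscore per sample and element class, each sample using its
#' own total breakpoint count for \eqn{P_u}.  With \code{adjust = "holm"}
#' the tail probabilities within each sample (family = all element classes)
#' undergo Holm step-down correction before taking \eqn{-\log_{10}};
#' adjusted scores are never larger than raw ones.
#'
#' @param catalog a cohort [bp_catalog()].
#' @param tracks named list of [bp_track()]s.
#' @param genome a [bp_genome()].
#' @param adjust \code{"none"} or \code{"holm"}.
#' @param cap finite value exported in place of infinite scores.
#' @param rescale a named numeric vector of per-sample multiplicative
#'   factors applied to the exported scores (presentation only, e.g. to tame
#'   outlier samples on a heatmap); default none.  Stored results are never
#'   rescaled.
#' @return numeric matrix samples x classes with attribute \code{"p_tail"}
#'   (matrix of the tail probabilities actually transformed).
#' @export
hscore_matrix <- function(catalog, tracks, genome,
                          adjust = c("none", "holm"), cap = 350,
                          rescale = NULL) {
  adjust <- match.arg(adjust)
  samples <- sort(unique(catalog$sample_id))
  if (!length(samples)) stop("empty cohort")
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, element_class, character(1))
  tracks <- lapply(tracks, merge_track)
  counts <- tbpc(catalog)[samples]
  if (any(counts == 0)) stop("sample(s) with no breakpoints")
  p <- matrix(NA_real_, length(samples), length(tracks),
              dimnames = list(samples, names(tracks)))
  for (cl in names(tracks)) {
    Li <- cumulative_length(tracks[[cl]])
    ni <- .count_bp_by_sample(catalog, tracks[[cl]], genome)[samples]
    p[, cl] <- vapply(samples, function(s)
      log10_binomial_tail(ni[s], Li,
                          uniform_break_probability(counts[s], genome))$p_tail,
      numeric(1))
  }
  if (adjust == "holm") {
    adj <- apply(p, 1, stats::p.adjust, method = "holm")
    p <- if (is.matrix(adj)) t(adj) else
      matrix(adj, ncol = 1, dimnames = dimnames(p))
  }
  h <- -log10(p)
  h[!is.finite(h)] <- cap
  if (!is.null(rescale)) {
    miss <- setdiff(names(rescale), samples)
    if (length(miss)) stop("rescale names unknown: ", paste(miss, collapse = ", "))
    h[names(rescale), ] <- h[names(rescale), , drop = FALSE] * rescale
  }
  attr(h, "p_tail") <- p
  attr(h, "adjust") <- adjust
  h
}

#' Hotspot / hot-region call from an Hscore and its flanking windows
#'
#' Classifies an element class from the Hscore of the elements themselves
#' (\code{center}) and of the immediately adjacent same-size windows
#' (offsets -1 and +1):
#' \itemize{
#' \item \emph{hotspot} when the center is significantly broken
#'   (Hscore >= 3) and both flanks are not (< 3);
#' \item \emph{hotspot} also when center and both flanks are >= 3 but the
#'   center is at least 1.5 times the larger flank;
#' \item \emph{hot region} when center and both flanks are >= 3 and the
#'   center is below 1.5 times the larger flank;
#' \item \emph{not significant} when the center is below 3.
#' }
#' The mixed case (center >= 3, exactly one flank >= 3) is not covered by
#' the two published rules; it is resolved by the 1.5-fold rule against the
#' larger flank and flagged via \code{mixed_flanks}.
#'
#' @param center,flank_minus,flank_plus Hscores (>= 0; \code{Inf} allowed).
#' @param h_min significance cutoff (default 3).
#' @param fold flank-dominance factor (default 1.5).
#' @return list with \code{verdict} (one of \code{"hotspot"},
#'   \code{"hot_region"}, \code{"not_significant"}), the three scores and
#'   \code{mixed_flanks}.
#' @export
classify_structure <- function(center, flank_minus, flank_plus,
                               h_min = 3, fold = 1.5) {
  hs <- c(center, flank_minus, flank_plus)
  if (any(is.na(hs)) || any(hs < 0)) stop("domain error: Hscores must be >= 0")
  fmax <- max(flank_minus, flank_plus)
  mixed <- (flank_minus >= h_min) != (flank_plus >= h_min)
  verdict <- if (center < h_min) {
    "not_significant"
  } else if (fmax < h_min) {
    "hotspot"
  } else if (is.infinite(center) && is.infinite(fmax)) {
    "hot_region"                       # indeterminate ratio: conservative
  } else if (center >= fold * fmax) {
    "hotspot"
  } else {
    "hot_region"
  }
  list(verdict = verdict, center = center,
       flank_minus = flank_minus, flank_plus = flank_plus,
       mixed_flanks = mixed)
}

#' Ratio of inside-gene to outside-gene Hscores
#'
#' \eqn{RHscore_{i/o} = H_{inside} / H_{outside}}: how much more
#' significantly an element class breaks inside gene bodies than outside.
#'
#' @param h_inside,h_outside Hscores of the inside-/outside-gene sub-tracks.
#' @return The ratio; \code{Inf} if only \code{h_inside} is infinite,
#'   \code{NaN} if both are.
#' @examples
#' rhscore_io(83.30, 6.41)
#' @export
rhscore_io <- function(h_inside, h_outside) {
  if (h_inside < 0 || h_outside < 0) stop("Hscores must be >= 0")
  if (h_outside == 0)
    stop("undefined ratio: outside-gene Hscore is 0")
  h_inside / h_outside
}

#' Export an Hscore results table
#'
#' @param results list of [hscore()] objects.
#' @param path TSV output path.
#' @return The table (invisibly written when \code{path} given): columns
#'   element_class, ni, Li, Pu, p_tail, hscore, adjusted, infinite.
#' @export
hscore_table <- function(results, path = NULL) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(element_class = r$element_class, ni = r$ni, Li = r$Li,
               Pu = r$Pu, p_tail = r$p_tail,
               hscore = r$hscore, adjusted = r$adjusted,
               infinite = r$infinite, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
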
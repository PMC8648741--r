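#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator.  Defaults
#' emulate the published study conditions at desk scale: a gap-free
#' 10 x 10 Mb genome; one interval track per element class of both index
#' memberships; per-sample total breakpoint counts drawn from a log-normal
#' calibrated to the reported cohort summary (median 181, mean about 222,
#' clipped to [26, 1200]); 67.4 percent of breakpoint sides on
#' intra-chromosomal SVs; and survival with group-wise exponential hazards
#' whose defaults produce the lambda-shaped risk (Medium group worst).
#'
#' @param n_samples cohort size.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param classes element classes to simulate tracks for.
#' @param n_elements,element_len_meanlog,element_len_sdlog per-class track
#'   spec: element count and log-normal length parameters (bp).
#' @param enrichment named per-class breakpoint enrichment factors
#'   (>= 0; 1 = random breakage); classes not named get 1.
#' @param tbpc_meanlog,tbpc_sdlog,tbpc_bounds log-normal parameters and
#'   clipping bounds of the per-sample total breakpoint count.
#' @param intra_sv_fraction fraction of SVs with both sides on one
#'   chromosome.
#' @param n_genes,gene_len_meanlog,gene_len_sdlog,expressed_fraction gene
#'   model spec.
#' @param hazards named per-group event hazards (per year).
#' @param censoring_rate fraction of samples censored (uniformly over
#'   their event time).
#' @param max_follow_years administrative censoring horizon.
#' @param treatment_prob named per-group probability of treatment.
#' @param seed integer seed recorded in the config and set by
#'   [simulate_cohort()].
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 100,
                       chrom_lengths = stats::setNames(rep(1e7, 10),
                                                       paste0("chr", 1:10)),
                       classes = c(trace_classes(), racine_classes()),
                       n_elements = 120,
                       element_len_meanlog = log(3000),
                       element_len_sdlog = 0.5,
                       enrichment = NULL,
                       tbpc_meanlog = log(181),
                       tbpc_sdlog = 0.64,
                       tbpc_bounds = c(26, 1200),
                       intra_sv_fraction = 0.674,
                       n_genes = 400,
                       gene_len_meanlog = log(30000),
                       gene_len_sdlog = 0.6,
                       expressed_fraction = 1,
                       hazards = c(Low = 0.05, Medium = 0.5, High = 0.05),
                       censoring_rate = 0.2,
                       max_follow_years = 15,
                       treatment_prob = c(Low = 0.2, Medium = 0.2,
                                          High = 0.2),
                       seed = NULL) {
  enr <- stats::setNames(rep(1, length(classes)), classes)
  if (!is.null(enrichment)) {
    unknown <- setdiff(names(enrichment), classes)
    if (length(unknown))
      stop("enrichment names unknown class(es): ",
           paste(unknown, collapse = ", "))
    if (any(enrichment < 0)) stop("enrichment factors must be >= 0")
    enr[names(enrichment)] <- enrichment
  }
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  structure(list(
    n_samples = n_samples, chrom_lengths = chrom_lengths, classes = classes,
    n_elements = n_elements, element_len_meanlog = element_len_meanlog,
    element_len_sdlog = element_len_sdlog, enrichment = enr,
    tbpc_meanlog = tbpc_meanlog, tbpc_sdlog = tbpc_sdlog,
    tbpc_bounds = tbpc_bounds, intra_sv_fraction = intra_sv_fraction,
    n_genes = n_genes, gene_len_meanlog = gene_len_meanlog,
    gene_len_sdlog = gene_len_sdlog, expressed_fraction = expressed_fraction,
    hazards = hazards, censoring_rate = censoring_rate,
    max_follow_years = max_follow_years, treatment_prob = treatment_prob,
    seed = seed), class = "sim_config")
}

## draw one set of non-overlapping intervals (overlaps merged away)
.sim_intervals <- function(n, chrom_lengths, meanlog, sdlog, class_label) {
  if (n == 0)
    return(bp_track(character(0), numeric(0), numeric(0),
                    element_class = class_label, merged = TRUE))
  len <- pmax(50, round(stats::rlnorm(n, meanlog, sdlog)))
  chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = chrom_lengths)
  maxstart <- chrom_lengths[chrom] - len
  if (any(maxstart < 0)) stop("element longer than its chromosome")
  start <- floor(stats::runif(n, 0, maxstart + 1))
  merge_track(bp_track(chrom, start, start + len,
                       element_class = class_label))
}

#' Simulate a genome, element tracks and a gene model
#'
#' @param config a [sim_config()].
#' @return list with \code{genome} ([bp_genome()]), \code{tracks} (named
#'   list of merged [bp_track()]s, one per class) and \code{genes}
#'   ([gene_model()] with the configured expressed fraction).
#' @export
simulate_genome_tracks <- function(config) {
  genome <- bp_genome(config$chrom_lengths)
  expected_mass <- length(config$classes) * config$n_elements *
    exp(config$element_len_meanlog + config$element_len_sdlog^2 / 2)
  if (expected_mass > 0.8 * sum(config$chrom_lengths))
    stop("requested track mass exceeds the genome")
  tracks <- lapply(config$classes, function(cl)
    .sim_intervals(config$n_elements, config$chrom_lengths,
                   config$element_len_meanlog, config$element_len_sdlog, cl))
  names(tracks) <- config$classes
  gt <- .sim_intervals(config$n_genes, config$chrom_lengths,
                       config$gene_len_meanlog, config$gene_len_sdlog, "gene")
  genes <- gene_model(gt$chrom, gt$start, gt$end,
                      expressed = stats::runif(nrow(gt)) <
                        config$expressed_fraction)
  list(genome = genome, tracks = tracks, genes = genes)
}

## Piecewise-constant sampling density: factor inside each enriched class's
## territory (factors multiply where territories overlap), 1 elsewhere.
## The geometry (disjoint pieces + which class covers which piece) depends
## only on the tracks, so it is computed once and reused across samples
## whose enrichment factors differ.
.density_geometry <- function(genome, tracks, classes) {
  base <- GenomicRanges::GRanges(
    seqnames = names(genome$chrom_lengths),
    ranges = IRanges::IRanges(start = 1,
                              end = as.numeric(genome$chrom_lengths)))
  grs <- lapply(classes, function(cl)
    GenomicRanges::reduce(.track_gr(merge_track(tracks[[cl]]))))
  pieces <- GenomicRanges::disjoin(do.call(c, c(list(base), grs)))
  hits <- vapply(grs, function(gr) IRanges::overlapsAny(pieces, gr),
                 logical(length(pieces)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = length(pieces))
  colnames(hits) <- classes
  list(segs = data.frame(
    chrom = as.character(GenomicRanges::seqnames(pieces)),
    start = GenomicRanges::start(pieces) - 1,
    end = as.numeric(GenomicRanges::end(pieces)),
    stringsAsFactors = FALSE),
    hits = hits)
}

.segments_with_factors <- function(geometry, enrichment) {
  fac <- rep(1, nrow(geometry$segs))
  for (cl in intersect(names(enrichment)[enrichment != 1],
                       colnames(geometry$hits)))
    fac[geometry$hits[, cl]] <- fac[geometry$hits[, cl]] * enrichment[cl]
  cbind(geometry$segs, factor = fac)
}

.density_segments <- function(genome, tracks, enrichment) {
  enriched <- names(enrichment)[enrichment != 1]
  geom <- .density_geometry(genome, tracks, enriched)
  .segments_with_factors(geom, enrichment)
}

.sample_positions <- function(segs, n, chrom_keep = NULL, chrom_drop = NULL) {
  if (!is.null(chrom_keep)) segs <- segs[segs$chrom %in% chrom_keep, ]
  if (!is.null(chrom_drop)) segs <- segs[!segs$chrom %in% chrom_drop, ]
  w <- (segs$end - segs$start) * segs$factor
  if (!nrow(segs) || sum(w) == 0)
    stop("no territory with positive density to sample from")
  i <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
  data.frame(chrom = segs$chrom[i],
             pos = floor(stats::runif(n, segs$start[i], segs$end[i])),
             stringsAsFactors = FALSE)
}

#' Simulate breakpoint catalogs for a cohort
#'
#' Per sample: the total breakpoint count is a rounded-to-even log-normal
#' draw clipped to the configured bounds; positions are drawn from the
#' piecewise-constant density (uniform under the random breakage model,
#' multiplied by each class's enrichment factor over its territory and
#' renormalized); consecutive breakpoints are paired into SVs, the second
#' side drawn on the same chromosome with the configured intra-SV
#' probability, otherwise on a different one.
#'
#' @param config a [sim_config()].
#' @param genome,tracks from [simulate_genome_tracks()].
#' @param enrichment optional per-class factor map overriding
#'   \code{config$enrichment} (e.g. per-sample factors); names must be
#'   simulated classes.
#' @param sample_ids sample names (default S001...).
#' @param tbpc optional vector of per-sample totals overriding the
#'   log-normal draw.
#' @return A cohort [bp_catalog()].
#' @export
simulate_cohort_breakpoints <- function(config, genome, tracks,
                                        enrichment = NULL,
                                        sample_ids = NULL, tbpc = NULL) {
  n <- config$n_samples
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(n))
  n <- length(sample_ids)
  if (is.null(tbpc)) {
    tbpc <- round(stats::rlnorm(n, config$tbpc_meanlog, config$tbpc_sdlog))
    tbpc <- pmin(pmax(tbpc, config$tbpc_bounds[1]), config$tbpc_bounds[2])
  }
  tbpc <- 2 * ceiling(tbpc / 2)          # sides come in pairs
  enr <- config$enrichment
  if (!is.null(enrichment)) {
    unknown <- setdiff(names(enrichment), names(enr))
    if (length(unknown))
      stop("enrichment names unknown class(es): ",
           paste(unknown, collapse = ", "))
    enr[names(enrichment)] <- enrichment
  }
  segs <- .density_segments(genome, tracks, enr)
  single_chrom <- length(genome$chrom_lengths) == 1
  out <- lapply(seq_len(n), function(s)
    .simulate_sample_bp(segs, sample_ids[s], tbpc[s] / 2,
                        config$intra_sv_fraction, single_chrom))
  bp_catalog(do.call(rbind, out), check_pairing = FALSE)
}

.simulate_sample_bp <- function(segs, sample_id, n_sv, intra_fraction,
                                single_chrom) {
  side1 <- .sample_positions(segs, n_sv)
  intra <- if (single_chrom) rep(TRUE, n_sv) else
    stats::runif(n_sv) < intra_fraction
  side2 <- side1
  for (chr in unique(side1$chrom)) {
    i_in <- which(intra & side1$chrom == chr)
    if (length(i_in))
      side2[i_in, ] <- .sample_positions(segs, length(i_in),
                                         chrom_keep = chr)
    i_out <- which(!intra & side1$chrom == chr)
    if (length(i_out))
      side2[i_out, ] <- .sample_positions(segs, length(i_out),
                                          chrom_drop = chr)
  }
  sv_id <- sprintf("%s_sv%05d", sample_id, seq_len(n_sv))
  data.frame(
    sample_id = sample_id,
    chrom = c(side1$chrom, side2$chrom),
    pos = c(side1$pos, side2$pos),
    sv_id = c(sv_id, sv_id),
    side = rep(1:2, each = n_sv),
    partner_chrom = c(side2$chrom, side1$chrom),
    partner_pos = c(side2$pos, side1$pos),
    stringsAsFactors = FALSE)
}

#' Simulate survival records for labelled samples
#'
#' Event times are exponential with the group's hazard; a configured
#' fraction of samples is censored uniformly over their event time; all
#' follow-up is administratively censored at the horizon.  Treatment flags
#' are drawn per group.
#'
#' @param groups factor/character of group labels named by sample id.
#' @param config a [sim_config()] (uses \code{hazards},
#'   \code{censoring_rate}, \code{max_follow_years},
#'   \code{treatment_prob}).
#' @return data.frame \code{sample_id}, \code{time_years}, \code{event},
#'   \code{treatment}, \code{group}.
#' @export
simulate_survival <- function(groups, config) {
  g <- as.character(groups)
  unknown <- setdiff(unique(g), names(config$hazards))
  if (length(unknown))
    stop("no hazard configured for group(s): ",
         paste(unknown, collapse = ", "))
  n <- length(g)
  t_event <- stats::rexp(n, rate = config$hazards[g])
  censored <- stats::runif(n) < config$censoring_rate
  time <- ifelse(censored, stats::runif(n, 0, t_event), t_event)
  event <- as.numeric(!censored)
  over <- time > config$max_follow_years
  time[over] <- config$max_follow_years
  event[over] <- 0
  tp <- config$treatment_prob[g]
  tp[is.na(tp)] <- 0
  treatment <- ifelse(stats::runif(n) < tp, "yes", "no")
  data.frame(sample_id = if (is.null(names(groups)))
    sprintf("S%03d", seq_len(n)) else names(groups),
    time_years = pmax(time, 1e-6), event = event,
    treatment = treatment, group = g, stringsAsFactors = FALSE)
}

#' Simulate a planted index-plus-survival cohort
#'
#' The desk-scale test bed for the iPART machinery alone: per-patient index
#' values drawn uniformly over a range, true groups assigned by fixed
#' thresholds, and survival drawn with group-wise hazards (defaults give
#' the lambda shape: the Medium group has a tenfold hazard).
#'
#' @param n cohort size.
#' @param thresholds true group thresholds on the value scale.
#' @param value_range range of the uniform index values.
#' @param config a [sim_config()] supplying hazards/censoring/treatment.
#' @return list with \code{values} (named vector), \code{survival}
#'   (data.frame) and \code{groups} (true labels).
#' @export
simulate_index_cohort <- function(n = 200, thresholds = c(1, 2),
                                  value_range = c(0, 3),
                                  config = sim_config()) {
  ids <- sprintf("P%03d", seq_len(n))
  values <- stats::setNames(
    stats::runif(n, value_range[1], value_range[2]), ids)
  groups <- .label_by_thresholds(values, thresholds,
                                 k = length(thresholds) + 1)
  names(groups) <- ids
  survival <- simulate_survival(groups, config)
  list(values = values, survival = survival, groups = groups)
}

#' Simulate a full cohort end-to-end
#'
#' Generates genome, tracks and genes; draws per-sample transcription- and
#' replication-associated enrichment factors (correlated log-normals,
#' reflecting that both instability axes grow with overall genomic
#' instability) applied to the TRACe and RACINe classes respectively, so
#' patients spread over iTRAC and iRACIN gradients; simulates breakpoints;
#' computes the per-patient indexes; assigns true groups from the iTRAC
#' value by \code{true_thresholds}; and simulates survival keyed to those
#' groups.  All stages honour \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @param itrac_factor_meanlog,itrac_factor_sdlog log-normal parameters of
#'   the per-sample TRACe enrichment factor.
#' @param racin_factor_meanlog,racin_factor_sdlog log-normal parameters of
#'   the per-sample RACINe enrichment factor.
#' @param index_correlation correlation of the two factors on the log
#'   scale.
#' @param true_thresholds thresholds on the resulting iTRAC value defining
#'   the survival groups; \code{NULL} uses the cohort terciles.
#' @return list with \code{genome}, \code{tracks}, \code{genes},
#'   \code{catalog}, \code{indexes} (sample_id/itrac/iracin),
#'   \code{true_groups}, \code{true_thresholds}, \code{clinical},
#'   \code{config}.
#' @export
simulate_cohort <- function(config = sim_config(),
                            itrac_factor_meanlog = log(4),
                            itrac_factor_sdlog = 0.8,
                            racin_factor_meanlog = log(3),
                            racin_factor_sdlog = 0.6,
                            index_correlation = 0.6,
                            true_thresholds = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  gt <- simulate_genome_tracks(config)
  ids <- sprintf("S%03d", seq_len(config$n_samples))
  z1 <- stats::rnorm(config$n_samples)
  z2 <- index_correlation * z1 +
    sqrt(1 - index_correlation^2) * stats::rnorm(config$n_samples)
  fac <- exp(itrac_factor_meanlog + itrac_factor_sdlog * z1)
  rfac <- exp(racin_factor_meanlog + racin_factor_sdlog * z2)
  trace_cl <- intersect(trace_classes(), config$classes)
  racine_cl <- intersect(racine_classes(), config$classes)
  geom <- .density_geometry(gt$genome, gt$tracks, c(trace_cl, racine_cl))
  single_chrom <- length(config$chrom_lengths) == 1
  tb <- round(stats::rlnorm(config$n_samples, config$tbpc_meanlog,
                            config$tbpc_sdlog))
  tb <- 2 * ceiling(pmin(pmax(tb, config$tbpc_bounds[1]),
                         config$tbpc_bounds[2]) / 2)
  cats <- lapply(seq_along(ids), function(s) {
    enr <- c(stats::setNames(rep(fac[s], length(trace_cl)), trace_cl),
             stats::setNames(rep(rfac[s], length(racine_cl)),
                             racine_cl))
    segs <- .segments_with_factors(geom, enr)
    .simulate_sample_bp(segs, ids[s], tb[s] / 2,
                        config$intra_sv_fraction, single_chrom)
  })
  catalog <- bp_catalog(do.call(rbind, lapply(cats, as.data.frame)),
                        check_pairing = FALSE)
  idx <- instability_indexes(catalog, gt$tracks, gt$genome)
  if (is.null(true_thresholds))
    true_thresholds <- unname(stats::quantile(idx$itrac, c(1/3, 2/3)))
  groups <- .label_by_thresholds(idx$itrac, true_thresholds, k = 3)
  names(groups) <- idx$sample_id
  clinical <- simulate_survival(groups, config)
  list(genome = gt$genome, tracks = gt$tracks, genes = gt$genes,
       catalog = catalog, indexes = idx, true_groups = groups,
       true_thresholds = true_thresholds, clinical = clinical,
       config = config)
}
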
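#' MAGIC risk call from iTRAC and iRACIN groups
#'
#' The mixed transcription- and replication-associated genomic instability
#' classifier: a patient is High risk if and only if either index places
#' them in its Medium group (the group with the worst outcome in the
#' lambda-shaped risk profile); everyone else is Low risk.
#'
#' @param itrac_group,iracin_group vectors of labels in
#'   \{Low, Medium, High\} (factors or characters); NA in either yields an
#'   NA risk with a warning.
#' @return factor in \{Low, High\} (vectorized).
#' @examples
#' magic_label("Medium", "Low")
#' @export
magic_label <- function(itrac_group, iracin_group) {
  it <- as.character(itrac_group)
  ir <- as.character(iracin_group)
  ok <- c("Low", "Medium", "High")
  bad <- stats::na.omit(setdiff(unique(c(it, ir)), ok))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  risk <- ifelse(it == "Medium" | ir == "Medium", "High", "Low")
  if (any(is.na(risk)))
    warning(sum(is.na(risk)), " sample(s) with a missing index group: NA risk")
  factor(risk, levels = c("Low", "High"))
}

#' MAGIC classification of a cohort from two iPART fits
#'
#' Combines the 3-group labels of an iTRAC and an iRACIN [ipart()] fit
#' into the MAGIC High/Low risk call.  Samples lacking either index are
#' excluded (their number is messaged).
#'
#' @param itrac_fit,iracin_fit [ipart()] fits (k = 3) or factors of labels
#'   named by sample id.
#' @return data.frame \code{sample_id}, \code{itrac_group},
#'   \code{iracin_group}, \code{magic_risk}.
#' @export
magic <- function(itrac_fit, iracin_fit) {
  lab <- function(x) if (inherits(x, "ipart")) x$labels else x
  it <- lab(itrac_fit)
  ir <- lab(iracin_fit)
  common <- intersect(names(it), names(ir))
  dropped <- length(union(names(it), names(ir))) - length(common)
  if (dropped > 0)
    message(dropped, " sample(s) lacking one index excluded from MAGIC")
  data.frame(sample_id = common,
             itrac_group = as.character(it[common]),
             iracin_group = as.character(ir[common]),
             magic_risk = magic_label(it[common], ir[common]),
             stringsAsFactors = FALSE)
}

#' Treatment contrast within each partition group
#'
#' Splits each group of a partition by treatment status and estimates,
#' within each group, the hazard of treated versus untreated patients
#' (Cox proportional hazards: HR, 95\% CI, Wald p) together with the
#' group-wise event counts.  Samples with missing treatment are excluded;
#' strata with fewer than 2 patients per arm or no events are flagged and
#' get no estimate.
#'
#' @param labels factor of group labels named by sample id (e.g. from an
#'   [ipart()] fit or [magic()]).
#' @param survival survival table with \code{sample_id}, \code{time} (or
#'   \code{time_years}), \code{event} and a \code{treatment} column
#'   (\code{"yes"}/\code{"no"}, NA allowed).
#' @return data.frame \code{group}, \code{n_treated}, \code{n_untreated},
#'   \code{events}, \code{hr}, \code{ci_low}, \code{ci_high},
#'   \code{wald_p}, \code{estimable}.
#' @export
treatment_stratified_survival <- function(labels, survival) {
  df <- .survival_df(survival)
  if (!"treatment" %in% names(df))
    stop("survival table needs a treatment column")
  df$group <- labels[df$sample_id]
  df <- df[!is.na(df$group) & df$treatment %in% c("yes", "no"), ]
  rows <- lapply(levels(factor(df$group)), function(g) {
    d <- df[df$group == g, ]
    nt <- sum(d$treatment == "yes")
    nu <- sum(d$treatment == "no")
    base <- data.frame(group = g, n_treated = nt, n_untreated = nu,
                       events = sum(d$event), hr = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       wald_p = NA_real_, estimable = FALSE,
                       stringsAsFactors = FALSE)
    if (nt < 2 || nu < 2 || sum(d$event) == 0) return(base)
    cx <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ treated,
                      data = transform(d, treated = treatment == "yes")),
      warning = function(w) suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ treated,
                        data = transform(d, treated = treatment == "yes"))),
      error = function(e) NULL)
    if (is.null(cx)) return(base)
    sm <- summary(cx)
    base$hr <- unname(sm$coefficients[1, "exp(coef)"])
    base$ci_low <- unname(sm$conf.int[1, "lower .95"])
    base$ci_high <- unname(sm$conf.int[1, "upper .95"])
    base$wald_p <- unname(sm$coefficients[1, "Pr(>|z|)"])
    base$estimable <- is.finite(base$hr)
    base
  })
  do.call(rbind, rows)
}

#' Published LMS / Pan-Cancer reference results
#'
#' Headline numbers reported for the original 112-patient leiomyosarcoma
#' WGS cohort and the TCGA Pan-Cancer reanalysis.  These required the
#' original datasets and are \emph{not} recomputable from synthetic data;
#' they are provided for context (e.g. annotating plots) only.
#'
#' @return Named list of reference values: iPART thresholds, stratification
#'   p-values, MAGIC medians, the low-iTRAC chemotherapy hazard ratio and
#'   the Pan-Cancer 5-group result.
#' @export
lms_reference <- function() {
  list(
    n_patients = 112,
    n_breakpoints = 24870,
    n_sv = 12435,
    pct_bpsv_intra = 67.4,
    readable_genome_bp = HG38_READABLE_BP,
    tbpc = list(min = 26, max = 1200, mean = 222.1, median = 181),
    itrac = list(tl = 0.99, th = 2.29, logrank_p = 3.08e-5),
    iracin = list(tl = 0.74, th = 1.30, logrank_p = 4.13e-5),
    magic = list(logrank_p = 8.75e-8,
                 median_mfs_high = 1.8, median_mfs_low = 10.5),
    chemo_low_itrac = list(hr = 4.47, ci = c(1.65, 12.08), p = 0.0032),
    pan_cancer = list(k = 5, logrank_p = 6.9e-10, max_hr = 4.75,
                      max_hr_p = 3.42e-9,
                      thresholds = c(0.14, 0.45, 0.67, 0.86))
  )
}
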
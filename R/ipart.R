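## ---- survival-data plumbing -------------------------------------------------

.survival_df <- function(survival) {
  df <- as.data.frame(survival)
  if ("time_years" %in% names(df) && !"time" %in% names(df))
    df$time <- df$time_years
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns sample_id, time (or time_years), event")
  if (any(df$time <= 0)) stop("follow-up times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df$sample_id <- as.character(df$sample_id)
  df[, intersect(c("sample_id", "time", "event", "treatment"), names(df))]
}

.values_df <- function(values) {
  if (is.data.frame(values)) {
    vcol <- intersect(c("value", "itrac", "iracin"), names(values))[1]
    if (is.na(vcol) || !"sample_id" %in% names(values))
      stop("values data.frame needs sample_id and a value column")
    data.frame(sample_id = as.character(values$sample_id),
               value = as.numeric(values[[vcol]]), stringsAsFactors = FALSE)
  } else {
    if (is.null(names(values))) stop("values vector must be named by sample_id")
    data.frame(sample_id = names(values), value = as.numeric(values),
               stringsAsFactors = FALSE)
  }
}

.join_values_survival <- function(values, survival) {
  v <- .values_df(values)
  s <- .survival_df(survival)
  df <- merge(v, s, by = "sample_id")
  if (!nrow(df)) stop("values and survival share no sample ids")
  if (any(is.na(df$value))) stop("NA index values")
  df[order(df$sample_id), ]
}

.group_names <- function(k) {
  if (k == 2) c("Low", "High")
  else if (k == 3) c("Low", "Medium", "High")
  else paste0("G.", seq_len(k))
}

## Label by thresholds: value <= t1 -> group 1, t1 < value <= t2 -> group 2, ...
.label_by_thresholds <- function(value, thresholds, k = length(thresholds) + 1) {
  idx <- findInterval(value, sort(thresholds), left.open = TRUE) + 1L
  factor(.group_names(k)[idx], levels = .group_names(k))
}

## ---- log-rank test ----------------------------------------------------------

#' Log-rank test p-value for a grouped survival sample
#'
#' Two-sided log-rank (score) test with k-1 degrees of freedom, computed
#' with [survival::survdiff()].
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (0/1).
#' @param group group labels (>= 2 non-empty groups).
#' @return p-value; exactly 1 (with a warning) when no events occurred.
#' @export
logrank_p <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need >= 2 non-empty groups")
  if (any(table(group) == 0)) stop("empty group")
  if (sum(event) == 0) {
    warning("no events: log-rank p set to 1")
    return(1)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data.frame(time = time, event = event,
                                             group = group))
  unname(stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE))
}

## Precomputed log-rank engine for the exhaustive threshold searches.
## The scan evaluates thousands of candidate groupings of the SAME survival
## data, so the risk-set bookkeeping (at-risk and death indicator matrices
## over the distinct death times) is computed once and each candidate costs
## two small matrix products.  The statistic is the standard k-group
## log-rank chi-square (identical to survival::survdiff's, which serves as
## the reference implementation in the tests).
.logrank_engine <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) return(NULL)
  M <- outer(dt, time, "<=")
  D <- outer(dt, time, "==") & rep(event == 1, each = length(dt))
  storage.mode(M) <- "double"
  storage.mode(D) <- "double"
  d <- rowSums(D)
  ntot <- rowSums(M)
  w <- d * (ntot - d) / pmax(ntot - 1, 1)
  function(z) {                      # z: n x k group indicator matrix
    k <- ncol(z)
    n1 <- M %*% z
    O <- colSums(D %*% z)
    P <- n1 / ntot
    E <- colSums(d * P)
    wP <- w * P
    V <- diag(colSums(wP), k) - crossprod(P, wP)
    x <- (O - E)[-1]
    chisq <- tryCatch(drop(crossprod(x, solve(V[-1, -1, drop = FALSE], x))),
                      error = function(e) NA_real_)
    if (is.na(chisq)) return(NA_real_)
    stats::pchisq(chisq, k - 1, lower.tail = FALSE)
  }
}

.group_indicator <- function(labels) {
  lv <- levels(labels)
  z <- matrix(0, length(labels), length(lv))
  z[cbind(seq_along(labels), as.integer(labels))] <- 1
  z
}

## ---- threshold scan ---------------------------------------------------------

#' Single-threshold log-rank scan of an index value
#'
#' Enumerates every binary split of the cohort that a threshold on the
#' value can produce.  Candidate thresholds are the midpoints between
#' consecutive distinct sorted values (a finite set covering all
#' label-distinct splits); candidates leaving either group below
#' \code{min_group_size} are excluded.  For each candidate the two-group
#' log-rank p-value is recorded.
#'
#' @param values named numeric vector or data.frame (\code{sample_id},
#'   \code{value}).
#' @param survival data.frame with \code{sample_id}, \code{time} (or
#'   \code{time_years}), \code{event}.
#' @param min_group_size smallest admissible group (default 5).
#' @return data.frame of class \code{"threshold_scan"} with columns
#'   \code{threshold}, \code{p}, \code{n_low}, \code{n_high}.
#' @export
threshold_scan <- function(values, survival, min_group_size = 5) {
  df <- .join_values_survival(values, survival)
  if (nrow(df) < 2 * min_group_size)
    stop("fewer than 2 * min_group_size samples")
  v <- sort(unique(df$value))
  if (length(v) < 2) stop("all index values identical: nothing to scan")
  cand <- (v[-1] + v[-length(v)]) / 2
  n_low <- vapply(cand, function(t) sum(df$value <= t), numeric(1))
  keep <- n_low >= min_group_size & (nrow(df) - n_low) >= min_group_size
  cand <- cand[keep]
  n_low <- n_low[keep]
  if (!length(cand))
    stop("no candidate threshold satisfies min_group_size")
  eng <- .logrank_engine(df$time, df$event)
  if (is.null(eng)) {
    warning("no events: all scan p-values are 1")
    p <- rep(1, length(cand))
  } else {
    p <- vapply(cand, function(t) {
      pp <- eng(cbind(df$value <= t, df$value > t))
      if (is.na(pp)) logrank_p(df$time, df$event, df$value <= t) else pp
    }, numeric(1))
  }
  structure(data.frame(threshold = cand, p = p,
                       n_low = n_low, n_high = nrow(df) - n_low),
            min_group_size = min_group_size, n = nrow(df),
            class = c("threshold_scan", "data.frame"))
}

#' Local minima of a threshold scan
#'
#' Thresholds whose p-value is lower than both neighbours' and below
#' \code{p_cap}.  A plateau of equal p-values bounded by larger neighbours
#' counts once, at its middle candidate; boundary candidates qualify
#' against their single neighbour.
#'
#' @param scan a [threshold_scan()].
#' @param p_cap only minima with p below this cap are kept (default 0.10;
#'   use a looser cap for weakly prognostic indexes).
#' @return Numeric vector of thresholds (possibly empty).
#' @export
local_minima <- function(scan, p_cap = 0.10) {
  p <- scan$p
  if (!length(p)) return(numeric(0))
  ## collapse plateaus: runs of equal consecutive p
  r <- rle(p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nruns <- length(r$values)
  is_min <- vapply(seq_len(nruns), function(i) {
    left_ok <- i == 1 || r$values[i] < r$values[i - 1]
    right_ok <- i == nruns || r$values[i] < r$values[i + 1]
    left_ok && right_ok
  }, logical(1))
  mid <- floor((starts + ends) / 2)
  th <- scan$threshold[mid[is_min & r$values < p_cap]]
  unname(th)
}

## ---- multi-threshold search -------------------------------------------------

#' Best k-group partition over candidate thresholds
#'
#' Evaluates every combination of k-1 candidate thresholds, labels the
#' cohort by them (value <= t1 is the lowest group), discards combinations
#' yielding a group below \code{min_group_size} and returns the combination
#' minimizing the k-group log-rank p-value.  Ties are broken towards the
#' more balanced partition (smaller spread of group sizes), then towards
#' smaller thresholds.
#'
#' @param values,survival,min_group_size as in [threshold_scan()].
#' @param k number of groups (>= 2).
#' @param candidates candidate thresholds (at least k-1 of them).
#' @return list with \code{k}, \code{thresholds}, \code{labels} (factor
#'   named by sample), \code{logrank_p}, \code{group_sizes}.
#' @export
best_partition <- function(values, survival, k, candidates,
                           min_group_size = 5) {
  if (k < 2) stop("k must be >= 2")
  candidates <- sort(unique(candidates))
  if (length(candidates) < k - 1)
    stop("need at least k-1 candidate thresholds (have ",
         length(candidates), ")")
  df <- .join_values_survival(values, survival)
  combos <- utils::combn(candidates, k - 1)
  eng <- .logrank_engine(df$time, df$event)
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    th <- combos[, j]
    lab <- .label_by_thresholds(df$value, th, k)
    sizes <- table(lab)
    if (any(sizes < min_group_size)) next
    p <- if (is.null(eng)) 1 else eng(.group_indicator(lab))
    if (is.na(p)) p <- logrank_p(df$time, df$event, lab)
    cand <- list(thresholds = th, labels = lab, p = p,
                 sizes = sizes, spread = stats::sd(as.numeric(sizes)))
    if (is.null(best) ||
        p < best$p ||
        (p == best$p && cand$spread < best$spread) ||
        (p == best$p && cand$spread == best$spread &&
         isTRUE(all(th <= best$thresholds)) && any(th < best$thresholds))) {
      best <- cand
    }
  }
  if (is.null(best))
    stop("no feasible combination of ", k - 1, " threshold(s) from ",
         length(candidates), " candidate(s) with groups >= ", min_group_size)
  list(k = k,
       thresholds = best$thresholds,
       labels = stats::setNames(best$labels, df$sample_id),
       logrank_p = best$p,
       group_sizes = best$sizes)
}

## ---- the fitted model -------------------------------------------------------

#' Fit an iPART survival partition
#'
#' Iterative multi-threshold partitioning: splits a cohort into k survival
#' groups by thresholds on a per-patient scalar (an instability index such
#' as iTRAC/iRACIN, or any prognostic value), choosing the thresholds that
#' minimize the k-group log-rank p-value.
#'
#' For \code{k = 2} the search is the full single-threshold scan.  For
#' \code{k >= 3} the candidate thresholds are the local minima of the
#' binary scan with p below \code{p_cap}, and every combination of k-1 of
#' them is evaluated (the search space of the double-threshold mode).
#' Pass \code{candidates} to override.
#'
#' The reported p-value is the minimum over the search and is therefore
#' optimistically biased as a test of association; use
#' [ipart_permutation_p()] for an honest permutation p-value.
#'
#' @param values named numeric vector, or data.frame with \code{sample_id}
#'   and a value column (\code{value}, \code{itrac} or \code{iracin}).
#' @param survival data.frame with \code{sample_id}, \code{time} (or
#'   \code{time_years}), \code{event}.
#' @param k number of groups (default 3: Low / Medium / High).
#' @param min_group_size smallest admissible group (default 5).
#' @param p_cap local-minima cap feeding the k >= 3 search (default 0.10).
#' @param candidates optional explicit candidate thresholds.
#' @return An object of class \code{"ipart"} with components \code{k},
#'   \code{thresholds}, \code{labels}, \code{logrank_p},
#'   \code{group_sizes}, \code{scan}, \code{data}, \code{call}.
#' @seealso [predict.ipart()], [plot.ipart()], [hazard_ratios()],
#'   [ipart_loocv()], [ipart_scan_k()]
#' @examples
#' set.seed(1)
#' sim <- simulate_index_cohort(n = 120)
#' fit <- ipart(sim$values, sim$survival)
#' fit
#' coef(fit)
#' @export
ipart <- function(values, survival, k = 3, min_group_size = 5,
                  p_cap = 0.10, candidates = NULL) {
  df <- .join_values_survival(values, survival)
  scan <- threshold_scan(df[, c("sample_id", "value")], df,
                         min_group_size = min_group_size)
  if (is.null(candidates)) {
    candidates <- if (k == 2) scan$threshold else local_minima(scan, p_cap)
    if (k > 2 && length(candidates) < k - 1)
      stop("only ", length(candidates), " local minima below p_cap = ", p_cap,
           "; need ", k - 1, " (loosen p_cap or pass candidates)")
  }
  bp <- best_partition(df[, c("sample_id", "value")], df, k = k,
                       candidates = candidates,
                       min_group_size = min_group_size)
  structure(list(k = k,
                 thresholds = bp$thresholds,
                 labels = bp$labels,
                 logrank_p = bp$logrank_p,
                 group_sizes = bp$group_sizes,
                 scan = scan,
                 candidates = candidates,
                 min_group_size = min_group_size,
                 p_cap = p_cap,
                 data = df,
                 call = match.call()),
            class = "ipart")
}

#' @export
print.ipart <- function(x, ...) {
  cat(sprintf("iPART partition: k = %d group(s), n = %d\n",
              x$k, nrow(x$data)))
  cat("  thresholds:", paste(format(x$thresholds, digits = 4),
                             collapse = ", "), "\n")
  sizes <- paste(sprintf("%s=%d", names(x$group_sizes),
                         as.integer(x$group_sizes)), collapse = ", ")
  cat("  group sizes:", sizes, "\n")
  cat(sprintf("  log-rank p = %.4g (minimized over the threshold search;\n", x$logrank_p))
  cat("  optimistically biased as a test -- see ipart_permutation_p)\n")
  invisible(x)
}

#' @export
coef.ipart <- function(object, ...) object$thresholds

#' Classify new samples by a fitted iPART partition
#'
#' @param object an [ipart()] fit.
#' @param newdata numeric vector of index values (optionally named); when
#'   missing, the training labels are returned.
#' @param ... unused.
#' @return Factor of group labels.
#' @export
predict.ipart <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  v <- if (is.data.frame(newdata)) .values_df(newdata)$value else
    as.numeric(newdata)
  lab <- .label_by_thresholds(v, object$thresholds, object$k)
  if (is.data.frame(newdata)) names(lab) <- .values_df(newdata)$sample_id
  else if (!is.null(names(newdata))) names(lab) <- names(newdata)
  lab
}

#' @export
summary.ipart <- function(object, ...) {
  hr <- tryCatch(hazard_ratios(object), error = function(e) NULL)
  med <- group_km_medians(object$labels, object$data)
  out <- list(fit = object, hazard_ratios = hr, km_medians = med)
  class(out) <- "summary.ipart"
  out
}

#' @export
print.summary.ipart <- function(x, ...) {
  print(x$fit)
  cat("\nKaplan-Meier median survival by group:\n")
  print(x$km_medians)
  if (!is.null(x$hazard_ratios)) {
    cat("\nHazard ratios vs", levels(x$fit$labels)[1], "(Cox PH):\n")
    print(x$hazard_ratios, row.names = FALSE)
  }
  invisible(x)
}

#' Kaplan-Meier curves of an iPART partition
#'
#' @param x an [ipart()] fit.
#' @param ... passed to [graphics::plot()] via \code{plot.survfit}.
#' @export
plot.ipart <- function(x, ...) {
  df <- x$data
  df$group <- x$labels[df$sample_id]
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  graphics::plot(fit, col = seq_len(x$k), xlab = "years",
                 ylab = "survival probability", mark.time = TRUE, ...)
  graphics::legend("bottomleft", legend = levels(x$labels),
                   col = seq_len(x$k), lty = 1, bty = "n")
  invisible(x)
}

#' Kaplan-Meier median survival per group
#'
#' @param labels factor of group labels named by sample id.
#' @param survival survival table (see [ipart()]).
#' @return Named numeric vector of KM median survival times (NA when the
#'   curve never crosses 0.5).
#' @export
group_km_medians <- function(labels, survival) {
  df <- .survival_df(survival)
  df$group <- labels[df$sample_id]
  df <- df[!is.na(df$group), ]
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, length(tab),
                                       dimnames = list("group", names(tab)))
  med <- tab[, "median"]
  names(med) <- sub("^group=", "", rownames(tab))
  med
}

## ---- hazard ratios ----------------------------------------------------------

#' Hazard ratios of partition groups against a reference group
#'
#' Cox proportional-hazards fit with group indicators; one hazard ratio
#' with 95\% confidence interval and Wald p per non-reference group.
#' Groups without events get an unbounded interval and are flagged.
#'
#' @param fit an [ipart()] object, or a factor of labels named by sample.
#' @param survival needed only when \code{fit} is a label factor.
#' @param reference reference group (default the first level).
#' @return data.frame \code{group}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{wald_p}, \code{n}, \code{events},
#'   \code{infinite_ci}.
#' @export
hazard_ratios <- function(fit, survival = NULL, reference = NULL) {
  if (inherits(fit, "ipart")) {
    labels <- fit$labels
    df <- fit$data
  } else {
    labels <- fit
    if (is.null(survival)) stop("survival table required with raw labels")
    df <- .survival_df(survival)
  }
  df$group <- factor(labels[df$sample_id])
  df <- droplevels(df[!is.na(df$group), ])
  if (!is.null(reference)) df$group <- stats::relevel(df$group, reference)
  ref <- levels(df$group)[1]
  if (sum(df$event[df$group == ref]) == 0)
    warning("reference group has no events; hazard ratios unstable")
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(cx)
  groups <- sub("^group", "", rownames(sm$coefficients))
  ev <- tapply(df$event, df$group, sum)
  n <- table(df$group)
  out <- data.frame(
    group = groups,
    hr = unname(sm$coefficients[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, "lower .95"]),
    ci_high = unname(sm$conf.int[, "upper .95"]),
    wald_p = unname(sm$coefficients[, "Pr(>|z|)"]),
    n = as.integer(n[groups]),
    events = as.integer(ev[groups]),
    stringsAsFactors = FALSE
  )
  out$infinite_ci <- out$events == 0 | !is.finite(out$ci_high) |
    out$ci_high > 1e6
  attr(out, "reference") <- ref
  out
}

## ---- model selection across k ----------------------------------------------

#' Fit iPART partitions for a range of group counts
#'
#' Fits k = 2..k_max partitions and reports, for each k, the minimized
#' log-rank p and the largest hazard ratio against the lowest group.  No
#' automatic winner is declared; inspect the table (or take the argmin p
#' yourself).
#'
#' @param values,survival,min_group_size,p_cap as in [ipart()].
#' @param k_max largest group count (default 8).
#' @return data.frame \code{k}, \code{logrank_p}, \code{max_hr},
#'   \code{feasible}; attribute \code{"fits"} holds the ipart objects.
#' @export
ipart_scan_k <- function(values, survival, k_max = 8, min_group_size = 5,
                         p_cap = 0.10) {
  fits <- vector("list", k_max - 1)
  rows <- lapply(2:k_max, function(k) {
    f <- tryCatch(ipart(values, survival, k = k,
                        min_group_size = min_group_size, p_cap = p_cap),
                  error = function(e) NULL)
    fits[[k - 1]] <<- f
    if (is.null(f))
      return(data.frame(k = k, logrank_p = NA_real_, max_hr = NA_real_,
                        feasible = FALSE))
    hr <- tryCatch(hazard_ratios(f), error = function(e) NULL)
    data.frame(k = k, logrank_p = f$logrank_p,
               max_hr = if (is.null(hr)) NA_real_ else max(hr$hr),
               feasible = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

## ---- honest p by permutation ------------------------------------------------

#' Permutation p-value for an iPART partition
#'
#' The p-value an iPART fit reports is minimized over the threshold search
#' and overstates significance.  This re-runs the identical search on
#' cohorts whose (time, event) rows are randomly permuted against the
#' values and returns the fraction of permutations achieving a minimized
#' p at most as small as the observed one (add-one estimator).
#'
#' @param fit an [ipart()] object.
#' @param n_perm number of permutations (default 200).
#' @return list with \code{p_perm}, \code{n_perm}, \code{p_observed}.
#' @export
ipart_permutation_p <- function(fit, n_perm = 200) {
  df <- fit$data
  hits <- 0L
  done <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nrow(df))
    perm <- df
    perm$time <- df$time[idx]
    perm$event <- df$event[idx]
    pb <- tryCatch(
      ipart(df[, c("sample_id", "value")], perm, k = fit$k,
            min_group_size = fit$min_group_size,
            p_cap = fit$p_cap)$logrank_p,
      error = function(e) NA_real_)
    if (!is.na(pb)) {
      done <- done + 1L
      if (pb <= fit$logrank_p) hits <- hits + 1L
    }
  }
  list(p_perm = (hits + 1) / (done + 1), n_perm = done,
       p_observed = fit$logrank_p)
}

## ---- leave-one-out cross-validation ----------------------------------------

#' Leave-one-out cross-validation of iPART classification
#'
#' For each sample in turn: refit the full iPART search on the remaining
#' n-1 samples and classify the held-out sample by the resulting
#' thresholds.  Folds where the search is infeasible yield NA labels.
#'
#' @param values,survival,k,min_group_size,p_cap as in [ipart()].
#' @return data.frame \code{sample_id}, \code{label_full},
#'   \code{label_heldout}; attributes \code{"logrank_p_heldout"} (log-rank
#'   p of the held-out labelling) and \code{"agreement"} (fraction of
#'   non-NA held-out labels equal to the full-fit labels).
#' @export
ipart_loocv <- function(values, survival, k = 3, min_group_size = 5,
                        p_cap = 0.10) {
  df <- .join_values_survival(values, survival)
  full <- ipart(df[, c("sample_id", "value")], df, k = k,
                min_group_size = min_group_size, p_cap = p_cap)
  held <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    rest <- df[-i, ]
    f <- tryCatch(
      ipart(rest[, c("sample_id", "value")], rest, k = k,
            min_group_size = min_group_size, p_cap = p_cap),
      error = function(e) NULL)
    if (!is.null(f))
      held[i] <- as.character(predict(f, df$value[i]))
  }
  out <- data.frame(sample_id = df$sample_id,
                    label_full = as.character(full$labels[df$sample_id]),
                    label_heldout = held, stringsAsFactors = FALSE)
  ok <- !is.na(out$label_heldout)
  attr(out, "agreement") <- mean(out$label_full[ok] == out$label_heldout[ok])
  attr(out, "n_failed_folds") <- sum(!ok)
  attr(out, "logrank_p_heldout") <- if (length(unique(held[ok])) >= 2)
    logrank_p(df$time[ok], df$event[ok], held[ok]) else NA_real_
  out
}
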
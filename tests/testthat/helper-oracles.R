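## Independent oracles used to cross-check the implementation.  These are
## deliberately naive (direct summation, bitmaps, per-pair scans,
## permutation) and never call the package routines they verify.

## Binomial upper tail by direct pmf summation (log-sum-exp for stability).
oracle_log10_tail <- function(ni, Li, Pu) {
  if (ni >= Li) return(list(p = 0, hscore = Inf))
  lp <- stats::dbinom((ni + 1):Li, Li, Pu, log = TRUE)
  m <- max(lp)
  if (!is.finite(m)) return(list(p = 0, hscore = Inf))
  ls <- m + log(sum(exp(lp - m)))
  list(p = exp(ls), hscore = -ls / log(10))
}

## Per-breakpoint x per-interval linear scan (half-open membership).
oracle_count_in_track <- function(pos, chrom, track) {
  n <- 0L
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(track))) {
      if (chrom[i] == track$chrom[j] &&
          pos[i] >= track$start[j] && pos[i] < track$end[j]) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

## Base-set (bitmap) union length on a small genome.
oracle_union_length <- function(tracks, chrom_lengths) {
  total <- 0
  for (chr in names(chrom_lengths)) {
    bits <- logical(chrom_lengths[[chr]])
    for (tr in tracks) {
      d <- as.data.frame(tr)
      d <- d[d$chrom == chr, , drop = FALSE]
      for (j in seq_len(nrow(d)))
        bits[(d$start[j] + 1):d$end[j]] <- TRUE
    }
    total <- total + sum(bits)
  }
  total
}

## Textbook k-group log-rank statistic from the counting-process formulas.
oracle_logrank <- function(time, event, group) {
  group <- factor(group)
  k <- nlevels(group)
  dt <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in dt) {
    at <- time >= t
    n <- sum(at)
    d <- sum(event == 1 & time == t)
    nj <- tapply(at, group, sum)
    nj[is.na(nj)] <- 0
    dj <- tapply(event == 1 & time == t, group, sum)
    dj[is.na(dj)] <- 0
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1)
      for (a in 1:k) for (b in 1:k)
        V[a, b] <- V[a, b] + d * ((n - d) / (n - 1)) *
          ((a == b) * nj[a] / n - nj[a] * nj[b] / n^2)
  }
  x <- (O - E)[-1]
  chisq <- drop(t(x) %*% solve(V[-1, -1]) %*% x)
  list(chisq = chisq,
       p = stats::pchisq(chisq, k - 1, lower.tail = FALSE))
}

## Monte-Carlo permutation p for the log-rank statistic.
oracle_permutation_logrank_p <- function(time, event, group, n_perm) {
  obs <- oracle_logrank(time, event, group)$chisq
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(group)
    if (oracle_logrank(time, event, perm)$chisq >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / n_perm
}

## Small uniform breakpoint catalog on one chromosome.
make_uniform_catalog <- function(n_bp, glen, sample_id = "S1",
                                 chrom = "c1") {
  n_bp <- 2 * ceiling(n_bp / 2)
  bp_catalog(data.frame(
    sample_id = sample_id, chrom = chrom,
    pos = floor(stats::runif(n_bp, 0, glen)),
    sv_id = rep(sprintf("%s_sv%d", sample_id, seq_len(n_bp / 2)), each = 2),
    side = rep(1:2, n_bp / 2), stringsAsFactors = FALSE))
}

## Catalog with a fixed number of breakpoints planted inside a territory.
make_enriched_catalog <- function(n_bp, glen, segs_factor_track, factor,
                                  sample_id = "S1", chrom = "c1") {
  ## piecewise-constant density: factor inside the (merged) track, 1 outside
  tr <- merge_track(segs_factor_track)
  w_in <- sum(tr$end - tr$start)
  p_in <- factor * w_in / (factor * w_in + (glen - w_in))
  n_bp <- 2 * ceiling(n_bp / 2)
  inside <- stats::runif(n_bp) < p_in
  pos <- numeric(n_bp)
  if (any(inside)) {
    j <- sample.int(nrow(tr), sum(inside), replace = TRUE,
                    prob = tr$end - tr$start)
    pos[inside] <- floor(stats::runif(sum(inside), tr$start[j], tr$end[j]))
  }
  if (any(!inside)) {
    ## rejection-sample the complement
    k <- sum(!inside)
    out <- numeric(0)
    while (length(out) < k) {
      cand <- floor(stats::runif(2 * k, 0, glen))
      ok <- !vapply(cand, function(x)
        any(x >= tr$start & x < tr$end), logical(1))
      out <- c(out, cand[ok])
    }
    pos[!inside] <- out[seq_len(k)]
  }
  bp_catalog(data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos,
    sv_id = rep(sprintf("%s_sv%d", sample_id, seq_len(n_bp / 2)), each = 2),
    side = rep(1:2, n_bp / 2), stringsAsFactors = FALSE))
}
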
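#' Expected heterozygosity from allele frequencies
#'
#' `H = 1 - sum(p_i^2)` over the allele frequencies at a biallelic site.
#' A single frequency is interpreted as the alternate-allele frequency
#' `p`, giving `H = 1 - p^2 - (1 - p)^2`.
#'
#' @param freqs Either the two allele frequencies (summing to 1) or a
#'   single alternate-allele frequency; vectorised over sites when given
#'   a single numeric vector of alternate frequencies.
#' @return Heterozygosity value(s) in `[0, 0.5]`.
#' @examples
#' heterozygosity(c(0.8, 0.2))  # 0.32
#' heterozygosity(0.5)          # 0.5
#' @export
heterozygosity <- function(freqs) {
  if (is.matrix(freqs)) return(1 - rowSums(freqs^2))
  if (length(freqs) == 2L && abs(sum(freqs) - 1) < 1e-8) {
    return(1 - sum(freqs^2))
  }
  1 - freqs^2 - (1 - freqs)^2
}

#' Pairwise pooled FST between two pools
#'
#' `FST = 1 - Hs/Ht`, where `Hs` is the mean heterozygosity of the two
#' compared pools and `Ht` the heterozygosity of the mean alternate-allele
#' frequency taken across the reference pools (by default exactly the two
#' compared pools). Sites where `Ht = 0` (no variation anywhere) are
#' undefined and returned as `NA`. Negative values (`Hs > Ht`) are
#' reported as-is unless `clamp = TRUE`.
#'
#' @param freq_a,freq_b Alternate-allele frequencies of the two compared
#'   pools (vectorised over sites).
#' @param reference_freqs List of alternate-frequency vectors for the
#'   pools over which total heterozygosity is computed; default
#'   `list(freq_a, freq_b)`.
#' @param clamp Floor negative estimates at 0?
#' @return Numeric FST per site (`<= 1`, `NA` where undefined).
#' @examples
#' pairwise_fst(1, 0)        # fixed difference: 1
#' pairwise_fst(0.3, 0.3)    # no differentiation: 0
#' pairwise_fst(0.9, 0.1)    # 0.64
#' @export
pairwise_fst <- function(freq_a, freq_b,
                         reference_freqs = list(freq_a, freq_b),
                         clamp = FALSE) {
  if (!length(reference_freqs)) abort("`reference_freqs` must be non-empty.")
  rng_ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!rng_ok(freq_a) || !rng_ok(freq_b)) abort("frequencies must be in [0, 1].")
  hs <- (heterozygosity(freq_a) + heterozygosity(freq_b)) / 2
  pbar <- Reduce(`+`, reference_freqs) / length(reference_freqs)
  ht <- heterozygosity(pbar)
  fst <- ifelse(ht == 0, NA_real_, 1 - hs / ht)
  if (clamp) fst <- pmax(fst, 0)
  fst
}

#' Per-site FST scan over a pool site table
#'
#' Filters sites (minimum depth in every involved pool), computes the
#' per-site pooled FST between two pools, and fits a cubic smoothing
#' spline along each chromosome.
#'
#' @param sites A pool site table (tibble with `chrom`, `pos` and
#'   `af_<pool>` / `dp_<pool>` columns, as produced by
#'   [simulate_pooled_freqs()] or [read_variants()]).
#' @param pool_a,pool_b Names of the compared pools.
#' @param ref_pools Pool names over which total heterozygosity is taken;
#'   default `c(pool_a, pool_b)`.
#' @param min_depth Minimum depth per involved pool for a site to enter
#'   the scan.
#' @param stiffness Smoothing-spline penalty `lambda` passed to
#'   [smooth_track()].
#' @param clamp Floor negative FST at 0?
#' @return An `fst_track` tibble: `chrom`, `pos`, `raw_fst`,
#'   `smoothed_fst`.
#' @examples
#' tab <- tibble::tibble(chrom = "X", pos = seq(1e5, 2e6, by = 1e4),
#'                       af_a = rep(c(0, 1), length.out = 191), dp_a = 100,
#'                       af_b = 0, dp_b = 100)
#' fst_scan(tab, "a", "b")
#' @export
fst_scan <- function(sites, pool_a, pool_b, ref_pools = c(pool_a, pool_b),
                     min_depth = 10, stiffness = 1e-6, clamp = FALSE) {
  for (p in unique(c(pool_a, pool_b, ref_pools))) {
    if (!paste0("af_", p) %in% names(sites)) {
      abort(sprintf("pool '%s' not found in site table.", p))
    }
  }
  keep <- rep(TRUE, nrow(sites))
  for (p in unique(c(pool_a, pool_b, ref_pools))) {
    dp <- sites[[paste0("dp_", p)]]
    if (!is.null(dp)) keep <- keep & dp >= min_depth
  }
  x <- sites[keep, , drop = FALSE]
  refs <- lapply(ref_pools, function(p) x[[paste0("af_", p)]])
  track <- tibble(
    chrom = x$chrom, pos = x$pos,
    raw_fst = pairwise_fst(x[[paste0("af_", pool_a)]],
                           x[[paste0("af_", pool_b)]],
                           refs, clamp = clamp)
  )
  track <- track[!is.na(track$raw_fst), , drop = FALSE]
  track <- arrange(track, .data$chrom, .data$pos)
  out <- smooth_track(track, stiffness = stiffness)
  class(out) <- c("fst_track", class(out))
  out
}

#' Smooth an FST track with a cubic smoothing spline
#'
#' A penalised cubic smoothing spline (penalty `lambda = stiffness`) is
#' fitted per chromosome over site positions and evaluated at each site.
#' Constant stretches are preserved (a spline through a constant is that
#' constant); as `stiffness` grows the fit tends to the least-squares
#' line. Chromosomes with fewer than four distinct sites keep their raw
#' values and are flagged with a warning.
#'
#' @param track Tibble with `chrom`, `pos` and `raw_fst` columns.
#' @param stiffness Spline roughness penalty (`lambda` of
#'   [stats::smooth.spline()]).
#' @return The track with a `smoothed_fst` column added.
#' @export
smooth_track <- function(track, stiffness = 1e-6) {
  sm <- numeric(nrow(track))
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    xs <- track$pos[idx]; ys <- track$raw_fst[idx]
    if (length(unique(xs)) < 4L) {
      warn(sprintf("chromosome '%s' has < 4 sites; smoothing skipped.", chr))
      sm[idx] <- ys
      next
    }
    fit <- smooth.spline(xs, ys, lambda = stiffness)
    sm[idx] <- predict(fit, xs)$y
  }
  track$smoothed_fst <- sm
  track
}

#' Call high-FST segments from a smoothed track
#'
#' Maximal runs of consecutive sites with `smoothed_fst >= threshold` are
#' taken per chromosome, runs separated by less than `max_gap` bp are
#' merged, and segments spanning less than `min_span` bp are discarded.
#'
#' @param track An `fst_track` with smoothed values (see [fst_scan()]).
#' @param threshold Minimum smoothed FST (default 0.8).
#' @param max_gap Merge runs separated by less than this many bp.
#' @param min_span Discard segments shorter than this many bp.
#' @return A tibble of segments: `chrom`, `start`, `end` (1-based
#'   inclusive site positions), `mean_smoothed_fst`, `n_sites`; sorted and
#'   non-overlapping.
#' @export
call_segments <- function(track, threshold = 0.8, max_gap = 100e3,
                          min_span = 200e3) {
  if (!"smoothed_fst" %in% names(track)) {
    abort("track has no `smoothed_fst` column; run fst_scan()/smooth_track().")
  }
  track <- arrange(track, .data$chrom, .data$pos)
  segs <- list()
  for (chr in unique(track$chrom)) {
    t0 <- track[track$chrom == chr, , drop = FALSE]
    hi <- t0$smoothed_fst >= threshold
    if (!any(hi)) next
    r <- rle(hi)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- tibble(start = t0$pos[starts_i[r$values]],
                   end = t0$pos[ends_i[r$values]],
                   i0 = starts_i[r$values], i1 = ends_i[r$values])
    # merge runs with small gaps
    merged <- list(runs[1, ])
    for (k in seq_len(nrow(runs))[-1]) {
      last <- merged[[length(merged)]]
      if (runs$start[k] - last$end < max_gap) {
        last$end <- runs$end[k]; last$i1 <- runs$i1[k]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- runs[k, ]
      }
    }
    m <- bind_rows(merged)
    m <- m[m$end - m$start + 1 >= min_span, , drop = FALSE]
    if (!nrow(m)) next
    m$chrom <- chr
    m$mean_smoothed_fst <- vapply(seq_len(nrow(m)), function(k) {
      mean(t0$smoothed_fst[m$i0[k]:m$i1[k]])
    }, numeric(1))
    m$n_sites <- vapply(seq_len(nrow(m)), function(k) {
      sum(t0$pos >= m$start[k] & t0$pos <= m$end[k])
    }, numeric(1))
    segs[[chr]] <- select(m, "chrom", "start", "end",
                          "mean_smoothed_fst", "n_sites")
  }
  if (!length(segs)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  mean_smoothed_fst = numeric(), n_sites = numeric()))
  }
  arrange(bind_rows(segs), .data$chrom, .data$start)
}
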
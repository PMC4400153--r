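#' Simulate pooled-sequencing allele frequencies for one or more strains
#'
#' The true alternate-allele frequency of a pool at a site is the mean of
#' the origin-conditional frequencies (`f_alt_M` / `f_alt_S` in the
#' [marker_panel()]) over all chromosome copies carried by the pool
#' members (two X copies per female, one per male). The observed
#' frequency adds pooled-sequencing noise: a binomial draw of `depth`
#' reads, then rounding to the nearest multiple of `1/ploidy_grid` --
#' mirroring variant callers run at an expected pool ploidy (grid 20
#' corresponds to frequencies in increments of 5%).
#'
#' @param strains A single strain (list of individuals) or a named list of
#'   strains, e.g. `list(RbMM = ..., RbSS = ...)`.
#' @param panel A [marker_panel()].
#' @param depth Sequencing depth per site (reads).
#' @param ploidy_grid Number of frequency increments (`>= 2`); observed
#'   frequencies are multiples of `1/ploidy_grid`.
#' @return A pool site table: tibble with `chrom`, `pos`, `ref`, `alt` and,
#'   per pool, `af_<pool>` and `dp_<pool>` columns.
#' @examples
#' \donttest{
#' sim <- run_introgression_design(design_config(seed = 1))
#' pools <- simulate_pooled_freqs(list(RbMM = sim$rbmm, RbSS = sim$rbss),
#'                                sim$panel)
#' }
#' @export
simulate_pooled_freqs <- function(strains, panel, depth = 200,
                                  ploidy_grid = 20) {
  if (depth <= 0) abort("`depth` must be > 0.")
  if (ploidy_grid < 2) abort("`ploidy_grid` must be >= 2.")
  if (inherits(strains, "mosquito")) strains <- list(strains)
  if (!length(strains)) abort("empty strain.")
  if (inherits(strains[[1]], "mosquito")) strains <- list(pool = strains)
  if (is.null(names(strains))) {
    names(strains) <- paste0("pool", seq_along(strains))
  }

  out <- tibble(chrom = panel$chrom, pos = panel$pos,
                ref = panel$ref, alt = panel$alt)
  for (nm in names(strains)) {
    strain <- strains[[nm]]
    if (!length(strain)) abort(sprintf("strain '%s' is empty.", nm))
    af <- numeric(nrow(panel))
    for (chr in unique(panel$chrom)) {
      idx <- which(panel$chrom == chr)
      pos0 <- panel$pos[idx] - 1
      haps <- unlist(lapply(strain, function(ind) {
        if (chr == "X") ind$x else ind$aut[[chr]]
      }), recursive = FALSE)
      if (is.null(haps) || !length(haps)) {
        af[idx] <- NA_real_
        next
      }
      acc <- numeric(length(idx))
      for (h in haps) {
        o <- origin_at_int(h, pos0)
        acc <- acc + ifelse(o == 1L, panel$f_alt_M[idx], panel$f_alt_S[idx])
      }
      af[idx] <- acc / length(haps)
    }
    obs <- rbinom(length(af), depth, af) / depth
    obs <- round(obs * ploidy_grid) / ploidy_grid
    out[[paste0("af_", nm)]] <- obs
    out[[paste0("dp_", nm)]] <- rep(depth, length(af))
  }
  arrange(out, .data$chrom, .data$pos)
}

#' Simulate an assortative-mating assay
#'
#' Each chooser independently mates assortatively (with a mate of matching
#' X-island type) with probability `preference`, otherwise disassortatively.
#'
#' @param n_choosers Number of choosing individuals.
#' @param preference Probability of an assortative mating, in `[0, 1]`.
#' @param chooser,offered Labels recorded in the output table (the chooser's
#'   island genotype and the offered alternatives).
#' @param replicate Replicate identifier.
#' @return A one-row mating count table: tibble with columns `replicate`,
#'   `chooser`, `offered`, `n_assortative`, `n_disassortative`.
#' @examples
#' simulate_mating_assay(30, preference = 0.9)
#' @export
simulate_mating_assay <- function(n_choosers, preference,
                                  chooser = "MM", offered = "M S",
                                  replicate = 1L) {
  if (preference < 0 || preference > 1) abort("`preference` must be in [0, 1].")
  k <- rbinom(1L, n_choosers, preference)
  tibble(replicate = replicate, chooser = chooser, offered = offered,
         n_assortative = as.integer(k),
         n_disassortative = as.integer(n_choosers - k))
}
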
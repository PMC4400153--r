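#' Build a synthetic marker panel for the X-island design
#'
#' The panel lists the biallelic SNP sites at which pooled allele
#' frequencies are simulated, together with the allele each founder form
#' carries. Two kinds of sites are generated:
#'
#' * **diagnostic** sites, fixed differences between the M and S founder
#'   gene pools, laid down on a regular grid inside the island regions
#'   (default one site per 10 kb). The rDNA marker used for selection
#'   during introgression is one of these, placed very near the
#'   centromere (default 24.3 Mb).
#' * **background** sites of shared polymorphism outside the islands:
#'   both founder forms segregate the alternate allele at the same
#'   frequency, drawn uniformly from `background_freq_range`.
#'
#' @param chrom_lengths Named lengths in bp (must include `"X"`).
#' @param island_regions Tibble with `chrom`, `start`, `end` (1-based
#'   inclusive) delimiting the divergence islands. Default: the X island
#'   from 18.1 Mb to the centromere end of a 24.4 Mb X.
#' @param diagnostic_spacing Spacing of diagnostic sites inside islands, bp.
#' @param background_spacing Spacing of shared-polymorphism sites outside
#'   islands, bp.
#' @param rdna_pos Position of the diagnostic rDNA marker site on X, bp.
#' @param background_freq_range Range of the shared alternate-allele
#'   frequency at background sites.
#' @return A tibble of class `marker_panel` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `diagnostic`, `f_alt_M`, `f_alt_S` (origin-conditional
#'   alternate-allele frequencies; for diagnostic sites the alternate
#'   allele is the S-form allele, so `f_alt_M = 0`, `f_alt_S = 1`).
#'   Island regions and the rDNA position are carried as attributes.
#' @examples
#' panel <- marker_panel()
#' dplyr::count(panel, chrom, diagnostic)
#' @export
marker_panel <- function(chrom_lengths = c(X = 24.4e6),
                         island_regions = NULL,
                         diagnostic_spacing = 10e3,
                         background_spacing = 50e3,
                         rdna_pos = 24.3e6,
                         background_freq_range = c(0.05, 0.95)) {
  if (is.null(island_regions)) {
    island_regions <- tibble(chrom = "X", start = 18.1e6,
                             end = chrom_lengths[["X"]])
  }
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (chr in names(chrom_lengths)) {
    L <- chrom_lengths[[chr]]
    isl <- island_regions[island_regions$chrom == chr, , drop = FALSE]
    diag_pos <- unlist(lapply(seq_len(nrow(isl)), function(i) {
      seq(isl$start[i], isl$end[i], by = diagnostic_spacing)
    }))
    if (chr == "X" && nrow(isl) > 0 && !(rdna_pos %in% diag_pos)) {
      diag_pos <- sort(c(diag_pos, rdna_pos))
    }
    bg_pos <- seq(background_spacing, L, by = background_spacing)
    in_island <- rep(FALSE, length(bg_pos))
    for (i in seq_len(nrow(isl))) {
      in_island <- in_island | (bg_pos >= isl$start[i] & bg_pos <= isl$end[i])
    }
    bg_pos <- bg_pos[!in_island]
    pos <- c(diag_pos, bg_pos)
    diagn <- c(rep(TRUE, length(diag_pos)), rep(FALSE, length(bg_pos)))
    ord <- order(pos)
    pos <- pos[ord]; diagn <- diagn[ord]
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    p_bg <- runif(length(pos), background_freq_range[1], background_freq_range[2])
    rows[[chr]] <- tibble(
      chrom = chr, pos = pos, ref = unname(ref), alt = unname(alt),
      diagnostic = diagn,
      f_alt_M = ifelse(diagn, 0, p_bg),
      f_alt_S = ifelse(diagn, 1, p_bg)
    )
  }
  out <- bind_rows(rows)
  attr(out, "island_regions") <- island_regions
  attr(out, "rdna_pos") <- rdna_pos
  class(out) <- c("marker_panel", class(out))
  out
}
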
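#' Synthetic gene models along the X island
#'
#' Lays out `n_genes` single-CDS gene models on a regular grid inside a
#' region, alternating strand. Each CDS is complete (length divisible by
#' 3, phase 0).
#'
#' @param n_genes Number of genes.
#' @param region `c(start, end)` in bp.
#' @param chrom Chromosome name.
#' @param cds_codons Codons per CDS.
#' @return Gene-model tibble (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `phase`), one row per CDS interval.
#' @export
synthetic_gene_models <- function(n_genes = 16, region = c(18.1e6, 24.3e6),
                                  chrom = "X", cds_codons = 300) {
  starts <- floor(seq(region[1], region[2] - 3 * cds_codons,
                      length.out = n_genes))
  tibble(
    gene_id = sprintf("SYNG%03d", seq_len(n_genes)),
    chrom = chrom,
    strand = rep(c("+", "-"), length.out = n_genes),
    start = starts,
    end = starts + 3 * cds_codons - 1,
    phase = 0L
  )
}

#' Synthetic reference sequence covering a set of gene models
#'
#' Builds one sequence per chromosome: `N` everywhere except over CDS
#' intervals, which are filled with random A/C/G/T. Kept deliberately
#' sparse so genome-scale coordinates stay cheap.
#'
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param models Gene-model tibble (see [synthetic_gene_models()]).
#' @return A named [Biostrings::DNAStringSet].
#' @export
synthetic_reference <- function(chrom_lengths, models) {
  seqs <- lapply(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    cds <- models[models$chrom == chr, , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    pieces <- character(0)
    at <- 1
    for (i in seq_len(nrow(cds))) {
      w <- cds$end[i] - cds$start[i] + 1
      pieces <- c(pieces,
                  strrep("N", cds$start[i] - at),
                  paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                        collapse = ""))
      at <- cds$end[i] + 1
    }
    pieces <- c(pieces, strrep("N", L - at + 1))
    paste(pieces, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(chrom_lengths)
  out
}

# pick an alt allele at a genomic position giving the requested effect
pick_alt <- function(chrom, pos, models, reference, want_nonsyn = TRUE) {
  ref <- fetch_base(reference, chrom, pos)
  for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
    eff <- classify_snp_effect(chrom, pos, ref, alt, models, reference)
    ok <- if (want_nonsyn) eff$effect == "nonsynonymous"
          else eff$effect == "synonymous"
    if (ok) return(list(ref = ref, alt = alt, ann = eff))
  }
  NULL
}

#' Synthetic planted-truth coding dataset
#'
#' Builds a complete miniature of the coding-difference analysis: gene
#' models inside the X island, a reference sequence, a set of fixed
#' nonsynonymous differences between two recombinant-strain pools (the
#' reference base plays the M-form allele, the alternate the S-form
#' allele), and field pool frequencies planted so that exactly
#' `n_conserved_high` differences (spread over `n_genes_conserved` genes)
#' are conserved at high stringency, `n_conserved_mid` at mid stringency,
#' and the rest not conserved.
#'
#' @param n_genes Total synthetic genes in the island.
#' @param n_conserved_high,n_genes_conserved,n_conserved_mid,n_not_conserved
#'   Planted truth-set sizes.
#' @param region Island region `c(start, end)` bp on X.
#' @param chrom_length X chromosome length.
#' @return A list with `models`, `reference`, `strain_sites` (pool table
#'   with `af_RbMM`/`af_RbSS`), `field_sites` (pool table with
#'   `af_field_M`/`af_field_S`), and `truth` (per-site planted status and
#'   gene).
#' @export
synthetic_coding_dataset <- function(n_genes = 16, n_conserved_high = 20,
                                     n_genes_conserved = 12,
                                     n_conserved_mid = 8,
                                     n_not_conserved = 12,
                                     region = c(18.1e6, 24.3e6),
                                     chrom_length = 24.4e6) {
  models <- synthetic_gene_models(n_genes, region)
  reference <- synthetic_reference(c(X = chrom_length), models)

  # distribute conserved-high sites over exactly n_genes_conserved genes
  genes_hi <- models$gene_id[seq_len(n_genes_conserved)]
  extra <- n_conserved_high - n_genes_conserved
  gene_of_site <- c(genes_hi, sample(genes_hi, extra, replace = TRUE))
  other_status <- c(rep("conserved_mid", n_conserved_mid),
                    rep("not_conserved", n_not_conserved))
  gene_other <- sample(models$gene_id, length(other_status), replace = TRUE)

  assign <- tibble(
    gene_id = c(gene_of_site, gene_other),
    planted_status = c(rep("conserved_high", n_conserved_high), other_status)
  )
  # per gene, plant its sites at distinct codons (2nd codon position is
  # almost always nonsynonymous; fall back to another codon if not)
  planted <- assign |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      g <- models[models$gene_id == key$gene_id, ]
      ncod <- (g$end - g$start + 1) %/% 3L
      codons <- sample.int(ncod, nrow(d) + 5L)
      out <- vector("list", nrow(d))
      ci <- 1L
      for (i in seq_len(nrow(d))) {
        repeat {
          pos <- g$start + (codons[ci] - 1L) * 3L + 1L  # 2nd codon position
          ci <- ci + 1L
          hit <- pick_alt("X", pos, models, reference, want_nonsyn = TRUE)
          if (!is.null(hit)) break
        }
        out[[i]] <- tibble(chrom = "X", pos = pos, ref = hit$ref,
                           alt = hit$alt, planted_status = d$planted_status[i])
      }
      bind_rows(out)
    }) |>
    ungroup() |>
    arrange(.data$pos)

  strain_sites <- planted |>
    select("chrom", "pos", "ref", "alt") |>
    mutate(af_RbMM = 0, dp_RbMM = 200, af_RbSS = 1, dp_RbSS = 200)

  field_af <- function(status) {
    n <- length(status)
    m_side <- ifelse(status == "not_conserved" & runif(n) < 0.5,
                     runif(n, 0.2, 0.6),        # M allele not conserved
                     runif(n, 0, 0.04))          # M allele (ref) near-fixed
    s_side <- dplyr::case_when(
      status == "conserved_high" ~ runif(n, 0.96, 1),
      status == "conserved_mid" ~ runif(n, 0.82, 0.94),
      TRUE ~ runif(n, 0.1, 0.5)
    )
    list(m = m_side, s = s_side)
  }
  fa <- field_af(planted$planted_status)
  field_sites <- planted |>
    select("chrom", "pos", "ref", "alt") |>
    mutate(af_field_M = fa$m,   # alternate (S) allele frequency in field M pool
           dp_field_M = 255,
           af_field_S = fa$s,   # alternate (S) allele frequency in field S pool
           dp_field_S = 200)

  list(models = models, reference = reference, truth = planted,
       strain_sites = strain_sites, field_sites = field_sites)
}
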
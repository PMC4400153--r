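#' Translate a codon with the standard genetic code
#'
#' @param codon Character vector of 3-letter nucleotide codons
#'   (case-insensitive). Stop codons return `"*"`.
#' @return One-letter amino acid code(s).
#' @examples
#' translate_codon(c("GGG", "GAG"))  # G, E
#' translate_codon("atg")            # M
#' @export
translate_codon <- function(codon) {
  cod <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", cod)
  if (any(bad)) {
    abort(sprintf("ambiguous or malformed codon at position %d: '%s'.",
                  which(bad)[1], codon[which(bad)[1]]))
  }
  unname(Biostrings::GENETIC_CODE[cod])
}

# reverse complement for plain character vectors of A/C/G/T
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

# CDS rows of one gene in transcription order (5' -> 3')
gene_cds <- function(models, gene) {
  cds <- models[models$gene_id == gene, , drop = FALSE]
  if (cds$strand[1] == "+") cds[order(cds$start), , drop = FALSE]
  else cds[order(-cds$start), , drop = FALSE]
}

# genomic positions of a gene's CDS in transcript (reading) order
transcript_positions <- function(cds) {
  unlist(lapply(seq_len(nrow(cds)), function(i) {
    if (cds$strand[i] == "+") seq(cds$start[i], cds$end[i])
    else seq(cds$end[i], cds$start[i])
  }))
}

fetch_base <- function(reference, chrom, pos) {
  if (!chrom %in% names(reference)) {
    abort(sprintf("chromosome '%s' not in reference.", chrom))
  }
  as.character(Biostrings::subseq(reference[[chrom]], start = pos, end = pos))
}

#' Classify the coding effect of a single-nucleotide substitution
#'
#' Looks the position up in the gene models; outside any CDS the effect is
#' `noncoding`. Inside a CDS the codon index and within-codon offset are
#' derived from the CDS chain, strand and phase; the reference and
#' alternate codons are built (reverse-complemented on the minus strand),
#' translated, and reported in the `xYz/xWz` dialect: lowercase context
#' with the substituted base uppercase, reference codon before alternate,
#' plus a protein change such as `G74E` (1-based codon coordinates).
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param ref_allele,alt_allele Single-base alleles on the forward strand.
#' @param models Gene-model tibble with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `phase` (one row per CDS interval; see
#'   [read_gene_models()]).
#' @param reference A named [Biostrings::DNAStringSet] (names = chromosome)
#'   covering the site.
#' @return A one-row tibble: `effect` (`noncoding` / `synonymous` /
#'   `nonsynonymous`), `codon_change`, `protein_change`, `gene_id`.
#' @examples
#' \dontrun{
#' classify_snp_effect("X", 220, "G", "A", models, reference)
#' }
#' @export
classify_snp_effect <- function(chrom, pos, ref_allele, alt_allele,
                                models, reference) {
  stopifnot(nchar(ref_allele) == 1L, nchar(alt_allele) == 1L)
  hit <- models[models$chrom == chrom & models$start <= pos &
                  models$end >= pos, , drop = FALSE]
  if (!nrow(hit)) {
    return(tibble(effect = "noncoding", codon_change = NA_character_,
                  protein_change = NA_character_, gene_id = NA_character_))
  }
  gene <- hit$gene_id[1]
  cds <- gene_cds(models, gene)
  tpos <- transcript_positions(cds)
  strand <- cds$strand[1]
  offset <- match(pos, tpos) - 1L            # 0-based transcript offset
  phase0 <- cds$phase[1]
  coding_offset <- offset - phase0
  if (coding_offset < 0) {
    abort(sprintf("position %d falls in the partial leading codon of gene %s.",
                  pos, gene))
  }
  codon_idx <- coding_offset %/% 3L          # 0-based codon index
  within <- coding_offset %% 3L
  cod_pos <- tpos[phase0 + codon_idx * 3L + 1:3]
  if (anyNA(cod_pos)) {
    abort(sprintf("codon %d of gene %s extends past the model bounds (incomplete model).",
                  codon_idx + 1L, gene))
  }
  bases <- vapply(cod_pos, function(p) fetch_base(reference, chrom, p),
                  character(1))
  if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  ref_t <- if (strand == "+") toupper(ref_allele) else chartr("ACGT", "TGCA", toupper(ref_allele))
  alt_t <- if (strand == "+") toupper(alt_allele) else chartr("ACGT", "TGCA", toupper(alt_allele))
  codon_ref <- bases
  codon_ref[within + 1L] <- ref_t
  codon_alt <- bases
  codon_alt[within + 1L] <- alt_t
  aa_ref <- translate_codon(paste(codon_ref, collapse = ""))
  aa_alt <- translate_codon(paste(codon_alt, collapse = ""))
  fmt <- function(cod) {
    s <- tolower(cod)
    s[within + 1L] <- toupper(s[within + 1L])
    paste(s, collapse = "")
  }
  tibble(
    effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
    codon_change = paste0(fmt(codon_ref), "/", fmt(codon_alt)),
    protein_change = paste0(aa_ref, codon_idx + 1L, aa_alt),
    gene_id = gene
  )
}

#' Annotate coding effects for a table of SNPs
#'
#' Row-wise wrapper around [classify_snp_effect()].
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `alt` columns (extra
#'   columns are carried through).
#' @inheritParams classify_snp_effect
#' @return `sites` with `effect`, `codon_change`, `protein_change`,
#'   `gene_id` columns appended.
#' @export
annotate_effects <- function(sites, models, reference) {
  ann <- purrr::pmap(
    list(sites$chrom, sites$pos, sites$ref, sites$alt),
    function(c., p., r., a.) classify_snp_effect(c., p., r., a., models, reference)
  ) |> bind_rows()
  dplyr::bind_cols(sites, ann)
}

#' Find (near-)fixed allele differences between two pools
#'
#' A site qualifies when one pool carries one allele at frequency
#' `>= fix_threshold` and the other pool carries the alternate allele at
#' frequency `>= fix_threshold`.
#'
#' @param sites A pool site table (`af_<pool>` columns of alternate-allele
#'   frequencies).
#' @param pool_a,pool_b Pool names; `allele_a` / `allele_b` in the output
#'   are the alleles carried by each pool.
#' @param fix_threshold Fixation threshold, in `(0.5, 1]`.
#' @return The qualifying rows with `allele_a`, `allele_b` columns added.
#' @examples
#' tab <- tibble::tibble(chrom = "X", pos = c(1, 2), ref = "A", alt = "G",
#'                       af_a = c(1, 0.96), af_b = c(0, 0.3))
#' find_fixed_differences(tab, "a", "b")
#' @export
find_fixed_differences <- function(sites, pool_a, pool_b,
                                   fix_threshold = 0.95) {
  if (fix_threshold <= 0.5 || fix_threshold > 1) {
    abort("`fix_threshold` must be in (0.5, 1].")
  }
  for (p in c(pool_a, pool_b)) {
    if (!paste0("af_", p) %in% names(sites)) {
      abort(sprintf("pool '%s' not found in site table.", p))
    }
  }
  fa <- sites[[paste0("af_", pool_a)]]
  fb <- sites[[paste0("af_", pool_b)]]
  a_alt <- fa >= fix_threshold & fb <= 1 - fix_threshold
  a_ref <- fb >= fix_threshold & fa <= 1 - fix_threshold
  keep <- !is.na(fa) & !is.na(fb) & (a_alt | a_ref)
  out <- sites[keep, , drop = FALSE]
  swap <- a_ref[keep]
  out$allele_a <- ifelse(swap, out$ref, out$alt)
  out$allele_b <- ifelse(swap, out$alt, out$ref)
  out
}

# frequency of a specific allele in a field pool at matching rows
allele_freq_in_pool <- function(tbl, allele, pool) {
  af <- tbl[[paste0("af_", pool)]]
  ifelse(allele == tbl$alt, af, ifelse(allele == tbl$ref, 1 - af, 0))
}

#' Conservation filtering of fixed differences against field populations
#'
#' Classifies each fixed difference by how well it is conserved in
#' independent field pools of the two forms. A difference is
#' `conserved_high` when the M-form allele is at frequency
#' `>= thr_hi` in the field M pool *and* the S-form allele is at frequency
#' `>= thr_hi` in the field S pool; `conserved_mid` when the M side passes
#' `thr_hi` and the S-form allele exceeds `thr_mid`; otherwise
#' `not_conserved`. Conserved-high calls are grouped by gene and the
#' onset (minimum position of a conserved-high call) is reported.
#'
#' @param diffs Fixed differences (rows with `chrom`, `pos`, `m_allele`,
#'   `s_allele`; [find_fixed_differences()] output can be renamed via
#'   `allele_a`/`allele_b` when pool a is the M-form strain). A `gene_id`
#'   column (e.g. from [annotate_effects()]) enables gene grouping.
#' @param field_sites Field pool site table with `af_<pool_m>` and
#'   `af_<pool_s>` columns.
#' @param pool_m,pool_s Names of the field M-form and S-form pools.
#' @param thr_hi Fixed-or-nearly-fixed threshold (inclusive; default 0.95).
#' @param thr_mid Mid-conservation threshold (exclusive; default 0.8).
#' @return A list of class `conservation_result`: `calls` (per-difference
#'   tibble with `field_m_freq`, `field_s_freq`, `status`), `genes`
#'   (conserved-high counts per gene), `onset` (minimum conserved-high
#'   position), `missing` (differences absent from the field table).
#' @export
conservation_filter <- function(diffs, field_sites, pool_m = "field_M",
                                pool_s = "field_S", thr_hi = 0.95,
                                thr_mid = 0.8) {
  if (!all(c("m_allele", "s_allele") %in% names(diffs))) {
    if (all(c("allele_a", "allele_b") %in% names(diffs))) {
      diffs <- dplyr::rename(diffs, m_allele = "allele_a", s_allele = "allele_b")
    } else {
      abort("`diffs` must have m_allele/s_allele (or allele_a/allele_b) columns.")
    }
  }
  key <- c("chrom", "pos")
  fcols <- c(key, "ref", "alt", paste0("af_", c(pool_m, pool_s)))
  if (!all(fcols %in% names(field_sites))) {
    abort(sprintf("field table must have columns: %s.", paste(fcols, collapse = ", ")))
  }
  joined <- left_join(diffs, select(field_sites, dplyr::all_of(fcols)),
                      by = key, suffix = c("", ".field"))
  miss <- is.na(joined[[paste0("af_", pool_m)]])
  missing <- joined[miss, , drop = FALSE]
  calls <- joined[!miss, , drop = FALSE]
  ref_col <- if ("ref.field" %in% names(calls)) "ref.field" else "ref"
  alt_col <- if ("alt.field" %in% names(calls)) "alt.field" else "alt"
  ftab <- tibble(ref = calls[[ref_col]], alt = calls[[alt_col]])
  ftab[[paste0("af_", pool_m)]] <- calls[[paste0("af_", pool_m)]]
  ftab[[paste0("af_", pool_s)]] <- calls[[paste0("af_", pool_s)]]
  calls$field_m_freq <- allele_freq_in_pool(ftab, calls$m_allele, pool_m)
  calls$field_s_freq <- allele_freq_in_pool(ftab, calls$s_allele, pool_s)
  calls$status <- dplyr::case_when(
    calls$field_m_freq >= thr_hi & calls$field_s_freq >= thr_hi ~ "conserved_high",
    calls$field_m_freq >= thr_hi & calls$field_s_freq > thr_mid ~ "conserved_mid",
    TRUE ~ "not_conserved"
  )
  hi <- calls[calls$status == "conserved_high", , drop = FALSE]
  genes <- if ("gene_id" %in% names(hi) && nrow(hi)) {
    hi |> filter(!is.na(.data$gene_id)) |>
      dplyr::count(.data$gene_id, name = "n_conserved_high")
  } else {
    tibble(gene_id = character(), n_conserved_high = integer())
  }
  structure(list(
    calls = calls, genes = genes,
    onset = if (nrow(hi)) min(hi$pos) else NA_real_,
    missing = missing,
    thresholds = c(thr_hi = thr_hi, thr_mid = thr_mid)
  ), class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf(
    "<conservation_result> %d calls: %d conserved_high (over %d genes), %d conserved_mid; onset %.0f\n",
    nrow(x$calls), sum(x$calls$status == "conserved_high"), nrow(x$genes),
    sum(x$calls$status == "conserved_mid"), x$onset))
  invisible(x)
}

#' @rdname conservation_filter
#' @param x A `conservation_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.conservation_result <- function(x, ...) x$calls

#' @rdname conservation_filter
#' @exportS3Method generics::glance
glance.conservation_result <- function(x, ...) {
  tibble(
    n_diffs = nrow(x$calls) + nrow(x$missing),
    n_conserved_high = sum(x$calls$status == "conserved_high"),
    n_conserved_mid = sum(x$calls$status == "conserved_mid"),
    n_genes_conserved = nrow(x$genes),
    onset_pos = x$onset
  )
}
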
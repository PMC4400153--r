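# Build a toy single-CDS gene model plus a reference sequence whose CDS
# is the concatenation of `codons`. Flanks are filled with "N".
toy_gene <- function(codons, strand = "+", start = 101, chrom = "chr1",
                     gene_id = "g1", chrom_length = 1000, phase = 0L) {
  cds_seq <- paste(codons, collapse = "")
  if (strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
  }
  end <- start + nchar(cds_seq) - 1L
  ref <- paste0(strrep("N", start - 1), cds_seq,
                strrep("N", chrom_length - end))
  reference <- Biostrings::DNAStringSet(ref)
  names(reference) <- chrom
  models <- tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                           start = start, end = end, phase = phase)
  list(models = models, reference = reference, start = start, end = end)
}

# Independent coding-effect oracle: substitute the base in the genomic
# sequence, translate the full CDS on both alleles with Biostrings, and
# diff the proteins.
oracle_effect <- function(chrom, pos, alt, models, reference) {
  g <- models[1, ]
  seqs <- as.character(reference[[chrom]])
  mut <- seqs
  substr(mut, pos, pos) <- alt
  get_prot <- function(s) {
    cds <- substr(s, g$start, g$end)
    dna <- Biostrings::DNAString(cds)
    if (g$strand == "-") dna <- Biostrings::reverseComplement(dna)
    as.character(Biostrings::translate(dna, no.init.codon = TRUE))
  }
  p0 <- get_prot(seqs)
  p1 <- get_prot(mut)
  if (pos < g$start || pos > g$end) return("noncoding")
  if (p0 == p1) "synonymous" else "nonsynonymous"
}

# A small pool site table with two pools for IO / FST tests.
tiny_pool_table <- function() {
  tibble::tibble(
    chrom = c("X", "X", "2L"),
    pos = c(100, 2000, 500),
    ref = c("A", "C", "G"),
    alt = c("G", "T", "A"),
    af_a = c(1, 0.35, 0),
    dp_a = c(200, 150, 90),
    af_b = c(0, 0.35, 1),
    dp_b = c(180, 160, 95)
  )
}

gff3_lines <- function(plus = TRUE) {
  strand <- if (plus) "+" else "-"
  c(
    "##gff-version 3",
    sprintf("chr1\ttest\tgene\t101\t220\t.\t%s\t.\tID=gene1", strand),
    sprintf("chr1\ttest\tmRNA\t101\t220\t.\t%s\t.\tID=mrna1;Parent=gene1", strand),
    sprintf("chr1\ttest\tCDS\t101\t160\t.\t%s\t0\tID=cds1a;Parent=mrna1", strand),
    sprintf("chr1\ttest\tCDS\t181\t219\t.\t%s\t0\tID=cds1b;Parent=mrna1", strand)
  )
}

# quick small design for tests that only need a working simulation
small_design <- function(seed, n_backcross = 2) {
  design_config(
    n_females_per_cross = 30, n_backcross_generations = n_backcross,
    n_families_oviposited = 20, n_larvae_genotyped_per_family = 6,
    n_strain_founders = 15, brood_size = 25, seed = seed,
    chrom_lengths = c(X = 24.4e6)
  )
}
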
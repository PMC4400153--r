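#' Create a founder individual of pure M or S ancestry
#'
#' Individuals carry ancestry haplotypes for the X chromosome (two in
#' females, one in males) and for each modelled autosome arm (two each),
#' plus unrecombining mitochondrial and Y labels.
#'
#' @param form `"M"` or `"S"` founder ancestry.
#' @param sex `"F"` or `"M"`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   must contain `"X"`, other entries are modelled autosome arms.
#' @return A list of class `mosquito` with fields `sex`, `x` (list of
#'   haplotypes), `aut` (list of 2-haplotype lists per arm), `mito`, `y`.
#' @examples
#' founder("S", "F", c(X = 24.4e6))
#' @export
founder <- function(form, sex, chrom_lengths = c(X = 24.4e6)) {
  stopifnot(form %in% c("M", "S"), sex %in% c("F", "M"), "X" %in% names(chrom_lengths))
  arms <- setdiff(names(chrom_lengths), "X")
  xlen <- chrom_lengths[["X"]]
  structure(list(
    sex = sex,
    x = if (sex == "F") list(haplotype(form, xlen), haplotype(form, xlen))
        else list(haplotype(form, xlen)),
    aut = stats::setNames(
      lapply(arms, function(a) {
        l <- chrom_lengths[[a]]
        list(haplotype(form, l), haplotype(form, l))
      }), arms),
    mito = form,
    y = if (sex == "M") form else NA_character_
  ), class = "mosquito")
}

# Produce one offspring of random (or given) sex from a mother and father.
# X inheritance: daughters receive the father's X intact plus a recombined
# maternal X; sons receive only a recombined maternal X and the father's Y.
# Autosomes recombine in both sexes. Mitochondria are maternal.
make_offspring <- function(mother, father, maps, sex = NULL) {
  if (is.null(sex)) sex <- if (runif(1) < 0.5) "F" else "M"
  mat_x <- meiosis(mother$x[[1L]], mother$x[[2L]], maps$X)
  aut <- lapply(names(mother$aut), function(a) {
    list(meiosis(mother$aut[[a]][[1L]], mother$aut[[a]][[2L]], maps[[a]]),
         meiosis(father$aut[[a]][[1L]], father$aut[[a]][[2L]], maps[[a]]))
  })
  names(aut) <- names(mother$aut)
  structure(list(
    sex = sex,
    x = if (sex == "F") list(mat_x, father$x[[1L]]) else list(mat_x),
    aut = aut,
    mito = mother$mito,
    y = if (sex == "M") father$y else NA_character_
  ), class = "mosquito")
}

#' Genotype an individual at a marker position
#'
#' Returns the rDNA-style marker genotype implied by the ancestry origin of
#' the haplotype block(s) covering the position: `"M"`/`"S"` for hemizygous
#' males, `"MM"`/`"MS"`/`"SS"` for females (heterozygotes always written
#' `"MS"`).
#'
#' @param ind A [founder()]-style individual.
#' @param pos Position in bp on the X chromosome (1-based).
#' @param chrom Chromosome name; only `"X"` markers and modelled autosome
#'   arms are supported.
#' @return Genotype label.
#' @export
genotype_at <- function(ind, pos, chrom = "X") {
  haps <- if (chrom == "X") ind$x else ind$aut[[chrom]]
  if (is.null(haps)) abort(sprintf("chromosome '%s' is not modelled.", chrom))
  if (pos < 1 || pos > haps[[1L]]$len) abort("marker position outside chromosome.")
  al <- vapply(haps, function(h) origin_at(h, pos), character(1))
  paste(sort(al), collapse = "")
}

# mean S-ancestry fraction across all autosomal haplotypes of individuals
mean_autosomal_s_fraction <- function(individuals) {
  fr <- unlist(lapply(individuals, function(ind) {
    unlist(lapply(ind$aut, function(pair) vapply(pair, s_fraction, numeric(1))))
  }))
  if (!length(fr)) return(NA_real_)
  mean(fr)
}
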
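#' Ancestry haplotypes
#'
#' A haplotype is represented as an ordered run-length partition of a
#' chromosome into ancestry blocks: a vector of block start positions
#' (the first always 0) and a parallel vector of origins, `"M"`
#' (*An. coluzzii* / Mopti) or `"S"` (*An. gambiae* s.s. / Kisumu).
#' Block arithmetic is half-open `[start, end)` in bp; user-facing tables
#' use 1-based inclusive coordinates (see [blocks_to_tibble()]).
#'
#' @param origin `"M"` or `"S"`: a chromosome of single ancestry.
#' @param chrom_length Chromosome length in bp.
#' @return A list with fields `b` (numeric block starts), `o` (integer
#'   origins, 1 = M, 2 = S) and `len`, of class `ancestry_haplotype`.
#' @examples
#' h <- haplotype("S", 24.4e6)
#' blocks_to_tibble(h)
#' @export
haplotype <- function(origin, chrom_length) {
  o <- match(origin, c("M", "S"))
  if (is.na(o)) abort("`origin` must be \"M\" or \"S\".")
  structure(list(b = 0, o = o, len = chrom_length),
            class = "ancestry_haplotype")
}

new_haplotype <- function(b, o, len) {
  structure(list(b = b, o = o, len = len), class = "ancestry_haplotype")
}

#' Convert a haplotype to a tibble of ancestry blocks
#'
#' @param hap An [haplotype()].
#' @return A tibble with 1-based inclusive `start`, `end` and `origin`
#'   columns; blocks tile the chromosome and adjacent blocks differ in
#'   origin.
#' @export
blocks_to_tibble <- function(hap) {
  stopifnot(inherits(hap, "ancestry_haplotype"))
  tibble(
    start = hap$b + 1,
    end = c(hap$b[-1], hap$len),
    origin = c("M", "S")[hap$o]
  )
}

#' Ancestry origin at one or more positions
#'
#' @param hap An [haplotype()].
#' @param pos Numeric vector of positions (bp, 1-based).
#' @return Character vector of `"M"`/`"S"` origins.
#' @export
origin_at <- function(hap, pos) {
  c("M", "S")[hap$o[findInterval(pos - 1, hap$b)]]
}

# integer-coded origin lookup used in hot paths
origin_at_int <- function(hap, pos0) {
  hap$o[findInterval(pos0, hap$b)]
}

# fraction of the chromosome with S (origin == 2) ancestry
s_fraction <- function(hap) {
  ends <- c(hap$b[-1], hap$len)
  sum((ends - hap$b)[hap$o == 2L]) / hap$len
}

# drop zero-length blocks and merge adjacent blocks of equal origin
merge_blocks <- function(b, o, len) {
  keep <- c(b[-1], len) > b
  b <- b[keep]; o <- o[keep]
  if (length(o) > 1L) {
    keep <- c(TRUE, o[-1L] != o[-length(o)])
    b <- b[keep]; o <- o[keep]
  }
  new_haplotype(b, o, len)
}

#' Simulate meiosis between two haplotypes
#'
#' Crossover positions are drawn from an inhomogeneous Poisson process with
#' intensity given by the recombination map (no crossover interference).
#' The gamete starts from one parental haplotype chosen by a fair coin and
#' switches source at every crossover.
#'
#' @param hap_a,hap_b Parental [haplotype()]s covering the same chromosome
#'   length.
#' @param map A [recomb_map()] for that chromosome.
#' @return A gamete [haplotype()].
#' @examples
#' rmap <- recomb_map(24.4e6)
#' g <- meiosis(haplotype("M", 24.4e6), haplotype("S", 24.4e6), rmap)
#' @export
meiosis <- function(hap_a, hap_b, map) {
  if (hap_a$len != hap_b$len) {
    abort("parental haplotypes cover different chromosome lengths.")
  }
  if (hap_a$len != map$chrom_length) {
    abort("haplotype and recombination map lengths differ.")
  }
  cur <- if (runif(1) < 0.5) 1L else 2L
  nco <- rpois(1L, map$length_morgans)
  parents <- list(hap_a, hap_b)
  if (nco == 0L) return(parents[[cur]])
  x <- unique(sample_crossovers(map, nco))
  L <- hap_a$len
  bounds <- c(0, x, L)
  b_out <- vector("list", length(bounds) - 1L)
  o_out <- vector("list", length(bounds) - 1L)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    p <- parents[[cur]]
    i0 <- findInterval(lo, p$b)
    i1 <- findInterval(hi, p$b, left.open = TRUE)
    idx <- i0:i1
    bs <- p$b[idx]
    bs[1L] <- lo
    b_out[[s]] <- bs
    o_out[[s]] <- p$o[idx]
    cur <- 3L - cur
  }
  merge_blocks(unlist(b_out), unlist(o_out), L)
}
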
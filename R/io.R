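#' Coordinate conversion between 1-based inclusive and 0-based half-open
#'
#' VCF/GFF coordinates are 1-based inclusive; BED is 0-based half-open.
#' All conversions in the package go through these two helpers.
#'
#' @param start,end 1-based inclusive interval (for `to_bed`) or 0-based
#'   half-open (for `from_bed`).
#' @return A list with converted `start` and `end`.
#' @export
to_bed <- function(start, end) list(start = start - 1, end = end)

#' @rdname to_bed
#' @export
from_bed <- function(start, end) list(start = start + 1, end = end)

pkg_header <- function(seed = NULL, params = list()) {
  h <- sprintf("islandswap %s", as.character(utils::packageVersion("islandswap")))
  if (!is.null(seed)) h <- paste0(h, "; seed=", seed)
  if (length(params)) h <- paste0(h, "; params_hash=", rlang::hash(params))
  h
}

# write lines atomically: tempfile in the target directory, then rename
write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a pool site table as a simplified VCF
#'
#' Minimal VCF v4.2 dialect: per-pool alternate-allele frequencies and
#' depths are carried in INFO as `AF_<pool>` / `DP_<pool>` keys (pools are
#' not diploid samples, so no sample columns are used). The header
#' records the tool version, seed and a parameter hash.
#'
#' @param sites Pool site table (tibble with `chrom`, `pos`, `ref`, `alt`
#'   and `af_<pool>` / `dp_<pool>` columns).
#' @param path Output file.
#' @param seed Optional seed recorded in the header.
#' @param params Optional parameter list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_variants <- function(sites, path, seed = NULL, params = list()) {
  pools <- sub("^af_", "", grep("^af_", names(sites), value = TRUE))
  if (!length(pools)) abort("site table has no af_<pool> columns.")
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", pkg_header(seed, params)),
    unlist(lapply(pools, function(p) c(
      sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Alt allele frequency in pool %s\">", p, p),
      sprintf("##INFO=<ID=DP_%s,Number=1,Type=Integer,Description=\"Depth in pool %s\">", p, p)
    ))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(sites)), function(i) {
    paste(unlist(lapply(pools, function(p) c(
      sprintf("AF_%s=%s", p, format(sites[[paste0("af_", p)]][i], digits = 10)),
      sprintf("DP_%s=%d", p, as.integer(sites[[paste0("dp_", p)]][i]))
    ))), collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  sites$chrom, as.integer(sites$pos), sites$ref, sites$alt, info)
  write_lines_atomic(c(hdr, body), path)
}

#' Read a simplified VCF of pooled allele frequencies
#'
#' Inverse of [write_variants()]: expects `AF_<pool>` / `DP_<pool>` INFO
#' keys declared in the header. Records are validated (frequencies in
#' `[0, 1]`, positions `>= 1`, single-base SNP alleles) and sorted;
#' malformed records are rejected with their line number.
#'
#' @param path VCF file.
#' @return Pool site table tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `af_<pool>`, `dp_<pool>`).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  lines <- readLines(path)
  hdr <- grep("^##", lines, value = TRUE)
  pools <- unique(sub("^##INFO=<ID=AF_([^,]+),.*$", "\\1",
                      grep("^##INFO=<ID=AF_", hdr, value = TRUE)))
  if (!length(pools)) abort("header declares no AF_<pool> INFO keys.")
  body_idx <- which(!startsWith(lines, "#"))
  if (!length(body_idx)) {
    out <- tibble(chrom = character(), pos = numeric(),
                  ref = character(), alt = character())
    for (p in pools) {
      out[[paste0("af_", p)]] <- numeric()
      out[[paste0("dp_", p)]] <- numeric()
    }
    return(out)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    abort(sprintf("malformed VCF record at line %d (%d fields).",
                  body_idx[which(nf < 8L)[1]], nf[which(nf < 8L)[1]]))
  }
  m <- do.call(rbind, fields)
  out <- tibble(chrom = m[, 1], pos = as.numeric(m[, 2]),
                ref = m[, 4], alt = m[, 5])
  info <- m[, 8]
  get_key <- function(key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    mm <- regmatches(info, regexec(pat, info))
    vapply(mm, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  for (p in pools) {
    af <- as.numeric(get_key(paste0("AF_", p)))
    dp <- as.numeric(get_key(paste0("DP_", p)))
    if (anyNA(af) || anyNA(dp)) {
      bad <- which(is.na(af) | is.na(dp))[1]
      abort(sprintf("missing AF_%s/DP_%s key at line %d.", p, p, body_idx[bad]))
    }
    if (any(af < 0 | af > 1)) {
      bad <- which(af < 0 | af > 1)[1]
      abort(sprintf("AF_%s=%g out of [0, 1] at line %d.", p, af[bad], body_idx[bad]))
    }
    out[[paste0("af_", p)]] <- af
    out[[paste0("dp_", p)]] <- dp
  }
  if (any(out$pos < 1)) {
    abort(sprintf("position < 1 at line %d.", body_idx[which(out$pos < 1)[1]]))
  }
  if (any(nchar(out$ref) != 1L | nchar(out$alt) != 1L)) {
    bad <- which(nchar(out$ref) != 1L | nchar(out$alt) != 1L)[1]
    abort(sprintf("non-SNP ref/alt at line %d.", body_idx[bad]))
  }
  arrange(out, .data$chrom, .data$pos)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/CDS features (via `rtracklayer`) and resolves each
#' CDS to its gene through `Parent` links (CDS -> mRNA -> gene, or CDS ->
#' gene directly). One CDS chain per gene is assumed. Genes whose total
#' CDS length is not divisible by 3 are flagged incomplete with a
#' warning.
#'
#' @param path GFF3 file.
#' @return Gene-model tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `phase` (one row per CDS interval, ordered 5'->3' within
#'   gene), with a logical `complete` column.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  if (!nrow(df)) {
    warn("empty GFF3: no gene models.")
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric(),
                  phase = integer(), complete = logical()))
  }
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID)
           else rep(NA_character_, nrow(df))
  parent_chr <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
  } else {
    rep(NA_character_, nrow(df))
  }
  id2parent <- stats::setNames(parent_chr, df$ID)
  id2type <- stats::setNames(as.character(df$type), df$ID)
  resolve_gene <- function(parent, what) {
    if (is.na(parent)) abort(sprintf("orphan CDS (no Parent): '%s'.", what))
    cur <- parent
    for (i in 1:5) {
      ty <- id2type[cur]
      if (!is.na(ty) && ty == "gene") return(cur)
      nxt <- id2parent[cur]
      if (is.na(nxt)) return(cur)  # parent is top-level (e.g. mRNA w/o gene)
      cur <- nxt
    }
    cur
  }
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) {
    warn("GFF3 contains no CDS features.")
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric(),
                  phase = integer(), complete = logical()))
  }
  gene_id <- vapply(seq_len(nrow(cds)), function(i) {
    resolve_gene(parent_chr[which(df$type == "CDS")[i]],
                 cds$ID[i] %||% sprintf("CDS@%d", cds$start[i]))
  }, character(1))
  out <- tibble(
    gene_id = unname(gene_id),
    chrom = as.character(cds$seqnames),
    strand = as.character(cds$strand),
    start = as.numeric(cds$start),
    end = as.numeric(cds$end),
    phase = as.integer(as.character(cds$phase))
  )
  out <- arrange(out, .data$gene_id, .data$start)
  lens <- out |> group_by(.data$gene_id) |>
    summarise(len = sum(.data$end - .data$start + 1), .groups = "drop")
  incomplete <- lens$gene_id[lens$len %% 3 != 0]
  if (length(incomplete)) {
    warn(sprintf("gene model(s) with CDS length not divisible by 3: %s.",
                 paste(incomplete, collapse = ", ")))
  }
  out$complete <- !(out$gene_id %in% incomplete)
  out
}

#' Write called segments as BED
#'
#' BED is 0-based half-open; segment coordinates (1-based inclusive) are
#' converted via [to_bed()]. The mean smoothed FST goes in the score
#' column.
#'
#' @param segments Segment tibble from [call_segments()].
#' @param path Output file.
#' @inheritParams write_variants
#' @export
write_segments_bed <- function(segments, path, seed = NULL, params = list()) {
  bed <- to_bed(segments$start, segments$end)
  lines <- c(
    paste0("# ", pkg_header(seed, params)),
    sprintf("%s\t%d\t%d\t%s\t%.4f", segments$chrom, as.integer(bed$start),
            as.integer(bed$end),
            sprintf("segment_%d", seq_len(nrow(segments))),
            segments$mean_smoothed_fst)
  )
  write_lines_atomic(lines, path)
}

#' Read / write a mating count table (TSV)
#'
#' Columns: `replicate`, `chooser`, `offered`, `n_assortative`,
#' `n_disassortative`. Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_mating_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("replicate", "chooser", "offered", "n_assortative",
            "n_disassortative")
  if (!all(need %in% names(tab))) {
    abort(sprintf("mating table must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (any(tab$n_assortative < 0 | tab$n_disassortative < 0)) {
    abort("negative counts in mating table.")
  }
  tab
}

#' Write a tibble as TSV with a reproducibility header comment
#'
#' @param x A data frame.
#' @param path Output file.
#' @inheritParams write_variants
#' @export
write_tsv_with_header <- function(x, path, seed = NULL, params = list()) {
  lines <- c(paste0("# ", pkg_header(seed, params)),
             readr::format_tsv(x))
  write_lines_atomic(sub("\n$", "", lines), path)
}

#' Export strain individuals as a tibble of ancestry blocks
#'
#' @param strain List of individuals (e.g. `sim$rbss`).
#' @param prefix Identifier prefix for individuals.
#' @return Tibble with `individual_id`, `sex`, `chrom`, `haplotype`,
#'   `start`, `end`, `origin` (1-based inclusive coordinates).
#' @export
strain_blocks <- function(strain, prefix = "ind") {
  purrr::imap(strain, function(ind, i) {
    id <- sprintf("%s_%03d", prefix, i)
    xs <- purrr::imap(ind$x, function(h, k) {
      mutate(blocks_to_tibble(h), chrom = "X", haplotype = k)
    })
    auts <- purrr::imap(ind$aut, function(pair, arm) {
      purrr::imap(pair, function(h, k) {
        mutate(blocks_to_tibble(h), chrom = arm, haplotype = k)
      }) |> bind_rows()
    })
    bind_rows(c(xs, auts)) |>
      mutate(individual_id = id, sex = ind$sex)
  }) |>
    bind_rows() |>
    select("individual_id", "sex", "chrom", "haplotype", "start", "end",
           "origin")
}
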
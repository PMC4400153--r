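#' Configuration of the selective-introgression crossing design
#'
#' Defaults follow the breeding scheme used to move the S-form X island
#' into an M-form genetic background: 100 females per mass cross, four
#' backcross generations with 80 individually-ovipositing females per
#' generation and ten 2nd-instar larvae genotyped per family, followed by
#' two generations of crosses within the introgressed strain that fix the
#' M and S island types.
#'
#' @param n_females_per_cross Females (and males) per mass-mating cage.
#' @param n_backcross_generations Backcross rounds of MS females x M males.
#' @param n_families_oviposited Females set up for individual oviposition
#'   per generation.
#' @param n_larvae_genotyped_per_family Larvae genotyped to classify each
#'   family as mixed (kept) or pure-MM (discarded).
#' @param fixation_cross_generations Random-mating generations within the
#'   introgressed strain after the backcrosses.
#' @param n_strain_founders Individuals of each sex collected to found each
#'   recombinant strain.
#' @param brood_size Maximum daughters (and sons) available per family.
#' @param chrom_lengths Named chromosome lengths in bp; `"X"` plus modelled
#'   autosome arms.
#' @param seed Optional integer seed recorded with the run.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_females_per_cross = 100,
                          n_backcross_generations = 4,
                          n_families_oviposited = 80,
                          n_larvae_genotyped_per_family = 10,
                          fixation_cross_generations = 2,
                          n_strain_founders = 50,
                          brood_size = 50,
                          chrom_lengths = c(X = 24.4e6, `2L` = 49.4e6),
                          seed = NULL) {
  cfg <- list(
    n_females_per_cross = n_females_per_cross,
    n_backcross_generations = n_backcross_generations,
    n_families_oviposited = n_families_oviposited,
    n_larvae_genotyped_per_family = n_larvae_genotyped_per_family,
    fixation_cross_generations = fixation_cross_generations,
    n_strain_founders = n_strain_founders,
    brood_size = brood_size,
    chrom_lengths = chrom_lengths,
    seed = seed
  )
  counts <- cfg[c("n_females_per_cross", "n_backcross_generations",
                  "n_families_oviposited", "n_larvae_genotyped_per_family",
                  "fixation_cross_generations", "n_strain_founders",
                  "brood_size")]
  if (any(unlist(counts) < 1)) abort("all design counts must be >= 1.")
  structure(cfg, class = "design_config")
}

#' Default recombination maps for a design
#'
#' One map per modelled chromosome: uniform `base_rate` everywhere except a
#' pericentromeric suppression window on X covering the island region,
#' where the rate is divided by `suppression_fold` (default 20, within the
#' 16--35 fold range reported for the X centromere).
#'
#' @param cfg A [design_config()].
#' @param base_rate Base crossover rate, cM/Mb.
#' @param suppression_window X window `c(start, end)` in bp; default the
#'   18.1 Mb--centromere island region.
#' @param suppression_fold Fold reduction inside the window.
#' @return Named list of [recomb_map()]s.
#' @export
design_maps <- function(cfg, base_rate = 1.5,
                        suppression_window = c(18.1e6, cfg$chrom_lengths[["X"]]),
                        suppression_fold = 20) {
  maps <- lapply(names(cfg$chrom_lengths), function(chr) {
    if (chr == "X") {
      recomb_map(cfg$chrom_lengths[[chr]], base_rate,
                 suppression_window, suppression_fold)
    } else {
      recomb_map(cfg$chrom_lengths[[chr]], base_rate)
    }
  })
  stats::setNames(maps, names(cfg$chrom_lengths))
}

# draw up to `n` offspring from a set of family (mother, father) pairs,
# cycling over families, honouring per-family brood caps
draw_from_families <- function(families, n, maps, sex = NULL, used = NULL,
                               brood_cap = Inf) {
  out <- vector("list", n)
  got <- 0L
  if (is.null(used)) used <- numeric(length(families))
  order_fam <- rep(seq_along(families), length.out = max(n * 2L, length(families)))
  i <- 1L
  while (got < n && i <= length(order_fam)) {
    f <- order_fam[i]
    if (used[f] < brood_cap) {
      fam <- families[[f]]
      got <- got + 1L
      out[[got]] <- make_offspring(fam$mother, fam$father, maps, sex = sex)
      used[f] <- used[f] + 1L
    }
    i <- i + 1L
  }
  list(offspring = out[seq_len(got)], used = used)
}

genotype_counts <- function(inds, pos) {
  g <- vapply(inds, genotype_at, character(1), pos = pos)
  tibble(
    n_MM = sum(g == "MM"), n_MS = sum(g == "MS"), n_SS = sum(g == "SS"),
    n_M = sum(g == "M"), n_S = sum(g == "S")
  )
}

#' Run the marker-assisted selective-introgression design
#'
#' Simulates the full breeding scheme: an initial cross of M males to SS
#' females, `n_backcross_generations` rounds in which MS hybrid females are
#' backcrossed to M males (families classified by genotyping larvae, pure
#' MM families discarded), then `fixation_cross_generations` rounds of
#' random mating within the introgressed strain, the last of which
#' contributes MM females/M males to the RbMM strain and SS females/S
#' males to the RbSS strain.
#'
#' @param cfg A [design_config()].
#' @param maps Named list of [recomb_map()]s, one per modelled chromosome;
#'   default [design_maps()].
#' @param panel A [marker_panel()]; its rDNA marker attribute gives the
#'   selection locus.
#' @return A list of class `introgression_sim` with elements `rbmm`,
#'   `rbss` (lists of founder individuals), `log` (per-generation tibble of
#'   genotype counts among genotyped larvae and families kept), `cfg`,
#'   `maps`, `panel`.
#' @examples
#' \donttest{
#' sim <- run_introgression_design(design_config(seed = 1))
#' tidy(sim)
#' }
#' @export
run_introgression_design <- function(cfg = design_config(),
                                     maps = design_maps(cfg),
                                     panel = marker_panel(chrom_lengths =
                                       cfg$chrom_lengths["X"])) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rdna <- attr(panel, "rdna_pos") %||% 24.3e6
  n_cross <- cfg$n_females_per_cross
  n_fam <- cfg$n_families_oviposited
  n_geno <- cfg$n_larvae_genotyped_per_family
  log_rows <- list()

  fresh_m_male <- function() founder("M", "M", cfg$chrom_lengths)

  # F0: M males x SS females -> all daughters MS, used as 1st backcross mothers
  ms_females <- lapply(seq_len(n_cross), function(i) {
    make_offspring(founder("S", "F", cfg$chrom_lengths), fresh_m_male(),
                   maps, sex = "F")
  })

  # Backcross generations: MS females x M males, family-level selection
  for (g in seq_len(cfg$n_backcross_generations)) {
    mothers <- ms_females[sample.int(length(ms_females),
                                     min(n_fam, length(ms_females)))]
    families <- lapply(mothers, function(m) list(mother = m, father = fresh_m_male()))
    larvae <- lapply(families, function(fam) {
      lapply(seq_len(n_geno), function(i) make_offspring(fam$mother, fam$father, maps))
    })
    mixed <- vapply(larvae, function(ls) {
      any(grepl("S", vapply(ls, genotype_at, character(1), pos = rdna)))
    }, logical(1))
    counts <- genotype_counts(unlist(larvae, recursive = FALSE), rdna)
    log_rows[[length(log_rows) + 1L]] <- mutate(
      counts, generation = paste0("backcross_", g),
      n_families = length(families), n_families_kept = sum(mixed),
      .before = 1L)
    if (!any(mixed)) {
      abort(sprintf(
        "MS families went extinct at backcross generation %d (families: %d, MS larvae: 0).",
        g, length(families)))
    }
    kept <- families[mixed]
    used <- vapply(larvae[mixed], function(ls) {
      sum(vapply(ls, function(x) x$sex == "F", logical(1)))
    }, numeric(1))
    # recruit the next generation of MS mothers from kept families
    next_ms <- list()
    while (length(next_ms) < n_cross) {
      dr <- draw_from_families(kept, n_cross, maps, sex = "F", used = used,
                               brood_cap = cfg$brood_size)
      used <- dr$used
      if (!length(dr$offspring)) break
      is_ms <- vapply(dr$offspring, function(d) genotype_at(d, rdna) == "MS",
                      logical(1))
      next_ms <- c(next_ms, dr$offspring[is_ms])
    }
    if (length(next_ms) < 1L) {
      abort(sprintf("no MS daughters recovered at backcross generation %d.", g))
    }
    ms_females <- next_ms[seq_len(min(n_cross, length(next_ms)))]
    last_kept <- kept; last_used <- used
  }

  # Fixation crosses: random mating within the introgressed strain
  pool_parents <- function(kept, used) {
    f <- draw_from_families(kept, n_cross, maps, sex = "F", used = used,
                            brood_cap = cfg$brood_size)
    m <- draw_from_families(kept, n_cross, maps, sex = "M", used = f$used,
                            brood_cap = cfg$brood_size)
    list(females = f$offspring, males = m$offspring)
  }
  parents <- pool_parents(last_kept, last_used)

  n_fix <- cfg$fixation_cross_generations
  for (g in seq_len(n_fix)) {
    if (!length(parents$females) || !length(parents$males)) {
      abort(sprintf("no parents available at fixation cross %d.", g))
    }
    idx_f <- sample.int(length(parents$females), min(n_fam, length(parents$females)))
    families <- lapply(idx_f, function(i) {
      list(mother = parents$females[[i]],
           father = parents$males[[sample.int(length(parents$males), 1L)]])
    })
    larvae <- lapply(families, function(fam) {
      lapply(seq_len(n_geno), function(i) make_offspring(fam$mother, fam$father, maps))
    })
    geno <- lapply(larvae, function(ls) vapply(ls, genotype_at, character(1), pos = rdna))
    mixed <- vapply(geno, function(gt) any(grepl("S", gt)) && any(grepl("M", gt)),
                    logical(1))
    counts <- genotype_counts(unlist(larvae, recursive = FALSE), rdna)
    log_rows[[length(log_rows) + 1L]] <- mutate(
      counts, generation = paste0("fixation_", g),
      n_families = length(families), n_families_kept = sum(mixed),
      .before = 1L)
    if (g < n_fix) {
      if (!any(mixed)) abort(sprintf("no mixed families at fixation cross %d.", g))
      used <- vapply(larvae[mixed], function(ls) {
        sum(vapply(ls, function(x) x$sex == "F", logical(1)))
      }, numeric(1))
      parents <- pool_parents(families[mixed], used)
    } else {
      # final generation: collect strain founders by genotype
      rbmm_f <- list(); rbmm_m <- list(); rbss_f <- list(); rbss_m <- list()
      used <- vapply(larvae, function(ls) length(ls), numeric(1))
      need <- function() {
        length(rbmm_f) < cfg$n_strain_founders ||
          length(rbmm_m) < cfg$n_strain_founders ||
          length(rbss_f) < cfg$n_strain_founders ||
          length(rbss_m) < cfg$n_strain_founders
      }
      # start from the genotyped larvae themselves, then draw more
      candidates <- unlist(larvae, recursive = FALSE)
      max_draws <- length(families) * cfg$brood_size * 2L
      drawn <- 0L
      while (TRUE) {
        for (ind in candidates) {
          gt <- genotype_at(ind, rdna)
          if (gt == "MM" && length(rbmm_f) < cfg$n_strain_founders) {
            rbmm_f[[length(rbmm_f) + 1L]] <- ind
          } else if (gt == "M" && length(rbmm_m) < cfg$n_strain_founders) {
            rbmm_m[[length(rbmm_m) + 1L]] <- ind
          } else if (gt == "SS" && length(rbss_f) < cfg$n_strain_founders) {
            rbss_f[[length(rbss_f) + 1L]] <- ind
          } else if (gt == "S" && length(rbss_m) < cfg$n_strain_founders) {
            rbss_m[[length(rbss_m) + 1L]] <- ind
          }
        }
        if (!need() || drawn >= max_draws) break
        dr <- draw_from_families(families, 200L, maps, used = used,
                                 brood_cap = cfg$brood_size * 2L)
        used <- dr$used
        if (!length(dr$offspring)) break
        drawn <- drawn + length(dr$offspring)
        candidates <- dr$offspring
      }
      if (need()) {
        warn(sprintf(
          "fewer strain founders than requested (RbMM %d F / %d M, RbSS %d F / %d M).",
          length(rbmm_f), length(rbmm_m), length(rbss_f), length(rbss_m)))
      }
      rbmm <- c(rbmm_f, rbmm_m)
      rbss <- c(rbss_f, rbss_m)
    }
  }

  structure(list(
    rbmm = rbmm, rbss = rbss,
    log = bind_rows(log_rows),
    cfg = cfg, maps = maps, panel = panel
  ), class = "introgression_sim")
}

#' @export
print.introgression_sim <- function(x, ...) {
  cat(sprintf("<introgression_sim> RbMM: %d founders, RbSS: %d founders\n",
              length(x$rbmm), length(x$rbss)))
  print(x$log)
  invisible(x)
}

#' @rdname run_introgression_design
#' @param x An `introgression_sim` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.introgression_sim <- function(x, ...) {
  mutate(x$log,
         ms_mm_ratio = ifelse(.data$n_MM > 0, .data$n_MS / .data$n_MM, NA_real_))
}

#' @rdname run_introgression_design
#' @exportS3Method generics::glance
glance.introgression_sim <- function(x, ...) {
  rdna <- attr(x$panel, "rdna_pos") %||% 24.3e6
  frac_s_at_rdna <- function(strain) {
    haps <- unlist(lapply(strain, function(i) i$x), recursive = FALSE)
    mean(vapply(haps, function(h) origin_at(h, rdna) == "S", logical(1)))
  }
  tibble(
    n_rbmm = length(x$rbmm), n_rbss = length(x$rbss),
    rbss_s_freq_at_marker = frac_s_at_rdna(x$rbss),
    rbmm_s_freq_at_marker = frac_s_at_rdna(x$rbmm),
    rbss_autosomal_s_fraction = mean_autosomal_s_fraction(x$rbss),
    n_generations = nrow(x$log)
  )
}
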
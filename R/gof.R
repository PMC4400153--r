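#' Likelihood-ratio (G) goodness-of-fit test
#'
#' The G statistic is `2 * sum(O * ln(O / E))` with expected counts
#' `E = N * p` and the convention `0 * ln(0) == 0`, compared to a
#' chi-square distribution on `k - 1` degrees of freedom. Zero observed
#' cells are legal; expected proportions are normalised internally, so
#' any positive rescaling of `expected_props` gives the same statistic.
#' No continuity correction is applied and no multiple-testing adjustment
#' is made.
#'
#' @param observed Non-negative integer counts, length `>= 2`.
#' @param expected_props Positive expected proportions (normalised to sum
#'   to one); default a uniform (e.g. 1:1) null.
#' @return A `gof_result`: list with `statistic`, `df`, `p_value`,
#'   `method`, `observed`, `expected`. Use [tidy()] for a one-row tibble.
#' @examples
#' g_test(c(29, 1))            # strongly assortative: G = 32.8
#' tidy(g_test(c(17, 8)))
#' @export
g_test <- function(observed, expected_props = rep(1, length(observed))) {
  check_gof_inputs(observed, expected_props)
  p <- expected_props / sum(expected_props)
  if (any(p == 0 & observed > 0)) {
    abort("expected proportion 0 with a positive observed count.")
  }
  n <- sum(observed)
  e <- n * p
  terms <- ifelse(observed == 0, 0, observed * log(observed / e))
  stat <- 2 * sum(terms)
  stat <- max(stat, 0)
  new_gof_result(stat, length(observed) - 1L, "likelihood_ratio", observed, e)
}

#' Pearson chi-square goodness-of-fit test
#'
#' `sum((O - E)^2 / E)` on `k - 1` degrees of freedom, uncorrected
#' (delegates to [stats::chisq.test()]).
#'
#' @inheritParams g_test
#' @return A `gof_result`.
#' @examples
#' pearson_test(c(29, 1))      # 26.13
#' @export
pearson_test <- function(observed, expected_props = rep(1, length(observed))) {
  check_gof_inputs(observed, expected_props)
  p <- expected_props / sum(expected_props)
  if (any(p == 0 & observed > 0)) {
    abort("expected proportion 0 with a positive observed count.")
  }
  ct <- suppressWarnings(chisq.test(observed, p = p, correct = FALSE))
  new_gof_result(unname(ct$statistic), unname(ct$parameter), "pearson",
                 observed, sum(observed) * p)
}

#' Test observed counts against a Mendelian ratio
#'
#' Convenience wrapper around [g_test()] for two-class Mendelian
#' expectations such as 1:1 (backcross MS/MM daughters) or 3:1.
#'
#' @param n_type1,n_type2 Observed counts of the two classes.
#' @param ratio Length-2 positive numeric, e.g. `c(1, 1)` or `c(3, 1)`.
#' @param method `"likelihood_ratio"` (default) or `"pearson"`.
#' @return A `gof_result`.
#' @examples
#' mendelian_ratio_test(36, 3)              # G = 32.9
#' mendelian_ratio_test(30, 10, c(3, 1))    # exact 3:1 fit: G = 0
#' @export
mendelian_ratio_test <- function(n_type1, n_type2, ratio = c(1, 1),
                                 method = c("likelihood_ratio", "pearson")) {
  method <- match.arg(method)
  if (length(ratio) != 2L || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers.")
  }
  fn <- if (method == "likelihood_ratio") g_test else pearson_test
  fn(c(n_type1, n_type2), ratio / sum(ratio))
}

#' Hardy-Weinberg expected genotype proportions
#'
#' For an allele at frequency `p`: females (or autosomal genotypes) follow
#' `(p^2, 2p(1-p), (1-p)^2)`; hemizygous males at an X-linked locus follow
#' `(p, 1-p)`.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @param x_linked Is the locus X-linked?
#' @param sex `"female"` or `"male"`; only relevant when `x_linked`.
#' @return Named numeric vector of genotype proportions.
#' @examples
#' hwe_expected_props(0.5)                     # 0.25, 0.5, 0.25
#' hwe_expected_props(0.2, TRUE, "male")       # 0.2, 0.8
#' @export
hwe_expected_props <- function(p, x_linked = FALSE, sex = "female") {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
  if (x_linked && sex == "male") {
    c(A = p, a = 1 - p)
  } else {
    c(AA = p^2, Aa = 2 * p * (1 - p), aa = (1 - p)^2)
  }
}

#' Summarise a mating assay table: per-replicate and pooled tests
#'
#' For each replicate row of a mating count table, a [g_test()] (or
#' [pearson_test()]) of the assortative/disassortative counts against a
#' 1:1 random-mating null; then, per mating combination, a pooled row
#' obtained by summing replicate counts, with percentages.
#'
#' @param table Tibble with columns `replicate`, `chooser`, `offered`,
#'   `n_assortative`, `n_disassortative` (see [read_mating_table()]).
#' @param method `"likelihood_ratio"` or `"pearson"`.
#' @param expected Length-2 expected ratio for (assortative,
#'   disassortative); default the 1:1 random-mating null.
#' @return A tibble with the input rows plus pooled `"both"` rows, and
#'   columns `pct_assortative`, `statistic`, `df`, `p_value`.
#' @examples
#' tab <- tibble::tibble(replicate = c(1, 2), chooser = "MM", offered = "M S",
#'                       n_assortative = c(29, 24), n_disassortative = c(1, 0))
#' summarize_assay(tab)
#' @export
summarize_assay <- function(table, method = c("likelihood_ratio", "pearson"),
                            expected = c(1, 1)) {
  method <- match.arg(method)
  fn <- if (method == "likelihood_ratio") g_test else pearson_test
  need <- c("replicate", "chooser", "offered", "n_assortative", "n_disassortative")
  if (!all(need %in% names(table))) {
    abort(sprintf("mating table must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  pooled <- table |>
    group_by(.data$chooser, .data$offered) |>
    summarise(n_assortative = sum(.data$n_assortative),
              n_disassortative = sum(.data$n_disassortative),
              .groups = "drop") |>
    mutate(replicate = "both")
  all_rows <- bind_rows(
    mutate(table, replicate = as.character(.data$replicate)),
    pooled
  )
  res <- purrr::pmap(
    list(all_rows$n_assortative, all_rows$n_disassortative),
    function(a, d) tidy(fn(c(a, d), expected))
  ) |> bind_rows()
  all_rows |>
    mutate(
      pct_assortative = 100 * .data$n_assortative /
        (.data$n_assortative + .data$n_disassortative),
      statistic = res$statistic, df = res$df, p_value = res$p.value,
      method = method
    )
}

check_gof_inputs <- function(observed, expected_props) {
  if (length(observed) != length(expected_props) || length(observed) < 2L) {
    abort("`observed` and `expected_props` must have equal length >= 2.")
  }
  if (any(observed < 0)) abort("negative observed counts.")
  if (sum(observed) == 0) abort("all observed counts are zero.")
  if (any(expected_props < 0) || sum(expected_props) == 0) {
    abort("expected proportions must be non-negative and not all zero.")
  }
}

new_gof_result <- function(statistic, df, method, observed, expected) {
  structure(list(
    statistic = statistic, df = df,
    p_value = pchisq(statistic, df, lower.tail = FALSE),
    method = method, observed = observed, expected = expected
  ), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  lbl <- if (x$method == "likelihood_ratio") "G" else "X-squared"
  cat(sprintf("%s goodness of fit: %s = %.1f, df = %d, p = %.3g\n",
              x$method, lbl, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname g_test
#' @param x A `gof_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gof_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = x$method)
}

#' @rdname g_test
#' @exportS3Method generics::glance
glance.gof_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = x$method, n = sum(x$observed), k = length(x$observed))
}
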
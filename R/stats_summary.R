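# Group-level statistics: two-tailed Mann-Whitney rank tests (exact for
# small samples, normal approximation with tie correction otherwise),
# per-group medians, taxon-by-category percentage summaries, and a
# confusion report against fixture ground truth.

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum U with midrank ties. For small samples (`min(n) <= 8`, and a
#' tractable number of group assignments) the two-tailed p-value is
#' computed by exact enumeration of the permutation distribution of U
#' conditional on the observed values, so identical groups yield exactly
#' p = 1. Larger samples use the normal approximation with tie and
#' continuity corrections. The p-value is reported rounded to four
#' decimals, the reporting convention of the source analyses.
#'
#' @param x,y numeric vectors (each non-empty; `NA` dropped).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses by sample size.
#' @param max_enum largest number of group assignments enumerated exactly.
#' @return list with `U` (statistic for the first group), `p.value`
#'   (rounded to 4 decimals), `p.unrounded` and `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL, max_enum = 5e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  do_exact <- if (!is.null(exact)) exact else {
    min(n1, n2) <= 8L && choose(n1 + n2, min(n1, n2)) <= max_enum
  }
  if (do_exact) {
    k <- min(n1, n2)
    idx <- combn(n1 + n2, k)
    # U of the smaller group under every assignment of ranks
    rk <- matrix(r[idx], nrow = k)
    u_small <- colSums(rk) - k * (k + 1) / 2
    mu <- n1 * n2 / 2
    u_obs_small <- if (n1 <= n2) u1 else n1 * n2 - u1
    p <- mean(abs(u_small - mu) >= abs(u_obs_small - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal approximation, tie + continuity correction"
  }
  list(U = u1, p.value = round(p, 4), p.unrounded = p, method = method)
}

#' Per-group medians of a metric
#'
#' Missing values (e.g. interface pAE when no interface was formed) are
#' dropped per group, never imputed.
#'
#' @param values numeric vector.
#' @param grouping factor/character of the same length.
#' @return data.frame: `group`, `n` (non-missing), `median` (`NA` when a
#'   group has no data).
#' @export
group_medians <- function(values, grouping) {
  grouping <- as.character(grouping)
  groups <- sort(unique(grouping))
  do.call(rbind, lapply(groups, function(g) {
    v <- values[grouping == g]
    v <- v[!is.na(v)]
    data.frame(group = g, n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Taxon-by-category percentage summary
#'
#' For each taxon group, the percentage of species in each category (the
#' heat-map summary: e.g. conserved / non-conserved / absent, or
#' interaction / no interaction). Rows sum to 100 within rounding. Groups
#' listed in `all_groups` but containing no species are reported with
#' `n = 0` and `NA` percentages (no data).
#'
#' @param categories named character vector: species -> category.
#' @param taxon_of named character vector: species -> taxon group.
#' @param all_groups optional group universe (adds empty "n.d." rows).
#' @param all_categories optional category universe (fixes the columns).
#' @return long data.frame: `taxon_group`, `category`, `n_species`,
#'   `n_group`, `percent`.
#' @export
taxon_heatmap <- function(categories, taxon_of, all_groups = NULL,
                          all_categories = NULL) {
  sp <- names(categories)
  if (is.null(sp)) stop("categories must be named by species")
  groups <- sort(unique(unname(taxon_of[sp])))
  if (!is.null(all_groups)) groups <- sort(unique(c(groups, all_groups)))
  cats <- sort(unique(unname(categories)))
  if (!is.null(all_categories)) cats <- sort(unique(c(cats, all_categories)))
  rows <- list()
  for (g in groups) {
    members <- sp[taxon_of[sp] == g]
    n_g <- length(members)
    for (cat in cats) {
      n_c <- sum(categories[members] == cat)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_group = g, category = cat, n_species = n_c, n_group = n_g,
        percent = if (n_g > 0L) 100 * n_c / n_g else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Confusion report of confident-interaction calls against ground truth
#'
#' Validates the scored pipeline on fixtures whose true interface presence
#' is known by construction.
#'
#' @param predicted logical vector: confident-interaction calls.
#' @param truth logical vector: fixture ground truth (true interface built
#'   with model-shared contacts).
#' @return list with counts `tp`, `fp`, `fn`, `tn`, `n`, and `accuracy`.
#' @export
classification_report <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth); tn <- sum(!predicted & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn, n = length(truth),
       accuracy = (tp + tn) / length(truth))
}
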
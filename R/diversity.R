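## Genotype-diversity statistics: distinct-genotype counts, rarefaction
## resampling to a common panel size, and bootstrap mean pairwise
## gene-content difference.

#' Count distinct gene-content genotypes
#'
#' A genotype is the presence/absence vector across the registry; two
#' individuals share a genotype only under exact vector equality.
#'
#' @param panel a [genotype_panel()].
#' @param unrelated_only restrict to the unrelated subset.
#' @return Integer count of unique genotypes.
#' @export
count_distinct_genotypes <- function(panel, unrelated_only = FALSE) {
  m <- panel_rows(panel, unrelated_only)
  if (nrow(m) == 0) stop("empty panel", call. = FALSE)
  nrow(unique(m, MARGIN = 1))
}

#' Rarefaction resampling of the distinct-genotype count
#'
#' Repeatedly draws `n` individuals (without replacement by default -
#' rarefaction, so panels of different sizes are compared at a common
#' `n`), counts distinct genotypes in each draw, and summarizes the
#' replicate counts by mean, standard deviation and a percentile 95%
#' confidence interval (2.5th-97.5th percentiles).
#'
#' @param panel a [genotype_panel()].
#' @param n subsample size (default 26, the size of an unrelated
#'   comparison panel). Must not exceed the panel (no extrapolation).
#' @param reps number of resamplings (default 5000).
#' @param seed integer seed; fixed seeds give bit-identical summaries.
#' @param unrelated_only restrict to the unrelated subset.
#' @param replace draw with replacement instead of rarefaction.
#' @return A `resample_summary` list: `mean`, `sd`, `ci_low`, `ci_high`,
#'   `reps`, `n`.
#' @export
resample_genotype_count <- function(panel, n = 26, reps = 5000, seed = 1L,
                                    unrelated_only = FALSE, replace = FALSE) {
  m <- panel_rows(panel, unrelated_only)
  if (!replace && n > nrow(m)) {
    stop("n exceeds panel size; rarefaction never extrapolates", call. = FALSE)
  }
  key <- apply(m, 1, paste, collapse = "")
  counts <- with_seed(seed, vapply(seq_len(reps), function(i) {
    length(unique(key[sample.int(length(key), n, replace = replace)]))
  }, 0L))
  q <- unname(stats::quantile(counts, c(0.025, 0.975)))
  structure(list(mean = mean(counts), sd = stats::sd(counts),
                 ci_low = q[1], ci_high = q[2],
                 reps = as.integer(reps), n = as.integer(n)),
            class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf("<resample_summary> n=%d reps=%d mean=%.3f sd=%.3f 95%% CI [%g, %g]\n",
              x$n, x$reps, x$mean, x$sd, x$ci_low, x$ci_high))
  invisible(x)
}

#' Bootstrap mean pairwise gene-content difference
#'
#' The point estimate is the mean Hamming distance (number of loci whose
#' presence differs) over all unordered pairs of individuals. Each locus
#' column is treated as a single polymorphic site and the bootstrap
#' resamples columns with replacement, recomputing the mean pairwise
#' distance per replicate; the standard error is the standard deviation
#' of the replicate means.
#'
#' @param panel a [genotype_panel()] with at least two individuals.
#' @param reps bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param unrelated_only restrict to the unrelated subset.
#' @return A `pairwise_diff_summary` list: `mean` (in loci units), `se`,
#'   `reps`.
#' @export
bootstrap_pairwise_difference <- function(panel, reps = 10000, seed = 1L,
                                          unrelated_only = FALSE) {
  m <- panel_rows(panel, unrelated_only)
  if (nrow(m) < 2) stop("need at least two individuals", call. = FALSE)
  mean_pairwise <- function(mm) {
    mean(stats::dist(mm, method = "manhattan"))
  }
  point <- mean_pairwise(m)
  L <- ncol(m)
  boot <- with_seed(seed, vapply(seq_len(reps), function(i) {
    mean_pairwise(m[, sample.int(L, L, replace = TRUE), drop = FALSE])
  }, 0))
  structure(list(mean = point, se = stats::sd(boot), reps = as.integer(reps)),
            class = "pairwise_diff_summary")
}

#' @export
print.pairwise_diff_summary <- function(x, ...) {
  cat(sprintf("<pairwise_diff_summary> mean=%.3f loci, se=%.3f (%d bootstrap reps)\n",
              x$mean, x$se, x$reps))
  invisible(x)
}
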
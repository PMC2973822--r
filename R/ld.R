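## Gene-content linkage disequilibrium on haplotype tables: pairing
## frequencies (observed vs expected under independence), Fisher exact
## tests on reconstructed haplotype counts, and association ratios
## relative to a reference gene.

## frequency-weighted presence frequency of one locus
presence_freq <- function(table, gene) {
  if (!gene %in% table$registry$loci) {
    stop("unknown locus: ", gene, call. = FALSE)
  }
  sum(table$frequency[table$haplotypes[, gene] == 1L])
}

#' Pairing frequency of two genes across haplotypes
#'
#' The observed pairing frequency is the total frequency of haplotypes on
#' which the two genes are either both present or both absent; the
#' expected value under random (independent) distribution is
#' `pA*pB + (1-pA)*(1-pB)` with `pA`, `pB` the frequency-weighted
#' presence frequencies.
#'
#' @param table a [haplotype_table()].
#' @param geneA,geneB locus names.
#' @param hap_count optional haplotype (chromosome) count; when given, a
#'   two-tailed Fisher exact test is run via [fisher_ld()].
#' @param alpha significance threshold for flagging LD (default 0.001).
#' @return A `pairing_result` list: `geneA`, `geneB`, `observed`,
#'   `expected`, and (with `hap_count`) `fisher_p` and `significant`.
#' @export
pairing_frequency <- function(table, geneA, geneB, hap_count = NULL,
                              alpha = 0.001) {
  f <- table$frequency
  a <- table$haplotypes[, {
    if (!geneA %in% table$registry$loci) stop("unknown locus: ", geneA, call. = FALSE)
    geneA
  }]
  b <- table$haplotypes[, {
    if (!geneB %in% table$registry$loci) stop("unknown locus: ", geneB, call. = FALSE)
    geneB
  }]
  observed <- sum(f[a == b])
  pA <- sum(f[a == 1L]); pB <- sum(f[b == 1L])
  expected <- pA * pB + (1 - pA) * (1 - pB)
  out <- list(geneA = geneA, geneB = geneB, observed = observed,
              expected = expected, fisher_p = NA_real_, significant = NA)
  if (!is.null(hap_count)) {
    out$fisher_p <- fisher_ld(table, geneA, geneB, hap_count)
    out$significant <- out$fisher_p < alpha
  }
  structure(out, class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("<pairing_result> %s-%s observed=%.3f expected=%.3f",
              x$geneA, x$geneB, x$observed, x$expected))
  if (!is.na(x$fisher_p)) {
    cat(sprintf(" Fisher p=%.3g%s", x$fisher_p,
                if (isTRUE(x$significant)) " *" else ""))
  }
  cat("\n")
  invisible(x)
}

#' Two-tailed Fisher exact p-value for a 2x2 table of counts
#'
#' The two-tailed value sums the probabilities of all tables with the
#' observed margins whose point (hypergeometric) probability does not
#' exceed that of the observed table. A zero margin makes every table
#' compatible with the margins equally likely and the p-value is 1 (with
#' a warning).
#'
#' @param counts 2x2 integer matrix.
#' @return p-value in (0, 1].
#' @export
fisher_two_tailed <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("zero marginal in 2x2 table; p-value defined as 1")
    return(1.0)
  }
  stats::fisher.test(counts, alternative = "two.sided")$p.value
}

#' Fisher exact test of gene-content LD on a haplotype table
#'
#' Haplotype frequencies are scaled to `hap_count` chromosomes (largest-
#' remainder rounding, so cell counts always total `hap_count`) to form
#' the 2x2 presence/absence table of the two genes, which is tested with
#' a two-tailed Fisher exact test.
#'
#' @param table a [haplotype_table()].
#' @param geneA,geneB locus names.
#' @param hap_count number of chromosomes (2N for a diploid panel).
#' @return p-value in (0, 1].
#' @export
fisher_ld <- function(table, geneA, geneB, hap_count) {
  for (g in c(geneA, geneB)) {
    if (!g %in% table$registry$loci) stop("unknown locus: ", g, call. = FALSE)
  }
  f <- table$frequency
  a <- table$haplotypes[, geneA]; b <- table$haplotypes[, geneB]
  cell <- c(sum(f[a == 1 & b == 1]), sum(f[a == 1 & b == 0]),
            sum(f[a == 0 & b == 1]), sum(f[a == 0 & b == 0]))
  counts <- matrix(apportion_counts(cell, hap_count), 2, 2, byrow = TRUE)
  fisher_two_tailed(counts)
}

#' Association ratios of every gene with a reference gene
#'
#' For each non-reference gene `g`, the ratio
#' `P(g present | reference present) / P(g present | reference absent)`
#' with haplotype-frequency weighting - the conditioning normalizes for
#' the difference in frequency between reference-positive and
#' reference-negative haplotypes. A gene found only with the reference
#' has ratio `Inf`, labelled `"AL"` (absolute linkage); a gene on no
#' haplotype has an undefined ratio (`NaN`). Declared absolute-linkage
#' `constraints` (pairs of loci) are enforced before computation: both
#' members are set present wherever either is, and affected genes are
#' flagged so their ratios can be reported in parentheses.
#'
#' @param table a [haplotype_table()].
#' @param reference reference locus; must be segregating (present on some
#'   haplotype mass and absent on some).
#' @param constraints optional list of length-2 character vectors.
#' @return A `data.frame`: `gene`, `ratio`, `label` (`"AL"`, `"undefined"`
#'   or the formatted ratio), `constrained`, plus attributes `n_ref_pos`
#'   and `n_ref_neg` (haplotype mass on each reference background).
#' @export
association_ratios <- function(table, reference, constraints = NULL) {
  reg <- table$registry
  if (!reference %in% reg$loci) stop("unknown locus: ", reference, call. = FALSE)
  H <- table$haplotypes
  flagged <- character(0)
  for (pc in constraints) {
    if (length(pc) != 2 || !all(pc %in% reg$loci)) {
      stop("constraints must be pairs of registry loci", call. = FALSE)
    }
    both <- (H[, pc[1]] | H[, pc[2]]) * 1L
    H[, pc[1]] <- both; H[, pc[2]] <- both
    flagged <- union(flagged, pc)
  }
  f <- table$frequency
  ref <- H[, reference]
  mass_pos <- sum(f[ref == 1]); mass_neg <- sum(f[ref == 0])
  if (mass_pos == 0 || mass_neg == 0) {
    stop("reference locus is fixed ", if (mass_pos == 0) "absent" else "present",
         " across haplotypes", call. = FALSE)
  }
  genes <- setdiff(reg$loci, reference)
  res <- lapply(genes, function(g) {
    p_pos <- sum(f[ref == 1 & H[, g] == 1]) / mass_pos
    p_neg <- sum(f[ref == 0 & H[, g] == 1]) / mass_neg
    if (p_neg == 0 && p_pos > 0) {
      list(ratio = Inf, label = "AL")
    } else if (p_neg == 0 && p_pos == 0) {
      list(ratio = NaN, label = "undefined")
    } else {
      r <- p_pos / p_neg
      list(ratio = r, label = format(round(r, 2)))
    }
  })
  out <- data.frame(gene = genes,
                    ratio = vapply(res, function(x) x$ratio, 0),
                    label = vapply(res, function(x) x$label, ""),
                    constrained = genes %in% flagged,
                    stringsAsFactors = FALSE)
  attr(out, "n_ref_pos") <- mass_pos
  attr(out, "n_ref_neg") <- mass_neg
  out
}

#' All-pairs LD table
#'
#' Convenience wrapper computing [pairing_frequency()] (and optionally
#' [fisher_ld()]) for every unordered locus pair.
#'
#' @param table a [haplotype_table()].
#' @param hap_count optional chromosome count enabling Fisher tests.
#' @param alpha significance threshold (default 0.001).
#' @return A `data.frame` with one row per pair.
#' @export
ld_table <- function(table, hap_count = NULL, alpha = 0.001) {
  loci <- table$registry$loci
  prs <- utils::combn(loci, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    pr <- pairing_frequency(table, prs[1, i], prs[2, i],
                            hap_count = hap_count, alpha = alpha)
    data.frame(geneA = pr$geneA, geneB = pr$geneB, observed = pr$observed,
               expected = pr$expected, fisher_p = pr$fisher_p,
               significant = pr$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
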
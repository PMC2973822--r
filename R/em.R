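## EM estimation of haplotype frequencies from presence/absence
## genotypes.
##
## A presence/absence genotype is the locus-wise OR of the individual's
## two haplotypes, so the likelihood of a genotype g under haplotype
## frequencies f is
##     P(g) = sum over unordered pairs (h1, h2) with h1 OR h2 = g of
##            f(h1) f(h2) (2 - delta(h1 == h2)),
## the Hardy-Weinberg random-pairing model.  The E-step assigns each
## individual posterior responsibilities over its compatible pairs; the
## M-step sets each haplotype's frequency to half its expected dosage per
## individual.  The log-likelihood is non-decreasing at every iteration.

#' Enumerate candidate haplotypes compatible with a panel
#'
#' The candidate set is the union over individuals of all presence
#' vectors `v` with `v <= genotype` locus-wise (every such `v` can serve
#' as one half of a pair whose OR is the genotype, its partner being the
#' genotype itself). The empty haplotype (framework only, no variable
#' gene) is always included. Enumeration stops with an error when the
#' candidate count exceeds `cap`.
#'
#' @param panel a [genotype_panel()].
#' @param cap maximum candidate count (default 4096).
#' @param unrelated_only restrict to the unrelated subset.
#' @return Integer 0/1 matrix of candidates (rows) by loci.
#' @export
enumerate_candidate_haplotypes <- function(panel, cap = 4096,
                                           unrelated_only = FALSE) {
  m <- panel_rows(panel, unrelated_only)
  L <- ncol(m)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (i in seq_len(nrow(m))) {
    pres <- which(m[i, ] == 1L)
    k <- length(pres)
    if (k > 25) stop("genotype with ", k, " present loci: candidate space too large",
                     call. = FALSE)
    for (mask in 0:(2^k - 1)) {
      v <- integer(L)
      if (k > 0) v[pres[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]] <- 1L
      key <- paste(v, collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- v
        if (length(out) > cap) {
          stop("candidate count exceeds cap (", cap,
               "); restrict loci or supply candidates", call. = FALSE)
        }
      }
    }
  }
  cand <- do.call(rbind, out)
  colnames(cand) <- colnames(m)
  rownames(cand) <- paste0("H", seq_len(nrow(cand)))
  cand
}

#' EM haplotype-frequency estimation from presence/absence genotypes
#'
#' Maximum-likelihood haplotype frequencies under the OR-genotype
#' random-pairing model (see the package vignette). Initialization is
#' uniform over candidates, so the fit is deterministic. Convergence is
#' declared when the largest frequency change in one iteration falls
#' below `tol`.
#'
#' Presence/absence genotypes can leave frequency combinations
#' non-identifiable (different pools implying identical genotype
#' distributions); candidates along such flat directions are reported in
#' `flat` when perturbing their frequency changes the log-likelihood by
#' less than `1e-6` (a curvature heuristic, not a formal test).
#'
#' @param panel a [genotype_panel()].
#' @param candidates optional candidate matrix (rows = presence vectors);
#'   default [enumerate_candidate_haplotypes()].
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter maximum EM iterations (default 10000).
#' @param cap candidate cap when enumerating (default 4096).
#' @param unrelated_only restrict to the unrelated subset.
#' @return An `em_result` list: `table` (a [haplotype_table()]), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `flat`.
#' @export
em_frequencies <- function(panel, candidates = NULL, tol = 1e-8,
                           max_iter = 10000, cap = 4096,
                           unrelated_only = FALSE) {
  m <- panel_rows(panel, unrelated_only)
  if (is.null(candidates)) {
    candidates <- enumerate_candidate_haplotypes(panel, cap = cap,
                                                 unrelated_only = unrelated_only)
  } else {
    candidates <- as.matrix(candidates)
    storage.mode(candidates) <- "integer"
    if (ncol(candidates) != ncol(m)) {
      stop("candidates must span the registry loci", call. = FALSE)
    }
    if (is.null(rownames(candidates))) {
      rownames(candidates) <- paste0("H", seq_len(nrow(candidates)))
    }
  }
  K <- nrow(candidates)
  n <- nrow(m)

  ## unique genotype patterns with multiplicities
  key <- apply(m, 1, paste, collapse = "")
  pat_key <- unique(key)
  pat_n <- as.numeric(table(key)[pat_key])
  pats <- m[match(pat_key, key), , drop = FALSE]

  ## compatible unordered candidate pairs per pattern
  pairs <- vector("list", length(pat_key))
  for (p in seq_along(pat_key)) {
    g <- pats[p, ]
    sub <- which(apply(candidates, 1, function(v) all(v <= g)))
    pl <- list()
    for (ii in seq_along(sub)) {
      for (jj in ii:length(sub)) {
        h1 <- sub[ii]; h2 <- sub[jj]
        if (all((candidates[h1, ] | candidates[h2, ]) == g)) {
          pl[[length(pl) + 1L]] <- c(h1, h2)
        }
      }
    }
    if (length(pl) == 0) {
      offender <- panel$individuals[match(pat_key[p], key)]
      stop("genotype of individual '", offender,
           "' is not expressible as OR of any candidate pair", call. = FALSE)
    }
    pairs[[p]] <- do.call(rbind, pl)
  }

  ## flatten pairs across patterns for vectorized E/M steps
  i1 <- unlist(lapply(pairs, function(pr) pr[, 1]))
  i2 <- unlist(lapply(pairs, function(pr) pr[, 2]))
  pid <- rep(seq_along(pairs), vapply(pairs, nrow, 0L))
  het <- ifelse(i1 == i2, 1, 2)

  loglik_of <- function(f) {
    w <- f[i1] * f[i2] * het
    tot <- as.numeric(rowsum(w, pid))
    sum(pat_n * log(tot))
  }

  f <- rep(1 / K, K)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- f[i1] * f[i2] * het
    tot <- as.numeric(rowsum(w, pid))
    trace <- c(trace, sum(pat_n * log(tot)))
    r <- w / tot[pid] * pat_n[pid]
    cn <- rowsum(c(r, r), c(i1, i2))
    counts <- numeric(K)
    counts[as.integer(rownames(cn))] <- cn
    f_new <- counts / (2 * n)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  loglik <- loglik_of(f)

  ## curvature heuristic for flat (non-identifiable) directions
  flat <- character(0)
  eps <- 1e-4
  for (h in which(f > eps)) {
    f_pert <- f
    f_pert[h] <- f_pert[h] - eps
    f_pert <- f_pert + eps / K
    f_pert <- f_pert / sum(f_pert)
    if (abs(loglik_of(f_pert) - loglik) < 1e-6) {
      flat <- c(flat, rownames(candidates)[h])
    }
  }

  keep <- f > 1e-9
  tab <- haplotype_table(candidates[keep, , drop = FALSE],
                         f[keep] / sum(f[keep]), panel$registry,
                         names = rownames(candidates)[keep])
  structure(list(table = tab, loglik = loglik, loglik_trace = trace,
                 n_iter = iter, converged = converged, flat = flat),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("<em_result> %d haplotypes, loglik=%.4f, %d iterations (%s)\n",
              nrow(x$table$haplotypes), x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$flat)) {
    cat("  flat (possibly non-identifiable) directions:",
        paste(x$flat, collapse = ", "), "\n")
  }
  invisible(x)
}
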
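## Independent oracles used across the suite. These deliberately avoid
## the code paths they check: brute-force enumeration, closed forms, and
## definitional formulas only.

## two-tailed Fisher p by explicit hypergeometric enumeration over all
## tables with the observed margins
oracle_fisher_two_tailed <- function(counts) {
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## exhaustive small-parsimony: minimum changes over all internal
## labelings; also per-transition count ranges among minimal labelings
oracle_parsimony <- function(tree, states, alphabet = sort(unique(states))) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  e <- tree$edge
  internal <- (ntip + 1):nnode
  S <- length(alphabet)
  grids <- expand.grid(rep(list(seq_len(S)), length(internal)))
  lab <- rep(NA_integer_, nnode)
  lab[seq_len(ntip)] <- match(states[tree$tip.label], alphabet)
  best <- Inf
  trans_min <- matrix(Inf, S, S); trans_max <- matrix(-Inf, S, S)
  for (row in seq_len(nrow(grids))) {
    lab[internal] <- as.integer(grids[row, ])
    changes <- lab[e[, 1]] != lab[e[, 2]]
    sc <- sum(changes)
    if (sc < best) {
      best <- sc
      trans_min[] <- Inf; trans_max[] <- -Inf
    }
    if (sc == best) {
      tc <- matrix(0L, S, S)
      if (any(changes)) {
        fr <- lab[e[changes, 1]]; to <- lab[e[changes, 2]]
        for (k in seq_along(fr)) tc[fr[k], to[k]] <- tc[fr[k], to[k]] + 1L
      }
      trans_min <- pmin(trans_min, tc)
      trans_max <- pmax(trans_max, tc)
    }
  }
  dimnames(trans_min) <- dimnames(trans_max) <- list(alphabet, alphabet)
  list(score = best, trans_min = trans_min, trans_max = trans_max)
}

## total-variation distance between two frequency sets keyed by
## presence-vector string
tv_distance <- function(tab_a, tab_b) {
  key_a <- apply(tab_a$haplotypes, 1, paste, collapse = "")
  key_b <- apply(tab_b$haplotypes, 1, paste, collapse = "")
  keys <- union(key_a, key_b)
  fa <- setNames(numeric(length(keys)), keys)
  fb <- fa
  fa[key_a] <- tab_a$frequency
  fb[key_b] <- tab_b$frequency
  sum(abs(fa - fb)) / 2
}

## random haplotype table over `L` loci with `k` haplotypes
random_haplotype_table <- function(L, k, seed) {
  reg <- locus_registry(paste0("L", seq_len(L)))
  kircontent:::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(k * L, 1, 0.5), k, L)
      if (!anyDuplicated(apply(m, 1, paste, collapse = ""))) break
    }
    f <- rgamma(k, 1); f <- f / sum(f)
  })
  haplotype_table(m, f, reg)
}

## random tip-state tree: ape::rtree topology with iid tip states
random_tip_state_tree <- function(ntips, n_states = 2, seed = 1) {
  kircontent:::with_seed(seed, {
    tr <- ape::rtree(ntips)
    st <- sample(letters[seq_len(n_states)], ntips, replace = TRUE)
  })
  tip_state_tree(tr, setNames(st, tr$tip.label))
}
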
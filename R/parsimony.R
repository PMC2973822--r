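## Sankoff small parsimony with unit costs, plus exact per-transition
## change-count ranges over all most-parsimonious reconstructions (MPRs).
##
## Unit-cost Sankoff handles polytomies and arbitrary state alphabets
## natively.  Because the subtree cost decomposes as
##   cost[v][s] = sum over children c of min_t ( cost[c][t] + [s != t] ),
## the set of MPRs is exactly the set of assignments in which every
## child's state attains that local minimum given its parent's state.
## Counts of a given transition (a -> b) are additive over edges, so
## their minimum and maximum over all MPRs can be computed by a second
## dynamic program over the same recursion, with no enumeration - the
## ranges are exact at any tree size.

## children list indexed by ape node number, from a postorder edge matrix
children_of <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ch <- vector("list", nnode)
  e <- tree$edge
  for (i in seq_len(nrow(e))) ch[[e[i, 1]]] <- c(ch[[e[i, 1]]], e[i, 2])
  ch
}

## postorder node sequence (children before parents)
postorder_nodes <- function(tree) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  unique(c(e[, 2], e[nrow(e), 1]))
}

#' Minimum state changes on a tree (Sankoff parsimony)
#'
#' Computes the unit-cost parsimony score for a single character on a
#' tree, one chosen most-parsimonious internal-state assignment, and for
#' every ordered state pair the exact minimum and maximum number of
#' edges carrying that transition over all most-parsimonious
#' reconstructions. Directional attribution varies between MPRs, so the
#' per-transition ranges - not a single number - are the honest summary;
#' the range minimum matches "at least k events" phrasing.
#'
#' @param x a [tip_state_tree()].
#' @param root_state optional state to fix at the root. If it is
#'   incompatible with every most-parsimonious reconstruction the
#'   incompatibility is reported (warning + `root_state_ok = FALSE`) and
#'   the unconstrained optimum is used instead of forcing it.
#' @return A `change_count` list: `min_changes`, `per_transition`
#'   (data frame `from`, `to`, `min`, `max`), `reconstruction` (named
#'   state vector over all nodes, tips first), `root_state_ok`.
#' @export
parsimony_changes <- function(x, root_state = NULL) {
  stopifnot(inherits(x, "tip_state_tree"))
  tree <- x$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- sort(unique(unname(x$states)))
  if (!is.null(root_state)) states <- sort(unique(c(states, root_state)))
  S <- length(states)
  ch <- children_of(tree)
  post <- postorder_nodes(tree)

  ## Sankoff DP
  cost <- matrix(Inf, nnode, S, dimnames = list(NULL, states))
  for (i in seq_len(ntip)) cost[i, x$states[tree$tip.label[i]]] <- 0
  for (v in post) {
    if (v <= ntip) next
    acc <- numeric(S)
    for (c_ in ch[[v]]) {
      ## min over t of cost[c][t] + (s != t), for each s
      mn <- min(cost[c_, ])
      acc <- acc + pmin(cost[c_, ], mn + 1)
    }
    cost[v, ] <- acc
  }
  unconstrained <- min(cost[root, ])
  root_states <- states[cost[root, ] == unconstrained]
  root_state_ok <- TRUE
  if (!is.null(root_state)) {
    if (cost[root, root_state] == unconstrained) {
      root_states <- root_state
    } else {
      warning("root_state '", root_state,
              "' is incompatible with every most-parsimonious reconstruction; ",
              "using the unconstrained optimum")
      root_state_ok <- FALSE
    }
  }
  min_changes <- as.integer(unconstrained)

  ## local argmin sets: admissible child states given parent state
  admissible <- function(c_, s_idx) {
    tot <- cost[c_, ] + (seq_len(S) != s_idx)
    which(tot == min(tot))
  }

  ## one reconstruction: prefer keeping the parent's state on ties
  recon <- rep(NA_character_, nnode)
  root_idx <- match(root_states[1], states)
  recon[root] <- states[root_idx]
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1]; c_ <- pre[i, 2]
    s_idx <- match(recon[par], states)
    adm <- admissible(c_, s_idx)
    pick <- if (s_idx %in% adm) s_idx else adm[1]
    recon[c_] <- states[pick]
  }
  names(recon) <- c(tree$tip.label, paste0("node", (ntip + 1):nnode))

  ## exact per-transition [min, max] over MPRs: bi-criteria DP.
  ## g[v, s] = extreme count of (a -> b) edges in the subtree of v among
  ## assignments where v has state s and the subtree attains cost[v, s].
  transition_range <- function(a_idx, b_idx, maximize) {
    g <- matrix(0, nnode, S)
    opt <- if (maximize) max else min
    for (v in post) {
      if (v <= ntip) next
      for (s_idx in seq_len(S)) {
        if (!is.finite(cost[v, s_idx])) next
        tot <- 0
        for (c_ in ch[[v]]) {
          adm <- admissible(c_, s_idx)
          contrib <- g[c_, adm] +
            as.numeric(s_idx == a_idx & adm == b_idx & s_idx != b_idx)
          ## tips have g = 0; transition counted when edge is a -> b
          tot <- tot + opt(contrib)
        }
        g[v, s_idx] <- tot
      }
    }
    opt(g[root, match(root_states, states)])
  }

  prs <- expand.grid(from = seq_len(S), to = seq_len(S))
  prs <- prs[prs$from != prs$to, , drop = FALSE]
  per <- data.frame(from = states[prs$from], to = states[prs$to],
                    min = rep(NA_integer_, nrow(prs)),
                    max = rep(NA_integer_, nrow(prs)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(prs))) {
    per$min[i] <- as.integer(transition_range(prs$from[i], prs$to[i], FALSE))
    per$max[i] <- as.integer(transition_range(prs$from[i], prs$to[i], TRUE))
  }

  structure(list(min_changes = min_changes, per_transition = per,
                 reconstruction = recon, root_state_ok = root_state_ok),
            class = "change_count")
}

#' @export
print.change_count <- function(x, ...) {
  cat("<change_count> minimum changes:", x$min_changes, "\n")
  shown <- x$per_transition[x$per_transition$max > 0, , drop = FALSE]
  if (nrow(shown)) {
    cat("  transitions over MPRs (min-max):\n")
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("    %s -> %s: %d-%d\n", shown$from[i], shown$to[i],
                  shown$min[i], shown$max[i]))
    }
  }
  invisible(x)
}

#' Count gains and losses of a derived state
#'
#' Ranges, over most-parsimonious reconstructions, of the number of
#' `ancestral -> derived` edges (gains) and `derived -> ancestral` edges
#' (losses, i.e. reversions), optionally with the root fixed to the
#' ancestral state.
#'
#' @param x a [tip_state_tree()].
#' @param ancestral,derived single-character states.
#' @param root_state optional root constraint, typically `ancestral`.
#' @return A list: `gains = c(min, max)`, `losses = c(min, max)`,
#'   `min_changes`, `root_state_ok`.
#' @export
count_reversions <- function(x, ancestral, derived, root_state = NULL) {
  cc <- parsimony_changes(x, root_state = root_state)
  pick <- function(fr, to) {
    row <- cc$per_transition[cc$per_transition$from == fr &
                             cc$per_transition$to == to, ]
    if (nrow(row) == 0) c(min = 0L, max = 0L)
    else c(min = row$min, max = row$max)
  }
  list(gains = pick(ancestral, derived), losses = pick(derived, ancestral),
       min_changes = cc$min_changes, root_state_ok = cc$root_state_ok)
}
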
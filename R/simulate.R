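## Synthetic-data generators.
##
## The generators emulate the statistical structure the downstream
## analyses assume: a chimpanzee-style haplotype pool built from
## independently present centromeric units with forced co-occurrence of
## strongly linked pairs; a human-style pool built as the cross product of
## centromeric and telomeric gene-content motifs; Hardy-Weinberg pairing
## of haplotypes into presence/absence genotypes; population frequency
## tables; and tip states produced by substitution events placed on tree
## edges.

#' Haplotype-pool specification
#'
#' Describes how synthetic gene-content haplotypes are assembled.
#'
#' In `"chimp"` mode, haplotypes are combinations of recombination units:
#' each unit (one or more loci that travel together) is independently
#' present with its own probability, and `pair_constraints` list locus
#' pairs in absolute linkage - unit combinations separating such a pair
#' are discarded and the distribution renormalized. The default of seven
#' units with two of them multi-locus mirrors a centromeric interval whose
#' diversity derives from asymmetric recombination between seven units,
#' three of which are high-LD gene pairs.
#'
#' In `"human"` mode, a haplotype is one centromeric motif combined with
#' one telomeric motif; motif frequencies multiply, mirroring a locus
#' whose diversity derives from recombination between independently
#' assorting centromeric and telomeric gene-content motifs.
#'
#' @param mode `"chimp"` or `"human"`.
#' @param registry a [locus_registry()] naming every locus used below.
#' @param units (`"chimp"`) named list; each element is
#'   `list(loci = <character>, prob = <presence probability>)`.
#' @param pair_constraints (`"chimp"`) list of length-2 character vectors:
#'   locus pairs forced to co-occur.
#' @param cen_motifs,tel_motifs (`"human"`) named lists of
#'   `list(loci = <character>, freq = <motif frequency>)`; frequencies
#'   must sum to 1 within each region. `loci` gives the loci present on
#'   the motif (possibly none).
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(mode = c("chimp", "human"), registry,
                      units = NULL, pair_constraints = list(),
                      cen_motifs = NULL, tel_motifs = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "locus_registry"))
  check_loci <- function(loci, what) {
    bad <- setdiff(loci, registry$loci)
    if (length(bad)) stop(what, " references unknown locus: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (mode == "chimp") {
    if (is.null(units) || length(units) == 0) {
      stop("chimp-like spec needs a non-empty unit list", call. = FALSE)
    }
    for (u in units) {
      check_loci(u$loci, "unit")
      assert_prob(u$prob, "unit presence probability")
    }
    for (pc in pair_constraints) {
      if (length(pc) != 2) stop("pair constraints are locus pairs", call. = FALSE)
      check_loci(pc, "pair constraint")
    }
  } else {
    for (m in c(cen_motifs, tel_motifs)) check_loci(m$loci, "motif")
    for (side in list(cen = cen_motifs, tel = tel_motifs)) {
      if (is.null(side) || length(side) == 0) {
        stop("human-like spec needs motifs for both regions", call. = FALSE)
      }
      f <- vapply(side, function(m) m$freq, 0)
      assert_prob(f, "motif frequencies")
      if (abs(sum(f) - 1) > 1e-6) {
        stop("motif frequencies must sum to 1 within each region", call. = FALSE)
      }
    }
  }
  structure(list(mode = mode, registry = registry, units = units,
                 pair_constraints = pair_constraints,
                 cen_motifs = cen_motifs, tel_motifs = tel_motifs),
            class = "pool_spec")
}

#' Default chimpanzee-style pool specification
#'
#' A 14-marker registry (2 framework loci, 2 markers of a conserved
#' fused-gene region, and 10 variable loci grouped into five centromeric
#' pairs) with seven variable recombination units: three high-LD pairs
#' kept in absolute linkage and the individual genes of the two remaining
#' pairs. Unit presence probabilities follow the observed gradient:
#' intermediate for the outermost pair, high for the central units, low
#' for the last pair.
#'
#' @return A [pool_spec()] in `"chimp"` mode.
#' @export
chimp_pool_spec <- function() {
  loci <- c("3DL3", "2DL4",                       # framework
            "2DS4", "2DL9",                       # pair 1 (high LD)
            "2DL6", "3DL4",                       # pair 2
            "2DL8", "2DL5",                       # pair 3 (absolute LD)
            "3DL1.2a", "3DL1.2b",                 # fused-gene region markers (conserved)
            "2DL7", "3DL5",                       # pair 4
            "3DS2", "3DS6")                       # pair 5 (high LD)
  fw <- c("3DL3", "2DL4", "3DL1.2a", "3DL1.2b")
  reg <- locus_registry(loci, region = c(
    stats::setNames(rep("framework", 4), fw),
    stats::setNames(rep("centromeric", 10), setdiff(loci, fw))))
  units <- list(
    framework = list(loci = fw, prob = 1.0),
    pair1     = list(loci = c("2DS4", "2DL9"), prob = 0.35),
    pair2a    = list(loci = "2DL6",  prob = 0.70),
    pair2b    = list(loci = "3DL4",  prob = 0.75),
    pair3     = list(loci = c("2DL8", "2DL5"), prob = 0.80),
    pair4a    = list(loci = "2DL7",  prob = 0.65),
    pair4b    = list(loci = "3DL5",  prob = 0.60),
    pair5     = list(loci = c("3DS2", "3DS6"), prob = 0.15))
  pool_spec("chimp", reg, units = units,
            pair_constraints = list(c("2DL8", "2DL5")))
}

#' Default human-style pool specification
#'
#' Two-region motif pools in the style of the human A/B haplotype groups:
#' centromeric motifs distinguished by 2DL2/2DL3 and 2DS2, telomeric
#' motifs distinguished by 2DS4 (A-style) versus 3DS1/2DL5/2DS1 (B-style),
#' on a framework of 3DL3, 2DL4 and 3DL2.
#'
#' @return A [pool_spec()] in `"human"` mode.
#' @export
human_pool_spec <- function() {
  loci <- c("3DL3", "2DS2", "2DL2", "2DL3", "2DL1", "2DL4",
            "3DL1", "3DS1", "2DL5", "2DS1", "2DS4", "3DL2")
  reg <- locus_registry(loci, region = c(
    "3DL3" = "framework", "2DL4" = "framework", "3DL2" = "framework",
    "2DS2" = "centromeric", "2DL2" = "centromeric", "2DL3" = "centromeric",
    "2DL1" = "centromeric",
    "3DL1" = "telomeric", "3DS1" = "telomeric", "2DL5" = "telomeric",
    "2DS1" = "telomeric", "2DS4" = "telomeric"))
  fw <- c("3DL3", "2DL4", "3DL2")
  cen <- list(
    cenA = list(loci = c("2DL3", "2DL1"), freq = 0.60),
    cenB1 = list(loci = c("2DS2", "2DL2", "2DL1"), freq = 0.30),
    cenB2 = list(loci = c("2DS2", "2DL2"), freq = 0.10))
  tel <- list(
    telA = list(loci = c("3DL1", "2DS4"), freq = 0.55),
    telB = list(loci = c("3DS1", "2DL5", "2DS1"), freq = 0.35),
    telAB = list(loci = c("3DL1", "2DL5", "2DS1", "2DS4"), freq = 0.10))
  ## framework loci ride on every centromeric motif
  cen <- lapply(cen, function(m) { m$loci <- union(m$loci, fw); m })
  pool_spec("human", reg, cen_motifs = cen, tel_motifs = tel)
}

vec_from_loci <- function(loci, registry) {
  as.integer(registry$loci %in% loci)
}

#' Simulate a haplotype pool from a specification
#'
#' By default the pool is computed exactly: in chimp-like mode every unit
#' combination is enumerated with its product probability and
#' combinations violating a pair constraint are dropped (the remainder
#' renormalized); in human-like mode the centromeric x telomeric cross
#' product is formed with product frequencies. Identical presence vectors
#' are merged with summed frequencies. With `n_draws`, a Monte Carlo pool
#' of that many sampled haplotypes is returned instead (frequencies =
#' sample proportions), using `seed`.
#'
#' @param spec a [pool_spec()].
#' @param seed integer seed (used only when `n_draws` is given).
#' @param n_draws optional number of Monte Carlo haplotype draws.
#' @return A [haplotype_table()].
#' @export
simulate_haplotype_pool <- function(spec, seed = 1L, n_draws = NULL) {
  stopifnot(inherits(spec, "pool_spec"))
  reg <- spec$registry
  if (spec$mode == "chimp") {
    k <- length(spec$units)
    probs <- vapply(spec$units, function(u) u$prob, 0)
    combos <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
    w <- apply(combos, 1, function(z) prod(ifelse(z == 1, probs, 1 - probs)))
    mat <- matrix(0L, nrow(combos), length(reg$loci),
                  dimnames = list(NULL, reg$loci))
    for (j in seq_len(k)) {
      mat[combos[, j] == 1L, vec_from_loci(spec$units[[j]]$loci, reg) == 1L] <- 1L
    }
    ## conditioning on pair constraints: drop separating combinations
    keep <- rep(TRUE, nrow(mat))
    for (pc in spec$pair_constraints) {
      keep <- keep & (mat[, pc[1]] == mat[, pc[2]])
    }
    mat <- mat[keep, , drop = FALSE]
    w <- w[keep]
    if (sum(w) == 0) stop("pair constraints leave no admissible haplotype",
                          call. = FALSE)
    w <- w / sum(w)
  } else {
    cen <- spec$cen_motifs; tel <- spec$tel_motifs
    grid <- expand.grid(ci = seq_along(cen), ti = seq_along(tel))
    mat <- t(apply(grid, 1, function(g) {
      as.integer(vec_from_loci(cen[[g[1]]]$loci, reg) |
                 vec_from_loci(tel[[g[2]]]$loci, reg))
    }))
    colnames(mat) <- reg$loci
    w <- vapply(seq_len(nrow(grid)), function(i) {
      cen[[grid$ci[i]]]$freq * tel[[grid$ti[i]]]$freq
    }, 0)
  }
  drop0 <- w > 0
  mat <- mat[drop0, , drop = FALSE]; w <- w[drop0]
  if (!is.null(n_draws)) {
    idx <- with_seed(seed, sample.int(nrow(mat), n_draws, replace = TRUE, prob = w))
    tab <- table(idx)
    mat <- mat[as.integer(names(tab)), , drop = FALSE]
    w <- as.numeric(tab) / n_draws
  }
  merge_identical_haplotypes(mat, w, reg)
}

#' Simulate presence/absence genotypes under random haplotype pairing
#'
#' Each individual's genotype is the locus-wise OR of two haplotypes drawn
#' independently from the table's frequencies (Hardy-Weinberg pairing).
#'
#' @param table a [haplotype_table()].
#' @param n number of individuals (>= 1).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return A [genotype_panel()] with all individuals marked unrelated.
#' @export
simulate_genotypes <- function(table, n, seed = 1L) {
  stopifnot(inherits(table, "haplotype_table"), n >= 1)
  H <- table$haplotypes
  if (nrow(H) == 0) stop("empty haplotype table", call. = FALSE)
  idx <- with_seed(seed, matrix(sample.int(nrow(H), 2 * n, replace = TRUE,
                                           prob = table$frequency), ncol = 2))
  m <- (H[idx[, 1], , drop = FALSE] | H[idx[, 2], , drop = FALSE]) * 1L
  rownames(m) <- sprintf("ind%03d", seq_len(n))
  genotype_panel(m, table$registry)
}

#' Simulate a population frequency table
#'
#' Draws each phenotype frequency uniformly within its key's range,
#' independently per population. `B46` is drawn (and flagged) only for the
#' populations named in `b46_pops`; elsewhere it is 0. Defaults emulate a
#' world panel: 33 populations in 8 groups, with realistic KIR2DL1-3 and
#' C1/C2 carrier-frequency ranges and a B*46 range of 0.087-0.275 for the
#' East Asian group.
#'
#' @param n_pops number of populations.
#' @param ranges named list of `c(low, high)` ranges for keys `KIR2DL1`,
#'   `KIR2DL2`, `KIR2DL3`, `C1`, `C2`, `B46`.
#' @param groups group label per population; default assigns 8 groups of
#'   sizes as even as possible.
#' @param b46_pops population names (or indices) that carry B*46; default:
#'   populations of group `"EAS"` when that group exists, otherwise none.
#' @param seed integer seed.
#' @return A [frequency_table()].
#' @export
simulate_frequency_table <- function(n_pops = 33,
                                     ranges = list(
                                       KIR2DL1 = c(0.85, 1.00),
                                       KIR2DL2 = c(0.25, 0.90),
                                       KIR2DL3 = c(0.70, 1.00),
                                       C1 = c(0.45, 1.00),
                                       C2 = c(0.25, 0.80),
                                       B46 = c(0.087, 0.275)),
                                     groups = NULL, b46_pops = NULL, seed = 1L) {
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    assert_prob(r, paste("range for", nm))
    if (r[2] < r[1]) stop("inverted range for ", nm, call. = FALSE)
  }
  if (is.null(groups)) {
    glab <- c("AFR", "EUR", "SWA", "EAS", "OCE", "NEA", "NAM", "SAM")
    sizes <- diff(round(seq(0, n_pops, length.out = length(glab) + 1)))
    groups <- rep(glab, times = sizes)
  }
  pops <- sprintf("pop%02d", seq_len(n_pops))
  if (is.null(b46_pops)) b46_pops <- pops[groups == "EAS"]
  if (is.numeric(b46_pops)) b46_pops <- pops[b46_pops]
  draw <- function(key) stats::runif(n_pops, ranges[[key]][1], ranges[[key]][2])
  with_seed(seed, {
    f1 <- draw("KIR2DL1"); f2 <- draw("KIR2DL2"); f3 <- draw("KIR2DL3")
    c1 <- draw("C1"); c2 <- draw("C2")
    b46 <- ifelse(pops %in% b46_pops, draw("B46"), 0)
  })
  frequency_table(pops, groups, f1, f2, f3, c1, c2, B46 = b46,
                  b46_flagged = pops %in% b46_pops)
}

#' Simulate tip states by placing substitution events on tree edges
#'
#' The root state is propagated towards the tips; each event replaces the
#' state on one edge, and the new state is inherited by the whole clade
#' below that edge (unless overwritten by a deeper event). Edges are
#' identified by the tip set of the child clade: an event's `edge` element
#' is a character vector of tip labels whose most recent common ancestor's
#' parent edge carries the event (a single tip label identifies a terminal
#' edge).
#'
#' @param tree an [ape::phylo] or Newick string (rooted).
#' @param events list of `list(edge = <tip labels>, from = <state>,
#'   to = <state>)`; at most one event per edge, and each event's `from`
#'   must match the state flowing into its edge.
#' @param root_state single-character state at the root.
#' @return A [tip_state_tree()].
#' @export
simulate_tip_states <- function(tree, events = list(), root_state) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  ## tip set below each node
  below <- tipsets_below(tree)
  find_child <- function(tips) {
    tips <- sort(as.character(tips))
    for (v in seq_len(nnode)) {
      if (identical(below[[v]], tips)) {
        if (v == root) stop("event edge is the root; no edge above the root",
                            call. = FALSE)
        return(v)
      }
    }
    stop("unknown edge: no clade with tip set {",
         paste(tips, collapse = ", "), "}", call. = FALSE)
  }
  ev_child <- vapply(events, function(e) find_child(e$edge), 0L)
  if (anyDuplicated(ev_child)) {
    stop("contradictory events: multiple events on one edge", call. = FALSE)
  }
  ev_from <- vapply(events, function(e) as.character(e$from), "")
  ev_to <- vapply(events, function(e) as.character(e$to), "")
  state <- rep(NA_character_, nnode)
  state[root] <- as.character(root_state)
  ## preorder propagation
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1]; ch <- pre[i, 2]
    s <- state[par]
    hit <- which(ev_child == ch)
    if (length(hit)) {
      if (ev_from[hit] != s) {
        stop(sprintf("event on edge to clade {%s} expects state '%s' but '%s' flows in",
                     paste(below[[ch]], collapse = ","), ev_from[hit], s),
             call. = FALSE)
      }
      s <- ev_to[hit]
    }
    state[ch] <- s
  }
  tip_state_tree(tree, stats::setNames(state[seq_len(ntip)], tree$tip.label))
}

## sorted tip-label set below every node (index = ape node number)
tipsets_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    par <- post[i, 1]; ch <- post[i, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  lapply(below, function(x) sort(unique(x)))
}
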
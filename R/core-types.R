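## Domain containers for gene-content analyses.
##
## All containers are plain S3 lists validated at construction.  A
## presence/absence matrix is stored as an integer matrix of 0/1 with
## individuals (or haplotypes) in rows and loci in columns, column order
## fixed by the locus registry.

REGION_LEVELS <- c("centromeric", "telomeric", "framework", "unassigned")

#' Locus registry
#'
#' An ordered set of KIR locus names with an optional genomic-region tag
#' per locus. The registry fixes the column order of every genotype panel
#' and haplotype table; its size is data-driven (e.g. 14 presence/absence
#' markers typing 13 genes when a fused-gene region carries two markers).
#'
#' @param loci character vector of unique locus names, in display order.
#' @param region optional named character vector mapping loci to one of
#'   `"centromeric"`, `"telomeric"`, `"framework"`, `"unassigned"`. Loci
#'   without a tag default to `"unassigned"`.
#' @return An object of class `locus_registry`.
#' @examples
#' reg <- locus_registry(c("2DL4", "2DL5", "2DS4"),
#'                       region = c("2DL4" = "framework"))
#' @export
locus_registry <- function(loci, region = NULL) {
  loci <- as.character(loci)
  if (length(loci) == 0) stop("registry needs at least one locus", call. = FALSE)
  if (anyDuplicated(loci)) stop("locus names must be unique", call. = FALSE)
  reg <- rep("unassigned", length(loci))
  names(reg) <- loci
  if (!is.null(region)) {
    bad <- setdiff(names(region), loci)
    if (length(bad)) {
      stop("region tags for unknown loci: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!all(region %in% REGION_LEVELS)) {
      stop("region tags must be one of: ", paste(REGION_LEVELS, collapse = ", "),
           call. = FALSE)
    }
    reg[names(region)] <- region
  }
  structure(list(loci = loci, region = reg), class = "locus_registry")
}

#' @export
print.locus_registry <- function(x, ...) {
  cat("<locus_registry> ", length(x$loci), " loci\n", sep = "")
  print(data.frame(locus = x$loci, region = unname(x$region[x$loci])))
  invisible(x)
}

#' @export
length.locus_registry <- function(x) length(x$loci)

check_binary_matrix <- function(m, what) {
  if (anyNA(m)) {
    stop(sprintf("%s contains missing cells; missingness is rejected, not imputed",
                 what), call. = FALSE)
  }
  if (!all(m %in% c(0L, 1L))) {
    stop(sprintf("non-binary value in %s", what), call. = FALSE)
  }
  invisible(m)
}

#' Genotype panel
#'
#' Individuals typed for presence/absence at each registry locus. A locus
#' is scored present when at least one copy exists on either chromosome:
#' the genotype is the logical OR of the individual's two haplotypes, and
#' copy number is not modeled.
#'
#' @param mat numeric/integer matrix of 0/1, individuals in rows, loci in
#'   columns. Column names must match the registry; columns are realigned
#'   to registry order.
#' @param registry a [locus_registry()].
#' @param individuals optional character vector of unique identifiers
#'   (defaults to rownames, then `ind1..indN`).
#' @param unrelated logical vector marking the unrelated subset used for
#'   population statistics (default: all).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(mat, registry, individuals = NULL, unrelated = NULL) {
  stopifnot(inherits(registry, "locus_registry"))
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(individuals)) {
    individuals <- rownames(mat) %||% paste0("ind", seq_len(nrow(mat)))
  }
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) {
    stop("duplicated individual id", call. = FALSE)
  }
  if (length(individuals) != nrow(mat)) {
    stop("individuals length does not match matrix rows", call. = FALSE)
  }
  if (is.null(colnames(mat))) {
    if (ncol(mat) != length(registry$loci)) {
      stop("matrix has ", ncol(mat), " columns but registry has ",
           length(registry$loci), " loci", call. = FALSE)
    }
    colnames(mat) <- registry$loci
  }
  unknown <- setdiff(colnames(mat), registry$loci)
  if (length(unknown)) {
    stop("unknown locus name: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(registry$loci, colnames(mat))
  if (length(missing)) {
    stop("registry loci absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mat <- mat[, registry$loci, drop = FALSE]
  check_binary_matrix(mat, "genotype matrix")
  rownames(mat) <- individuals
  if (is.null(unrelated)) unrelated <- rep(TRUE, nrow(mat))
  unrelated <- as.logical(unrelated)
  if (length(unrelated) != nrow(mat) || anyNA(unrelated)) {
    stop("unrelated mask must be a complete logical vector, one per individual",
         call. = FALSE)
  }
  structure(list(registry = registry, individuals = individuals,
                 matrix = mat, unrelated = unrelated),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$matrix), " individuals x ",
      ncol(x$matrix), " loci (", sum(x$unrelated), " unrelated)\n", sep = "")
  invisible(x)
}

## rows of the panel used for population statistics
panel_rows <- function(panel, unrelated_only = FALSE) {
  m <- panel$matrix
  if (unrelated_only) {
    if (!any(panel$unrelated)) {
      stop("unrelated subset is empty", call. = FALSE)
    }
    m <- m[panel$unrelated, , drop = FALSE]
  }
  m
}

#' Haplotype table
#'
#' Gene-content haplotypes (presence vectors over the registry) with
#' population frequencies summing to one.
#'
#' @param mat 0/1 matrix, haplotypes in rows, loci in columns (registry
#'   order enforced as for [genotype_panel()]).
#' @param frequency numeric vector of haplotype frequencies in `[0, 1]`
#'   summing to 1 within `1e-6`.
#' @param registry a [locus_registry()].
#' @param names optional unique haplotype names (default `H1..Hn`).
#' @return An object of class `haplotype_table`.
#' @export
haplotype_table <- function(mat, frequency, registry, names = NULL) {
  stopifnot(inherits(registry, "locus_registry"))
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(colnames(mat))) {
    if (ncol(mat) != length(registry$loci)) {
      stop("matrix has ", ncol(mat), " columns but registry has ",
           length(registry$loci), " loci", call. = FALSE)
    }
    colnames(mat) <- registry$loci
  }
  unknown <- setdiff(colnames(mat), registry$loci)
  if (length(unknown)) {
    stop("unknown locus name: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mat <- mat[, registry$loci, drop = FALSE]
  check_binary_matrix(mat, "haplotype matrix")
  if (is.null(names)) names <- rownames(mat) %||% paste0("H", seq_len(nrow(mat)))
  names <- as.character(names)
  if (anyDuplicated(names)) stop("haplotype names must be unique", call. = FALSE)
  if (length(frequency) != nrow(mat)) {
    stop("one frequency per haplotype required", call. = FALSE)
  }
  assert_prob(frequency, "haplotype frequencies")
  if (abs(sum(frequency) - 1) > 1e-6) {
    stop("haplotype frequencies must sum to 1 (got ", format(sum(frequency)), ")",
         call. = FALSE)
  }
  rownames(mat) <- names
  structure(list(registry = registry, haplotypes = mat,
                 frequency = stats::setNames(as.numeric(frequency), names)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " loci\n", sep = "")
  df <- as.data.frame(x$haplotypes)
  df$frequency <- round(unname(x$frequency), 4)
  print(df)
  invisible(x)
}

## merge identical presence vectors, summing frequencies; keeps first name
merge_identical_haplotypes <- function(mat, frequency, registry, names = NULL) {
  key <- apply(mat, 1, paste, collapse = "")
  if (is.null(names)) names <- paste0("H", seq_len(nrow(mat)))
  keep <- !duplicated(key)
  agg <- tapply(frequency, key, sum)
  mat2 <- mat[keep, , drop = FALSE]
  key2 <- key[keep]
  haplotype_table(mat2, as.numeric(agg[key2]), registry, names = names[keep])
}

#' Population frequency table
#'
#' Per-population phenotype (carrier) frequencies for the KIR2DL1-3
#' receptors and the HLA-C1, HLA-C2 and HLA-B*46 ligands, with a group
#' label per population. `B46` may be omitted (treated as 0) and a
#' per-population flag marks populations where B*46-mediated interactions
#' apply.
#'
#' @param population unique population names.
#' @param group group label per population (e.g. geographic group).
#' @param KIR2DL1,KIR2DL2,KIR2DL3,C1,C2 phenotype frequencies in `[0, 1]`.
#' @param B46 HLA-B*46 phenotype frequency (default 0).
#' @param b46_flagged logical; whether B*46 interaction terms apply to this
#'   population (default `B46 > 0`).
#' @return A `data.frame` of class `frequency_table`.
#' @export
frequency_table <- function(population, group, KIR2DL1, KIR2DL2, KIR2DL3,
                            C1, C2, B46 = 0, b46_flagged = NULL) {
  population <- as.character(population)
  n <- length(population)
  if (anyDuplicated(population)) {
    stop("population names must be unique", call. = FALSE)
  }
  B46 <- rep_len(B46, n)
  for (nm in c("KIR2DL1", "KIR2DL2", "KIR2DL3", "C1", "C2", "B46")) {
    assert_prob(get(nm), nm)
  }
  if (is.null(b46_flagged)) b46_flagged <- B46 > 0
  df <- data.frame(population = population, group = as.character(rep_len(group, n)),
                   KIR2DL1 = KIR2DL1, KIR2DL2 = KIR2DL2, KIR2DL3 = KIR2DL3,
                   C1 = C1, C2 = C2, B46 = B46,
                   b46_flagged = rep_len(as.logical(b46_flagged), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("frequency_table", "data.frame")
  df
}

#' Residue pairs at MHC positions 76 and 80
#'
#' One row per allotype: the one-letter amino acids at the two positions
#' that determine the C1/C2/Bw4 KIR-binding epitopes. Unknown residues
#' (alignment gaps) are stored as `NA`.
#'
#' @param allotype character vector of allotype names.
#' @param res76,res80 one-letter amino-acid codes (or `NA` for unknown).
#' @return A `data.frame` of class `residue_pairs`.
#' @export
residue_pairs <- function(allotype, res76, res80) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res76 <- toupper(as.character(res76)); res80 <- toupper(as.character(res80))
  res76[res76 %in% c("-", ".", "X", "")] <- NA
  res80[res80 %in% c("-", ".", "X", "")] <- NA
  ok <- function(r) all(is.na(r) | r %in% aa)
  if (!ok(res76) || !ok(res80)) {
    stop("residues must be valid one-letter amino-acid codes or unknown",
         call. = FALSE)
  }
  df <- data.frame(allotype = as.character(allotype), res76 = res76,
                   res80 = res80, stringsAsFactors = FALSE)
  class(df) <- c("residue_pairs", "data.frame")
  df
}

#' Tree with single-character tip states
#'
#' Couples a phylogeny (rooted or unrooted, polytomies allowed) with one
#' character state per tip, for parsimony change counting.
#'
#' @param tree an [ape::phylo] object or a Newick string.
#' @param states named character vector, one single-character state per
#'   tip label. Every tip must be stated; internal labels are ignored.
#' @return An object of class `tip_state_tree`.
#' @export
tip_state_tree <- function(tree, states) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  states <- vapply(states, as.character, "")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop("unstated tip: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  states <- states[tree$tip.label]
  if (any(nchar(states) != 1L) || anyNA(states)) {
    stop("tip states must be single characters", call. = FALSE)
  }
  structure(list(tree = tree, states = states), class = "tip_state_tree")
}

#' @export
print.tip_state_tree <- function(x, ...) {
  cat("<tip_state_tree> ", length(x$tree$tip.label), " tips, states {",
      paste(sort(unique(x$states)), collapse = ", "), "}\n", sep = "")
  invisible(x)
}
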
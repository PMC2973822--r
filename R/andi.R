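## ANDI: the average number of distinct KIR2DL-HLA interactions in a
## population, computed from phenotype (carrier) frequencies.
##
## Base model terms (PF = phenotype frequency):
##   2DL1*C2 + 2DL2*C2 + 2DL2*C1 + 2DL3*C1
## B*46 extension (for populations carrying HLA-B*46, which is a ligand
## for KIR2DL2/3):                       + 2DL2*B46 + 2DL3*B46
## Alternative model: the 2DL2*C2 interaction is not counted.

ANDI_MODELS <- c("base", "b46", "alternative", "alternative_b46")

andi_terms <- function(row, model) {
  t <- c("2DL1*C2" = row$KIR2DL1 * row$C2,
         "2DL2*C2" = row$KIR2DL2 * row$C2,
         "2DL2*C1" = row$KIR2DL2 * row$C1,
         "2DL3*C1" = row$KIR2DL3 * row$C1)
  if (startsWith(model, "alternative")) t <- t[names(t) != "2DL2*C2"]
  if (model %in% c("b46", "alternative_b46")) {
    t <- c(t, "2DL2*B46" = row$KIR2DL2 * row$B46,
              "2DL3*B46" = row$KIR2DL3 * row$B46)
  }
  t
}

#' Compute ANDI for one population
#'
#' @param row one row of a [frequency_table()] (or a list with elements
#'   `KIR2DL1`, `KIR2DL2`, `KIR2DL3`, `C1`, `C2`, and `B46` for the B*46
#'   models).
#' @param model one of `"base"`, `"b46"`, `"alternative"`,
#'   `"alternative_b46"`.
#' @return An `andi_result` list: `population`, `andi`, `terms`, `model`.
#' @export
compute_andi <- function(row, model = c("base", "b46", "alternative",
                                        "alternative_b46")) {
  model <- match.arg(model)
  need <- c("KIR2DL1", "KIR2DL2", "KIR2DL3", "C1", "C2",
            if (model %in% c("b46", "alternative_b46")) "B46")
  for (nm in need) {
    if (is.null(row[[nm]])) stop("missing key for model: ", nm, call. = FALSE)
    assert_prob(row[[nm]], nm)
  }
  terms <- andi_terms(row, model)
  structure(list(population = row$population %||% NA_character_,
                 andi = sum(terms), terms = terms, model = model),
            class = "andi_result")
}

#' @export
print.andi_result <- function(x, ...) {
  cat(sprintf("<andi_result> %s model, ANDI = %.3f\n", x$model, x$andi))
  print(round(x$terms, 4))
  invisible(x)
}

#' Per-population ANDI over a frequency table
#'
#' Computes ANDI for every population. With `use_b46 = TRUE` the B*46
#' interaction terms are added for populations flagged `b46_flagged`
#' (and only those), matching the practice of extending the formula for
#' B*46-carrying populations rather than globally.
#'
#' @param table a [frequency_table()].
#' @param model `"base"` or `"alternative"`.
#' @param use_b46 add B*46 terms for flagged populations (default TRUE).
#' @return A `data.frame`: `population`, `group`, `model`, `andi`.
#' @export
andi_table <- function(table, model = c("base", "alternative"),
                       use_b46 = TRUE) {
  model <- match.arg(model)
  if (nrow(table) == 0) stop("empty frequency table", call. = FALSE)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    row <- as.list(table[i, ])
    m <- if (use_b46 && isTRUE(row$b46_flagged)) paste0(model, "_b46") else model
    m <- sub("^base_b46$", "b46", m)
    data.frame(population = row$population, group = row$group, model = m,
               andi = compute_andi(row, m)$andi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summary of ANDI across populations and groups
#'
#' Reports the minimum, maximum, median and 25-75 percentile band of
#' per-population ANDI, both over all populations and per group label,
#' plus the median of the group medians (the two readings of a
#' "median over population groups").
#'
#' @inheritParams andi_table
#' @return An `andi_summary` list: `per_population` (the [andi_table()]),
#'   `overall` (named vector `min`, `q25`, `median`, `q75`, `max`),
#'   `per_group` (data frame of the same statistics per group),
#'   `median_of_group_medians`.
#' @export
andi_summary <- function(table, model = c("base", "alternative"),
                         use_b46 = TRUE) {
  model <- match.arg(model)
  per <- andi_table(table, model = model, use_b46 = use_b46)
  fivenum_named <- function(x) {
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    stats::setNames(q, c("min", "q25", "median", "q75", "max"))
  }
  overall <- fivenum_named(per$andi)
  groups <- split(per$andi, per$group)
  per_group <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, t(fivenum_named(groups[[g]])),
               n = length(groups[[g]]), stringsAsFactors = FALSE)
  }))
  structure(list(per_population = per, overall = overall,
                 per_group = per_group,
                 median_of_group_medians = stats::median(per_group$median)),
            class = "andi_summary")
}

#' @export
print.andi_summary <- function(x, ...) {
  cat("<andi_summary>\n  over populations: ")
  cat(paste(names(x$overall), round(x$overall, 3), sep = "=", collapse = " "), "\n")
  cat("  median of group medians:", round(x$median_of_group_medians, 3), "\n")
  invisible(x)
}

#' Maximum ANDI under Hardy-Weinberg equilibrium at HLA-C
#'
#' Treats C1/C2 as a biallelic epitope system at HLA-C: with C1-allele
#' frequency `c`, carrier frequencies are `C1 = 1 - (1 - c)^2` and
#' `C2 = 1 - c^2`. The HLA-C terms of the chosen model are maximized over
#' `c` in `[0, 1]` by bounded scalar optimization; any B*46 term is not
#' part of the HLA-C system and is held at the supplied constant value.
#'
#' @param KIR2DL1,KIR2DL2,KIR2DL3 KIR phenotype frequencies in `[0, 1]`.
#' @param model ANDI model tag.
#' @param B46 B*46 phenotype frequency for the B*46 models (default 0).
#' @return The maximum ANDI (scalar).
#' @export
hwe_max_andi <- function(KIR2DL1, KIR2DL2, KIR2DL3,
                         model = c("base", "b46", "alternative",
                                   "alternative_b46"), B46 = 0) {
  model <- match.arg(model)
  assert_prob(c(KIR2DL1, KIR2DL2, KIR2DL3, B46), "frequencies")
  f <- function(c_) {
    row <- list(KIR2DL1 = KIR2DL1, KIR2DL2 = KIR2DL2, KIR2DL3 = KIR2DL3,
                C1 = 1 - (1 - c_)^2, C2 = 1 - c_^2, B46 = B46)
    sum(andi_terms(row, model))
  }
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)
  ## the optimum can sit on a boundary; check both ends
  max(opt$objective, f(0), f(1))
}

#' Pearson product-moment correlation with optional leave-one-out report
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @param leave_one_out also report the correlation with each point
#'   removed, to surface outlier populations.
#' @return The correlation coefficient, or (with `leave_one_out`) a list
#'   `r` plus data frame `loo` (`excluded`, `r`).
#' @export
pearson_correlation <- function(x, y, leave_one_out = FALSE) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (!leave_one_out) return(r)
  loo <- vapply(seq_along(x), function(i) stats::cor(x[-i], y[-i]), 0)
  list(r = r, loo = data.frame(excluded = seq_along(x), r = loo))
}

#' Phenotype (carrier) frequency from an allele frequency under HWE
#'
#' `PF = 1 - (1 - af)^2`: the chance a diploid individual carries at
#' least one copy of an allele at frequency `af`.
#'
#' @param af allele frequency in `[0, 1]`.
#' @return Phenotype frequency in `[0, 1]`.
#' @export
pf_from_allele_freq <- function(af) {
  assert_prob(af, "allele frequency")
  1 - (1 - af)^2
}
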
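## C1/C2/Bw4 epitope classification from MHC class I residues 76 and 80,
## cohort epitope-frequency summaries, and the binomial test for
## recurrent V76 creation on N80 backgrounds.
##
## Rule table (one-letter codes at positions 76 / 80):
##   V76 + N80          -> C1
##   V76 + K80          -> C2
##   I80 or T80         -> Bw4 (any residue 76; V76 is flagged as a
##                        conflict - it perturbs KIR3DL1 binding without
##                        creating C1 or C2)
##   anything else      -> none
##   unknown residue    -> none, flagged unknown

#' Classify C1/C2/Bw4 epitopes from residues 76 and 80
#'
#' @param pairs a [residue_pairs()] data frame (or anything with columns
#'   `allotype`, `res76`, `res80`).
#' @return A `data.frame`: `allotype`, `res76`, `res80`, `epitope`
#'   (factor over `C1`, `C2`, `Bw4`, `none`), and logical flags
#'   `v76_with_bw4_position`, `unknown_residue`.
#' @export
classify_epitope <- function(pairs) {
  r76 <- pairs$res76; r80 <- pairs$res80
  unknown <- is.na(r76) | is.na(r80)
  epi <- rep("none", length(r76))
  epi[!unknown & r76 == "V" & r80 == "N"] <- "C1"
  epi[!unknown & r76 == "V" & r80 == "K"] <- "C2"
  epi[!unknown & r80 %in% c("I", "T")] <- "Bw4"
  conflict <- !unknown & r76 == "V" & r80 %in% c("I", "T")
  data.frame(allotype = pairs$allotype, res76 = r76, res80 = r80,
             epitope = factor(epi, levels = c("C1", "C2", "Bw4", "none")),
             v76_with_bw4_position = conflict,
             unknown_residue = unknown,
             stringsAsFactors = FALSE)
}

#' Epitope frequencies in a set of allotypes
#'
#' Fractions of classified allotypes carrying each epitope. Allotypes
#' with an unknown residue are excluded from the denominator and counted
#' separately.
#'
#' @param pairs a [residue_pairs()] data frame.
#' @return A list: `fractions` (named over `C1`, `C2`, `Bw4`, `none`,
#'   summing to 1), `n_classified`, `n_unknown`.
#' @export
epitope_frequencies <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty allotype list", call. = FALSE)
  calls <- classify_epitope(pairs)
  known <- calls[!calls$unknown_residue, ]
  if (nrow(known) == 0) stop("no classifiable allotype", call. = FALSE)
  tab <- table(known$epitope)
  fractions <- stats::setNames(as.numeric(tab) / nrow(known), names(tab))
  list(fractions = fractions,
       n_classified = nrow(known),
       n_unknown = sum(calls$unknown_residue))
}

#' Binomial test for co-occurrence on a background
#'
#' Upper-tail probability that at least `k_on_background` of `k_total`
#' independent events fall on a background present at
#' `background_fraction`, under the null of random placement:
#' `P(X >= k)` for `X ~ Binomial(k_total, background_fraction)`. When all
#' events are on the background this is `background_fraction^k_total`.
#' The test is one-sided because the hypothesis is directional (e.g.
#' V76-creating substitutions always arising on N80 allotypes).
#'
#' @param k_on_background events observed on the background.
#' @param k_total total independent events.
#' @param background_fraction background frequency in `[0, 1]`.
#' @return Tail probability in `[0, 1]`.
#' @export
binomial_cooccurrence_test <- function(k_on_background, k_total,
                                       background_fraction) {
  assert_prob(background_fraction, "background_fraction")
  if (k_total < 0 || k_on_background < 0 || k_on_background > k_total) {
    stop("need 0 <= k_on_background <= k_total", call. = FALSE)
  }
  if (k_total == 0) return(1.0)
  stats::pbinom(k_on_background - 1, size = k_total,
                prob = background_fraction, lower.tail = FALSE)
}

#' N80 background fraction from an allotype list
#'
#' Convenience helper: `1 - fraction(I80 or T80)` among allotypes with a
#' known residue 80, the background used by
#' [binomial_cooccurrence_test()] for the V76/N80 analysis.
#'
#' @param pairs a [residue_pairs()] data frame.
#' @return Fraction in `[0, 1]`.
#' @export
n80_background_fraction <- function(pairs) {
  r80 <- pairs$res80[!is.na(pairs$res80)]
  if (length(r80) == 0) stop("no known residue-80 states", call. = FALSE)
  1 - mean(r80 %in% c("I", "T"))
}
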
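## TSV / FASTA readers and writers for the domain containers.
## All TSV is tab-delimited UTF-8; lines starting with '#' are comments.

read_tsv_raw <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

decode_presence <- function(x, what) {
  x <- trimws(as.character(x))
  out <- ifelse(x %in% c("1", "+"), 1L, ifelse(x %in% c("0", "-"), 0L, NA_integer_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop(sprintf("non-binary value in %s: %s", what,
                 paste(dQuote(bad), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a genotype panel from TSV
#'
#' Expects a header row with an `id` column, one column per registry locus
#' (cells `0`/`1` or `-`/`+`), and optionally an `unrelated` column
#' (`0`/`1`). Column order may differ from the registry; it is realigned.
#'
#' @param path TSV file path.
#' @param registry a [locus_registry()].
#' @return A [genotype_panel()].
#' @export
read_genotype_panel <- function(path, registry) {
  df <- read_tsv_raw(path)
  if (!"id" %in% names(df)) stop("panel TSV needs an 'id' column", call. = FALSE)
  ids <- df$id
  if (anyDuplicated(ids)) stop("duplicated individual id", call. = FALSE)
  unrelated <- if ("unrelated" %in% names(df)) {
    decode_presence(df$unrelated, "unrelated column") == 1L
  } else NULL
  loci_cols <- setdiff(names(df), c("id", "unrelated"))
  unknown <- setdiff(loci_cols, registry$loci)
  if (length(unknown)) {
    stop("unknown locus name: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- vapply(loci_cols, function(cn) decode_presence(df[[cn]], paste("locus", cn)),
              integer(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(ids, loci_cols))
  genotype_panel(m, registry, individuals = ids, unrelated = unrelated)
}

#' Write a genotype panel to TSV
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_panel <- function(panel, path) {
  df <- data.frame(id = panel$individuals, panel$matrix,
                   unrelated = as.integer(panel$unrelated),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype table from TSV
#'
#' Expects columns `name`, one per registry locus, and `frequency`.
#'
#' @param path TSV file path.
#' @param registry a [locus_registry()].
#' @return A [haplotype_table()].
#' @export
read_haplotype_table <- function(path, registry) {
  df <- read_tsv_raw(path)
  need <- c("name", "frequency")
  if (!all(need %in% names(df))) {
    stop("haplotype TSV needs 'name' and 'frequency' columns", call. = FALSE)
  }
  loci_cols <- setdiff(names(df), need)
  unknown <- setdiff(loci_cols, registry$loci)
  if (length(unknown)) {
    stop("unknown locus name: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- vapply(loci_cols, function(cn) decode_presence(df[[cn]], paste("locus", cn)),
              integer(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(df$name, loci_cols))
  haplotype_table(m, as.numeric(df$frequency), registry, names = df$name)
}

#' Write a haplotype table to TSV
#'
#' @param table a [haplotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  df <- data.frame(name = rownames(table$haplotypes), table$haplotypes,
                   frequency = unname(table$frequency), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population frequency table from TSV
#'
#' Expects columns `population`, `group`, `2DL1`/`KIR2DL1`, `2DL2`/`KIR2DL2`,
#' `2DL3`/`KIR2DL3`, `C1`, `C2`, optionally `B46` (absent means 0) and
#' `b46_flagged`.
#'
#' @param path TSV file path.
#' @return A [frequency_table()].
#' @export
read_frequency_table <- function(path) {
  df <- read_tsv_raw(path)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(as.numeric(df[[nm]]))
    NULL
  }
  need <- list(KIR2DL1 = pick("KIR2DL1", "2DL1"), KIR2DL2 = pick("KIR2DL2", "2DL2"),
               KIR2DL3 = pick("KIR2DL3", "2DL3"), C1 = pick("C1"), C2 = pick("C2"))
  if (any(vapply(need, is.null, TRUE)) || !all(c("population", "group") %in% names(df))) {
    stop("frequency TSV needs population, group, 2DL1-3, C1, C2 columns",
         call. = FALSE)
  }
  b46 <- pick("B46") %||% 0
  flag <- if ("b46_flagged" %in% names(df)) as.logical(as.integer(df$b46_flagged)) else NULL
  frequency_table(df$population, df$group, need$KIR2DL1, need$KIR2DL2,
                  need$KIR2DL3, need$C1, need$C2, B46 = b46, b46_flagged = flag)
}

#' Write a population frequency table to TSV
#'
#' @param table a [frequency_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  df <- as.data.frame(table)
  df$b46_flagged <- as.integer(df$b46_flagged)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract residue pairs from aligned protein sequences or a TSV
#'
#' For FASTA input, reads aligned mature-protein sequences and extracts
#' the amino acids at the two epitope-determining positions (1-based in
#' the alignment of the mature protein; apply any leader-peptide offset
#' before calling). A gap at either position yields an unknown residue.
#' For TSV input, expects columns `allotype` (or `name`), `res76`, `res80`.
#'
#' @param path FASTA or TSV file path.
#' @param pos76,pos80 1-based positions of the two epitope residues
#'   (defaults 76 and 80).
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return A [residue_pairs()] data frame.
#' @export
read_residue_pairs <- function(path, pos76 = 76, pos80 = 80,
                               format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa|aln)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0) stop("empty FASTA file", call. = FALSE)
    widths <- Biostrings::width(seqs)
    if (any(widths < max(pos76, pos80))) {
      stop("position beyond sequence length for: ",
           paste(names(seqs)[widths < max(pos76, pos80)], collapse = ", "),
           call. = FALSE)
    }
    r76 <- as.character(Biostrings::subseq(seqs, pos76, pos76))
    r80 <- as.character(Biostrings::subseq(seqs, pos80, pos80))
    residue_pairs(names(seqs), r76, r80)
  } else {
    df <- read_tsv_raw(path)
    if (nrow(df) == 0) stop("empty residue-pair file", call. = FALSE)
    nm <- if ("allotype" %in% names(df)) df$allotype else df[[1]]
    if (!all(c("res76", "res80") %in% names(df))) {
      if (ncol(df) < 3) stop("residue TSV needs 3 columns", call. = FALSE)
      residue_pairs(nm, df[[2]], df[[3]])
    } else {
      residue_pairs(nm, df$res76, df$res80)
    }
  }
}
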
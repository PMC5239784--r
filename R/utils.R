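#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Rcpp evalCpp
#' @useDynLib vdjlineage, .registration = TRUE
NULL

# reverse complement of a character vector of nt strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# element-wise complement, no reversal (used by the TDT two-strand rule)
complement_nt <- function(x) {
  chartr("ACGT", "TGCA", x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# structured log line for refinement decisions (CLI turns this on)
vl_log <- function(...) {
  if (isTRUE(getOption("vdjlineage.verbose"))) rlang::inform(paste0(...))
  invisible(NULL)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# translate an in-frame nt string; incomplete trailing codon dropped
translate_nt <- function(x) {
  n <- 3L * (nchar(x) %/% 3L)
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

# codon start positions for a given frame (1-based)
codon_starts <- function(len, frame = 1L) {
  if (len < frame + 2L) return(integer(0))
  seq.int(frame, len - 2L, by = 3L)
}

# parse "IGHV1-2*01" / "rIGHD1-1*01" style allele names
parse_gene_family <- function(name) {
  m <- regmatches(name, regexec("^(r?)(IG[HKL][VDJ])([0-9]+)", name))
  fam <- vapply(m, function(g) {
    if (length(g) == 0L) NA_character_ else paste0(g[2], g[3], g[4])
  }, character(1))
  num <- vapply(m, function(g) {
    if (length(g) == 0L) NA_integer_ else as.integer(g[4])
  }, integer(1))
  list(family = fam, family_number = num)
}
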
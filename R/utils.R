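# Shared validators and small lookup tables.

# The 20 standard amino acids, one-letter code.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_1L <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# amino acid -> list of synonymous codons (back-translation sampling space)
CODONS_BY_AA <- split(names(GENETIC_CODE_1L), GENETIC_CODE_1L)

#' Translate an in-frame nucleotide sequence to amino acids
#'
#' Standard genetic code; used by the synthetic generator and validators.
#' @param nt Character vector of uppercase ACGT sequences with length
#'   divisible by 3.
#' @return Character vector of single-letter amino-acid sequences
#'   (`"*"` marks a stop codon).
#' @export
translate_nt <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(NA_character_)
    if (nchar(s) %% 3L != 0L) {
      abort(sprintf("sequence length %d is not a multiple of 3", nchar(s)))
    }
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    paste(GENETIC_CODE_1L[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

assert_aa_strings <- function(x, arg = "x") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
  bad[is.na(x)] <- FALSE
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-amino-acid characters in: %s",
      arg, paste(head(unique(x[bad]), 5), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Canonicalize IMGT-style V/J gene names
#'
#' Strips allele suffixes (`*01`), converts dot-separated family/member
#' dialects (`TRBV13.1`) to the hyphenated IMGT form (`TRBV13-1`), and
#' trims whitespace.
#' @param x Character vector of gene names.
#' @return Character vector of canonical names.
#' @export
normalize_gene_name <- function(x) {
  x <- stringr::str_trim(x)
  x <- stringr::str_remove(x, "\\*\\d+$")
  # TRBV13.1 -> TRBV13-1 (dots between digits are a separator dialect)
  x <- stringr::str_replace_all(x, "(?<=\\d)\\.(?=\\d)", "-")
  x
}

# "True"/"true"/"TRUE" -> TRUE; "False"/"None"/"" -> FALSE; logicals pass.
parse_flag <- function(x, default = NA) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- dplyr::case_when(
    lx %in% c("true", "t", "1") ~ TRUE,
    lx %in% c("false", "f", "0", "none", "") ~ FALSE,
    .default = NA
  )
  out[is.na(out)] <- default
  out
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_clone_tbl <- function(clones, need_expansion = FALSE) {
  assert_cols(
    clones,
    c("sample_id", "group_label", "clone_id", "cdr3b_nt", "cdr3a_nt",
      "cdr3b_aa", "cdr3a_aa", "size", "member_barcodes", "v_pairs"),
    "clone table"
  )
  if (need_expansion && !"expansion_class" %in% names(clones)) {
    abort("clone table lacks 'expansion_class'; run classify_expansion() first")
  }
  invisible(clones)
}
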
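## Genetic-code tables and translation, including six-frame ORF extraction
## used to take nucleotide transcriptome data into protein space for profile
## searches.

#' Fetch a genetic-code table
#'
#' Thin wrapper over [Biostrings::getGeneticCode()]: NCBI numeric table ids
#' (1 = standard, 4 = mold/protozoan mt, 5 = invertebrate mt, ...).
#'
#' @param table_id NCBI genetic-code table id.
#' @return named character vector, 64 codons to one-letter amino acid
#'   (`"*"` = stop), with attribute `table_id`.
#' @export
genetic_code <- function(table_id = 1L) {
  gc <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(gc) == 64L)
  attr(gc, "table_id") <- as.integer(table_id)
  gc
}

#' Translate an in-frame coding sequence
#'
#' Codons containing ambiguity characters translate to `"X"`; `mask_codon`
#' (if given) is rendered `"X"` regardless of the code, which is how an
#' unknown-code genome is translated before aligning it to references.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @param code a [genetic_code()] table.
#' @param mask_codon optional 3-mer masked to `"X"`.
#' @return amino-acid string (stops as `"*"`).
#' @export
translate_cds <- function(cds, code = genetic_code(1L), mask_codon = NULL) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (!is.null(mask_codon)) aa[codons == toupper(mask_codon)] <- "X"
  paste(aa, collapse = "")
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D")

#' Reverse complement of a nucleotide string
#' @param x nucleotide string (IUPAC codes allowed).
#' @export
revcomp <- function(x) {
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  cc <- .COMPLEMENT[ch]
  cc[is.na(cc)] <- "N"
  paste(cc, collapse = "")
}

#' Six-frame open-reading-frame extraction
#'
#' Extracts stop-to-stop segments of length at least `min_len` residues from
#' all six frames.  Output ids are `<id>|<frame>|<offset>` with frames in
#' `{+1,+2,+3,-1,-2,-3}` and 0-based half-open offsets counted in amino acids
#' within the frame translation.
#'
#' @param record single-element nucleotide [seq_set()] (or named string).
#' @param code a [genetic_code()] table.
#' @param min_len minimum ORF length in residues (default 30, a typical
#'   fragment floor for profile hits).
#' @return amino-acid [seq_set()] (possibly empty).
#' @export
translate_six_frames <- function(record, code = genetic_code(1L), min_len = 30L) {
  stopifnot(length(record) == 1L, min_len >= 1L)
  id <- names(record)
  nt <- toupper(record[[1]])
  rc <- revcomp(nt)
  out <- character(0)
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0L) substring(nt, fr) else substring(rc, -fr)
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) next
    aa <- translate_cds(substring(s, 1L, n), code)
    # stop-to-stop segments
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    off <- 0L
    for (seg in segs) {
      if (nchar(seg) >= min_len && grepl("[^X]", seg)) {
        nm <- sprintf("%s|%+d|%d", id, fr, off)
        out[nm] <- seg
      }
      off <- off + nchar(seg) + 1L
    }
  }
  if (!length(out)) return(structure(character(0), alphabet = "AA", class = "seq_set"))
  seq_set(out, "AA")
}
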
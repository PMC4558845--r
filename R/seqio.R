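## Sequence and alignment containers + readers/writers.
##
## Sequence sets are named character vectors of residue strings carrying an
## "alphabet" attribute ("AA" or "DNA"); alignments are character matrices
## (rows = sequences, columns = aligned positions) of class "msa".  Gap
## characters '-' and '.' are both accepted on input and normalized to '-'.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                "F","P","S","T","W","Y","V")
AA_AMBIG <- c("X","B","Z","J","U","O","*")
DNA_AMBIG <- c("N","R","Y","S","W","K","M","B","D","H","V")

.valid_symbols <- function(alphabet, gaps = FALSE) {
  s <- if (alphabet == "AA") c(AA_LETTERS, AA_AMBIG) else c("A","C","G","T", DNA_AMBIG)
  if (gaps) s <- c(s, "-")
  s
}

#' Construct a sequence set
#'
#' @param x named character vector of residue strings; names are sequence ids.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param gapped allow gap characters (alignment rows).
#' @return the validated vector with class `"seq_set"`.
#' @export
seq_set <- function(x, alphabet = c("AA", "DNA"), gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  if (length(x) == 0L)
    return(structure(stats::setNames(character(0), character(0)),
                     alphabet = alphabet, class = "seq_set"))
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  x <- toupper(gsub("\\.", "-", x))
  ok <- .valid_symbols(alphabet, gaps = gapped)
  for (i in seq_along(x)) {
    ch <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% ok)
    if (length(bad))
      stop(sprintf("illegal %s residue '%s' in '%s' at position %d",
                   alphabet, ch[bad[1]], ids[i], bad[1]))
  }
  structure(x, alphabet = alphabet, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("%s sequence set: %d sequences\n", attr(x, "alphabet"), length(x)))
  show <- utils::head(seq_along(x), 6L)
  for (i in show)
    cat(sprintf("  %s  (%d residues)\n", names(x)[i], nchar(x[[i]])))
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' Read sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header; order is
#' preserved.  Duplicate ids, an empty file, or illegal residue symbols are
#' errors.
#'
#' @param path FASTA file.
#' @param alphabet `"AA"` or `"DNA"`.
#' @return a [seq_set()].
#' @export
read_sequences <- function(path, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- if (alphabet == "AA") Biostrings::readAAStringSet(path)
        else Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  x <- as.character(ss)
  names(x) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seq_set(x, alphabet)
}

#' Write sequences or an alignment to FASTA
#' @param x a `seq_set` or `msa`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "msa")) x <- msa_strings(x)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment
#'
#' @param x named character vector of equal-length gapped rows, or a character
#'   matrix with row names.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param metadata free-form tag list (e.g. source taxon domain).
#' @return character matrix of class `"msa"`; one row per sequence.
#' @export
msa <- function(x, alphabet = c("AA", "DNA"), metadata = list()) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(x)) {
    m <- toupper(x)
    m[m == "."] <- "-"
    ids <- rownames(m)
    x <- apply(m, 1L, paste, collapse = "")
    names(x) <- ids
  }
  w <- nchar(x)
  if (length(unique(w)) != 1L) {
    off <- names(x)[w != stats::median(w)]
    stop("ragged alignment rows: ", paste(off, collapse = ", "))
  }
  x <- unclass(seq_set(x, alphabet, gapped = TRUE))
  allgap <- vapply(x, function(s) !grepl("[^-]", s), TRUE)
  if (any(allgap))
    stop("row(s) with no non-gap residue: ",
         paste(names(x)[allgap], collapse = ", "))
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- names(x)
  structure(m, alphabet = alphabet, metadata = metadata, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("%s alignment: %d sequences x %d columns\n",
              attr(x, "alphabet"), nrow(x), ncol(x)))
  invisible(x)
}

#' Number of alignment columns
#' @param x an `msa`.
#' @export
n_columns <- function(x) ncol(x)

#' Alignment rows as gapped strings
#' @param x an `msa`.
#' @export
msa_strings <- function(x) {
  s <- apply(unclass(x), 1L, paste, collapse = "")
  names(s) <- rownames(x)
  s
}

#' Drop gap-only columns and return ungapped row strings
#' @param x an `msa`.
#' @export
ungap <- function(x) {
  s <- msa_strings(x)
  gsub("-", "", s, fixed = TRUE)
}

#' Read a multiple sequence alignment
#'
#' FASTA, Stockholm (`.` gaps normalized to `-`) and relaxed PHYLIP
#' (sequential; name and row separated by whitespace) are supported.
#'
#' @param path alignment file.
#' @param format `"fasta"`, `"stockholm"` or `"phylip"`.
#' @param alphabet `"AA"` or `"DNA"`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm", "phylip"),
                           alphabet = c("AA", "DNA")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  rows <- switch(format,
    fasta = unclass(read_sequences_gapped(path, alphabet)),
    stockholm = .read_stockholm(path),
    phylip = .read_relaxed_phylip(path))
  msa(rows, alphabet)
}

## FASTA reader tolerating gap characters (alignment rows)
read_sequences_gapped <- function(path, alphabet) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  ids <- vapply(strsplit(sub("^>", "", lines[hdr]), "\\s+"), `[`, "", 1L)
  body <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  names(body) <- ids
  seq_set(body, alphabet, gapped = TRUE)
}

.read_stockholm <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed Stockholm row: ", lines[which(bad)[1]])
  ids <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, `[`, "", 2L)
  # interleaved blocks concatenate per id, preserving first-seen order
  out <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                paste, "", collapse = "")
  out
}

.read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1]); len <- as.integer(hdr[2])
  if (is.na(n) || is.na(len)) stop("bad PHYLIP header: ", lines[1])
  body <- lines[-1]
  if (length(body) < n) stop("PHYLIP body shorter than declared count")
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  # sequential relaxed phylip; interleaved continuation lines have no id slot
  # handled by concatenating rows beyond the first n back onto ids cyclically
  if (length(seqs) > n) {
    extra <- seqs[-(1:n)]
    extra_full <- vapply(parts[-(1:n)], paste, "", collapse = "")
    for (i in seq_along(extra_full))
      seqs[((i - 1L) %% n) + 1L] <- paste0(seqs[((i - 1L) %% n) + 1L], extra_full[i])
    seqs <- seqs[1:n]; ids <- ids[1:n]
  }
  if (any(nchar(seqs) != len))
    stop("PHYLIP row length disagrees with header for: ",
         paste(ids[nchar(seqs) != len], collapse = ", "))
  names(seqs) <- ids
  seqs
}
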
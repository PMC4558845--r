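## Entropy/gap-filtered scan for mitochondrial genetic-code reassignments at
## a target codon.  The focal coding sequence (translated with the scanned
## codon masked to 'X', mirroring a genome whose code is unknown) is a row of
## a reference amino-acid alignment; each focal codon maps through that row's
## gaps to an alignment column, whose reference residue distribution supports
## or refutes a reassignment call.

#' Shannon entropy of a residue count vector
#'
#' @param counts named non-negative counts (gaps excluded).
#' @param base logarithm base; `exp(1)` (nats, the default) or 2 (bits).
#' @return entropy; 0 iff a single residue is present.
#' @export
shannon_entropy <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero counts")
  p <- counts / sum(counts)
  unname(-sum(p * log(p) / log(base)))
}

#' Map focal codons to reference-alignment columns
#'
#' The focal CDS is translated (target codon masked to `"X"`) and checked
#' against the named focal row of the alignment; the row's non-gap positions
#' establish the codon-to-column map.  Each codon yields its reference
#' residue counts, gap fraction and entropy.
#'
#' @param focal_cds nucleotide string, length divisible by 3.
#' @param ref_alignment amino-acid `msa` containing the focal row.
#' @param code a [genetic_code()].
#' @param focal_id row id of the focal sequence (default `"focal"`).
#' @param target_codon codon masked to `"X"` during translation (optional but
#'   needed when the focal code is unknown at the scanned codon).
#' @param gene_id carried into the output.
#' @param entropy_base base for [shannon_entropy()].
#' @return data.frame of class `"codon_columns"`: one row per codon with
#'   `gene_id`, `codon_index` and `column_index` (0-based), `focal_codon`,
#'   `n_refs`, `gap_fraction`, `entropy`, `plurality` (ties joined by `/`).
#' @export
map_codons_to_columns <- function(focal_cds, ref_alignment,
                                  code = genetic_code(4L), focal_id = "focal",
                                  target_codon = NULL, gene_id = focal_id,
                                  entropy_base = exp(1)) {
  stopifnot(inherits(ref_alignment, "msa"))
  n <- nchar(focal_cds)
  if (n %% 3L != 0L) stop("focal CDS length ", n, " not divisible by 3")
  if (!focal_id %in% rownames(ref_alignment))
    stop("focal row '", focal_id, "' absent from alignment")
  aa <- translate_cds(focal_cds, code, mask_codon = target_codon)
  m <- unclass(ref_alignment)
  focal_row <- m[focal_id, ]
  cols <- which(focal_row != "-")
  if (length(cols) != nchar(aa))
    stop("focal row has ", length(cols), " residues but the CDS translates to ",
         nchar(aa))
  if (paste(focal_row[cols], collapse = "") != aa)
    stop("focal row does not match the translated CDS")
  refs <- m[setdiff(rownames(m), focal_id), , drop = FALSE]
  n_total <- nrow(refs)
  codons <- substring(toupper(focal_cds), seq(1L, n, 3L), seq(3L, n, 3L))
  out <- lapply(seq_along(cols), function(i) {
    col <- refs[, cols[i]]
    gap_fraction <- mean(col == "-")
    res <- col[col %in% AA_LETTERS]
    cnt <- table(res)
    ent <- if (length(cnt)) shannon_entropy(cnt, base = entropy_base) else NA_real_
    plur <- if (length(cnt)) paste(sort(names(cnt)[cnt == max(cnt)]),
                                   collapse = "/") else ""
    data.frame(gene_id = gene_id, codon_index = i - 1L,
               column_index = cols[i] - 1L, focal_codon = codons[i],
               n_refs = length(res), gap_fraction = gap_fraction,
               entropy = ent, plurality = plur)
  })
  out <- do.call(rbind, out)
  class(out) <- c("codon_columns", "data.frame")
  out
}

#' Scan for a codon reassignment
#'
#' Retains columns whose focal codon equals `target_codon`, whose reference
#' entropy is below `entropy_max` and whose gap fraction is below `gap_max`
#' (the conserved-position filter), then summarizes which amino acid the
#' retained columns' plurality reference residues correspond to.  Plurality
#' ties contribute fractionally.
#'
#' @param columns a [map_codons_to_columns()] result (rows from several genes
#'   may be concatenated).
#' @param target_codon 3-mer, e.g. `"TGA"`.
#' @param entropy_max conserved-position entropy ceiling (default 1.0 nats).
#' @param gap_max gap-fraction ceiling (default 0.20).
#' @return object of class `"reassignment_report"`.
#' @export
scan_codon_reassignment <- function(columns, target_codon = "TGA",
                                    entropy_max = 1.0, gap_max = 0.20) {
  stopifnot(entropy_max > 0, gap_max > 0)
  target_codon <- toupper(target_codon)
  cand <- columns[columns$focal_codon == target_codon, , drop = FALSE]
  keep <- cand[!is.na(cand$entropy) & cand$entropy < entropy_max &
                 cand$gap_fraction < gap_max & nzchar(cand$plurality), ,
               drop = FALSE]
  frac <- stats::setNames(numeric(20L), AA_LETTERS)
  for (pl in keep$plurality) {
    tied <- strsplit(pl, "/", fixed = TRUE)[[1]]
    frac[tied] <- frac[tied] + 1 / length(tied)
  }
  if (nrow(keep)) frac <- frac / nrow(keep)
  call_aa <- if (nrow(keep)) names(which.max(frac)) else NA_character_
  structure(list(target_codon = target_codon,
                 n_candidate_columns = nrow(cand),
                 n_retained = nrow(keep),
                 modal_fractions = frac,
                 call = call_aa,
                 call_fraction = if (nrow(keep)) max(frac) else NA_real_,
                 entropy_max = entropy_max, gap_max = gap_max),
            class = "reassignment_report")
}

#' @export
print.reassignment_report <- function(x, ...) {
  cat(sprintf("codon reassignment scan: %s, %d candidate columns, %d retained (entropy < %g, gaps < %g%%)\n",
              x$target_codon, x$n_candidate_columns, x$n_retained,
              x$entropy_max, 100 * x$gap_max))
  if (x$n_retained > 0)
    cat(sprintf("  call: %s -> %s (%.0f%% of retained columns)\n",
                x$target_codon, x$call, 100 * x$call_fraction))
  else cat("  no columns pass the conserved-position filter\n")
  invisible(x)
}

#' Write a reassignment report (TSV table + JSON summary)
#' @param report a [scan_codon_reassignment()] result.
#' @param path_tsv,path_json output files (either may be NULL).
#' @export
write_reassignment_report <- function(report, path_tsv = NULL, path_json = NULL) {
  tab <- data.frame(amino_acid = names(report$modal_fractions),
                    modal_fraction = unname(report$modal_fractions))
  if (!is.null(path_tsv)) {
    con <- file(path_tsv, "w")
    writeLines(sprintf("# %s scan: %d/%d columns retained (entropy < %g, gaps < %g)",
                       report$target_codon, report$n_retained,
                       report$n_candidate_columns, report$entropy_max,
                       report$gap_max), con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(path_json))
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         digits = 10)
  invisible(report)
}
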
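## Pairwise maximum-likelihood distances: the K80 closed form for nucleotide
## (mt-tRNA) sequences and numerically maximized WAG likelihood for amino-acid
## (aaRS) sequences, plus the mean-to-outgroup rates that feed the
## compensatory-substitution regression.
##
## Columns with a gap or ambiguity in either member of a pair are excluded
## pairwise.  Saturated pairs carry an infinite distance flag rather than
## raising an error, and are dropped (with a warning) from means.

.dist_estimate <- function(distance, se = NA_real_, n_sites, saturated = FALSE,
                           extra = list()) {
  structure(c(list(distance = distance, se = se, n_sites = n_sites,
                   saturated = saturated), extra),
            class = "dist_estimate")
}

#' @export
print.dist_estimate <- function(x, ...) {
  if (x$saturated)
    cat(sprintf("ML distance: saturated (infinite) over %d sites\n", x$n_sites))
  else
    cat(sprintf("ML distance: %.6f subst/site (n_sites = %d%s)\n", x$distance,
                x$n_sites,
                if (is.finite(x$se)) sprintf(", se = %.4f", x$se) else ""))
  invisible(x)
}

.pair_chars <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")")
  list(a = a, b = b)
}

#' Kimura two-parameter ML distance
#'
#' Closed-form maximum-likelihood estimate
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)}
#' with P and Q the transition and transversion proportions over columns where
#' both sequences carry an unambiguous base.  When a logarithm argument is
#' non-positive the pair is flagged saturated (infinite distance), not an
#' error.
#'
#' @param a,b equal-length (gapped) nucleotide strings or character vectors.
#' @return a `"dist_estimate"` with fields `distance`, `se`, `n_sites`,
#'   `saturated`, `p_transition`, `p_transversion`.
#' @export
k80_distance <- function(a, b) {
  p <- .pair_chars(a, b)
  ia <- .nt_index(p$a); ib <- .nt_index(p$b)
  keep <- !is.na(ia) & !is.na(ib)
  n <- sum(keep)
  if (n == 0L) stop("no comparable (both-ungapped, unambiguous) columns")
  ia <- ia[keep]; ib <- ib[keep]
  diffs <- ia != ib
  # purine A(1)<->G(3), pyrimidine C(2)<->T(4): transition iff same parity
  transition <- diffs & ((ia %% 2L) == (ib %% 2L))
  P <- sum(transition) / n
  Q <- sum(diffs & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  extra <- list(p_transition = P, p_transversion = Q)
  if (w1 <= 0 || w2 <= 0)
    return(.dist_estimate(Inf, n_sites = n, saturated = TRUE, extra = extra))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  # delta-method standard error (Kimura 1980)
  c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  .dist_estimate(max(d, 0), se = sqrt(max(v, 0)), n_sites = n, extra = extra)
}

## 20x20 site-pattern count table over both-unambiguous columns
.aa_pair_counts <- function(a, b) {
  p <- .pair_chars(a, b)
  ia <- .aa_index(p$a); ib <- .aa_index(p$b)
  keep <- !is.na(ia) & !is.na(ib)
  if (!sum(keep)) stop("no comparable (both-ungapped, unambiguous) columns")
  tab <- matrix(0, 20L, 20L)
  tt <- table(factor(ia[keep], levels = 1:20), factor(ib[keep], levels = 1:20))
  tab[] <- as.numeric(tt)
  tab
}

#' WAG maximum-likelihood pairwise distance
#'
#' Maximizes the reversible pairwise likelihood
#' \eqn{\sum_{sites} \ln (\pi_{a_i} P(t)_{a_i b_i})} over t by bounded scalar
#' search on \[1e-8, 50\] (tolerance 1e-6).  Rate-homogeneous (no Gamma), as
#' is standard for pairwise "WAG distances".
#'
#' @param a,b equal-length (gapped) amino-acid strings or character vectors.
#' @param model an [aa_model()]; defaults to [wag_model()].
#' @return a `"dist_estimate"`; `log_likelihood` holds the maximized value.
#' @export
wag_ml_distance <- function(a, b, model = wag_model()) {
  counts <- .aa_pair_counts(a, b)
  n <- sum(counts)
  lpi <- log(model$freqs)
  nll <- function(t) {
    P <- transition_probs(model, t)
    -sum(counts * (log(pmax(P, 1e-300)) + lpi))
  }
  if (sum(diag(counts)) == n)   # identical over compared columns: d = 0 exactly
    return(.dist_estimate(0, n_sites = n, extra = list(log_likelihood = -nll(1e-8))))
  opt <- stats::optimize(nll, interval = c(1e-8, 50), tol = 1e-6)
  .dist_estimate(opt$minimum, n_sites = n,
                 extra = list(log_likelihood = -opt$objective))
}

#' Mean ML distance from an outgroup to a set of ingroup sequences
#'
#' The per-family substitution rate: the arithmetic mean of the pairwise ML
#' distances between the outgroup row and each ingroup row of the alignment.
#' Saturated pairs are excluded with a warning; all pairs saturated is an
#' error.
#'
#' @param family an `msa` containing outgroup and ingroup rows.
#' @param outgroup_id row id of the outgroup sequence.
#' @param ingroup_ids row ids of the ingroup sequences.
#' @param kind `"WAG"` (amino acid) or `"K80"` (nucleotide).
#' @param model [aa_model()] used when `kind = "WAG"`.
#' @return numeric rate with attributes `n_pairs` and `n_saturated`.
#' @export
mean_outgroup_distance <- function(family, outgroup_id, ingroup_ids,
                                   kind = c("WAG", "K80"),
                                   model = NULL) {
  kind <- match.arg(kind)
  ids <- rownames(family)
  if (!outgroup_id %in% ids) stop("outgroup '", outgroup_id, "' not in alignment")
  ingroup_ids <- setdiff(ingroup_ids, outgroup_id)
  missing <- setdiff(ingroup_ids, ids)
  if (length(missing)) stop("ingroup id(s) not in alignment: ",
                            paste(missing, collapse = ", "))
  if (!length(ingroup_ids)) stop("no ingroup sequences")
  if (kind == "WAG" && is.null(model)) model <- wag_model()
  og <- unclass(family)[outgroup_id, ]
  ests <- lapply(ingroup_ids, function(id) {
    row <- unclass(family)[id, ]
    if (kind == "WAG") wag_ml_distance(og, row, model) else k80_distance(og, row)
  })
  sat <- vapply(ests, `[[`, TRUE, "saturated")
  if (all(sat)) stop("all outgroup-ingroup pairs saturated")
  if (any(sat))
    warning(sum(sat), " saturated pair(s) excluded from the mean: ",
            paste(ingroup_ids[sat], collapse = ", "))
  d <- vapply(ests[!sat], `[[`, 0, "distance")
  structure(mean(d), n_pairs = sum(!sat), n_saturated = sum(sat))
}

#' Write a distance matrix as a tab-separated table
#' @param d square numeric matrix with dimnames.
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  df <- data.frame(id = rownames(d),
                   apply(d, 2L, function(col) sprintf("%.6f", col)),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(d))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
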
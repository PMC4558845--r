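## Position-specific profile models built from curated alignments, the search
## instrument of the profiling pipeline.  The architecture is a lean local
## profile HMM (match/insert/delete states, uniform local entry/exit) with
## seeded Gumbel E-value calibration on background decoys -- a calibrated
## profile search, not a byte-compatible reimplementation of any particular
## search tool.

#' Build a profile model from an alignment
#'
#' Match columns are those with gap fraction below `gap_threshold`.  Emission
#' probabilities are Henikoff position-based weighted counts plus
#' background-proportional pseudocounts (total pseudocount mass 1 per
#' column); transitions come from weighted state-path counts with Laplace
#' smoothing.
#'
#' @param aln an amino-acid `msa`.
#' @param background 20 amino-acid background frequencies; defaults to the
#'   WAG equilibrium frequencies.
#' @param gap_threshold columns with at least this gap fraction become insert
#'   columns (0 < gap_threshold < 1).
#' @param id provenance tag; defaults to a digest of the row ids.
#' @return object of class `"profile_model"`.
#' @export
build_profile <- function(aln, background = NULL, gap_threshold = 0.5,
                          id = NULL) {
  stopifnot(inherits(aln, "msa"), nrow(aln) >= 1L,
            gap_threshold > 0, gap_threshold < 1)
  if (is.null(background)) background <- wag_model()$freqs
  background <- background / sum(background)
  m <- unclass(aln)
  nseq <- nrow(m); ncol_ <- ncol(m)
  gapfrac <- colMeans(m == "-")
  match_cols <- which(gapfrac < gap_threshold)
  M <- length(match_cols)
  if (M == 0L) stop("no match columns at gap threshold ", gap_threshold)

  w <- .henikoff_weights(m)

  enc <- .encode_msa(aln)                       # NA for gaps/ambiguity
  emis <- matrix(0, M, 20L, dimnames = list(NULL, AA_LETTERS))
  for (j in seq_len(M)) {
    col <- enc[, match_cols[j]]
    ok <- !is.na(col)
    cnt <- numeric(20L)
    if (any(ok)) {
      tt <- tapply(w[ok], col[ok], sum)
      cnt[as.integer(names(tt))] <- tt
    }
    e <- cnt + background                       # pseudocount mass 1
    emis[j, ] <- e / sum(e)
  }

  # state paths: M if residue at a match column, D if gap there; residues in
  # inter-match columns are I events attached to the preceding match column
  trans_counts <- matrix(0, M, 7L,
                         dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  is_match <- logical(ncol_); is_match[match_cols] <- TRUE
  prev_match <- cumsum(is_match)                # match column at or before j
  for (s in seq_len(nseq)) {
    row_res <- m[s, ] != "-"
    core <- ifelse(row_res[match_cols], "M", "D")
    j_ins <- which(!is_match & row_res)
    ins_count <- tabulate(prev_match[j_ins][prev_match[j_ins] >= 1L &
                                            prev_match[j_ins] < M], M)
    for (q in seq_len(M - 1L)) {
      a <- core[q]; b <- core[q + 1L]; ni <- ins_count[q]
      if (ni > 0L && a == "M") {
        # M -> I ... I -> next core state (I -> D has no Plan7 analogue;
        # the re-entry is counted as I -> M and smoothing absorbs the rest)
        trans_counts[q, "MI"] <- trans_counts[q, "MI"] + w[s]
        if (ni > 1L) trans_counts[q, "II"] <- trans_counts[q, "II"] + w[s] * (ni - 1L)
        trans_counts[q, "IM"] <- trans_counts[q, "IM"] + w[s]
      } else {
        trans_counts[q, paste0(a, b)] <- trans_counts[q, paste0(a, b)] + w[s]
      }
    }
  }
  # Laplace smoothing within each outgoing distribution
  tm <- matrix(0, M, 7L, dimnames = dimnames(trans_counts))
  cM <- trans_counts[, c("MM","MI","MD"), drop = FALSE] + 1
  tm[, c("MM","MI","MD")] <- cM / rowSums(cM)
  cI <- trans_counts[, c("IM","II"), drop = FALSE] + 1
  tm[, c("IM","II")] <- cI / rowSums(cI)
  cD <- trans_counts[, c("DM","DD"), drop = FALSE] + 1
  tm[, c("DM","DD")] <- cD / rowSums(cD)

  if (is.null(id))
    id <- sprintf("profile_%d x %d", nseq, M)
  structure(list(match_emissions = emis, insert_emissions = background,
                 transitions = tm, background = background,
                 n_match = M, match_columns = match_cols,
                 n_ref_columns = ncol_, source_alignment_id = id,
                 calibration = NULL),
            class = "profile_model")
}

## Henikoff position-based sequence weights, normalized to sum to nseq
.henikoff_weights <- function(m) {
  nseq <- nrow(m)
  if (nseq == 1L) return(1)
  w <- numeric(nseq)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ok <- col != "-"
    if (!any(ok)) next
    tab <- table(col[ok])
    r <- length(tab)
    w[ok] <- w[ok] + 1 / (r * tab[col[ok]])
  }
  if (sum(w) == 0) w[] <- 1
  w / sum(w) * nseq
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile model '%s': %d match columns (of %d alignment columns)%s\n",
              x$source_alignment_id, x$n_match, x$n_ref_columns,
              if (is.null(x$calibration)) ", uncalibrated" else ", calibrated"))
  invisible(x)
}

#' Score a target sequence against a profile
#'
#' Bit score is the log2 odds of the target under the profile (local
#' alignment, forward algorithm over all paths) against the background;
#' `match_path` is the Viterbi traceback mapping target residues to profile
#' match columns.  The forward score is always at least the Viterbi score.
#'
#' @param profile a [build_profile()] model.
#' @param target amino-acid string (or single-element [seq_set()]).
#' @return list: `bit_score`, `viterbi_bits`, `match_path` (data.frame
#'   `target_pos` 1-based, `match_col`), `target_interval` (0-based
#'   half-open).
#' @export
score_sequence <- function(profile, target) {
  if (inherits(target, "seq_set") || !is.null(names(target))) target <- target[[1]]
  stopifnot(nzchar(target))
  x <- .aa_index(strsplit(toupper(target), "", fixed = TRUE)[[1]])
  x[is.na(x)] <- 0L
  mesc <- log2(profile$match_emissions) -
    rep(log2(profile$background), each = profile$n_match)
  res <- .profile_dp_cpp(mesc, log2(profile$transitions), x,
                         entry = -log2(profile$n_match),
                         exit_ = -log2(profile$n_match))
  path <- data.frame(target_pos = res$path_i, match_col = res$path_k)
  interval <- if (nrow(path)) c(min(path$target_pos) - 1L, max(path$target_pos))
              else c(0L, 0L)
  list(bit_score = res$forward_bits, viterbi_bits = res$viterbi_bits,
       match_path = path, target_interval = interval)
}

#' Calibrate E-values for a profile
#'
#' Scores `n_decoys` i.i.d. background-sampled decoy sequences and fits a
#' Gumbel law to the bit scores by maximum likelihood.  The E-value of a
#' score S against a database of N sequences is `N * (1 - GumbelCDF(S))`.
#'
#' @param profile a profile model.
#' @param n_decoys number of decoys (>= 100).
#' @param decoy_length decoy length in residues; defaults to the profile
#'   length.
#' @param seed integer seed (calibration is deterministic under it).
#' @return the profile with a `calibration` element (`mu`, `beta`, ...).
#' @export
calibrate_evalues <- function(profile, n_decoys = 200L, decoy_length = NULL,
                              seed = 1L) {
  stopifnot(n_decoys >= 100L)
  if (is.null(decoy_length)) decoy_length <- profile$n_match
  scores <- .with_seed(child_seed(seed, paste0("calib_", profile$source_alignment_id)), {
    vapply(seq_len(n_decoys), function(i) {
      s <- paste(sample(AA_LETTERS, decoy_length, replace = TRUE,
                        prob = profile$background), collapse = "")
      score_sequence(profile, s)$bit_score
    }, 0)
  })
  if (stats::sd(scores) < 1e-9) stop("degenerate decoy score variance")
  fit <- .fit_gumbel(scores)
  profile$calibration <- c(fit, list(n_decoys = n_decoys,
                                     decoy_length = decoy_length, seed = seed))
  profile
}

## Gumbel (location mu, scale beta) maximum likelihood via the profile
## likelihood fixed point in beta
.fit_gumbel <- function(x) {
  xbar <- mean(x)
  g <- function(b) {
    w <- exp(-(x - max(x)) / b)
    b - xbar + sum(x * w) / sum(w)
  }
  s <- stats::sd(x)
  lo <- s / 20; hi <- s * 20
  # expand until sign change (g is increasing in b)
  while (g(lo) > 0 && lo > 1e-8) lo <- lo / 2
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
  mx <- max(x)
  mu <- mx - beta * log(mean(exp(-(x - mx) / beta)))
  list(mu = mu, beta = beta)
}

#' E-value of a bit score under a profile's calibration
#' @param profile calibrated profile.
#' @param score bit score(s).
#' @param n_db database size.
#' @export
profile_evalue <- function(profile, score, n_db) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated")
  z <- (score - cal$mu) / cal$beta
  n_db * (1 - exp(-exp(-z)))
}

#' Search a sequence database with a calibrated profile
#'
#' Keeps the best-scoring hit per target id, retains hits with E-value at or
#' below `e_cutoff`, and sorts ascending by E-value with ties broken by
#' descending bit score then lexicographic target id.
#'
#' @param profile calibrated profile.
#' @param db a [seq_set()] of amino-acid sequences.
#' @param e_cutoff E-value cutoff (default 1e-5, the pipeline's search gate).
#' @return data.frame of hits: `target_id`, `bit_score`, `e_value`,
#'   `start`, `end` (0-based half-open); `match_path` list-column.
#' @export
search_database <- function(profile, db, e_cutoff = 1e-5) {
  if (is.null(profile$calibration)) stop("profile is not calibrated")
  if (length(db) == 0L)
    return(data.frame(target_id = character(0), bit_score = numeric(0),
                      e_value = numeric(0), start = integer(0), end = integer(0)))
  scored <- lapply(seq_along(db), function(i) score_sequence(profile, db[[i]]))
  bits <- vapply(scored, `[[`, 0, "bit_score")
  ev <- profile_evalue(profile, bits, n_db = length(db))
  hits <- data.frame(target_id = names(db), bit_score = bits, e_value = ev,
                     start = vapply(scored, function(s) s$target_interval[1], 0L),
                     end = vapply(scored, function(s) s$target_interval[2], 0L))
  hits$match_path <- lapply(scored, `[[`, "match_path")
  hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  hits <- hits[order(hits$e_value, -hits$bit_score, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "profile_id") <- profile$source_alignment_id
  hits
}

#' Align a search hit into reference-alignment coordinates
#'
#' Places the hit's residues at the reference columns its Viterbi match path
#' maps to; unmatched reference columns are gapped; insert-state residues are
#' dropped.
#'
#' @param hit one row of a [search_database()] result (data.frame).
#' @param profile the profile the hit came from.
#' @param db the searched [seq_set()] (for the residue strings).
#' @return gapped amino-acid string of length `profile$n_ref_columns`.
#' @export
align_hit_to_reference <- function(hit, profile, db) {
  pid <- attr(hit, "profile_id")
  if (!is.null(pid) && !identical(pid, profile$source_alignment_id))
    stop("hit/profile provenance mismatch: hit from '", pid, "'")
  stopifnot(nrow(hit) == 1L)
  target <- strsplit(toupper(db[[hit$target_id]]), "", fixed = TRUE)[[1]]
  row <- rep("-", profile$n_ref_columns)
  mp <- hit$match_path[[1]]
  if (nrow(mp))
    row[profile$match_columns[mp$match_col]] <- target[mp$target_pos]
  paste(row, collapse = "")
}

#' Write a profile model to a plain-text file
#' @param profile profile model.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# profile %s", profile$source_alignment_id),
               sprintf("n_match\t%d", profile$n_match),
               sprintf("n_ref_columns\t%d", profile$n_ref_columns),
               sprintf("match_columns\t%s",
                       paste(profile$match_columns, collapse = ",")),
               sprintf("background\t%s",
                       paste(sprintf("%.8f", profile$background), collapse = ","))),
             con)
  for (k in seq_len(profile$n_match))
    writeLines(sprintf("M%d\t%s\t%s", k,
                       paste(sprintf("%.8f", profile$match_emissions[k, ]),
                             collapse = ","),
                       paste(sprintf("%.8f", profile$transitions[k, ]),
                             collapse = ",")), con)
  invisible(path)
}

#' Read a profile model written by [write_profile()]
#' @param path profile file.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  id <- sub("^# profile ", "", lines[1])
  kv <- strsplit(lines[2:5], "\t")
  n_match <- as.integer(kv[[1]][2])
  n_ref <- as.integer(kv[[2]][2])
  mc <- as.integer(strsplit(kv[[3]][2], ",")[[1]])
  bg <- as.numeric(strsplit(kv[[4]][2], ",")[[1]])
  names(bg) <- AA_LETTERS
  emis <- matrix(0, n_match, 20L, dimnames = list(NULL, AA_LETTERS))
  tm <- matrix(0, n_match, 7L,
               dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  for (k in seq_len(n_match)) {
    parts <- strsplit(lines[5L + k], "\t")[[1]]
    emis[k, ] <- as.numeric(strsplit(parts[2], ",")[[1]])
    tm[k, ] <- as.numeric(strsplit(parts[3], ",")[[1]])
  }
  structure(list(match_emissions = emis, insert_emissions = bg,
                 transitions = tm, background = bg, n_match = n_match,
                 match_columns = mc, n_ref_columns = n_ref,
                 source_alignment_id = id, calibration = NULL),
            class = "profile_model")
}
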
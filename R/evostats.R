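## The compensatory-substitution linear model.  Per amino-acid specificity i,
## Y_i is the aaRS substitution rate (mean WAG distance to the outgroup),
## X_i the mt-tRNA rate of the same specificity (mean K80 distance), and
## delta_mt indicates a mitochondrially functioning aaRS:
##
##   Y_i = beta0 + beta1 * delta_mt + beta2 * X_i + beta3 * X_i * delta_mt + eps_i
##
## beta1 captures rate elevation in mt-aaRS under relaxed selection, beta2
## the shared-specificity coupling to mt-tRNA rates, and beta3 the
## interaction attributable to compensatory substitutions.  Nested cases
## (beta3 = 0; beta3 = beta2 = 0) are compared by F-tests.  Fitting is plain
## homoskedastic OLS with two-sided t tests, as in the source analysis.

#' Construct a rate table
#'
#' @param x data.frame with columns `specificity`, `delta_mt` (0/1), `X`
#'   (mt-tRNA rate), `Y` (aaRS rate).
#' @param allow_negative permit negative Y (used by the Gaussian-noise
#'   simulator; measured rate tables must be non-negative).
#' @return the validated data.frame with class `"rate_table"`.
#' @export
rate_table <- function(x, allow_negative = FALSE) {
  need <- c("specificity", "delta_mt", "X", "Y")
  if (!all(need %in% names(x))) stop("rate table needs columns: ",
                                     paste(need, collapse = ", "))
  x <- as.data.frame(x)[, need]
  if (!all(x$delta_mt %in% c(0L, 1L))) stop("delta_mt must be 0 or 1")
  if (!all(is.finite(x$X)) || !all(is.finite(x$Y)))
    stop("X and Y must be finite")
  if (any(x$X < 0)) stop("X must be >= 0")
  if (!allow_negative && any(x$Y < 0)) stop("Y must be >= 0")
  key <- paste(x$specificity, x$delta_mt)
  if (anyDuplicated(key)) stop("duplicate (specificity, delta_mt) pair(s): ",
                               paste(unique(key[duplicated(key)]), collapse = ", "))
  class(x) <- c("rate_table", "data.frame")
  x
}

#' Assemble a rate table from distance summaries
#'
#' Pairs each aaRS rate with the mt-tRNA rate of the same specificity; the
#' tRNA rate is shared between the mitochondrial and cytosolic rows of a
#' specificity.  Saturation-flagged (non-finite) rates are dropped with a
#' warning; a specificity with an aaRS rate but no tRNA rate is an error.
#'
#' @param aars_rates data.frame with columns `specificity`, `lineage`
#'   (`"mt"`/`"cy"`), `rate`.
#' @param trna_rates named numeric vector, one rate per specificity.
#' @return a [rate_table()].
#' @export
assemble_rate_table <- function(aars_rates, trna_rates) {
  if (!nrow(aars_rates))
    return(rate_table(data.frame(specificity = character(0),
                                 delta_mt = integer(0),
                                 X = numeric(0), Y = numeric(0))))
  stopifnot(all(c("specificity", "lineage", "rate") %in% names(aars_rates)),
            all(aars_rates$lineage %in% c("mt", "cy")))
  miss <- setdiff(unique(aars_rates$specificity), names(trna_rates))
  if (length(miss)) stop("no mt-tRNA rate for specificity: ",
                         paste(miss, collapse = ", "))
  tab <- data.frame(specificity = aars_rates$specificity,
                    delta_mt = as.integer(aars_rates$lineage == "mt"),
                    X = unname(trna_rates[aars_rates$specificity]),
                    Y = aars_rates$rate)
  bad <- !is.finite(tab$X) | !is.finite(tab$Y)
  if (any(bad)) {
    warning(sum(bad), " row(s) with saturated/non-finite rates dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  rate_table(tab)
}

#' Fit the compensatory-substitution model
#'
#' Ordinary least squares (QR) for the full model or one of its nested
#' cases: `"no_interaction"` sets beta3 = 0, `"intercepts_only"` sets
#' beta3 = beta2 = 0.  Standard errors from sigma^2 (D'D)^-1, two-sided t
#' p-values on the residual degrees of freedom.
#'
#' @param table a [rate_table()].
#' @param model `"full"`, `"no_interaction"` or `"intercepts_only"`.
#' @return object of class `"comp_fit"`.
#' @export
fit_compensatory_model <- function(table,
                                   model = c("full", "no_interaction",
                                             "intercepts_only")) {
  model <- match.arg(model)
  stopifnot(inherits(table, "rate_table") || is.data.frame(table))
  form <- switch(model,
                 full = Y ~ delta_mt + X + delta_mt:X,
                 no_interaction = Y ~ delta_mt + X,
                 intercepts_only = Y ~ delta_mt)
  D <- stats::model.matrix(form, table)
  if (nrow(D) <= ncol(D)) stop("need more rows than parameters")
  if (qr(D)$rank < ncol(D)) stop("design matrix is rank deficient")
  fit <- stats::lm(form, data = table)
  sm <- suppressWarnings(summary(fit))   # noiseless tables trip the
                                         # "essentially perfect fit" warning
  cf <- sm$coefficients
  nice <- c(`(Intercept)` = "beta0", delta_mt = "beta1", X = "beta2",
            `delta_mt:X` = "beta3")
  rownames(cf) <- unname(nice[rownames(cf)])
  res <- stats::residuals(fit)
  structure(list(model_tag = model,
                 coefficients = cf[, 1],
                 standard_errors = cf[, 2],
                 t_statistics = cf[, 3],
                 p_values = cf[, 4],
                 residual_df = fit$df.residual,
                 sse = sum(res^2),
                 r_squared = sm$r.squared,
                 lm = fit, data = table),
            class = "comp_fit")
}

#' @export
coef.comp_fit <- function(object, ...) object$coefficients

#' @export
residuals.comp_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
predict.comp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$lm)
  else stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
print.comp_fit <- function(x, ...) {
  cat(sprintf("compensatory-substitution model (%s), n = %d\n",
              x$model_tag, nrow(x$data)))
  print(round(cbind(estimate = x$coefficients, se = x$standard_errors,
                    t = x$t_statistics, p = x$p_values), 5))
  cat(sprintf("SSE %.5g, R^2 %.3f, residual df %d\n",
              x$sse, x$r_squared, x$residual_df))
  invisible(x)
}

#' @export
summary.comp_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

.MODEL_ORDER <- c(intercepts_only = 1L, no_interaction = 2L, full = 3L)

#' F-test between nested compensatory-model fits
#'
#' @param restricted,full `"comp_fit"` objects on the same data, restricted
#'   nested inside full.
#' @return list of class `"nested_comparison"`: `f_statistic`, `df_num`,
#'   `df_den`, `p_value`, `model_pair`.
#' @export
nested_f_test <- function(restricted, full) {
  stopifnot(inherits(restricted, "comp_fit"), inherits(full, "comp_fit"))
  if (.MODEL_ORDER[restricted$model_tag] >= .MODEL_ORDER[full$model_tag])
    stop("'", restricted$model_tag, "' is not nested inside '",
         full$model_tag, "'")
  if (nrow(restricted$data) != nrow(full$data))
    stop("fits are not on the same data")
  df_num <- restricted$residual_df - full$residual_df
  df_den <- full$residual_df
  f <- ((restricted$sse - full$sse) / df_num) / (full$sse / df_den)
  f <- max(f, 0)
  p <- if (f == 0) 1 else stats::pf(f, df_num, df_den, lower.tail = FALSE)
  structure(list(model_pair = c(restricted$model_tag, full$model_tag),
                 f_statistic = f, df_num = df_num, df_den = df_den,
                 p_value = p),
            class = "nested_comparison")
}

#' @export
print.nested_comparison <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4f, p = %.4g  [%s vs %s]\n", x$df_num, x$df_den,
              x$f_statistic, x$p_value, x$model_pair[1], x$model_pair[2]))
  invisible(x)
}

#' Backward model selection by nested F-tests
#'
#' Operationalizes "most parsimonious linear model": starting from the full
#' model, drop the interaction if its F-test is non-significant at `alpha`,
#' then the slope likewise.  All three fits and both comparisons are
#' returned alongside the selection.
#'
#' @param table a [rate_table()].
#' @param alpha selection level (default 0.05).
#' @export
select_parsimonious_model <- function(table, alpha = 0.05) {
  fits <- list(full = fit_compensatory_model(table, "full"),
               no_interaction = fit_compensatory_model(table, "no_interaction"),
               intercepts_only = fit_compensatory_model(table, "intercepts_only"))
  cmp_interaction <- nested_f_test(fits$no_interaction, fits$full)
  cmp_slope <- nested_f_test(fits$intercepts_only, fits$no_interaction)
  selected <- if (cmp_interaction$p_value < alpha) "full"
              else if (cmp_slope$p_value < alpha) "no_interaction"
              else "intercepts_only"
  list(selected = fits[[selected]], selected_tag = selected, fits = fits,
       comparisons = list(interaction = cmp_interaction, slope = cmp_slope))
}

#' Correlation between mt- and cy-aaRS rates of shared specificity
#'
#' Pearson correlation (two-sided t-based p) between Y of the mitochondrial
#' and cytosolic rows across specificities having both.
#'
#' @param table a [rate_table()].
#' @return list: `r`, `p_value`, `n` (number of paired specificities).
#' @export
mt_cy_rate_correlation <- function(table) {
  mt <- table[table$delta_mt == 1L, c("specificity", "Y")]
  cy <- table[table$delta_mt == 0L, c("specificity", "Y")]
  both <- intersect(mt$specificity, cy$specificity)
  if (length(both) < 3L) stop("need >= 3 specificities with both mt and cy rows")
  ymt <- mt$Y[match(both, mt$specificity)]
  ycy <- cy$Y[match(both, cy$specificity)]
  ct <- stats::cor.test(ymt, ycy, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(both))
}

#' Write a rate table (tab-separated, with a provenance header comment)
#' @param table a [rate_table()].
#' @param path output file.
#' @param comment header comment (seeds, row counts).
#' @export
write_rate_table <- function(table, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# rate table: %d rows%s", nrow(table),
                     if (is.null(comment)) "" else paste0("; ", comment)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rate table written by [write_rate_table()]
#' @param path file.
#' @export
read_rate_table <- function(path) {
  rate_table(utils::read.table(path, header = TRUE, sep = "\t",
                               comment.char = "#"),
             allow_negative = TRUE)
}
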
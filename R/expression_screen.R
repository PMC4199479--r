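#' Preprocess a raw expression matrix
#'
#' Mirrors the standard bead-array post-processing arithmetic: subtract a
#' per-sample background offset, floor negative values to zero, quantile
#' normalize across samples (each sample's sorted values are replaced by
#' the rank-wise mean profile, with average-rank tie handling, via
#' limma), then transform to `log2(x + 1)`.
#'
#' @param raw numeric matrix, transcripts in rows, samples in columns,
#'   nonnegative intensities.
#' @param background scalar or per-sample vector of background offsets
#'   (default 0).
#' @return The processed log2-scale matrix, same dimnames.
#' @export
preprocess_expression <- function(raw, background = 0) {
  stopifnot(is.matrix(raw))
  x <- sweep(raw, 2, rep_len(background, ncol(raw)), `-`)
  x <- pmax(x, 0)
  zero_var <- apply(x, 2, function(col) var(col) == 0)
  if (any(zero_var))
    warning("zero-variance sample column(s): ",
            paste(colnames(x)[zero_var], collapse = ", "))
  x <- limma::normalizeQuantiles(x, ties = TRUE)
  log2(x + 1)
}

#' Simple regression of a trait on one transcript's expression
#'
#' Ordinary least squares of the phenotype (response) on expression
#' (predictor) over paired non-missing observations; the two-sided
#' p-value comes from the t distribution with n - 2 degrees of freedom.
#' A perfect fit is reported with the smallest representable positive
#' p-value rather than a division failure; zero-variance expression
#' yields a flagged result with missing slope and p.
#'
#' @param trait numeric phenotype vector.
#' @param expression numeric expression vector, same length.
#' @return list with `slope`, `se`, `p_value`, `n_used`, `reason` (`NA`
#'   on success).
#' @export
regress_trait_on_transcript <- function(trait, expression) {
  stopifnot(length(trait) == length(expression))
  cc <- complete.cases(trait, expression)
  n <- sum(cc)
  if (n < 3)
    return(list(slope = NA_real_, se = NA_real_, p_value = NA_real_,
                n_used = n, reason = "too_few_observations"))
  x <- expression[cc]; y <- trait[cc]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    return(list(slope = NA_real_, se = NA_real_, p_value = NA_real_,
                n_used = n, reason = "zero_variance_expression"))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  ssr <- sum((y - mean(y) - slope * (x - mean(x)))^2)
  se <- sqrt(ssr / (n - 2) / sxx)
  p <- if (se == 0) .Machine$double.xmin
       else max(2 * pt(abs(slope / se), n - 2, lower.tail = FALSE),
                .Machine$double.xmin)
  list(slope = slope, se = se, p_value = p, n_used = n, reason = NA_character_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity (via
#' [stats::p.adjust()]); missing entries are excluded from the adjustment
#' and returned missing, and input order is preserved.
#'
#' @param p numeric vector of p-values in (0, 1] (NAs allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Screen every transcript against a phenotype
#'
#' Runs [regress_trait_on_transcript()] for each transcript of an
#' expression matrix (closed-form OLS, vectorised), attaches per-transcript
#' mean level and range, and BH-adjusts the p-values.
#'
#' @param expr log2 expression matrix, transcripts x samples.
#' @param trait phenotype vector aligned with the columns of `expr`.
#' @return A data.frame (one row per transcript): `transcript_id`,
#'   `mean_level`, `range`, `slope`, `p_value`, `fdr_q`, `n_used`,
#'   `reason`.
#' @export
screen_transcripts <- function(expr, trait) {
  stopifnot(is.matrix(expr), ncol(expr) == length(trait))
  cc <- !is.na(trait)
  y <- trait[cc]
  X <- expr[, cc, drop = FALSE]
  res <- t(apply(X, 1, function(x) {
    r <- regress_trait_on_transcript(y, x)
    c(r$slope, r$se, r$p_value, r$n_used)
  }))
  out <- data.frame(transcript_id = rownames(expr),
                    mean_level = rowMeans(expr, na.rm = TRUE),
                    range = apply(expr, 1, function(x)
                      if (all(is.na(x))) NA_real_
                      else diff(range(x, na.rm = TRUE))),
                    slope = res[, 1], se = res[, 2], p_value = res[, 3],
                    n_used = as.integer(res[, 4]))
  out$fdr_q <- bh_fdr(out$p_value)
  out$reason <- ifelse(is.na(out$p_value), "degenerate_fit", NA_character_)
  rownames(out) <- NULL
  out
}

#' Filter screened transcripts into candidates
#'
#' A transcript passes when its BH q-value is below `fdr_threshold` and
#' its mean log2 level and expression range are not below the level and
#' range thresholds (exclusion is strict "below"). Transcripts on the
#' rescue list are exempted from the level/range filters -- but not the
#' FDR filter -- and flagged `rescued`, reflecting candidates retained
#' for biological importance despite low or flat expression.
#'
#' @param summaries data.frame from [screen_transcripts()].
#' @param fdr_threshold,level_threshold,range_threshold defaults 0.3, 6
#'   and 2.
#' @param rescue character vector of transcript ids to exempt.
#' @return `summaries` with an added `candidate_flag` column
#'   (`"pass"`/`"fail"`/`"rescued"`); the candidate set is the rows with
#'   flag != "fail".
#' @export
filter_candidates <- function(summaries, fdr_threshold = 0.3,
                              level_threshold = 6, range_threshold = 2,
                              rescue = character(0)) {
  q_ok <- !is.na(summaries$fdr_q) & summaries$fdr_q < fdr_threshold
  expr_ok <- summaries$mean_level >= level_threshold &
    summaries$range >= range_threshold
  flag <- rep("fail", nrow(summaries))
  flag[q_ok & expr_ok] <- "pass"
  flag[q_ok & !expr_ok & summaries$transcript_id %in% rescue] <- "rescued"
  summaries$candidate_flag <- flag
  summaries
}

#' Relative expression by the double-delta-Ct method
#'
#' `2^-((Ct_target_sample - Ct_control_sample) -
#' (Ct_target_reference - Ct_control_reference))`: one qPCR cycle of
#' difference corresponds to a two-fold expression change.
#'
#' @param ct_target_sample,ct_control_sample Ct of the target and the
#'   control (housekeeping) gene in the test sample.
#' @param ct_target_ref,ct_control_ref the same pair in the reference
#'   sample.
#' @return Relative expression (fold change), vectorised.
#' @examples
#' delta_delta_ct(25, 20, 24, 20)  # 0.5
#' @export
delta_delta_ct <- function(ct_target_sample, ct_control_sample,
                           ct_target_ref, ct_control_ref) {
  ddct <- (ct_target_sample - ct_control_sample) -
    (ct_target_ref - ct_control_ref)
  2^(-ddct)
}

#' Verify screen candidates on qPCR measurements
#'
#' Re-runs the trait-on-expression regression on qPCR-derived relative
#' expression for each candidate and keeps those with nominal p < alpha.
#'
#' @param qpcr numeric matrix, candidates x samples, relative expression
#'   (e.g. from [delta_delta_ct()]).
#' @param trait phenotype vector aligned with the columns.
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame `transcript_id`, `slope`, `p_value`, `verified`.
#' @export
verify_candidates <- function(qpcr, trait, alpha = 0.05) {
  stopifnot(is.matrix(qpcr))
  if (nrow(qpcr) == 0)
    return(data.frame(transcript_id = character(), slope = numeric(),
                      p_value = numeric(), verified = logical()))
  res <- lapply(seq_len(nrow(qpcr)), function(i)
    regress_trait_on_transcript(trait, qpcr[i, ]))
  data.frame(transcript_id = rownames(qpcr),
             slope = vapply(res, `[[`, numeric(1), "slope"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             verified = vapply(res, function(r)
               !is.na(r$p_value) && r$p_value < alpha, logical(1)),
             row.names = NULL)
}
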
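#' Covariate-adjusted single-variant regression
#'
#' Ordinary least squares of the (optionally log-transformed) trait on an
#' intercept, age, sex and one coded genotype column, on complete cases.
#' The reported beta, standard error and two-sided t-test p-value belong
#' to the genotype coefficient. Sex enters the design as female = 0,
#' male = 1.
#'
#' @param trait numeric trait vector (raw counts; transformed internally
#'   when the model tag requests `log`).
#' @param pheno data.frame aligned with `trait`, providing `age` and
#'   `sex`.
#' @param geno coded genotype column aligned with `trait`.
#' @param model model tag `"unt_add"`, `"log_add"`, `"unt_dom"` or
#'   `"log_dom"`; only the `unt`/`log` prefix changes the fit (the coding
#'   is assumed already applied to `geno`), but the tag is carried into
#'   the result.
#' @param target_id identifier copied into the result row.
#' @return A one-row data.frame of class `association_results`:
#'   `target_id`, `model`, `beta`, `se`, `p_value`, `n_used`, `reason`
#'   (`NA` on success, a code such as `"constant_genotype"` otherwise).
#' @export
single_variant_regression <- function(trait, pheno, geno,
                                      model = "unt_add",
                                      target_id = "variant") {
  stopifnot(length(trait) == nrow(pheno), length(geno) == length(trait))
  y <- if (startsWith(model, "log")) transform_trait(trait) else trait
  sexn <- sex_numeric(pheno$sex)
  cc <- complete.cases(y, pheno$age, sexn, geno)
  n <- sum(cc)
  empty <- function(reason)
    structure(data.frame(target_id = target_id, model = model,
                         beta = NA_real_, se = NA_real_, p_value = NA_real_,
                         n_used = n, reason = reason),
              class = c("association_results", "data.frame"))
  if (n < 6) return(empty("too_few_complete_cases"))
  if (var(geno[cc]) == 0) return(empty("constant_genotype"))
  fit <- lm(y[cc] ~ pheno$age[cc] + sexn[cc] + geno[cc])
  co <- summary(fit)$coefficients
  if (!"geno[cc]" %in% rownames(co)) return(empty("collinear_genotype"))
  structure(data.frame(target_id = target_id, model = model,
                       beta = co["geno[cc]", "Estimate"],
                       se = co["geno[cc]", "Std. Error"],
                       p_value = co["geno[cc]", "Pr(>|t|)"],
                       n_used = n, reason = NA_character_),
            class = c("association_results", "data.frame"))
}

sex_numeric <- function(sex) {
  if (is.numeric(sex)) return(sex)
  out <- rep(NA_real_, length(sex))
  out[sex == "female"] <- 0
  out[sex == "male"] <- 1
  out
}

#' Residualize a trait on age and sex
#'
#' Pre-adjustment used before tiled regression: the trait is regressed on
#' an intercept, age and sex, and the residuals (mean zero on the
#' complete cases) are returned in the original sample order with `NA`
#' where any input was missing.
#'
#' @inheritParams single_variant_regression
#' @param transform `"unt"` or `"log"`.
#' @return Numeric residual vector, same length as `trait`.
#' @export
residualize_trait <- function(trait, pheno, transform = "unt") {
  y <- if (transform == "log") transform_trait(trait) else trait
  sexn <- sex_numeric(pheno$sex)
  cc <- complete.cases(y, pheno$age, sexn)
  out <- rep(NA_real_, length(y))
  fit <- lm(y[cc] ~ pheno$age[cc] + sexn[cc])
  out[cc] <- stats::residuals(fit)
  out
}

# p-value of each coefficient (excluding intercept) of lm(y ~ X[, cols]).
# Returns the summary coefficient table rows for the requested columns.
fit_terms <- function(y, X, cols) {
  d <- data.frame(y = y, X[, cols, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = d)
  co <- summary(fit)$coefficients
  rn <- rownames(co)
  # lm backtick-quotes non-syntactic names
  clean <- gsub("`", "", rn)
  list(fit = fit, coefs = co, names = clean)
}

coef_p <- function(ft, col) {
  i <- match(col, ft$names)
  if (is.na(i)) NA_real_ else ft$coefs[i, "Pr(>|t|)"]
}

#' Forward stepwise regression with backward elimination
#'
#' At each forward step the candidate with the smallest partial p-value
#' enters if that p-value is below `entry_alpha` (ties broken by the
#' lowest genomic coordinate via `order_key`); after every entry, terms
#' whose p-value in the refitted joint model is `>= stay_alpha` are
#' removed one at a time (worst first) until all retained terms are
#' significant. The procedure stops when no candidate can enter.
#'
#' @param y response vector (typically a residualized trait).
#' @param X numeric design-column matrix.
#' @param candidates column names of `X` eligible for selection.
#' @param entry_alpha,stay_alpha entry and retention critical levels
#'   (default 0.05 each).
#' @param order_key numeric vector (parallel to `candidates`) used for
#'   deterministic tie-breaking; smaller wins.
#' @return list with `selected` (character vector, entry order),
#'   `trace` (data.frame of step, action, term, p).
#' @export
stepwise_select <- function(y, X, candidates = colnames(X),
                            entry_alpha = 0.05, stay_alpha = 0.05,
                            order_key = seq_along(candidates)) {
  stopifnot(length(order_key) == length(candidates))
  selected <- character(0)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > 10L * (length(candidates) + 1L)) break  # cycle guard
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    pvals <- vapply(pool, function(cd) {
      ft <- tryCatch(fit_terms(y, X, c(selected, cd)),
                     error = function(e) NULL)
      if (is.null(ft)) NA_real_ else coef_p(ft, cd)
    }, numeric(1))
    ok <- !is.na(pvals)
    if (!any(ok)) break
    best_p <- min(pvals[ok])
    if (best_p >= entry_alpha) break
    tied <- pool[ok][pvals[ok] <= best_p]
    best <- tied[which.min(order_key[match(tied, candidates)])]
    selected <- c(selected, best)
    trace[[length(trace) + 1]] <-
      data.frame(step = step, action = "enter", term = best, p = best_p)
    # backward look: prune any term no longer holding its own
    repeat {
      ft <- fit_terms(y, X, selected)
      ps <- vapply(selected, function(tm) coef_p(ft, tm), numeric(1))
      ps[is.na(ps)] <- 1  # collinear term carries no information
      if (max(ps) < stay_alpha) break
      worst <- selected[which.max(ps)]
      selected <- setdiff(selected, worst)
      trace[[length(trace) + 1]] <-
        data.frame(step = step, action = "remove", term = worst,
                   p = max(ps))
      if (length(selected) == 0) break
    }
  }
  list(selected = selected,
       trace = if (length(trace) > 0) do.call(rbind, trace)
               else data.frame(step = integer(), action = character(),
                               term = character(), p = numeric()))
}

#' Hotspot-tiled stepwise regression
#'
#' The tiled procedure for selecting independent trait-associated
#' variants: (1) each hotspot-delimited tile is screened by the overall
#' F-test of the multiple regression of the (pre-adjusted) trait on all
#' of the tile's columns, and by per-column simple regressions -- a tile
#' survives if the F-test p-value is below `tile_alpha` (0.2) or any
#' single column is significant below `snv_alpha` (0.05); (2) within each
#' surviving tile a forward stepwise regression with backward elimination
#' ([stepwise_select()], entry and retention at 0.05) picks the tile's
#' independent columns; (3) tile survivors are pooled per chromosome and
#' the stepwise is rerun; (4) chromosome survivors are pooled genome-wide
#' and the stepwise is rerun once more. The final joint model is refitted
#' and reported.
#'
#' When a tile holds more columns than available complete cases, its
#' F-test is skipped (single-column screen only) and this is noted in the
#' screen table.
#'
#' @param y_resid residualized trait (see [residualize_trait()]).
#' @param coded a [code_genotypes()] result (design matrix plus column
#'   map); collapsed columns are tile-level terms.
#' @param tiles the tile map (used for screen bookkeeping; the column map
#'   already carries tile assignments).
#' @param entry_alpha,stay_alpha,tile_alpha,snv_alpha critical levels;
#'   defaults 0.05, 0.05, 0.2, 0.05.
#' @return An object of class `tiled_model`: list with `selected`
#'   (data.frame `column_id`, `beta`, `se`, `p_value` from the final
#'   joint fit), `intercept`, `screen` (per-tile screen outcomes),
#'   `tile_survivors`, `trace` (stepwise traces per level), `n_used`.
#' @export
tiled_regression <- function(y_resid, coded, tiles = NULL,
                             entry_alpha = 0.05, stay_alpha = 0.05,
                             tile_alpha = 0.2, snv_alpha = 0.05) {
  X <- coded$X
  map <- coded$map
  stopifnot(nrow(X) == length(y_resid))
  tile_ids <- unique(map$tile_id)
  screen <- data.frame(tile_id = tile_ids, n_columns = NA_integer_,
                       f_p = NA_real_, min_single_p = NA_real_,
                       f_skipped = FALSE, retained = FALSE)
  survivors <- list()
  traces <- list()
  for (tl in tile_ids) {
    cols <- map$column_id[map$tile_id %in% tl]
    i <- which(screen$tile_id == tl)
    screen$n_columns[i] <- length(cols)
    cc <- complete.cases(y_resid, X[, cols, drop = FALSE])
    single_p <- vapply(cols, function(cd) {
      ft <- tryCatch(fit_terms(y_resid, X, cd), error = function(e) NULL)
      if (is.null(ft)) NA_real_ else coef_p(ft, cd)
    }, numeric(1))
    screen$min_single_p[i] <- suppressWarnings(min(single_p, na.rm = TRUE))
    if (length(cols) >= sum(cc) - 1) {
      screen$f_skipped[i] <- TRUE
      message("tile ", tl, ": more columns than complete cases; ",
              "F-test skipped, single-column screen only")
    } else {
      ft <- tryCatch(fit_terms(y_resid, X, cols), error = function(e) NULL)
      if (!is.null(ft)) {
        fs <- summary(ft$fit)$fstatistic
        if (!is.null(fs))
          screen$f_p[i] <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
      }
    }
    screen$retained[i] <-
      (!is.na(screen$f_p[i]) && screen$f_p[i] < tile_alpha) ||
      (is.finite(screen$min_single_p[i]) &&
         screen$min_single_p[i] < snv_alpha)
    if (screen$retained[i]) {
      sw <- stepwise_select(y_resid, X, cols, entry_alpha, stay_alpha,
                            order_key = map$pos[match(cols, map$column_id)])
      survivors[[tl]] <- sw$selected
      traces[[paste0("tile:", tl)]] <- sw$trace
    }
  }
  # chromosome level
  chrom_of <- map$chrom[match(unlist(survivors), map$column_id)]
  chrom_survivors <- character(0)
  for (ch in unique(chrom_of)) {
    cols <- unlist(survivors)[chrom_of == ch]
    sw <- stepwise_select(y_resid, X, cols, entry_alpha, stay_alpha,
                          order_key = map$pos[match(cols, map$column_id)])
    chrom_survivors <- c(chrom_survivors, sw$selected)
    traces[[paste0("chrom:", ch)]] <- sw$trace
  }
  # genome level
  final <- character(0)
  if (length(chrom_survivors) > 0) {
    sw <- stepwise_select(y_resid, X, chrom_survivors, entry_alpha,
                          stay_alpha,
                          order_key = map$pos[match(chrom_survivors,
                                                    map$column_id)])
    final <- sw$selected
    traces[["genome"]] <- sw$trace
  }
  selected <- data.frame(column_id = character(), beta = numeric(),
                         se = numeric(), p_value = numeric())
  intercept <- NA_real_
  n_used <- NA_integer_
  if (length(final) > 0) {
    ft <- fit_terms(y_resid, X, final)
    i <- match(final, ft$names)
    selected <- data.frame(column_id = final,
                           beta = ft$coefs[i, "Estimate"],
                           se = ft$coefs[i, "Std. Error"],
                           p_value = ft$coefs[i, "Pr(>|t|)"])
    rownames(selected) <- NULL
    intercept <- ft$coefs[match("(Intercept)", ft$names), "Estimate"]
    n_used <- length(stats::fitted(ft$fit))
  }
  structure(list(selected = selected, intercept = intercept,
                 screen = screen, tile_survivors = survivors,
                 trace = traces, n_used = n_used),
            class = "tiled_model")
}

#' @export
print.tiled_model <- function(x, ...) {
  cat("tiled regression:", sum(x$screen$retained), "of",
      nrow(x$screen), "tiles past screen;",
      nrow(x$selected), "column(s) in the final model\n")
  if (nrow(x$selected) > 0) print(x$selected)
  invisible(x)
}

#' Liptak (weighted-Z) meta-analysis of cohort p-values
#'
#' Each cohort's p-value is mapped to a normal quantile
#' `z_i = qnorm(1 - p_i)` and the quantiles are combined with
#' square-root-of-sample-size weights:
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, reported as
#' `combined_p = 1 - pnorm(Z)`. By default the mapping uses the p-values
#' alone, ignoring the sign of the cohort effect estimates (the
#' convention under which the published meta column is reproduced even
#' where cohort betas disagree in sign); with `signs` supplied, the
#' signed variant `z_i = sign_i * qnorm(1 - p_i / 2)` is used instead.
#'
#' @param p numeric vector of cohort p-values, strictly inside (0, 1).
#' @param n positive cohort sample sizes, same length.
#' @param target_id,model identifiers carried into the result.
#' @param signs optional vector of effect signs (+1/-1) switching to the
#'   signed two-sided convention.
#' @return A one-row data.frame of class `meta_results`: `target_id`,
#'   `model`, per-cohort `p_i`/`n_i` columns, `combined_z`, `combined_p`.
#' @examples
#' liptak_meta(c(0.030, 0.329, 0.208), c(89, 29, 62))$combined_p  # ~0.024
#' @export
liptak_meta <- function(p, n, target_id = "target", model = "unt_add",
                        signs = NULL) {
  stopifnot(length(p) == length(n), length(p) >= 1)
  if (any(p <= 0 | p >= 1))
    stop("p-values must lie strictly inside (0, 1)")
  if (any(n < 1)) stop("cohort sizes must be >= 1")
  z <- if (is.null(signs)) qnorm(1 - p)
       else {
         stopifnot(length(signs) == length(p), all(signs %in% c(-1, 1)))
         signs * qnorm(1 - p / 2)
       }
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  out <- data.frame(target_id = target_id, model = model)
  for (i in seq_along(p)) out[[paste0("p_", i)]] <- p[i]
  for (i in seq_along(n)) out[[paste0("n_", i)]] <- n[i]
  out$combined_z <- Z
  out$combined_p <- pnorm(Z, lower.tail = FALSE)
  structure(out, class = c("meta_results", "data.frame"))
}

#' Pooled mega-analysis across cohorts
#'
#' Stacks the cohorts' individual-level data and fits one OLS model of
#' the trait on intercept, age, sex, cohort indicator variables and the
#' coded genotype; the genotype coefficient is reported.
#'
#' @param trait,pheno,geno stacked trait vector, phenotype table (with a
#'   `cohort` column) and coded genotype, all aligned.
#' @inheritParams single_variant_regression
#' @return A one-row `association_results` data.frame (see
#'   [single_variant_regression()]).
#' @export
mega_analysis <- function(trait, pheno, geno, model = "unt_add",
                          target_id = "variant") {
  stopifnot(length(trait) == nrow(pheno), length(geno) == length(trait))
  if (length(unique(pheno$cohort)) < 2)
    stop("mega-analysis needs at least two cohorts")
  y <- if (startsWith(model, "log")) transform_trait(trait) else trait
  sexn <- sex_numeric(pheno$sex)
  cohort <- factor(pheno$cohort)
  cc <- complete.cases(y, pheno$age, sexn, geno) & !is.na(cohort)
  n <- sum(cc)
  empty <- function(reason)
    structure(data.frame(target_id = target_id, model = model,
                         beta = NA_real_, se = NA_real_, p_value = NA_real_,
                         n_used = n, reason = reason),
              class = c("association_results", "data.frame"))
  if (n < length(levels(cohort)) + 4) return(empty("too_few_complete_cases"))
  if (var(geno[cc]) == 0) return(empty("constant_genotype"))
  d <- data.frame(y = y[cc], age = pheno$age[cc], sex = sexn[cc],
                  cohort = droplevels(cohort[cc]), geno = geno[cc])
  fit <- lm(y ~ age + sex + cohort + geno, data = d)
  co <- summary(fit)$coefficients
  if (!"geno" %in% rownames(co)) return(empty("collinear_genotype"))
  structure(data.frame(target_id = target_id, model = model,
                       beta = co["geno", "Estimate"],
                       se = co["geno", "Std. Error"],
                       p_value = co["geno", "Pr(>|t|)"],
                       n_used = n, reason = NA_character_),
            class = c("association_results", "data.frame"))
}
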
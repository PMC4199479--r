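# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# OLS via explicit normal equations (no lm): returns beta, se, two-sided
# t p-values for every coefficient of y ~ [1, X].
ols_oracle <- function(y, X) {
  X1 <- cbind(Intercept = 1, X)
  XtX <- t(X1) %*% X1
  beta <- solve(XtX, t(X1) %*% y)
  res <- y - X1 %*% beta
  df <- length(y) - ncol(X1)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  list(beta = drop(beta), se = se,
       p = 2 * pt(abs(drop(tval)), df, lower.tail = FALSE),
       residuals = drop(res), df = df)
}

# Exact HWE test by the Wigginton-style recurrence: builds the full
# conditional distribution of heterozygote counts from probability
# ratios (no lgamma), then sums probabilities <= the observed one.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nm <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    # P(h+2)/P(h) = 4 * n_hom_minor(h) * n_hom_major(h) / ((h+2)(h+1))
    probs[k] <- probs[k - 1] * 4 * ((nm - h) / 2) * (n - (nm + h) / 2) /
      ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# Full conditional het-count distribution for a given (n, nm), plus the
# p-value of every possible observed het count, via the same recurrence.
# Used to check hwe_exact_test exhaustively without 1e5 recurrences.
hwe_oracle_all <- function(n, nm) {
  hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    probs[k] <- probs[k - 1] * 4 * ((nm - h) / 2) * (n - (nm + h) / 2) /
      ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  pvals <- vapply(probs, function(po)
    min(1, sum(probs[probs <= po * (1 + 1e-12)])), numeric(1))
  list(hets = hets, pvals = pvals)
}

# Benjamini-Hochberg by explicit step-up enumeration: for the item of
# ascending rank r among m, q = min over j >= r of m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (r in seq_len(m)) {
    cand <- Inf
    for (j in r:m) cand <- min(cand, m * ps[j] / j)
    q[r] <- min(1, cand)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# All length-k combinations (with repetition, ascending) from a grid.
grid_combos <- function(grid, k) {
  idx <- utils::combn(length(grid) + k - 1, k)
  idx <- idx - (seq_len(k) - 1)
  matrix(grid[idx], nrow = k)
}

# Independent forward-stepwise-with-backward-look executor, written as a
# direct transcription of the procedure (drop1-style, separate from the
# package's stepwise_select). Returns the same trace shape.
stepwise_oracle <- function(y, X, candidates, entry = 0.05, stay = 0.05,
                            pos = seq_along(candidates)) {
  sel <- character(0)
  trace <- list()
  step <- 0L
  term_p <- function(cols, term) {
    d <- as.data.frame(X[, cols, drop = FALSE])
    names(d) <- cols
    d$..y <- y
    fit <- stats::lm(..y ~ ., data = d)
    sm <- summary(fit)$coefficients
    i <- match(term, gsub("`", "", rownames(sm)))
    if (is.na(i)) NA_real_ else sm[i, 4]
  }
  repeat {
    step <- step + 1L
    pool <- setdiff(candidates, sel)
    if (length(pool) == 0 || step > 200) break
    ps <- vapply(pool, function(cd) term_p(c(sel, cd), cd), numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= entry) break
    best_p <- min(ps, na.rm = TRUE)
    tied <- pool[!is.na(ps) & ps <= best_p]
    best <- tied[order(pos[match(tied, candidates)])[1]]
    sel <- c(sel, best)
    trace[[length(trace) + 1]] <- c(action = "enter", term = best)
    repeat {
      ps2 <- vapply(sel, function(tm) term_p(sel, tm), numeric(1))
      ps2[is.na(ps2)] <- 1
      if (max(ps2) < stay) break
      worst <- sel[which.max(ps2)]
      sel <- setdiff(sel, worst)
      trace[[length(trace) + 1]] <- c(action = "remove", term = worst)
      if (length(sel) == 0) break
    }
  }
  list(selected = sel,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

# Small genotype_matrix builder for hand fixtures.
make_gm <- function(calls, quality = NULL, chrom = "chr1",
                    pos = NULL) {
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("v%02d", seq_len(ncol(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 100L
  nv <- ncol(calls)
  ids <- colnames(calls)
  if (is.null(ids)) ids <- character(0)
  genotype_matrix(calls,
                  data.frame(variant_id = ids,
                             chrom = rep(chrom, nv), pos = pos,
                             ref_allele = rep("A", nv),
                             alt_allele = rep("G", nv)),
                  quality)
}

# Minimal phenotype table for regression fixtures.
make_pheno <- function(n, seed = 1, cohort = "DISC") {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             age = round(runif(n, 5, 60), 1),
             sex = sample(c("male", "female"), n, replace = TRUE),
             cohort = cohort, stringsAsFactors = FALSE)
}
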
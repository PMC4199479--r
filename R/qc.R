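#' Mask low-quality genotype calls
#'
#' Calls whose per-call quality score falls strictly below the threshold
#' (polyphred convention: 99) are set to missing; all other calls are left
#' untouched.
#'
#' @param gm a [genotype_matrix()] with quality scores.
#' @param threshold calls with `quality < threshold` become missing.
#' @return The masked `genotype_matrix`.
#' @export
mask_low_quality_calls <- function(gm, threshold = 99) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$quality)) stop("genotype matrix carries no quality scores")
  gm$calls[!is.na(gm$quality) & gm$quality < threshold] <- NA_integer_
  gm
}

#' Exclude samples with excessive genotype missingness
#'
#' @param gm a [genotype_matrix()] (quality masking already applied).
#' @param threshold samples whose fraction of missing calls is strictly
#'   greater than this are excluded (default 0.30).
#' @return list with `genotypes` (remaining samples, original order) and
#'   `excluded`, a data.frame of `sample_id`, `missing_rate`, `reason`.
#' @export
filter_samples_by_missingness <- function(gm, threshold = 0.30) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rate <- rowMeans(is.na(gm$calls))
  if (ncol(gm$calls) == 0) rate[] <- 0
  drop <- rate > threshold
  excluded <- data.frame(sample_id = rownames(gm$calls)[drop],
                         missing_rate = unname(rate[drop]),
                         reason = rep("sample_missingness", sum(drop)))
  list(genotypes = subset_genotypes(gm, samples = !drop), excluded = excluded)
}

#' Exclude variants with excessive genotype missingness
#'
#' @param gm a [genotype_matrix()] (sample filter already applied; the
#'   QC order is mask, then samples, then variants).
#' @param threshold variants with missing fraction strictly greater than
#'   this among retained samples are excluded (default 0.20).
#' @return list with `genotypes` and `excluded` (`variant_id`,
#'   `missing_rate`, `reason`).
#' @export
filter_variants_by_missingness <- function(gm, threshold = 0.20) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rate <- colMeans(is.na(gm$calls))
  if (nrow(gm$calls) == 0) rate[] <- 0
  drop <- rate > threshold
  excluded <- data.frame(variant_id = colnames(gm$calls)[drop],
                         missing_rate = unname(rate[drop]),
                         reason = rep("variant_missingness", sum(drop)))
  list(genotypes = subset_genotypes(gm, variants = !drop), excluded = excluded)
}

#' Drop monomorphic variants
#'
#' A variant is monomorphic when all of its non-missing calls are equal;
#' a variant with no non-missing calls at all is also dropped, with its
#' own reason code.
#'
#' @param gm a [genotype_matrix()].
#' @return list with `genotypes` and `excluded` (`variant_id`, `reason`
#'   one of `"monomorphic"`/`"all_missing"`).
#' @export
drop_monomorphic <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_distinct <- apply(gm$calls, 2, function(x) length(unique(x[!is.na(x)])))
  reason <- ifelse(n_distinct == 0, "all_missing",
                   ifelse(n_distinct == 1, "monomorphic", NA))
  drop <- !is.na(reason)
  excluded <- data.frame(variant_id = colnames(gm$calls)[drop],
                         reason = reason[drop])
  list(genotypes = subset_genotypes(gm, variants = !drop), excluded = excluded)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' The exact conditional test: conditional on the observed allele counts,
#' the p-value is the sum of the probabilities of all heterozygote counts
#' whose probability does not exceed that of the observed configuration.
#' Genotype probabilities follow the standard conditional distribution
#' `P(n_het | n, n_minor)` with the `2^n_het` phase factor.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (major homozygote,
#'   heterozygote, minor homozygote).
#' @return The exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # ~1: perfect HW proportions
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1, length(n_Aa) == 1, length(n_aa) == 1)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("no genotypes observed")
  nm <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  # log P(n_het = h | n, nm) up to the common normalising constant
  logp <- lgamma(n + 1) - lgamma((nm - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (nm + hets) / 2 + 1) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Select one representative per family
#'
#' Families are the connected components of the parent-offspring links in
#' the phenotype table. Within each multi-member family the
#' lexicographically smallest sample id is retained; singletons are always
#' retained. Used to form the unrelated subset on which Hardy-Weinberg
#' proportions are tested.
#'
#' @param pheno data.frame with `sample_id` and optional `father_id`,
#'   `mother_id`.
#' @return Character vector of retained (unrelated) sample ids.
#' @export
select_unrelated <- function(pheno) {
  ids <- as.character(pheno$sample_id)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  link <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (col in intersect(c("father_id", "mother_id"), names(pheno))) {
    p <- as.character(pheno[[col]])
    for (i in which(!is.na(p) & p %in% ids)) link(i, match(p[i], ids))
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  keep <- unlist(lapply(split(seq_along(ids), comp),
                        function(ix) ix[order(ids[ix])[1]]))
  sort(ids[keep])
}

#' Mendelian consistency of a trio genotype
#'
#' A child call is consistent when some pair of alleles transmissible from
#' the father and the mother sums to it; any missing member makes the trio
#' untestable at that site.
#'
#' @param child,father,mother minor-allele dosages in `{0, 1, 2, NA}`.
#' @return `"consistent"`, `"inconsistent"` or `"untestable"`.
#' @examples
#' mendelian_trio_check(2, 0, 0)  # inconsistent
#' mendelian_trio_check(1, 0, 2)  # consistent (forced heterozygote)
#' @export
mendelian_trio_check <- function(child, father, mother) {
  if (is.na(child) || is.na(father) || is.na(mother)) return("untestable")
  stopifnot(child %in% 0:2, father %in% 0:2, mother %in% 0:2)
  transmissible <- function(g) switch(as.character(g),
                                      `0` = 0L, `1` = 0:1, `2` = 1L)
  possible <- outer(transmissible(father), transmissible(mother), `+`)
  if (child %in% possible) "consistent" else "inconsistent"
}

#' Minor allele frequency of a call vector
#'
#' Frequencies are folded to at most 0.5: when the coded allele exceeds
#' frequency 0.5 the complementary (reference-side) allele is reported as
#' the minor one.
#'
#' @param calls dosages in `{0,1,2,NA}` counting the coded allele.
#' @return list with `maf` (in `[0, 0.5]`) and `minor` (`"coded"` if the
#'   coded allele is minor, `"other"` if the frequency was folded).
#' @export
compute_maf <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("all calls missing; MAF undefined")
  f <- sum(calls) / (2 * length(calls))
  if (f > 0.5) list(maf = 1 - f, minor = "other")
  else list(maf = f, minor = "coded")
}

#' Run the full variant QC pipeline
#'
#' Applies, in order: (1) call-quality masking (< 99 by default), (2)
#' sample missingness filter (> 30%), (3) variant missingness filter
#' (> 20%), (4) monomorphic-variant exclusion. Hardy-Weinberg proportions
#' are then tested on the unrelated subset and variants with exact p below
#' `hwe_alpha` are flagged but retained; trios present in the phenotype
#' table are checked for Mendelian consistency (annotation only). Minor
#' allele frequencies and the rare/common classification (MAF < 0.05) are
#' computed on the retained data.
#'
#' @param gm a [genotype_matrix()] with quality scores.
#' @param pheno phenotype table ([read_phenotype_table()]).
#' @param quality_threshold,sample_threshold,variant_threshold,hwe_alpha
#'   QC thresholds; defaults 99, 0.30, 0.20 and 0.03.
#' @return list of class `qc_result` with `genotypes` (filtered), and
#'   `report`: excluded samples/variants with reasons, count of masked
#'   calls, HWE table (`variant_id`, `p_hwe`, `flagged`), Mendelian error
#'   table, per-variant `maf` table with `rarity_class`, and
#'   `retained_dimensions`.
#' @export
run_variant_qc <- function(gm, pheno, quality_threshold = 99,
                           sample_threshold = 0.30,
                           variant_threshold = 0.20, hwe_alpha = 0.03) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_before <- sum(!is.na(gm$calls))
  gm1 <- mask_low_quality_calls(gm, quality_threshold)
  masked <- n_before - sum(!is.na(gm1$calls))
  sf <- filter_samples_by_missingness(gm1, sample_threshold)
  vf <- filter_variants_by_missingness(sf$genotypes, variant_threshold)
  mono <- drop_monomorphic(vf$genotypes)
  g <- mono$genotypes

  unrel <- intersect(select_unrelated(pheno), rownames(g$calls))
  hwe <- data.frame(variant_id = colnames(g$calls),
                    p_hwe = NA_real_, flagged = FALSE)
  for (j in seq_len(ncol(g$calls))) {
    x <- g$calls[unrel, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) next
    hwe$p_hwe[j] <- hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }
  hwe$flagged <- !is.na(hwe$p_hwe) & hwe$p_hwe < hwe_alpha

  mendel <- mendelian_error_table(g, pheno)

  maf <- do.call(rbind, lapply(seq_len(ncol(g$calls)), function(j) {
    m <- compute_maf(g$calls[, j])
    data.frame(variant_id = colnames(g$calls)[j], maf = m$maf,
               rarity_class = if (m$maf < 0.05) "rare" else "common")
  }))
  if (is.null(maf))
    maf <- data.frame(variant_id = character(), maf = numeric(),
                      rarity_class = character())

  structure(list(
    genotypes = g,
    report = list(
      excluded_samples = sf$excluded,
      excluded_variants = rbind(
        vf$excluded,
        cbind(mono$excluded,
              missing_rate = rep(NA_real_, nrow(mono$excluded)))[,
              names(vf$excluded)]),
      masked_calls = masked,
      hwe = hwe,
      mendelian = mendel,
      maf = maf,
      retained_dimensions = c(n_samples = nrow(g$calls),
                              n_variants = ncol(g$calls)))),
    class = "qc_result")
}

# Per-trio, per-variant Mendelian consistency summary.
mendelian_error_table <- function(gm, pheno) {
  has_links <- all(c("father_id", "mother_id") %in% names(pheno))
  out <- data.frame(child = character(), variant_id = character(),
                    status = character())
  if (!has_links) return(out)
  ids <- rownames(gm$calls)
  trios <- pheno[!is.na(pheno$father_id) & !is.na(pheno$mother_id) &
                 pheno$sample_id %in% ids &
                 pheno$father_id %in% ids & pheno$mother_id %in% ids, ,
                 drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(trios))) {
    ch <- trios$sample_id[i]
    for (j in seq_len(ncol(gm$calls))) {
      st <- mendelian_trio_check(gm$calls[ch, j],
                                 gm$calls[trios$father_id[i], j],
                                 gm$calls[trios$mother_id[i], j])
      if (st == "inconsistent")
        rows[[length(rows) + 1]] <-
          data.frame(child = ch, variant_id = colnames(gm$calls)[j],
                     status = st)
    }
  }
  if (length(rows) > 0) out <- do.call(rbind, rows)
  out
}

#' @export
print.qc_result <- function(x, ...) {
  d <- x$report$retained_dimensions
  cat("variant QC:", d["n_samples"], "samples x", d["n_variants"],
      "variants retained;", nrow(x$report$excluded_samples),
      "samples and", nrow(x$report$excluded_variants),
      "variants excluded;", x$report$masked_calls, "calls masked;",
      sum(x$report$hwe$flagged), "HWE flags\n")
  invisible(x)
}
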
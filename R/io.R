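#' Read a phenotype/covariate table
#'
#' Expects a tab-separated file with a header and at least the columns
#' `sample_id`, `age`, `sex`, `cohort`; optional `father_id`, `mother_id`
#' link trios, and every remaining numeric column is treated as a trait
#' (empty cells become `NA`).
#'
#' @param path path to the TSV file.
#' @return A data.frame with one row per sample, `sex` normalised to
#'   `"male"`/`"female"`, traits numeric.
#' @export
read_phenotype_table <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE)
  required <- c("sample_id", "age", "sex", "cohort")
  miss <- setdiff(required, names(ph))
  if (length(miss) > 0)
    stop("phenotype table is missing required column(s): ",
         paste(miss, collapse = ", "))
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample_id in phenotype table: ",
         ph$sample_id[duplicated(ph$sample_id)][1])
  age_num <- suppressWarnings(as.numeric(ph$age))
  bad <- which(!is.na(ph$age) & is.na(age_num))
  if (length(bad) > 0)
    stop("non-numeric age at line ", bad[1] + 1L,  # +1 for the header line
         " (sample ", ph$sample_id[bad[1]], ")")
  if (any(age_num < 0, na.rm = TRUE)) stop("age must be nonnegative")
  ph$age <- age_num
  sex <- tolower(as.character(ph$sex))
  sex[sex %in% c("m", "1")] <- "male"
  sex[sex %in% c("f", "0")] <- "female"
  if (!all(sex %in% c("male", "female", NA)))
    stop("sex must be male/female (or M/F, 0/1)")
  ph$sex <- sex
  for (link in intersect(c("father_id", "mother_id"), names(ph))) {
    ph[[link]] <- as.character(ph[[link]])
    orphan <- !is.na(ph[[link]]) & !(ph[[link]] %in% ph$sample_id)
    if (any(orphan))
      warning("trio link(s) in ", link, " reference absent samples: ",
              paste(unique(ph[[link]][orphan]), collapse = ", "))
  }
  meta_cols <- c(required, "father_id", "mother_id", "ancestry")
  for (tr in setdiff(names(ph), meta_cols)) {
    v <- suppressWarnings(as.numeric(ph[[tr]]))
    if (any(!is.na(ph[[tr]]) & is.na(v)))
      stop("trait column '", tr, "' contains non-numeric values")
    ph[[tr]] <- v
  }
  ph
}

#' Write a phenotype/covariate table
#'
#' Inverse of [read_phenotype_table()]; missing values are written as
#' empty cells.
#'
#' @param pheno data.frame as returned by [read_phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a genotype matrix from TSV or minimal VCF
#'
#' The TSV dialect stores variants in rows and samples in columns, with a
#' leading annotation block (`variant_id`, `chrom`, `pos`, `ref_allele`,
#' `alt_allele`) and per-sample cells `"dosage:quality"` (`"."` for a
#' missing call). The VCF dialect parses unphased `GT` (and `GQ` when
#' present) from an uncompressed VCF via the vcfR package. In both
#' dialects dosages are re-expressed on the minor allele: if the coded
#' allele turns out to be the major one in the data, calls are folded as
#' `2 - dosage` and the recorded minor allele switches accordingly.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param samples optional character vector of expected sample ids; a
#'   mismatch raises an error listing the symmetric difference, and the
#'   returned matrix follows this ordering.
#' @return A [genotype_matrix()]. `variants$minor_allele` records which
#'   allele the dosages count.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"), samples = NULL) {
  dialect <- match.arg(dialect)
  gm <- switch(dialect,
               tsv = read_genotypes_tsv(path),
               vcf = read_genotypes_vcf(path))
  if (!is.null(samples)) {
    extra <- setdiff(rownames(gm$calls), samples)
    absent <- setdiff(samples, rownames(gm$calls))
    if (length(extra) > 0 || length(absent) > 0)
      stop("sample sets disagree; only in genotypes: {",
           paste(extra, collapse = ","), "}; only in phenotypes: {",
           paste(absent, collapse = ","), "}")
    gm <- subset_genotypes(gm, samples = samples)
  }
  gm
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  anno_cols <- c("variant_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(c("variant_id", "chrom", "pos"), names(tab))
  if (length(miss) > 0)
    stop("genotype TSV is missing column(s): ", paste(miss, collapse = ", "))
  sample_ids <- setdiff(names(tab), anno_cols)
  nv <- nrow(tab)
  calls <- matrix(NA_integer_, length(sample_ids), nv,
                  dimnames = list(sample_ids, tab$variant_id))
  qual <- matrix(NA_real_, length(sample_ids), nv,
                 dimnames = list(sample_ids, tab$variant_id))
  for (s in sample_ids) {
    cell <- as.character(tab[[s]])
    is_miss <- cell == "."
    parts <- strsplit(cell[!is_miss], ":", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0) {
      v <- which(!is_miss)[bad[1]]
      stop("malformed genotype cell at variant ", tab$variant_id[v],
           ", sample ", s, ": '", cell[v], "'")
    }
    d <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    q <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    if (any(is.na(d)) || any(is.na(q)) || any(!(d %in% 0:2))) {
      v <- which(!is_miss)[which(is.na(d) | is.na(q) | !(d %in% 0:2))[1]]
      stop("malformed genotype cell at variant ", tab$variant_id[v],
           ", sample ", s, ": '", cell[v], "'")
    }
    calls[s, !is_miss] <- d
    qual[s, !is_miss] <- q
  }
  vinfo <- tab[, intersect(anno_cols, names(tab)), drop = FALSE]
  fold_to_minor(genotype_matrix(calls, vinfo, qual))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  qual <- tryCatch(
    matrix(suppressWarnings(
      as.numeric(vcfR::extract.gt(vcf, element = "GQ"))),
      nrow(gt), ncol(gt), dimnames = dimnames(gt)),
    error = function(e) NULL)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix))  # single-variant VCFs drop dimensions
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vinfo <- data.frame(variant_id = fix[, "ID"],
                      chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref_allele = fix[, "REF"],
                      alt_allele = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  calls <- t(dos)
  rownames(calls) <- colnames(gt)
  colnames(calls) <- vinfo$variant_id
  if (!is.null(qual)) qual <- t(qual)
  fold_to_minor(genotype_matrix(calls, vinfo, qual))
}

# Re-express dosages on the minor allele (fold when coded-allele freq > 0.5).
fold_to_minor <- function(gm) {
  f <- colMeans(gm$calls, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  gm$calls[, flip] <- 2L - gm$calls[, flip]
  has_alt <- all(c("ref_allele", "alt_allele") %in% names(gm$variants))
  gm$variants$minor_allele <- if (has_alt) {
    ifelse(flip, gm$variants$ref_allele, gm$variants$alt_allele)
  } else ifelse(flip, "ref", "alt")
  gm
}

#' Write a genotype matrix in the TSV dialect
#'
#' @param gm a [genotype_matrix()]; quality scores default to 99 when
#'   absent.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  qual <- gm$quality
  if (is.null(qual)) qual <- matrix(99, nrow(gm$calls), ncol(gm$calls))
  cell <- matrix(".", nrow(gm$calls), ncol(gm$calls))
  ok <- !is.na(gm$calls)
  cell[ok] <- paste0(gm$calls[ok], ":", format(qual[ok], trim = TRUE))
  anno_cols <- intersect(c("variant_id", "chrom", "pos",
                           "ref_allele", "alt_allele"),
                         names(gm$variants))
  out <- cbind(gm$variants[, anno_cols, drop = FALSE],
               as.data.frame(t(cell)))
  names(out) <- c(anno_cols, rownames(gm$calls))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an unphased single-sample-field VCF with `GT:GQ` calls, suitable
#' for round-tripping through [read_genotypes()]'s `vcf` dialect. Dosages
#' are written on the ALT allele: when the recorded minor allele is the
#' reference, calls are unfolded back so that `GT` counts ALT copies.
#'
#' @param gm a [genotype_matrix()] whose `variants` carry `ref_allele` and
#'   `alt_allele`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(c("ref_allele", "alt_allele") %in% names(gm$variants)))
  calls <- gm$calls
  if ("minor_allele" %in% names(gm$variants)) {
    flip <- gm$variants$minor_allele == gm$variants$ref_allele
    calls[, flip] <- 2L - calls[, flip]
  }
  qual <- gm$quality
  if (is.null(qual)) qual <- matrix(99, nrow(calls), ncol(calls))
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  v <- gm$variants
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    gt <- ifelse(is.na(calls[, j]), "./.",
                 gt_of[as.character(calls[, j])])
    gq <- ifelse(is.na(calls[, j]), ".",
                 format(round(qual[, j]), trim = TRUE))
    lines <- c(lines,
               paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref_allele[j],
                       v$alt_allele[j], ".", "PASS", ".", "GT:GQ",
                       paste0(gt, ":", gq)), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read recombination hotspots from BED and build the tile map
#'
#' @param path BED file (0-based half-open) of hotspot intervals; at least
#'   three columns `chrom`, `start`, `end`. Zero data lines yield one
#'   unbounded tile per chromosome in `chrom_lengths`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return A [build_tiles()] tile map.
#' @export
read_hotspots <- function(path, chrom_lengths = NULL) {
  n_lines <- length(readLines(path))
  hs <- if (n_lines == 0) {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    bed <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    data.frame(chrom = as.character(bed[[1]]),
               start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]))
  }
  build_tiles(hs, chrom_lengths)
}

#' Write association or meta-analysis results as TSV
#'
#' Association results are written with columns `target_id`, `model`,
#' `beta`, `se`, `p_value`, `n_used`; meta-analysis results append
#' `combined_z` and `combined_p` after per-cohort p-value columns. Floats
#' keep at least six significant digits so the file round-trips through
#' [read_results()].
#'
#' @param results a data.frame of class `association_results` or
#'   `meta_results` (as produced by the analysis functions), or a list of
#'   such data.frames of one single class.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results)) results <- list(results)
  cls <- vapply(results, function(r)
    intersect(class(r), c("association_results", "meta_results"))[1],
    character(1))
  if (any(is.na(cls)))
    stop("results must be association_results or meta_results")
  if (length(unique(cls)) > 1)
    stop("cannot mix association and meta results in one file")
  tab <- do.call(rbind, lapply(results, as.data.frame))
  num <- vapply(tab, is.numeric, logical(1))
  for (j in which(num)) tab[[j]] <- signif(tab[[j]], 10)
  cat(paste0("#type=", cls[1], "\n"), file = path)
  suppressWarnings(
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", append = TRUE))
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path input path.
#' @return The results data.frame with its class restored.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  cls <- sub("^#type=", "", first)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#",
                    na.strings = "")
  class(tab) <- c(cls, "data.frame")
  tab
}
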
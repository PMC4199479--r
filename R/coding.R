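#' Additive and dominant genotype codings
#'
#' Additive coding is the number of minor alleles (the dosage itself);
#' dominant coding is presence/absence of the minor allele. Missing calls
#' propagate.
#'
#' @param calls dosage vector or matrix in `{0,1,2,NA}`.
#' @return Numeric coding of the same shape.
#' @export
code_additive <- function(calls) {
  storage.mode(calls) <- "double"
  calls
}

#' @rdname code_additive
#' @export
code_dominant <- function(calls) {
  out <- ifelse(is.na(calls), NA_real_, as.numeric(calls >= 1))
  if (is.matrix(calls)) dim(out) <- dim(calls)
  if (is.matrix(calls)) dimnames(out) <- dimnames(calls)
  out
}

#' Collapse rare variants into per-tile burden codes
#'
#' For each sample and tile, the collapsed code is the proportion of the
#' tile's rare sites at which the sample carries at least one minor allele,
#' among the sites non-missing for that sample ("proportion of the minor
#' allele"). Tiles with no rare variants produce no column; a sample
#' missing at every rare site of a tile gets `NA`. With
#' `method = "allele_fraction"` the alternative reading -- minor-allele
#' count over twice the non-missing site count -- is used instead.
#'
#' @param gm a [genotype_matrix()] restricted to (or containing) the rare
#'   variants to collapse.
#' @param tiles a [build_tiles()] tile map.
#' @param rare_ids variant ids to collapse (default: all variants in `gm`).
#' @param method `"presence"` (default) or `"allele_fraction"`.
#' @return A numeric matrix samples x tiles-with-rare-variants, values in
#'   `[0, 1]`, column names = tile ids.
#' @export
collapse_rare_variants <- function(gm, tiles, rare_ids = NULL,
                                   method = c("presence", "allele_fraction")) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(rare_ids)) rare_ids <- colnames(gm$calls)
  g <- subset_genotypes(gm, variants = rare_ids)
  tile_of <- assign_tiles(g$variants$chrom, g$variants$pos, tiles)
  out <- NULL
  for (tl in unique(tile_of)) {
    calls <- g$calls[, tile_of == tl, drop = FALSE]
    nonmiss <- rowSums(!is.na(calls))
    num <- if (method == "presence") rowSums(calls >= 1, na.rm = TRUE)
           else rowSums(calls, na.rm = TRUE)
    den <- if (method == "presence") nonmiss else 2 * nonmiss
    col <- ifelse(nonmiss == 0, NA_real_, num / den)
    out <- cbind(out, col)
    colnames(out)[ncol(out)] <- tl
  }
  if (is.null(out))
    out <- matrix(numeric(0), nrow(g$calls), 0,
                  dimnames = list(rownames(g$calls), NULL))
  rownames(out) <- rownames(gm$calls)
  out
}

#' Build the design columns for a genotype coding scheme
#'
#' The three schemes mirror the study's variant codings:
#' * `add` -- number of minor alleles for every variant (common and rare,
#'   uncollapsed);
#' * `dom` -- presence/absence of the minor allele for every variant;
#' * `add_collapsed` -- additive coding for common variants plus one
#'   collapsed burden column per hotspot tile containing rare variants.
#'
#' @param gm a post-QC [genotype_matrix()].
#' @param scheme `"add"`, `"dom"` or `"add_collapsed"`.
#' @param tiles a tile map; required for `add_collapsed` and for the tile
#'   annotation of the column map.
#' @param maf optional per-variant MAF table (`variant_id`, `maf`,
#'   `rarity_class`) as in a [run_variant_qc()] report; recomputed from
#'   the calls when absent.
#' @param collapse_method passed to [collapse_rare_variants()].
#' @return list with `X` (numeric samples x columns design matrix) and
#'   `map`, a data.frame per column: `column_id`, `type`
#'   (`"snv"`/`"collapsed"`), `tile_id`, `chrom`, `pos` (tile start for
#'   collapsed columns, used for deterministic ordering/tie-breaks).
#' @export
code_genotypes <- function(gm, scheme = c("add", "dom", "add_collapsed"),
                           tiles = NULL, maf = NULL,
                           collapse_method = "presence") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(maf)) {
    maf <- do.call(rbind, lapply(seq_len(ncol(gm$calls)), function(j) {
      m <- compute_maf(gm$calls[, j])
      data.frame(variant_id = colnames(gm$calls)[j], maf = m$maf,
                 rarity_class = if (m$maf < 0.05) "rare" else "common")
    }))
  }
  maf <- maf[match(colnames(gm$calls), maf$variant_id), ]
  tile_of <- if (!is.null(tiles))
    assign_tiles(gm$variants$chrom, gm$variants$pos, tiles)
  else rep(NA_character_, ncol(gm$calls))

  snv_map <- data.frame(column_id = colnames(gm$calls), type = "snv",
                        tile_id = tile_of, chrom = gm$variants$chrom,
                        pos = as.numeric(gm$variants$pos))
  if (scheme == "add") {
    X <- code_additive(gm$calls)
    map <- snv_map
  } else if (scheme == "dom") {
    X <- code_dominant(gm$calls)
    map <- snv_map
  } else {
    if (is.null(tiles)) stop("add_collapsed coding needs a tile map")
    common <- maf$rarity_class == "common"
    rare_ids <- colnames(gm$calls)[!common]
    Xc <- code_additive(gm$calls[, common, drop = FALSE])
    map <- snv_map[common, , drop = FALSE]
    if (length(rare_ids) > 0) {
      Xr <- collapse_rare_variants(gm, tiles, rare_ids,
                                   method = collapse_method)
      tmap <- data.frame(column_id = colnames(Xr), type = "collapsed",
                         tile_id = colnames(Xr),
                         chrom = tiles$chrom[match(colnames(Xr),
                                                   tiles$tile_id)],
                         pos = tiles$start[match(colnames(Xr),
                                                 tiles$tile_id)])
      X <- cbind(Xc, Xr)
      map <- rbind(map, tmap)
    } else X <- Xc
  }
  rownames(map) <- NULL
  list(X = X, map = map)
}
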
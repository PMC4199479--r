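#' Construct a genotype matrix
#'
#' Bundles minor-allele dosage calls with per-call quality scores and a
#' variant annotation table. Calls are stored samples x variants with `NA`
#' for missing genotypes; every non-missing call must be 0, 1 or 2 copies
#' of the minor allele.
#'
#' @param calls integer matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids); values in `{0,1,2,NA}`.
#' @param variants data.frame with one row per column of `calls`, columns
#'   `variant_id`, `chrom`, `pos` (1-based), and optionally `ref_allele`,
#'   `alt_allele`, `minor_allele`.
#' @param quality optional numeric matrix of nonnegative per-call quality
#'   scores, same dimensions as `calls` (e.g. polyphred scores).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `quality`, `variants`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("v1", "v2"))),
#'   data.frame(variant_id = c("v1", "v2"), chrom = "chr1", pos = c(10L, 20L)))
#' dim(gm$calls)
#' @export
genotype_matrix <- function(calls, variants, quality = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stop("`calls` must carry sample rownames and variant colnames")
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L, 2L))
  if (any(bad))
    stop("non-missing calls must be in {0,1,2}; first offender at [",
         which(bad)[1], "]")
  if (!is.data.frame(variants) || nrow(variants) != ncol(calls))
    stop("`variants` must be a data.frame with one row per variant column")
  if (!all(c("variant_id", "chrom", "pos") %in% names(variants)))
    stop("`variants` needs columns variant_id, chrom, pos")
  if (ncol(calls) > 0 &&
      !identical(as.character(variants$variant_id), colnames(calls)))
    stop("variants$variant_id must match colnames(calls) in order")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids in genotype matrix")
  if (!is.null(quality)) {
    if (!is.matrix(quality) || !identical(dim(quality), dim(calls)))
      stop("`quality` must match the dimensions of `calls`")
    if (any(quality < 0, na.rm = TRUE)) stop("quality scores must be >= 0")
  }
  structure(list(calls = calls, quality = quality,
                 variants = as.data.frame(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "variants;", sum(is.na(x$calls)), "missing calls",
      if (is.null(x$quality)) "(no quality scores)" else "", "\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a [genotype_matrix()].
#' @param samples,variants character or logical/integer index vectors; `NULL`
#'   keeps everything.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(samples)) samples <- rownames(gm$calls)
  if (is.null(variants)) variants <- colnames(gm$calls)
  calls <- gm$calls[samples, variants, drop = FALSE]
  qual <- if (!is.null(gm$quality))
    gm$quality[samples, variants, drop = FALSE]
  vinfo <- gm$variants[match(colnames(calls), gm$variants$variant_id), ,
                       drop = FALSE]
  rownames(vinfo) <- NULL
  genotype_matrix(calls, vinfo, qual)
}

#' Build a tile map from recombination-hotspot intervals
#'
#' Tiles are the segments of a chromosome between consecutive hotspot
#' midpoints: the i-th internal boundary sits at the midpoint of the i-th
#' hotspot, so a chromosome with k hotspots yields k + 1 tiles and every
#' base -- including bases inside a hotspot -- belongs to exactly one tile.
#' Intervals are 0-based half-open `[start, end)` (BED convention).
#'
#' @param hotspots data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open hotspot intervals). Zero rows for a chromosome is
#'   allowed and yields a single whole-chromosome tile.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   chromosomes absent from it get an unbounded (`Inf`) last tile.
#' @return A data.frame of class `tile_map` with columns `tile_id`,
#'   `chrom`, `start`, `end`, ordered by chromosome then position.
#' @examples
#' hs <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600))
#' build_tiles(hs, c(chr1 = 1000))
#' @export
build_tiles <- function(hotspots, chrom_lengths = NULL) {
  stopifnot(is.data.frame(hotspots),
            all(c("chrom", "start", "end") %in% names(hotspots)))
  if (nrow(hotspots) > 0 && any(hotspots$end <= hotspots$start))
    stop("hotspot intervals must have end > start")
  chroms <- unique(as.character(hotspots$chrom))
  if (!is.null(chrom_lengths))
    chroms <- union(chroms, names(chrom_lengths))
  out <- list()
  for (ch in chroms) {
    hs <- hotspots[as.character(hotspots$chrom) == ch, , drop = FALSE]
    if (nrow(hs) > 0 && is.unsorted(hs$start)) {
      message("hotspots on ", ch, " were unsorted; sorting")
      hs <- hs[order(hs$start), , drop = FALSE]
    }
    if (nrow(hs) > 1 && any(hs$start[-1] < hs$end[-nrow(hs)]))
      stop("overlapping hotspots on ", ch)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      unname(chrom_lengths[ch]) else Inf
    mids <- if (nrow(hs) > 0) (hs$start + hs$end) / 2 else numeric(0)
    bounds <- c(0, mids, len)
    out[[ch]] <- data.frame(chrom = ch,
                            start = bounds[-length(bounds)],
                            end = bounds[-1])
  }
  tiles <- do.call(rbind, out)
  rownames(tiles) <- NULL
  tiles <- cbind(tile_id = paste0(tiles$chrom, "_tile",
                                  stats::ave(seq_len(nrow(tiles)),
                                             tiles$chrom, FUN = seq_along)),
                 tiles)
  class(tiles) <- c("tile_map", "data.frame")
  tiles
}

#' Assign variant positions to tiles
#'
#' A variant at 1-based position `p` occupies the 0-based interval
#' `[p-1, p)` and is assigned to the tile containing `p - 1`.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param tiles a [build_tiles()] tile map.
#' @return Character vector of tile ids; errors if any position falls
#'   outside every tile of its chromosome.
#' @export
assign_tiles <- function(chrom, pos, tiles) {
  stopifnot(inherits(tiles, "tile_map"), length(chrom) == length(pos))
  out <- character(length(pos))
  for (i in seq_along(pos)) {
    hit <- which(tiles$chrom == chrom[i] &
                 tiles$start <= pos[i] - 1 & pos[i] - 1 < tiles$end)
    if (length(hit) != 1)
      stop("position ", chrom[i], ":", pos[i],
           " maps to ", length(hit), " tiles")
    out[i] <- tiles$tile_id[hit]
  }
  out
}

#' Log-transform a nonnegative count trait
#'
#' The transformation used for skewed count phenotypes such as CALM count:
#' `log10(x + 10)`. It is strictly increasing and maps 0 to exactly 1, so
#' zero counts remain representable.
#'
#' @param raw nonnegative numeric vector (NAs pass through).
#' @return `log10(raw + 10)`.
#' @examples
#' transform_trait(c(0, 90))  # 1, 2
#' @export
transform_trait <- function(raw) {
  if (any(raw < 0, na.rm = TRUE))
    stop("trait values must be nonnegative")
  log10(raw + 10)
}
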
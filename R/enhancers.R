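#' Window enrichment of ChIP over input
#'
#' Counts ChIP and input fragments in non-overlapping windows (fragment
#' midpoint assignment), scales the input count by the library-size ratio
#' to an expected ChIP count `e`, and scores enrichment with a Poisson
#' approximation `z = (chip - e)/sqrt(e)`. Windows with zero input have `e`
#' floored at the genome-mean input count and are flagged. The enrichment
#' fold is chip CPM / input CPM (with the same flooring).
#'
#' @param chip_fs,input_fs `fragment_set`s (both non-empty).
#' @param window window size in bp (default 200).
#' @param chrom_lengths named vector (defaults to the ChIP set's own).
#' @return data.table(chrom, start, end, chip, input, e, z, fold,
#'   input_floored).
#' @export
window_enrichment <- function(chip_fs, input_fs, window = 200,
                              chrom_lengths = NULL) {
  if (chip_fs$library_size == 0 || input_fs$library_size == 0)
    stop("both ChIP and input sets must be non-empty")
  cl <- chrom_lengths %||% chip_fs$chrom_lengths
  chip <- bin_frequencies(chip_fs, window, cl, normalize = FALSE)
  inp <- bin_frequencies(input_fs, window, cl, normalize = FALSE)
  dt <- track_to_dt(chip)
  setnames(dt, "value", "chip")
  dt[, input := track_to_dt(inp)$value]
  ratio <- chip_fs$library_size / input_fs$library_size
  mean_input <- mean(dt$input)
  dt[, input_floored := input == 0]
  dt[, e := pmax(input, mean_input * as.numeric(input == 0)) * ratio]
  dt[input > 0, e := input * ratio]
  dt[, z := (chip - e) / sqrt(e)]
  cpm_ratio <- (1e6 / chip_fs$library_size) / (1e6 / input_fs$library_size)
  dt[, fold := ifelse(input > 0, (chip / input) / ratio,
                      (chip / (mean_input)) / ratio)]
  dt[]
}

#' Merge enriched windows into regions
#'
#' Windows exceeding the Z threshold are merged when the gap between them
#' is strictly smaller than `join_gap`.
#'
#' @param windows data.table with chrom, start, end, z (from
#'   [window_enrichment()]), or any interval table with a `z` column.
#' @param z_thresh enrichment threshold (default 10); windows with
#'   `z > z_thresh` are selected.
#' @param join_gap regions closer than this many bp are joined (strict <;
#'   default 150).
#' @return data.table(chrom, start, end) of merged regions (possibly empty).
#' @export
call_enriched_regions <- function(windows, z_thresh = 10, join_gap = 150) {
  sel <- as.data.table(windows)[z > z_thresh]
  if (!nrow(sel))
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  gr <- GenomicRanges::GRanges(sel$chrom,
                               IRanges::IRanges(sel$start + 1L, sel$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = join_gap)
  data.table(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1L,
             end = GenomicRanges::end(merged))
}

regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

gr_to_regions <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Keep regions supported by both replicates
#'
#' A region survives iff it overlaps an enriched region in the other
#' replicate; surviving coordinates are the intersection (conservative).
#'
#' @param regions_rep1,regions_rep2 interval tables (chrom, start, end).
#' @return data.table of intersected regions.
#' @export
replicate_consistent <- function(regions_rep1, regions_rep2) {
  if (!nrow(regions_rep1) || !nrow(regions_rep2))
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  g1 <- regions_to_gr(regions_rep1)
  g2 <- regions_to_gr(regions_rep2)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  if (!length(hits))
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  inter <- GenomicRanges::pintersect(g1[S4Vectors::queryHits(hits)],
                                     g2[S4Vectors::subjectHits(hits)])
  gr_to_regions(GenomicRanges::reduce(inter))
}

#' Remove promoter-proximal regions
#'
#' Excludes regions overlapping the promoter zone of any gene: from `up` bp
#' upstream to `down` bp downstream of the TSS in transcription
#' orientation (mirrored for minus-strand genes).
#'
#' @param regions interval table (chrom, start, end).
#' @param genes data.frame with chrom, tss, strand.
#' @param up,down zone extent upstream / downstream of the TSS (default
#'   1000 / 500 bp).
#' @return data.table of retained regions.
#' @export
exclude_promoter_proximal <- function(regions, genes, up = 1000, down = 500) {
  if (!nrow(regions)) return(as.data.table(regions))
  genes <- as.data.table(genes)
  zone_start <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  zone_end <- ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  zones <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(pmax(zone_start, 0) + 1L,
                                                   zone_end))
  gr <- regions_to_gr(regions)
  keep <- !IRanges::overlapsAny(gr, zones)
  as.data.table(regions)[keep]
}

#' Classify enhancers across the time course
#'
#' `up_regulated`: enrichment increased at least twofold over both tested
#' intervals (Methods variant, default: 0-1 h and 0-4 h; Results variant:
#' 0-1 h and 1-4 h), with the significance flag when supplied.
#' `constitutive_high`: no significant twofold change in either direction
#' but ChIP/input fold above 4 at all three time points. Everything else is
#' `other`.
#'
#' @param folds data.frame/matrix with columns fold_0h, fold_1h, fold_4h,
#'   one row per region.
#' @param significant logical vector (twofold changes confirmed in
#'   replicates); defaults to TRUE for all regions.
#' @param intervals `"methods"` (0-1 h and 0-4 h, default) or `"results"`
#'   (0-1 h and 1-4 h).
#' @return Character vector of classes.
#' @export
classify_enhancers <- function(folds, significant = NULL,
                               intervals = c("methods", "results")) {
  intervals <- match.arg(intervals)
  folds <- as.data.table(folds)
  need <- c("fold_0h", "fold_1h", "fold_4h")
  if (!all(need %in% names(folds)))
    stop("need columns fold_0h, fold_1h, fold_4h")
  if (anyNA(folds[, ..need])) stop("missing time point fold")
  if (is.null(significant)) significant <- rep(TRUE, nrow(folds))
  r01 <- folds$fold_1h / folds$fold_0h
  r04 <- folds$fold_4h / folds$fold_0h
  r14 <- folds$fold_4h / folds$fold_1h
  up <- if (intervals == "methods") r01 >= 2 & r04 >= 2 & significant
        else r01 >= 2 & r14 >= 2 & significant
  two_fold_change <- (pmax(r01, 1 / r01) >= 2 | pmax(r04, 1 / r04) >= 2) &
    significant
  high <- folds$fold_0h > 4 & folds$fold_1h > 4 & folds$fold_4h > 4
  ifelse(up, "up_regulated",
         ifelse(!two_fold_change & high, "constitutive_high", "other"))
}

#' Call and classify enhancers from ChIP/input fragment sets
#'
#' Full recipe: per-replicate window Z-scoring at each time point, Z
#' thresholding with gap joining, replicate intersection, promoter
#' exclusion, union of time-point calls, then per-region fold time courses
#' (mean of replicate folds over the region's windows) and classification.
#'
#' @param chip_sets,input_sets nested lists `[[time_point]][[replicate]]` of
#'   `fragment_set`s; time points `"0h"`, `"1h"`, `"4h"`.
#' @param genes gene table for promoter exclusion (chrom, tss, strand).
#' @param window,z_thresh,join_gap see [window_enrichment()] and
#'   [call_enriched_regions()].
#' @param up,down promoter exclusion zone (bp).
#' @param intervals classification variant, see [classify_enhancers()].
#' @param chrom_lengths named vector.
#' @return data.table of enhancers: chrom, start, end, fold_0h/1h/4h, class.
#' @export
call_enhancers <- function(chip_sets, input_sets, genes,
                           window = 200, z_thresh = 10, join_gap = 150,
                           up = 1000, down = 500,
                           intervals = "methods", chrom_lengths = NULL) {
  tps <- names(chip_sets)
  per_tp <- lapply(tps, function(tp) {
    reps <- lapply(seq_along(chip_sets[[tp]]), function(r) {
      we <- window_enrichment(chip_sets[[tp]][[r]], input_sets[[tp]][[r]],
                              window, chrom_lengths)
      call_enriched_regions(we, z_thresh, join_gap)
    })
    Reduce(replicate_consistent, reps)
  })
  all_regions <- rbindlist(per_tp)
  if (!nrow(all_regions))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), fold_0h = numeric(),
                      fold_1h = numeric(), fold_4h = numeric(),
                      class = character()))
  merged <- gr_to_regions(GenomicRanges::reduce(regions_to_gr(all_regions)))
  merged <- exclude_promoter_proximal(merged, genes, up, down)
  if (!nrow(merged)) return(merged)
  # per-region fold time course: replicate-averaged window folds
  for (tp in tps) {
    fold_reps <- lapply(seq_along(chip_sets[[tp]]), function(r) {
      we <- window_enrichment(chip_sets[[tp]][[r]], input_sets[[tp]][[r]],
                              window, chrom_lengths)
      wgr <- regions_to_gr(we)
      rgr <- regions_to_gr(merged)
      hits <- GenomicRanges::findOverlaps(rgr, wgr)
      v <- rep(NA_real_, nrow(merged))
      agg <- tapply(we$fold[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
      v[as.integer(names(agg))] <- agg
      v
    })
    merged[, (paste0("fold_", tp)) := rowMeans(do.call(cbind, fold_reps))]
  }
  merged[, class := classify_enhancers(.SD, intervals = intervals),
         .SDcols = c("fold_0h", "fold_1h", "fold_4h")]
  merged[]
}

#' Write enhancers as BED with the class in the name field
#'
#' @param enhancers table from [call_enhancers()].
#' @param path output BED file.
#' @export
write_enhancers_bed <- function(enhancers, path) {
  dt <- as.data.table(enhancers)
  out <- dt[, .(chrom, start, end,
                name = paste0(class, "_", seq_len(.N)),
                score = 0L, strand = ".")]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
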
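#' Counts-per-million normalization of peak counts
#'
#' Scales each sample's peak-count row to one million. Samples with a zero
#' total are dropped with a warning.
#'
#' @param peak_counts Numeric matrix, samples x peaks (rownames = sample
#'   ids).
#' @return CPM matrix (possibly with fewer rows).
#' @export
cpm_normalize <- function(peak_counts) {
  m <- as.matrix(peak_counts)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warn(sprintf("Dropping %d zero-total sample(s).", sum(rs == 0)))
    m <- m[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  m / rs * 1e6
}

# BED-convention (0-based half-open) tibble -> GRanges (1-based inclusive).
bed_to_granges <- function(bed) {
  if (any(bed$start >= bed$end) || any(bed$start < 0)) {
    abort("BED intervals need 0 <= start < end.")
  }
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
}

#' Normalized locus accessibility per (region, cell class, population group)
#'
#' The four-step risk-locus normalization over pseudobulked ATAC peak
#' counts: (1) within-sample CPM (done upstream or via `cpm_normalize()`),
#' (2) per sample, CPM of all peaks overlapping the locus by at least one
#' base pair are summed and divided by the total length of those peaks
#' (full peak lengths by default; set `clip = TRUE` to use the
#' intersection lengths instead), (3) length-normalized values are averaged
#' over the samples of each (region, cell class, population group) combo
#' (samples weighted equally), and (4) each locus's values are divided by
#' the maximum across all combos, so the most accessible combo sits at 1.
#'
#' Intervals follow the BED convention (0-based, half-open), so a peak
#' ending at position x does not overlap a locus starting at x.
#'
#' @param cpm CPM matrix, samples x peaks (from [cpm_normalize()]); column
#'   names must match `peaks$name`.
#' @param peaks Peak intervals: tibble with `chrom`, `start`, `end`, `name`.
#' @param loci Locus intervals: tibble with `chrom`, `start`, `end`,
#'   `locus`.
#' @param sample_info Tibble with `sample_id` (matching `rownames(cpm)`),
#'   `group`, `region`, `cell_class`.
#' @param clip Divide by summed intersection lengths instead of full peak
#'   lengths (default `FALSE`).
#' @return Tibble: `locus`, `region`, `cell_class`, `group`, `value`
#'   (normalized accessibility in \[0, 1\]), `mean_lcpm` (pre-max-scaling
#'   mean), `no_peaks` (TRUE when the locus overlapped no peak; its values
#'   are 0).
#' @export
locus_values <- function(cpm, peaks, loci, sample_info, clip = FALSE) {
  peaks <- as_tibble(peaks)
  loci <- as_tibble(loci)
  if (!all(colnames(cpm) == peaks$name)) {
    peaks <- peaks[match(colnames(cpm), peaks$name), ]
    if (anyNA(peaks$name)) abort("`peaks` must describe every CPM column.")
  }
  info <- as_tibble(sample_info)
  info <- info[match(rownames(cpm), info$sample_id), ]
  if (anyNA(info$sample_id)) abort("`sample_info` must cover every sample.")

  pk <- bed_to_granges(peaks)
  lc <- bed_to_granges(loci)
  hits <- GenomicRanges::findOverlaps(lc, pk) # >= 1 bp by default

  combos <- dplyr::distinct(info, region, cell_class, group)
  out <- purrr::map_dfr(seq_len(nrow(loci)), function(li) {
    pidx <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == li]
    if (!length(pidx)) {
      res <- combos
      res$locus <- loci$locus[li]
      res$mean_lcpm <- 0
      res$no_peaks <- TRUE
      return(res)
    }
    if (clip) {
      ov_start <- pmax(peaks$start[pidx], loci$start[li])
      ov_end <- pmin(peaks$end[pidx], loci$end[li])
      total_len <- sum(ov_end - ov_start)
    } else {
      total_len <- sum(peaks$end[pidx] - peaks$start[pidx])
    }
    per_sample <- rowSums(cpm[, pidx, drop = FALSE]) / total_len
    df <- info
    df$lcpm <- per_sample
    res <- dplyr::summarise(
      dplyr::group_by(df, region, cell_class, group),
      mean_lcpm = mean(lcpm), .groups = "drop"
    )
    res$locus <- loci$locus[li]
    res$no_peaks <- FALSE
    res
  })
  out <- dplyr::group_by(out, locus)
  out <- dplyr::mutate(out, value = if (max(mean_lcpm) > 0) {
    mean_lcpm / max(mean_lcpm)
  } else {
    0
  })
  out <- dplyr::ungroup(out)
  dplyr::select(out, locus, region, cell_class, group, value, mean_lcpm,
                no_peaks)
}

utils::globalVariables("lcpm")

#' Convert 1-based inclusive prose coordinates to a BED interval
#'
#' Genome-browser prose such as "chr17: 46,029,916 - 46,223,808" is 1-based
#' and inclusive; BED is 0-based and half-open, so the start shifts down by
#' one and the end is unchanged.
#'
#' @param chrom Chromosome label.
#' @param first,last 1-based inclusive bounds.
#' @param locus Optional locus name.
#' @return One-row tibble with `chrom`, `start`, `end`, `locus`.
#' @export
#' @examples
#' locus_from_prose("chr17", 46029916, 46223808, "KANSL1")
locus_from_prose <- function(chrom, first, last, locus = NA_character_) {
  tibble(chrom = chrom, start = first - 1, end = last, locus = locus)
}
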
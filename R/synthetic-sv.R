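SV_TYPES <- c("INS", "DEL", "DUP", "INV", "TRA", "INVDUP")

#' Simulate a structural-variant call set
#'
#' For each accession and SV type, the number of events is drawn
#' `Poisson(rate * genome_length)` and event lengths from a log-uniform
#' law on `length_range` (the scale at which long-read SV callers report
#' insertions, deletions and duplications, 50 bp to 100 kb by default).
#'
#' @param accessions character vector of accession names.
#' @param rates named numeric vector of per-bp event rates; names must be
#'   a subset of `INS, DEL, DUP, INV, TRA, INVDUP`.  Types absent from
#'   `rates` (or with rate 0) produce no records.
#' @param genome_length genome size in bp used to scale rates and place
#'   events.
#' @param length_range numeric length-law support `c(min, max)` in bp.
#' @param chrom chromosome name for the records.
#' @param seed integer seed.
#' @return An `sv_call_set` data.frame with columns `accession`, `chrom`,
#'   `pos`, `svtype`, `svlen` (absolute bp) and `end`.
#' @export
simulate_sv_calls <- function(accessions, rates, genome_length = 1e6,
                              length_range = c(50, 1e5), chrom = "Chr01",
                              seed = 1L) {
  bad <- setdiff(names(rates), SV_TYPES)
  if (length(bad)) stop("unknown SVTYPE in rate spec: ", paste(bad, collapse = ", "))
  if (any(rates < 0)) stop("rates must be >= 0")
  if (length_range[1] < 1 || length_range[1] > length_range[2])
    stop("invalid length_range")
  set.seed(as.integer(seed))
  out <- list()
  for (acc in accessions) {
    for (tp in names(rates)) {
      k <- stats::rpois(1, rates[[tp]] * genome_length)
      if (k == 0) next
      pos <- sample.int(genome_length, k, replace = TRUE)
      len <- round(exp(stats::runif(k, log(length_range[1]), log(length_range[2]))))
      out[[length(out) + 1]] <- data.frame(
        accession = acc, chrom = chrom, pos = pos, svtype = tp,
        svlen = len, end = pos + len - 1L, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(accession = character(0), chrom = character(0),
               pos = integer(0), svtype = character(0),
               svlen = integer(0), end = integer(0), stringsAsFactors = FALSE)
  sv_call_set(calls)
}

#' Simulate paired window read counts over CNV segments
#'
#' Emulates the CNV-seq input: the genome is tiled into windows; the
#' reference sample has copy number 2 everywhere and its window counts are
#' `Poisson(lambda)` with `lambda = mean_depth * window / read_length`
#' (expected read starts per window at the given sequencing depth).  The
#' test sample's counts are Poisson with mean scaled by `copy_number / 2`
#' of the segment covering the window midpoint (copy number 2 outside all
#' segments); a homozygous deletion (copy number 0) yields counts near 0.
#'
#' @param cnv_segments data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and `copy_number` (>= 0), or `NULL` for a flat
#'   copy-number-2 genome.
#' @param mean_depth sequencing depth (x coverage) of both samples.
#' @param window window width in bp.
#' @param chrom_length chromosome length in bp (single chromosome).
#' @param chrom chromosome name.
#' @param read_length read length in bp used to convert depth to expected
#'   read counts.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open windows), `copy_number`, `test_count`, `ref_count`.
#' @export
simulate_window_read_counts <- function(cnv_segments = NULL, mean_depth = 30,
                                        window = 1e5, chrom_length = 1e7,
                                        chrom = "Chr01", read_length = 150,
                                        seed = 1L) {
  if (!is.null(cnv_segments)) {
    stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(cnv_segments)))
    if (any(cnv_segments$copy_number < 0)) stop("copy_number must be >= 0")
  }
  set.seed(as.integer(seed))
  win <- tile_windows(chrom_length, window)
  mid <- (win$start + win$end) / 2
  cn <- rep(2, nrow(win))
  if (!is.null(cnv_segments)) {
    seg <- cnv_segments[cnv_segments$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(seg)))
      cn[mid >= seg$start[i] - 1 & mid < seg$end[i]] <- seg$copy_number[i]
  }
  lam <- mean_depth * window / read_length
  data.frame(chrom = chrom, start = win$start, end = win$end,
             copy_number = cn,
             test_count = stats::rpois(nrow(win), lam * cn / 2),
             ref_count = stats::rpois(nrow(win), lam),
             stringsAsFactors = FALSE)
}
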
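#' Validate a structural-variant call set
#'
#' Records carry an accession, coordinates, an SV type among
#' `INS, DEL, DUP, INV, TRA, INVDUP`, and the absolute event length
#' `svlen` (signed VCF SVLEN values are stored as absolute values).
#'
#' @param df data.frame with columns `accession`, `chrom`, `pos`,
#'   `svtype`, `svlen` and optionally `end`.
#' @return The validated data.frame with class `sv_call_set`.
#' @export
sv_call_set <- function(df) {
  need <- c("accession", "chrom", "pos", "svtype", "svlen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SV calls lack columns: ", paste(miss, collapse = ", "))
  bad <- !df$svtype %in% SV_TYPES
  if (any(bad))
    stop("unknown SVTYPE in record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(df$svtype[bad]), collapse = ", "))
  df$svlen <- abs(df$svlen)
  if (nrow(df) && any(df$svlen <= 0)) stop("SVLEN must be > 0 after normalization")
  if (!"end" %in% names(df)) df$end <- df$pos + df$svlen - 1
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("sv_call_set", "data.frame"))
}

#' Read an SV call set from a Sniffles-style VCF
#'
#' Parses a VCF whose INFO field carries `SVTYPE`, `SVLEN` and `END`
#' keys (the long-read SV caller dialect), one file per accession.
#'
#' @param path VCF file path.
#' @param accession accession name attached to every record.
#' @return An `sv_call_set`.
#' @export
read_sv_vcf <- function(path, accession) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  get_info <- function(key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    m <- regexec(pat, fix$INFO)
    vapply(regmatches(fix$INFO, m), function(x)
      if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  svtype <- get_info("SVTYPE")
  svlen <- suppressWarnings(as.numeric(get_info("SVLEN")))
  end <- suppressWarnings(as.numeric(get_info("END")))
  if (anyNA(svtype)) stop("record(s) without SVTYPE in ", path)
  svlen[is.na(svlen)] <- abs(end - as.numeric(fix$POS))[is.na(svlen)]
  sv_call_set(data.frame(accession = accession, chrom = fix$CHROM,
                         pos = as.numeric(fix$POS), svtype = svtype,
                         svlen = abs(svlen), end = end,
                         stringsAsFactors = FALSE))
}

#' Per-accession, per-type SV counts
#'
#' @param calls an `sv_call_set`.
#' @return data.frame with one row per accession, one column per SV type
#'   (all six types always present) and a `Total` column equal to the
#'   row sum.
#' @export
summarize_sv_calls <- function(calls) {
  calls <- sv_call_set(calls)      # re-validate (errors on unknown types)
  acc <- unique(calls$accession)
  tb <- table(factor(calls$accession, levels = acc),
              factor(calls$svtype, levels = SV_TYPES))
  out <- as.data.frame.matrix(tb)
  out <- cbind(accession = rownames(out), out, Total = rowSums(out))
  rownames(out) <- NULL
  out
}

#' Length/type filter for SV calls
#'
#' Retains records whose type is in `types` and whose absolute length
#' lies in `[min_len, max_len]` (inclusive bounds).  Translocation
#' (`TRA`) records have no meaningful linear length and are exempt from
#' the length bounds whenever `TRA` is included in `types`.
#'
#' @param calls an `sv_call_set`.
#' @param min_len,max_len length bounds in bp (default 1-50 kb).
#' @param types SV types to keep (default insertions, deletions,
#'   duplications).
#' @return The filtered `sv_call_set`.
#' @export
filter_svs_by_length <- function(calls, min_len = 1000, max_len = 50000,
                                 types = c("INS", "DEL", "DUP")) {
  if (min_len > max_len) stop("min_len exceeds max_len")
  calls <- sv_call_set(calls)
  keep <- calls$svtype %in% types &
    (calls$svtype == "TRA" |
       (calls$svlen >= min_len & calls$svlen <= max_len))
  sv_call_set(calls[keep, , drop = FALSE])
}

#' Windowed SV density per subgroup
#'
#' Counts SV records in non-overlapping windows per subgroup, for joint
#' display with diversity tracks.
#'
#' @param calls an `sv_call_set` (typically [filter_svs_by_length()]
#'   output).
#' @param groups named character vector mapping accession -> subgroup.
#' @param window window width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the maximum record coordinate per chromosome.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open) and
#'   one count column per subgroup.
#' @export
sv_window_density <- function(calls, groups, window = 500000,
                              chrom_lengths = NULL) {
  calls <- sv_call_set(calls)
  gi <- groups[calls$accession]
  if (anyNA(gi)) stop("accession(s) without group label: ",
                      paste(unique(calls$accession[is.na(gi)]), collapse = ", "))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(calls$pos, calls$chrom, max)
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    win <- tile_windows(chrom_lengths[[ch]], window)
    on_ch <- calls$chrom == ch
    wi <- findInterval(calls$pos - 1, win$start)
    res <- data.frame(chrom = ch, start = win$start, end = win$end,
                      stringsAsFactors = FALSE)
    for (gn in sort(unique(groups))) {
      res[[paste0("n_", gn)]] <-
        tabulate(wi[on_ch & gi == gn], nbins = nrow(win))
    }
    out[[ch]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' CNV-seq style windowed read-depth ratio test
#'
#' For each window the depth-normalized count ratio
#' `r = (x1/N1) / (x2/N2)` between a test and a reference sample is
#' tested against the null of equal copy number with the Geary-Hinkley
#' transformation of a ratio of two Gaussians (Poisson approximation,
#' mean = variance = the expected window count):
#' `t = (mu2 r - mu1) / sqrt(sigma2^2 r^2 + sigma1^2)`, referred
#' two-tailed to N(0, 1).  P-values are Benjamini-Hochberg corrected
#' across windows by default; a window is called `gain` when its
#' (adjusted) p <= alpha and log2 r > 0, `loss` when log2 r < 0, else
#' `neutral`.  Windows with a zero reference count have an undefined
#' ratio and are flagged `loss-candidate/undefined` rather than
#' erroring.
#'
#' @param counts data.frame with columns `chrom`, `start`, `end`,
#'   `test_count`, `ref_count` (e.g. from
#'   [simulate_window_read_counts()] where `test_count`/`ref_count` map
#'   to x1/x2).
#' @param N1,N2 total mapped read counts of the test and reference
#'   samples; default the column sums.
#' @param alpha significance level applied to the (adjusted) p-values.
#'   No field-standard default exists; it must be chosen by the analyst
#'   (0.01 here).
#' @param adjust apply BH correction across windows (default TRUE).
#' @return data.frame of class `cnv_window_result`: input columns plus
#'   `ratio`, `log2_ratio`, `t`, `p`, `p_adj` and `call`.
#' @export
cnv_ratio_test <- function(counts, N1 = sum(counts$test_count),
                           N2 = sum(counts$ref_count), alpha = 0.01,
                           adjust = TRUE) {
  stopifnot(all(c("test_count", "ref_count") %in% names(counts)))
  if (N1 <= 0 || N2 <= 0) stop("total read counts must be > 0")
  if (any(counts$test_count < 0 | counts$ref_count < 0))
    stop("window counts must be >= 0")
  x1 <- counts$test_count; x2 <- counts$ref_count
  nw <- nrow(counts)
  mu1 <- N1 / nw; mu2 <- N2 / nw
  r <- (x1 / N1) / (x2 / N2)
  undef <- x2 == 0
  tstat <- (mu2 * r - mu1) / sqrt(mu2 * r^2 + mu1)
  p <- 2 * stats::pnorm(-abs(tstat))
  p[undef] <- NA_real_
  ok <- !is.na(p)
  p_adj <- rep(NA_real_, nw)
  sig <- rep(FALSE, nw)
  if (any(ok)) {
    pok <- pmax(p[ok], .Machine$double.xmin)
    if (adjust) {
      sig[ok] <- bh_fdr(pok, q = alpha)$significant
      p_adj[ok] <- stats::p.adjust(pok, method = "BH")  # reporting only
    } else {
      sig[ok] <- pok <= alpha
      p_adj[ok] <- pok
    }
  }
  l2 <- log2(r)
  call <- rep("neutral", nw)
  call[sig & l2 > 0] <- "gain"
  call[sig & l2 < 0] <- "loss"
  call[undef] <- "loss-candidate/undefined"
  out <- cbind(counts,
               data.frame(ratio = r, log2_ratio = l2, t = tstat, p = p,
                          p_adj = p_adj, call = call,
                          stringsAsFactors = FALSE))
  class(out) <- c("cnv_window_result", "data.frame")
  out
}
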
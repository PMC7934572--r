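#' Simulate a toy reference genome with gene models
#'
#' Generates a single synthetic chromosome carrying `n_genes` protein
#' coding genes on random strands.  Each gene has a 5' UTR, one to four
#' coding exons separated by `GT..AG` introns, and a 3' UTR.  The CDS
#' starts with `ATG`, ends with a stop codon, contains no internal stop
#' (codons are drawn from the 61 sense codons) and its concatenated
#' length is divisible by 3 by construction.  Intron boundaries may fall
#' inside codons, as in real gene models.
#'
#' @param n_genes number of genes.
#' @param protein_len integer range `c(min, max)` of protein lengths (aa).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return A list with `genome` (a [Biostrings::DNAStringSet] of length
#'   1), `models` (a `gene_models` data.frame, see [gene_models()]) and
#'   `proteins` (named character vector of the encoded proteins, without
#'   the terminal stop).
#' @export
simulate_gene_models <- function(n_genes = 5, protein_len = c(40, 150),
                                 chrom = "ChrS1", seed = 1L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  feats <- list()
  chrom_seq <- character(0)
  offset <- 0
  proteins <- character(0)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", i)
    gap <- sample(500:2000, 1)
    chrom_seq <- c(chrom_seq, rand_seq(gap))
    offset <- offset + gap

    L <- sample(protein_len[1]:protein_len[2], 1)
    aa_codons <- sample(sense, L, replace = TRUE)
    cds <- paste0("ATG", paste(aa_codons, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
    cds_len <- nchar(cds)
    n_ex <- sample(1:4, 1)
    cuts <- if (n_ex > 1)
      sort(sample(seq(3, cds_len - 3), n_ex - 1)) else integer(0)
    piece_bounds <- cbind(c(1, cuts + 1), c(cuts, cds_len))
    utr5 <- rand_seq(sample(30:80, 1))
    utr3 <- rand_seq(sample(30:80, 1))
    introns <- replicate(max(0, n_ex - 1),
                         paste0("GT", rand_seq(sample(26:116, 1)), "AG"))

    # assemble gene-sense sequence and local feature coordinates
    local <- list()
    seq_parts <- utr5
    cur <- nchar(utr5)
    local$utr5 <- c(1, cur)
    cds_local <- matrix(NA_real_, n_ex, 2)
    exon_local <- matrix(NA_real_, n_ex, 2)
    for (e in seq_len(n_ex)) {
      plen <- piece_bounds[e, 2] - piece_bounds[e, 1] + 1
      cds_local[e, ] <- c(cur + 1, cur + plen)
      seq_parts <- c(seq_parts, substr(cds, piece_bounds[e, 1], piece_bounds[e, 2]))
      cur <- cur + plen
      if (e < n_ex) {
        seq_parts <- c(seq_parts, introns[e])
        cur <- cur + nchar(introns[e])
      }
    }
    local$utr3 <- c(cur + 1, cur + nchar(utr3))
    seq_parts <- c(seq_parts, utr3)
    cur <- cur + nchar(utr3)
    glen <- cur
    exon_local[1, ] <- c(1, cds_local[1, 2])
    if (n_ex > 1) {
      for (e in 2:n_ex) exon_local[e, ] <- cds_local[e, ]
    }
    exon_local[n_ex, 2] <- glen

    strand <- sample(c("+", "-"), 1)
    gseq <- paste(seq_parts, collapse = "")
    if (strand == "-")
      gseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
    chrom_seq <- c(chrom_seq, gseq)
    gstart <- offset + 1

    to_genomic <- function(ab) {
      if (strand == "+") c(gstart + ab[1] - 1, gstart + ab[2] - 1)
      else c(gstart + glen - ab[2], gstart + glen - ab[1])
    }
    # CDS phase in transcription order
    plens <- cds_local[, 2] - cds_local[, 1] + 1
    phase <- (3 - cumsum(c(0, plens[-n_ex])) %% 3) %% 3

    add <- function(type, ab, ph = NA_integer_) {
      g <- to_genomic(ab)
      data.frame(seqid = chrom, type = type, start = g[1], end = g[2],
                 strand = strand, gene_id = gid, phase = ph,
                 stringsAsFactors = FALSE)
    }
    rows <- list(add("gene", c(1, glen)),
                 add("five_prime_UTR", local$utr5),
                 add("three_prime_UTR", local$utr3))
    for (e in seq_len(n_ex)) {
      rows[[length(rows) + 1]] <- add("exon", exon_local[e, ])
      rows[[length(rows) + 1]] <- add("CDS", cds_local[e, ], phase[e])
    }
    feats[[i]] <- do.call(rbind, rows)
    offset <- offset + glen
    proteins[gid] <- substr(
      as.character(Biostrings::translate(Biostrings::DNAString(cds))),
      1, L + 1)
  }
  chrom_seq <- c(chrom_seq, rand_seq(sample(500:2000, 1)))
  genome <- Biostrings::DNAStringSet(paste(chrom_seq, collapse = ""))
  names(genome) <- chrom
  models <- gene_models(do.call(rbind, feats))
  list(genome = genome, models = models, proteins = proteins)
}

#' Write / read gene models as GFF3
#'
#' Thin wrappers around [rtracklayer::export()] / [rtracklayer::import()]
#' that map between the package's `gene_models` data.frame and GFF3
#' (gene rows carry `ID=<gene_id>`, feature rows `Parent=<gene_id>`).
#'
#' @param models a `gene_models` data.frame.
#' @param path file path of the GFF3 file.
#' @return `read_gene_models` returns a `gene_models` data.frame;
#'   `write_gene_models` returns `path` invisibly.
#' @export
write_gene_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$seqid,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = models$strand)
  S4Vectors::mcols(gr)$type <- models$type
  S4Vectors::mcols(gr)$phase <- as.integer(models$phase)
  is_gene <- models$type == "gene"
  S4Vectors::mcols(gr)$ID <- ifelse(is_gene, models$gene_id, NA_character_)
  parent <- ifelse(is_gene, NA_character_, models$gene_id)
  S4Vectors::mcols(gr)$Parent <-
    IRanges::CharacterList(lapply(parent, function(p) p[!is.na(p)]))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gid <- ifelse(is.na(parent), as.character(mc$ID), parent)
  phase <- if ("phase" %in% names(mc)) as.integer(mc$phase) else NA_integer_
  gene_models(data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid, phase = phase, stringsAsFactors = FALSE))
}

#' Write / read a reference genome as FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path FASTA file path.
#' @return `read_reference_fasta` returns a `DNAStringSet`;
#'   `write_reference_fasta` returns `path` invisibly.
#' @export
write_reference_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) Biostrings::readDNAStringSet(path)
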
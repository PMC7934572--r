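# fixture: simulated genome with genes on both strands
ann_fix <- local({
  gm <- simulate_gene_models(n_genes = 8, seed = 21)
  gm
})

test_that("codon-level worked cases: stop gain, stop loss, silent, frameshift", {
  # build a dedicated plus-strand gene whose second codon is AAA (Lys)
  cds <- paste0("ATG", "AAA", "GGC", "CTG", "TAA")
  utr5 <- strrep("C", 10); utr3 <- strrep("G", 10)
  genome <- Biostrings::DNAStringSet(paste0(strrep("T", 50), utr5, cds, utr3,
                                            strrep("T", 50)))
  names(genome) <- "chrT"
  gstart <- 51; cds_start <- gstart + 10
  models <- gene_models(data.frame(
    seqid = "chrT",
    type = c("gene", "five_prime_UTR", "exon", "CDS", "three_prime_UTR"),
    start = c(gstart, gstart, gstart, cds_start, cds_start + 15),
    end = c(gstart + 34, gstart + 9, gstart + 34, cds_start + 14,
            gstart + 34),
    strand = "+", gene_id = "geneT", stringsAsFactors = FALSE))

  # A->T at codon-2 position 1: AAA (Lys) -> TAA premature stop
  v <- data.frame(chrom = "chrT", pos = cds_start + 3, ref = "A", alt = "T")
  call <- annotate_variants(v, models, genome)
  expect_equal(call$effect, "stop_gained")
  expect_equal(call$impact, "High")
  expect_equal(call$functional_class, "Nonsense")
  expect_equal(call$ref_codon, "AAA")
  expect_equal(call$alt_codon, "TAA")
  expect_equal(call$ref_aa, "K")

  # T->C at the stop codon TAA -> CAA (Gln): stop loss
  v2 <- data.frame(chrom = "chrT", pos = cds_start + 12, ref = "T", alt = "C")
  call2 <- annotate_variants(v2, models, genome)
  expect_equal(call2$effect, "stop_lost")
  expect_equal(call2$impact, "High")
  expect_equal(call2$alt_codon, "CAA")
  expect_equal(call2$alt_aa, "Q")

  # third-position change preserving the amino acid: GGC -> GGT (Gly)
  v3 <- data.frame(chrom = "chrT", pos = cds_start + 8, ref = "C", alt = "T")
  call3 <- annotate_variants(v3, models, genome)
  expect_equal(call3$effect, "synonymous")
  expect_equal(call3$impact, "Low")
  expect_equal(call3$functional_class, "Silent")

  # 5-bp insertion inside the CDS: frameshift, High
  v4 <- data.frame(chrom = "chrT", pos = cds_start + 4, ref = "A",
                   alt = "AGGGGG")
  call4 <- annotate_variants(v4, models, genome)
  expect_equal(call4$effect, "frameshift")
  expect_equal(call4$impact, "High")
  # 3-bp in-frame insertion: Moderate
  v5 <- data.frame(chrom = "chrT", pos = cds_start + 4, ref = "A",
                   alt = "AGGG")
  expect_equal(annotate_variants(v5, models, genome)$effect, "inframe_indel")

  # UTR / intergenic / ref-mismatch behaviour
  v6 <- data.frame(chrom = "chrT", pos = gstart + 2, ref = "C", alt = "A")
  expect_equal(annotate_variants(v6, models, genome)$effect, "UTR")
  v7 <- data.frame(chrom = "chrT", pos = 5, ref = "T", alt = "A")
  expect_equal(annotate_variants(v7, models, genome)$impact, "Modifier")
  v8 <- data.frame(chrom = "chrT", pos = cds_start + 3, ref = "G", alt = "T")
  expect_error(annotate_variants(v8, models, genome), "mismatch at chrT:")
})

test_that("splice-site and intron classification uses the 2 bp window", {
  gm <- ann_fix
  models <- gm$models
  # pick a gene with >= 2 exons
  multi <- names(which(table(models$gene_id[models$type == "exon"]) >= 2))
  gid <- multi[1]
  ex <- models[models$gene_id == gid & models$type == "exon", ]
  ex <- ex[order(ex$start), ]
  int_s <- ex$end[1] + 1; int_e <- ex$start[2] - 1
  mkv <- function(pos) {
    ref <- as.character(Biostrings::subseq(gm$genome[[1]], pos, pos))
    data.frame(chrom = names(gm$genome), pos = pos, ref = ref,
               alt = if (ref == "A") "G" else "A")
  }
  expect_equal(annotate_variants(mkv(int_s), models, gm$genome)$effect,
               "splice_site")
  expect_equal(annotate_variants(mkv(int_s + 1), models, gm$genome)$effect,
               "splice_site")
  expect_equal(annotate_variants(mkv(int_e), models, gm$genome)$effect,
               "splice_site")
  mid <- (int_s + int_e) %/% 2
  if (mid - int_s >= 2 && int_e - mid >= 2)
    expect_equal(annotate_variants(mkv(mid), models, gm$genome)$effect,
                 "intronic")
})

test_that("coding SNV calls agree with the full-CDS translation-diff oracle", {
  gm <- ann_fix
  models <- gm$models
  genome_str <- as.character(gm$genome[[1]])
  set.seed(99)
  n_checked <- 0
  for (gid in unique(models$gene_id)) {
    pos_all <- cds_positions(models, gid)
    for (pos in sample(pos_all, min(45, length(pos_all)))) {
      ref <- substr(genome_str, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- data.frame(chrom = names(gm$genome), pos = pos, ref = ref,
                        alt = alt)
        got <- annotate_variants(v, models, gm$genome)
        want <- effect_oracle_snv(models, gm$genome, names(gm$genome),
                                  pos, ref, alt, gid)
        expect_equal(got$effect, want,
                     label = sprintf("pos %d %s>%s (gene %s): %s",
                                     pos, ref, alt, gid, got$effect))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("reverse-strand annotation is strand-symmetric", {
  gm <- ann_fix
  models <- gm$models
  minus <- unique(models$gene_id[models$type == "gene" & models$strand == "-"])
  expect_gte(length(minus), 1)
  genome_str <- as.character(gm$genome[[1]])
  # mirror the whole chromosome: reverse-complement genome and coordinates
  L <- nchar(genome_str)
  rc <- as.character(Biostrings::reverseComplement(gm$genome[[1]]))
  genome_rc <- Biostrings::DNAStringSet(rc); names(genome_rc) <- "chrRC"
  models_rc <- models
  models_rc$seqid <- "chrRC"
  models_rc$start <- L - models$end + 1
  models_rc$end <- L - models$start + 1
  models_rc$strand <- ifelse(models$strand == "+", "-", "+")
  models_rc <- gene_models(models_rc)
  set.seed(7)
  for (gid in minus[1]) {
    pos_all <- cds_positions(models, gid)
    for (pos in sample(pos_all, 40)) {
      ref <- substr(genome_str, pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      v <- data.frame(chrom = names(gm$genome), pos = pos, ref = ref, alt = alt)
      comp <- chartr("ACGT", "TGCA", c(ref, alt))
      v_rc <- data.frame(chrom = "chrRC", pos = L - pos + 1,
                         ref = comp[1], alt = comp[2])
      expect_equal(annotate_variants(v, models, gm$genome)$effect,
                   annotate_variants(v_rc, models_rc, genome_rc)$effect)
    }
  }
})

test_that("impact summaries tally correctly and join sharing categories", {
  calls <- data.frame(
    impact = c("High", "Moderate", "Moderate", "Low", "Modifier"),
    functional_class = c("Nonsense", "Missense", "Missense", "Silent", "none"),
    stringsAsFactors = FALSE)
  sm <- summarize_impacts(calls)
  expect_equal(unname(sm$impact_counts[c("High", "Moderate", "Low", "Modifier")]),
               as.integer(c(1, 2, 1, 1)), ignore_attr = TRUE)
  expect_equal(sm$functional_total, 4)
  expect_equal(sm$functional$percent[sm$functional$class == "Missense"], 50)
  sm2 <- summarize_impacts(calls, sharing = c("private-J", "shared-all",
                                              "private-J", "shared-all",
                                              "absent"))
  expect_equal(sum(sm2$impact_by_sharing), 5)
  expect_equal(unname(sm2$impact_by_sharing["Moderate", "private-J"]), 1)
  # empty call set -> all-zero table
  empty <- summarize_impacts(calls[0, ])
  expect_equal(sum(empty$impact_counts), 0)
  expect_equal(empty$functional_total, 0)
  # counting oracle on a random fixture; order invariance
  set.seed(12)
  big <- calls[sample(5, 500, replace = TRUE), ]
  smb <- summarize_impacts(big)
  expect_equal(unname(smb$impact_counts["Moderate"]),
               sum(big$impact == "Moderate"), ignore_attr = TRUE)
  shuf <- big[sample(nrow(big)), ]
  expect_equal(summarize_impacts(shuf)$impact_counts, smb$impact_counts)
})
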
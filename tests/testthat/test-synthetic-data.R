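test_that("generator is deterministic and honours rates and invariants", {
  cfg <- sim_config(n_per_group = c(A = 10, B = 10, C = 10), n_variants = 400,
                    chrom_length = 1e5, F = 0.1, missing_rate = 0.05, seed = 42)
  s1 <- simulate_structured_genotypes(cfg)
  s2 <- simulate_structured_genotypes(cfg)
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_identical(s1$truth$subpop_freqs, s2$truth$subpop_freqs)

  # positions strictly increasing within bounds
  pos <- s1$panel$variants$pos
  expect_true(all(diff(pos) > 0))
  expect_true(all(pos >= 1 & pos <= cfg$chrom_length))

  # missingness close to the configured rate (averaged over several seeds)
  miss <- sapply(1:5, function(sd) {
    cfg2 <- sim_config(n_per_group = c(A = 20, B = 20, C = 20),
                       n_variants = 1000, chrom_length = 1e6,
                       F = 0.1, missing_rate = 0.05, seed = sd)
    mean(is.na(simulate_structured_genotypes(cfg2)$panel$geno))
  })
  expect_lt(abs(mean(miss) - 0.05), 0.01)

  expect_error(sim_config(F = 0), "F must")
  expect_error(sim_config(F = 1.2), "F must")
  expect_error(sim_config(n_per_group = c(A = 1, B = 5)), "n_per_group")
})

test_that("Balding-Nichols differentiation is recovered by Weir-Cockerham theta", {
  # Monte-Carlo over seeds; oracle is the Balding-Nichols expectation F
  thetas <- sapply(1:10, function(sd) {
    cfg <- sim_config(n_per_group = c(A = 50, B = 50, C = 50),
                      n_variants = 2000, chrom_length = 1e6, F = 0.1, seed = sd)
    sim <- simulate_structured_genotypes(cfg)
    wc_theta_oracle(sim$panel$geno, sim$panel$samples$group)
  })
  expect_lt(abs(mean(thetas) - 0.1), 0.02)

  # near-zero differentiation limit
  cfg0 <- sim_config(n_per_group = c(A = 60, B = 60), n_variants = 2000,
                     chrom_length = 1e6, F = 0.002, seed = 9)
  sim0 <- simulate_structured_genotypes(cfg0)
  expect_lt(abs(wc_theta_oracle(sim0$panel$geno, sim0$panel$samples$group)),
            0.01)
})

test_that("haplotype copying induces LD that decays with distance", {
  adj_r2 <- function(rho, seed) {
    cfg <- sim_config(n_per_group = c(A = 100), n_variants = 500,
                      chrom_length = 1e5, F = 0.1, rho = rho, seed = seed)
    g <- simulate_structured_genotypes(cfg)$panel$geno
    mean(sapply(seq_len(ncol(g) - 1), function(j)
      suppressWarnings(cor(g[, j], g[, j + 1]))^2), na.rm = TRUE)
  }
  # rho = 0: adjacent r2 indistinguishable from a permuted-site baseline
  cfg <- sim_config(n_per_group = c(A = 100), n_variants = 500,
                    chrom_length = 1e5, F = 0.1, rho = 0, seed = 3)
  g <- simulate_structured_genotypes(cfg)$panel$geno
  obs <- mean(sapply(seq_len(ncol(g) - 1), function(j)
    suppressWarnings(cor(g[, j], g[, j + 1]))^2), na.rm = TRUE)
  set.seed(31)
  gp <- g[, sample(ncol(g))]
  perm <- mean(sapply(seq_len(ncol(gp) - 1), function(j)
    suppressWarnings(cor(gp[, j], gp[, j + 1]))^2), na.rm = TRUE)
  expect_lt(abs(obs - perm), 0.01)

  # rho > 0: mean r2 decreases with index distance (averaged over seeds)
  r2_at_lag <- function(g, lag) {
    mean(sapply(seq_len(ncol(g) - lag), function(j)
      suppressWarnings(cor(g[, j], g[, j + lag]))^2), na.rm = TRUE)
  }
  lags <- sapply(1:3, function(sd) {
    cfg <- sim_config(n_per_group = c(A = 100), n_variants = 400,
                      chrom_length = 1e5, F = 0.1, rho = 0.8, seed = sd)
    g <- simulate_structured_genotypes(cfg)$panel$geno
    c(r2_at_lag(g, 1), r2_at_lag(g, 4), r2_at_lag(g, 16))
  })
  avg <- rowMeans(lags)
  expect_true(avg[1] > avg[2] && avg[2] > avg[3])
})

test_that("phenotype generator realizes the requested architecture", {
  cfg <- sim_config(n_per_group = c(A = 100, B = 100, C = 100),
                    n_variants = 500, chrom_length = 1e6, F = 0.05, seed = 11)
  sim <- simulate_structured_genotypes(cfg)

  # noiseless single-site limit: exactly beta per allele
  tr1 <- set_trait_truth(sim$truth, sim$panel$variants$id[5], 2, h2 = 1)
  y1 <- simulate_phenotype(sim$panel, tr1, seed = 1)
  d <- sim$panel$geno[, 5]
  expect_equal(unname(y1), unname(2 * d))

  # null heritability: slope on the causal dosage is ~0 over replicates
  tr0 <- set_trait_truth(sim$truth, sim$panel$variants$id[5], 2, h2 = 0)
  slopes <- sapply(1:20, function(sd) {
    y <- simulate_phenotype(sim$panel, tr0, seed = sd)
    coef(lm(y ~ d))[2]
  })
  expect_lt(abs(mean(slopes)), 0.05)

  # realized h2 matches the target
  cs <- sim$panel$variants$id[seq(10, 100, by = 10)]
  tr <- set_trait_truth(sim$truth, cs, rnorm(10), h2 = 0.5)
  h2s <- sapply(1:10, function(sd) {
    y <- simulate_phenotype(sim$panel, tr, seed = sd)
    X <- sim$panel$geno[, match(cs, sim$panel$variants$id)]
    g <- drop(X %*% tr$effect_sizes)
    var(g) / var(y)
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.1)

  expect_error(simulate_phenotype(
    sim$panel, set_trait_truth(sim$truth, "nope", 1, 0.5), 1), "nope")
})

test_that("SV and CNV generators match their sampling laws", {
  # all rates zero -> empty set
  empty <- simulate_sv_calls(c("a1", "a2"), c(DEL = 0), genome_length = 1e5,
                             seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_sv_calls("a", c(BAD = 1e-5)), "unknown SVTYPE")

  # single-type rates: only that type appears; counts near Poisson mean
  del <- simulate_sv_calls("acc", c(DEL = 5e-4), genome_length = 1e5, seed = 2)
  sm <- summarize_sv_calls(del)
  expect_true(all(sm[, c("INS", "DUP", "INV", "TRA", "INVDUP")] == 0))
  expect_gt(sm$DEL, 0)

  # type shares over seeds follow the rate spec (Poisson sampling oracle)
  rates <- c(INS = 785, DEL = 452, DUP = 132, INV = 41, TRA = 623) / 1e6
  shares <- sapply(1:10, function(sd) {
    calls <- simulate_sv_calls("w82", rates, genome_length = 1e6, seed = sd)
    tb <- table(factor(calls$svtype, levels = names(rates)))
    as.numeric(tb / sum(tb))
  })
  expect_true(all(abs(rowMeans(shares) - rates / sum(rates)) < 0.03))

  # CNV counts: copy 2 -> log2 ratio ~0; copy 4 -> ~1; copy 0 -> ~0 reads
  seg <- data.frame(chrom = "Chr01", start = c(2e5, 6e5), end = c(3e5, 7e5),
                    copy_number = c(4, 0))
  cw <- simulate_window_read_counts(seg, mean_depth = 30, window = 1e5,
                                    chrom_length = 1e6, seed = 3)
  l2 <- log2((cw$test_count + 0.5) / (cw$ref_count + 0.5))
  expect_lt(max(abs(l2[cw$copy_number == 2])), 0.1)
  expect_lt(abs(mean(l2[cw$copy_number == 4]) - 1), 0.1)
  expect_equal(sum(cw$test_count[cw$copy_number == 0]), 0)
})

test_that("simulated gene models are internally consistent and round-trip", {
  gm <- simulate_gene_models(n_genes = 6, seed = 7)
  models <- gm$models
  # every CDS translates without internal stop, ends in a stop codon
  for (gid in unique(models$gene_id)) {
    cds <- models[models$gene_id == gid & models$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    strand <- cds$strand[1]
    pieces <- vapply(seq_len(nrow(cds)), function(i)
      as.character(Biostrings::subseq(gm$genome[[1]], cds$start[i], cds$end[i])),
      character(1))
    if (strand == "-")
      pieces <- rev(vapply(pieces, function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
        character(1)))
    seq <- paste(pieces, collapse = "")
    expect_equal(nchar(seq) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
    expect_equal(substr(seq, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(paste0(substr(aa, 1, nchar(aa) - 1), "*"),
                 paste0(gm$proteins[gid], "*"))
    # features nested within the gene span
    gene <- models[models$gene_id == gid & models$type == "gene", ]
    feats <- models[models$gene_id == gid & models$type != "gene", ]
    expect_true(all(feats$start >= gene$start & feats$end <= gene$end))
  }
  # GFF3 + FASTA round trip preserves everything material
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_gene_models(models, gff)
  write_reference_fasta(gm$genome, fa)
  back <- read_gene_models(gff)
  cols <- c("seqid", "type", "start", "end", "strand", "gene_id")
  ord <- function(d) d[order(d$gene_id, d$type, d$start), cols]
  expect_equal(ord(as.data.frame(back)), ord(as.data.frame(models)),
               ignore_attr = TRUE)
  genome2 <- read_reference_fasta(fa)
  expect_equal(as.character(genome2[[1]]), as.character(gm$genome[[1]]))
})
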
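EFFECT_IMPACT <- c(stop_gained = "High", stop_lost = "High",
                   start_lost = "High", frameshift = "High",
                   splice_site = "High",
                   missense = "Moderate", inframe_indel = "Moderate",
                   synonymous = "Low",
                   intronic = "Modifier", UTR = "Modifier",
                   intergenic = "Modifier")

# severity order for resolving overlapping gene models
EFFECT_SEVERITY <- names(EFFECT_IMPACT)

EFFECT_FUNCTIONAL_CLASS <- c(stop_gained = "Nonsense", stop_lost = "Missense",
                             missense = "Missense", synonymous = "Silent")

#' Validate a gene-model table
#'
#' Gene models are stored as a flat data.frame with one canonical
#' transcript per gene: rows of type `gene`, `exon`, `CDS`,
#' `five_prime_UTR`, `three_prime_UTR` with 1-based inclusive `start`,
#' `end`, `strand` and `gene_id`.  Validates that CDS intervals are
#' non-overlapping, fall inside exons, and that each gene's concatenated
#' CDS length is divisible by 3.
#'
#' @param df data.frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `gene_id` (and optionally `phase`).
#' @return The validated data.frame with class `gene_models`.
#' @export
gene_models <- function(df) {
  need <- c("seqid", "type", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene models lack columns: ", paste(miss, collapse = ", "))
  if (!"phase" %in% names(df)) df$phase <- NA_integer_
  for (gid in unique(df$gene_id)) {
    cds <- df[df$gene_id == gid & df$type == "CDS", , drop = FALSE]
    if (nrow(cds) == 0) next
    cds <- cds[order(cds$start), , drop = FALSE]
    if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))
      stop("overlapping CDS intervals in gene ", gid)
    if (sum(cds$end - cds$start + 1) %% 3 != 0)
      stop("CDS length of gene ", gid, " not divisible by 3")
    ex <- df[df$gene_id == gid & df$type == "exon", , drop = FALSE]
    if (nrow(ex)) {
      inside <- vapply(seq_len(nrow(cds)), function(i)
        any(ex$start <= cds$start[i] & ex$end >= cds$end[i]), logical(1))
      if (!all(inside)) stop("CDS outside exons in gene ", gid)
    }
  }
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("gene_models", "data.frame"))
}

# spliced CDS sequence of a gene (transcription order), plus interval table
gene_cds_info <- function(models, gid, genome) {
  rows <- models[models$gene_id == gid & models$type == "CDS", , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  strand <- rows$strand[1]
  chrom <- rows$seqid[1]
  pieces <- vapply(seq_len(nrow(rows)), function(i)
    as.character(Biostrings::subseq(genome[[chrom]], rows$start[i], rows$end[i])),
    character(1))
  if (strand == "-") {
    pieces <- rev(vapply(pieces, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1)))
    rows <- rows[rev(seq_len(nrow(rows))), , drop = FALSE]
  }
  list(seq = paste(pieces, collapse = ""), intervals = rows, strand = strand)
}

# 1-based position within the spliced CDS (transcription order), or NA
cds_coordinate <- function(info, pos) {
  iv <- info$intervals
  cum <- 0
  for (i in seq_len(nrow(iv))) {
    if (pos >= iv$start[i] && pos <= iv$end[i]) {
      off <- if (info$strand == "+") pos - iv$start[i] else iv$end[i] - pos
      return(cum + off + 1)
    }
    cum <- cum + iv$end[i] - iv$start[i] + 1
  }
  NA_integer_
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# classify one variant against one gene; returns a one-row data.frame
classify_in_gene <- function(chrom, pos, ref, alt, models, gid, genome,
                             splice_window = 2) {
  rows <- models[models$gene_id == gid, , drop = FALSE]
  strand <- rows$strand[1]
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  cds <- rows[rows$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  ex <- rows[rows$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]

  in_cds <- nrow(cds) > 0 && any(pos >= cds$start & pos <= cds$end)
  in_exon <- nrow(ex) > 0 && any(pos >= ex$start & pos <= ex$end)

  blank <- list(ref_codon = NA_character_, alt_codon = NA_character_,
                ref_aa = NA_character_, alt_aa = NA_character_)
  mk <- function(term, extra = blank) {
    data.frame(gene_id = gid, effect = term, impact = EFFECT_IMPACT[[term]],
               functional_class = if (is_snv && term %in% names(EFFECT_FUNCTIONAL_CLASS))
                 EFFECT_FUNCTIONAL_CLASS[[term]] else "none",
               ref_codon = extra$ref_codon, alt_codon = extra$alt_codon,
               ref_aa = extra$ref_aa, alt_aa = extra$alt_aa,
               stringsAsFactors = FALSE)
  }

  if (in_cds) {
    if (!is_snv) {
      shift <- abs(nchar(ref) - nchar(alt))
      return(mk(if (shift %% 3 != 0) "frameshift" else "inframe_indel"))
    }
    obs <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
    if (obs != ref)
      stop("ref allele mismatch at ", chrom, ":", pos,
           " (reference has ", obs, ", variant claims ", ref, ")")
    info <- gene_cds_info(models, gid, genome)
    cpos <- cds_coordinate(info, pos)
    codon_i <- (cpos - 1) %/% 3
    within <- (cpos - 1) %% 3
    ref_codon <- substr(info$seq, codon_i * 3 + 1, codon_i * 3 + 3)
    alt_base <- if (strand == "-") chartr("ACGT", "TGCA", alt) else alt
    alt_codon <- ref_codon
    substr(alt_codon, within + 1, within + 1) <- alt_base
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    extra <- list(ref_codon = ref_codon, alt_codon = alt_codon,
                  ref_aa = ref_aa, alt_aa = alt_aa)
    term <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else if (codon_i == 0 && ref_codon == "ATG") "start_lost"
    else "missense"
    return(mk(term, extra))
  }
  if (in_exon) return(mk("UTR"))
  # intronic: within splice_window bp of an exon boundary -> splice_site
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      int_s <- ex$end[i] + 1; int_e <- ex$start[i + 1] - 1
      if (pos >= int_s && pos <= int_e) {
        if (pos - int_s < splice_window || int_e - pos < splice_window)
          return(mk("splice_site"))
        return(mk("intronic"))
      }
    }
  }
  mk("intronic")   # inside gene span but outside exons and introns gaps
}

#' Annotate variants against gene models
#'
#' SnpEff-style codon-aware classification of SNVs and indels.  Each
#' variant is located against the gene models (strand-aware, one
#' canonical transcript per gene).  Coding SNVs mutate their codon and
#' are translated under the standard nuclear code (synonymous /
#' missense / stop_gained / stop_lost / start_lost); coding indels are
#' `frameshift` when the length change is not a multiple of 3, else
#' `inframe_indel`.  Intronic positions within 2 bp of an exon boundary
#' are `splice_site`; exonic non-coding positions are `UTR`; variants
#' outside all genes are `intergenic`.  When gene models overlap, the
#' most severe call wins (High > Moderate > Low > Modifier; ties by
#' lowest gene id).  Impacts: stop/start/frameshift/splice -> High,
#' missense/inframe -> Moderate, synonymous -> Low, everything
#' non-coding -> Modifier.  Functional classes (coding SNVs and stop
#' events): stop_gained -> Nonsense, missense and stop_lost -> Missense,
#' synonymous -> Silent.
#'
#' A variant whose stated ref allele disagrees with the reference
#' sequence raises an error naming the position.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (a [genotype_panel()]'s `$variants` works directly).
#' @param models a [gene_models()] table.
#' @param genome a [Biostrings::DNAStringSet] holding the reference.
#' @return data.frame of effect calls: `id`, `chrom`, `pos`, `gene_id`,
#'   `effect`, `impact`, `functional_class`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`.
#' @export
annotate_variants <- function(variants, models, genome) {
  stopifnot(inherits(models, "gene_models"))
  if (inherits(variants, "genotype_panel")) variants <- variants$variants
  genes <- models[models$type == "gene", , drop = FALSE]
  out <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    chrom <- variants$chrom[v]; pos <- variants$pos[v]
    ref <- variants$ref[v]; alt <- variants$alt[v]
    hit <- genes$seqid == chrom & genes$start <= pos & genes$end >= pos
    if (!any(hit)) {
      call <- data.frame(gene_id = NA_character_, effect = "intergenic",
                         impact = "Modifier", functional_class = "none",
                         ref_codon = NA_character_, alt_codon = NA_character_,
                         ref_aa = NA_character_, alt_aa = NA_character_,
                         stringsAsFactors = FALSE)
    } else {
      calls <- do.call(rbind, lapply(sort(genes$gene_id[hit]), function(gid)
        classify_in_gene(chrom, pos, ref, alt, models, gid, genome)))
      sev <- match(calls$effect, EFFECT_SEVERITY)
      best <- order(sev, calls$gene_id)[1]   # ties: lowest gene id
      call <- calls[best, , drop = FALSE]
    }
    id <- if ("id" %in% names(variants)) variants$id[v] else
      paste0(chrom, "_", pos)
    out[[v]] <- cbind(data.frame(id = id, chrom = chrom, pos = pos,
                                 stringsAsFactors = FALSE), call)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Summarize effect calls by impact and functional class
#'
#' Contingency counts of impact classes (optionally crossed with the
#' sharing categories of [classify_sharing()]) and totals over the
#' Nonsense/Missense/Silent functional classes with percentages to one
#' decimal.
#'
#' @param calls effect-call data.frame from [annotate_variants()], or any
#'   data.frame with columns `impact` and `functional_class`.
#' @param sharing optional `sharing_table` aligned with `calls` (or a
#'   character vector of per-variant categories).
#' @return list with `impact_counts`, `impact_by_sharing` (or `NULL`),
#'   `functional` (data.frame class/count/percent) and
#'   `functional_total`.
#' @export
summarize_impacts <- function(calls, sharing = NULL) {
  impacts <- factor(calls$impact, levels = c("High", "Moderate", "Low", "Modifier"))
  impact_counts <- table(impact = impacts)
  by_sharing <- NULL
  if (!is.null(sharing)) {
    cat_vec <- if (inherits(sharing, "sharing_table")) sharing$category else sharing
    if (length(cat_vec) != nrow(calls))
      stop("sharing categories do not align with the effect calls")
    by_sharing <- table(impact = impacts, category = cat_vec)
  }
  fc <- calls$functional_class
  classes <- c("Nonsense", "Missense", "Silent")
  counts <- vapply(classes, function(cl) sum(fc == cl), numeric(1))
  total <- sum(counts)
  functional <- data.frame(class = classes, count = counts,
                           percent = if (total > 0)
                             round(100 * counts / total, 1) else rep(NA_real_, 3),
                           row.names = NULL, stringsAsFactors = FALSE)
  list(impact_counts = impact_counts, impact_by_sharing = by_sharing,
       functional = functional, functional_total = total)
}
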
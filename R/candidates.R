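#' Generate a synthetic reference genome and gene annotation
#'
#' Builds a random nucleotide reference with `n_genes` non-overlapping
#' single-exon protein-coding genes (open reading frames: ATG start, no
#' internal stop, terminal stop), on both strands when `n_genes >= 2`, and
#' the matching GFF3 gene models (gene/mRNA/CDS; 1-based inclusive
#' coordinates on write). CDS lengths are divisible by 3. This synthetic
#' fixture provides the sequence context for coding-effect classification.
#'
#' @param genome_length reference length in bp.
#' @param n_genes number of genes (>= 0).
#' @param gene_length CDS length in bp (multiple of 3).
#' @param layout `"random"` placement, or `"tiled"`: gene `g` centred in the
#'   `g`-th consecutive region of `region_length` bp (one gene per region,
#'   used by the candidate-screen experiments).
#' @param region_length region size for the tiled layout.
#' @param chrom chromosome name.
#' @param fasta_path,gff3_path optional output paths; written when given.
#' @param seed optional integer seed.
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `genes`
#'   (data.frame: `gene_id`, `chrom`, `start`, `end` 0-based half-open,
#'   `strand`) and `models` (a `gene_models` object).
#' @export
make_annotation_fixture <- function(genome_length, n_genes,
                                    gene_length = 900,
                                    layout = c("random", "tiled"),
                                    region_length = NULL, chrom = "chr1",
                                    fasta_path = NULL, gff3_path = NULL,
                                    seed = NULL) {
  layout <- match.arg(layout)
  stopifnot(genome_length >= 1, n_genes >= 0, gene_length %% 3 == 0,
            gene_length >= 9)
  if (n_genes * gene_length > genome_length) stop("infeasible packing")
  local_seed(seed)
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, genome_length, replace = TRUE)
  if (n_genes > 0) {
    if (layout == "random") {
      slack <- genome_length - n_genes * gene_length
      starts <- floor(sort(stats::runif(n_genes, 0, slack))) +
        (seq_len(n_genes) - 1L) * gene_length
    } else {
      if (is.null(region_length)) stop("tiled layout needs region_length")
      if (n_genes * region_length > genome_length) stop("infeasible packing")
      if (gene_length > region_length) stop("infeasible packing")
      starts <- (seq_len(n_genes) - 1L) * region_length +
        floor((region_length - gene_length) / 2)
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (n_genes >= 2 && length(unique(strand)) == 1)
      strand[1] <- setdiff(c("+", "-"), strand[1])
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste0,
                    collapse = "")
    sense <- setdiff(codons, stops)
    for (g in seq_len(n_genes)) {
      n_cod <- gene_length / 3
      orf <- c("ATG", sample(sense, n_cod - 2, replace = TRUE),
               sample(stops, 1))
      orf_chars <- strsplit(paste(orf, collapse = ""), "")[[1]]
      if (strand[g] == "-")
        orf_chars <- rev(c(A = "T", C = "G", G = "C", T = "A")[orf_chars])
      seq_chars[(starts[g] + 1):(starts[g] + gene_length)] <- orf_chars
    }
    genes <- data.frame(gene_id = sprintf("gene%02d", seq_len(n_genes)),
                        chrom = chrom, start = starts,
                        end = starts + gene_length, strand = strand,
                        stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- chrom
  if (!is.null(fasta_path)) Biostrings::writeXStringSet(genome, fasta_path)
  if (!is.null(gff3_path)) write_gff3(genes, gff3_path)
  list(genome = genome, genes = genes, models = gene_models_from_table(genes))
}

# minimal GFF3 emission: gene / mRNA / single CDS per gene, 1-based inclusive
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in seq_len(nrow(genes))) {
    with(genes[g, ], {
      s1 <- start + 1L
      lines <<- c(lines,
        sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, s1, end,
                strand, gene_id),
        sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s", chrom,
                s1, end, strand, gene_id, gene_id),
        sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                chrom, s1, end, strand, gene_id, gene_id))
    })
  }
  writeLines(lines, path)
  invisible(path)
}

# internal gene-model container: transcript list + gene table
gene_models_from_table <- function(genes) {
  tx <- lapply(seq_len(nrow(genes)), function(g)
    list(tx_id = paste0(genes$gene_id[g], ".t1"),
         gene_id = genes$gene_id[g], chrom = genes$chrom[g],
         strand = genes$strand[g],
         cds = data.frame(start = genes$start[g], end = genes$end[g])))
  names(tx) <- vapply(tx, `[[`, "", "tx_id")
  structure(list(transcripts = tx, genes = genes), class = "gene_models")
}

#' Read gene models from a GFF3 file
#'
#' Imports CDS features via [rtracklayer::import()], groups them by parent
#' transcript and transcripts by gene, and converts the 1-based inclusive
#' GFF3 coordinates to 0-based half-open at this boundary. CDS total length
#' per transcript must be divisible by 3.
#'
#' @param path GFF3 file path.
#' @return a `gene_models` object (transcript list plus gene table).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_cds <- md$type == "CDS"
  is_tx <- md$type %in% c("mRNA", "transcript")
  tx_gene <- setNames(vapply(md$Parent[is_tx], `[`, "", 1), md$ID[is_tx])
  cds_parent <- vapply(md$Parent[is_cds], `[`, "", 1)
  cds <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[is_cds],
                    start = BiocGenerics::start(gr)[is_cds] - 1L,
                    end = BiocGenerics::end(gr)[is_cds],
                    strand = as.character(BiocGenerics::strand(gr))[is_cds],
                    tx = cds_parent, stringsAsFactors = FALSE)
  tx <- lapply(split(cds, cds$tx), function(d) {
    d <- d[order(d$start), ]
    if (sum(d$end - d$start) %% 3 != 0)
      stop("CDS length not divisible by 3 for transcript ", d$tx[1])
    list(tx_id = d$tx[1], gene_id = unname(tx_gene[d$tx[1]]),
         chrom = d$chrom[1], strand = d$strand[1],
         cds = d[, c("start", "end")])
  })
  gene_id <- vapply(tx, `[[`, "", "gene_id")
  genes <- data.frame(
    gene_id = unique(gene_id),
    chrom = vapply(unique(gene_id), function(g)
      tx[[which(gene_id == g)[1]]]$chrom, ""),
    start = vapply(unique(gene_id), function(g)
      min(vapply(tx[gene_id == g], function(t) min(t$cds$start), 0)), 0),
    end = vapply(unique(gene_id), function(g)
      max(vapply(tx[gene_id == g], function(t) max(t$cds$end), 0)), 0),
    strand = vapply(unique(gene_id), function(g)
      tx[[which(gene_id == g)[1]]]$strand, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(transcripts = tx, genes = genes), class = "gene_models")
}

#' Classify the coding effect of a substitution
#'
#' For every transcript whose CDS contains the site, the reference codon and
#' the codon carrying the substituted allele are translated (strand-aware,
#' standard nuclear codon table). The site is `nonsynonymous` if the amino
#' acid differs in ANY transcript, `synonymous` if it falls in CDS and the
#' amino acid is identical in all, and `noncoding` otherwise.
#'
#' @param pos 0-based genomic position of the site.
#' @param alt_base substituted allele (must differ from the reference base).
#' @param gene_models a `gene_models` object.
#' @param genome reference as a [Biostrings::DNAStringSet].
#' @param chrom chromosome of the site.
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"noncoding"`.
#' @examples
#' fx <- make_annotation_fixture(3000, 2, seed = 1)
#' classify_coding_effect(fx$genes$start[1] + 3, "A", fx$models, fx$genome)
#' @export
classify_coding_effect <- function(pos, alt_base, gene_models, genome,
                                   chrom = names(genome)[1]) {
  seqs <- genome[[chrom]]
  if (pos < 0 || pos >= length(seqs)) stop("site beyond reference length")
  ref_base <- as.character(Biostrings::subseq(seqs, pos + 1, pos + 1))
  alt_base <- toupper(alt_base)
  if (alt_base == ref_base) stop("alt allele equals the reference base")
  if (!alt_base %in% c("A", "C", "G", "T")) stop("invalid allele")
  in_cds <- FALSE
  nonsyn <- FALSE
  for (t in gene_models$transcripts) {
    if (t$chrom != chrom) next
    hit <- which(t$cds$start <= pos & pos < t$cds$end)
    if (length(hit) == 0) next
    in_cds <- TRUE
    d <- t$cds[order(t$cds$start), , drop = FALSE]
    lens <- d$end - d$start
    e <- which(d$start <= pos & pos < d$end)
    rel_plus <- sum(lens[seq_len(e - 1)]) + (pos - d$start[e])
    cds_plus <- paste(vapply(seq_len(nrow(d)), function(i)
      as.character(Biostrings::subseq(seqs, d$start[i] + 1, d$end[i])), ""),
      collapse = "")
    if (t$strand == "+") {
      cds_seq <- cds_plus
      rel <- rel_plus
      sub_base <- alt_base
    } else {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_plus)))
      rel <- nchar(cds_plus) - 1 - rel_plus
      sub_base <- c(A = "T", C = "G", G = "C", T = "A")[[alt_base]]
    }
    if (nchar(cds_seq) %% 3 != 0) stop("CDS phase inconsistency")
    ci <- rel %/% 3
    codon <- substr(cds_seq, ci * 3 + 1, ci * 3 + 3)
    mutated <- codon
    substr(mutated, rel %% 3 + 1, rel %% 3 + 1) <- sub_base
    if (Biostrings::GENETIC_CODE[[codon]] !=
        Biostrings::GENETIC_CODE[[mutated]]) nonsyn <- TRUE
  }
  if (!in_cds) return("noncoding")
  if (nonsyn) "nonsynonymous" else "synonymous"
}

#' Screen significant regions for candidate domestication genes
#'
#' A gene is a candidate iff it overlaps a significant region AND contains at
#' least one nonsynonymous site whose Fst triplet shows the
#' selected-and-introgressed pattern: `Fst(I, R) > thr_high`,
#' `Fst(J, R) > thr_high` and `Fst(I, J) < thr_low` (strict inequalities) --
#' a mutation distinguishing both cultivars jointly from the wild taxon.
#'
#' @param significant_regions data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. KS-significant overlapping LDRs.
#' @param fst_records data.frame with `chrom`, `pos` (0-based genomic),
#'   `alt_base`, and the Fst triplet columns `fst_IJ`, `fst_RI`, `fst_RJ`.
#' @param gene_models a `gene_models` object.
#' @param genome reference as a [Biostrings::DNAStringSet].
#' @param thr_high,thr_low Fst thresholds.
#' @return data.frame with one row per candidate gene: `gene_id`, `region`
#'   (index into `significant_regions`), `n_sites` (qualifying nonsynonymous
#'   sites), `max_fst_RI`, `max_fst_RJ`, `min_fst_IJ`.
#' @export
screen_candidate_genes <- function(significant_regions, fst_records,
                                   gene_models, genome, thr_high = 0.8,
                                   thr_low = 0.1) {
  out <- data.frame(gene_id = character(), region = integer(),
                    n_sites = integer(), max_fst_RI = numeric(),
                    max_fst_RJ = numeric(), min_fst_IJ = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(significant_regions) == 0 || nrow(fst_records) == 0) return(out)
  qual <- fst_records[fst_records$fst_RI > thr_high &
                      fst_records$fst_RJ > thr_high &
                      fst_records$fst_IJ < thr_low, , drop = FALSE]
  if (nrow(qual) == 0) return(out)
  genes <- gene_models$genes
  for (g in seq_len(nrow(genes))) {
    reg <- which(significant_regions$chrom == genes$chrom[g] &
                 significant_regions$start < genes$end[g] &
                 genes$start[g] < significant_regions$end)
    if (length(reg) == 0) next
    sites <- qual[qual$chrom == genes$chrom[g] &
                  qual$pos >= genes$start[g] &
                  qual$pos < genes$end[g], , drop = FALSE]
    if (nrow(sites) == 0) next
    eff <- vapply(seq_len(nrow(sites)), function(i)
      classify_coding_effect(sites$pos[i], sites$alt_base[i], gene_models,
                             genome, sites$chrom[i]), "")
    sites <- sites[eff == "nonsynonymous", , drop = FALSE]
    if (nrow(sites) == 0) next
    out <- rbind(out, data.frame(
      gene_id = genes$gene_id[g], region = reg[1],
      n_sites = nrow(sites), max_fst_RI = max(sites$fst_RI),
      max_fst_RJ = max(sites$fst_RJ), min_fst_IJ = min(sites$fst_IJ),
      stringsAsFactors = FALSE))
  }
  out
}

#' Candidate counts per significant region
#'
#' @param candidates data.frame from [screen_candidate_genes()].
#' @param significant_regions the region table that was screened.
#' @return list with `n_regions`, `regions_with_candidates`,
#'   `single_candidate_regions` (count), `single_candidate_genes`
#'   (character vector), and `per_region` (candidate count per region).
#' @export
single_candidate_regions <- function(candidates, significant_regions) {
  n_reg <- nrow(significant_regions)
  per <- integer(n_reg)
  if (nrow(candidates) > 0) {
    tab <- table(factor(candidates$region, levels = seq_len(n_reg)))
    per <- as.integer(tab)
  }
  singles <- which(per == 1L)
  single_genes <- if (nrow(candidates))
    candidates$gene_id[candidates$region %in% singles] else character()
  list(n_regions = n_reg, regions_with_candidates = sum(per > 0),
       single_candidate_regions = length(singles),
       single_candidate_genes = single_genes, per_region = per)
}
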
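# deterministic miniature genome: one 12 bp gene (ATG GCT TTA TAA) on the
# plus strand at offset 3, and its reverse-complement twin on the minus
# strand at offset 18, inside a 33 bp reference
tiny_fixture <- function() {
  plus_orf <- "ATGGCTTTATAA"
  minus_orf <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_orf)))
  seqs <- paste0("CCC", plus_orf, "CCC", minus_orf, "CCC")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- "chr1"
  genes <- data.frame(gene_id = c("gplus", "gminus"), chrom = "chr1",
                      start = c(3, 18), end = c(15, 30),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  list(genome = genome, genes = genes,
       models = ldrscan:::gene_models_from_table(genes))
}

test_that("coding-effect calls follow the codon table", {
  fx <- tiny_fixture()
  # gene codons: ATG | GCT (Ala) | TTA (Leu) | TAA
  # GCT -> GCC (position 8, T->C): Ala -> Ala, synonymous
  expect_identical(classify_coding_effect(8, "C", fx$models, fx$genome),
                   "synonymous")
  # GCT -> CCT (position 6, G->C): Ala -> Pro, nonsynonymous
  expect_identical(classify_coding_effect(6, "C", fx$models, fx$genome),
                   "nonsynonymous")
  # intergenic site
  expect_identical(classify_coding_effect(0, "T", fx$models, fx$genome),
                   "noncoding")
  expect_error(classify_coding_effect(99, "A", fx$models, fx$genome),
               "beyond")
  expect_error(classify_coding_effect(6, "G", fx$models, fx$genome),
               "reference")
})

test_that("effect calls are strand-consistent", {
  fx <- tiny_fixture()
  # the minus-strand gene is the reverse complement of the plus-strand one:
  # the homologous substitution must classify identically
  # plus gene position 6 (G in GCT) corresponds to minus gene position
  # 18 + (15 - 1 - 6) = 26, with the complementary alternative allele
  expect_identical(classify_coding_effect(26, "G", fx$models, fx$genome),
                   classify_coding_effect(6, "C", fx$models, fx$genome))
  expect_identical(classify_coding_effect(24, "G", fx$models, fx$genome),
                   classify_coding_effect(8, "C", fx$models, fx$genome))
})

test_that("annotation fixtures are valid and round-trip through GFF3", {
  fx <- make_annotation_fixture(20000, 8, seed = 81)
  expect_identical(nrow(fx$genes), 8L)
  expect_true(all((fx$genes$end - fx$genes$start) %% 3 == 0))
  expect_true(all(fx$genes$start >= 0 & fx$genes$end <= 20000))
  expect_setequal(unique(fx$genes$strand), c("+", "-"))
  ord <- order(fx$genes$start)
  expect_true(all(fx$genes$start[ord][-1] >= head(fx$genes$end[ord], -1)))
  # every CDS is a translatable ORF: starts with M, no internal stop
  for (g in seq_len(8)) {
    cds <- Biostrings::subseq(fx$genome[[1]], fx$genes$start[g] + 1,
                              fx$genes$end[g])
    if (fx$genes$strand[g] == "-") cds <- Biostrings::reverseComplement(cds)
    aa <- as.character(Biostrings::translate(cds))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(sub("\\*$", "", aa), gsub("\\*", "", aa))
  }
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  fx2 <- make_annotation_fixture(20000, 8, seed = 81, fasta_path = fa,
                                 gff3_path = gff)
  expect_identical(readLines(gff)[1], "##gff-version 3")
  models <- read_gene_models(gff)
  expect_setequal(models$genes$gene_id, fx$genes$gene_id)
  m <- models$genes[order(models$genes$start), ]
  f <- fx$genes[order(fx$genes$start), ]
  expect_equal(m$start, f$start)
  expect_equal(m$end, f$end)
  expect_identical(m$strand, f$strand)
  genome_rt <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(genome_rt[[1]]), as.character(fx$genome[[1]]))
})

test_that("degenerate annotation inputs behave", {
  fx0 <- make_annotation_fixture(1000, 0, seed = 82)
  expect_identical(nrow(fx0$genes), 0L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  ldrscan:::write_gff3(fx0$genes, gff)
  expect_identical(readLines(gff), "##gff-version 3")
  expect_error(make_annotation_fixture(1000, 5, gene_length = 900), "packing")
})

test_that("the Fst-triplet screen applies strict thresholds and region gating", {
  fx <- tiny_fixture()
  regions <- data.frame(chrom = "chr1", start = 0, end = 16)  # covers gplus
  rec <- function(pos, alt, ri, rj, ij)
    data.frame(chrom = "chr1", pos = pos, alt_base = alt, fst_RI = ri,
               fst_RJ = rj, fst_IJ = ij, stringsAsFactors = FALSE)
  # qualifying nonsynonymous site in a covered gene -> candidate
  hit <- screen_candidate_genes(regions, rec(6, "C", 0.9, 0.85, 0.05),
                                fx$models, fx$genome)
  expect_identical(hit$gene_id, "gplus")
  expect_identical(hit$n_sites, 1L)
  # Fst(I, J) at the threshold boundary (0.15 >= 0.1): excluded
  expect_identical(nrow(screen_candidate_genes(
    regions, rec(6, "C", 0.9, 0.85, 0.15), fx$models, fx$genome)), 0L)
  # thresholds are strict: exactly 0.8 / 0.1 do not qualify
  expect_identical(nrow(screen_candidate_genes(
    regions, rec(6, "C", 0.8, 0.9, 0.05), fx$models, fx$genome)), 0L)
  expect_identical(nrow(screen_candidate_genes(
    regions, rec(6, "C", 0.9, 0.9, 0.1), fx$models, fx$genome)), 0L)
  # synonymous qualifying site: not a candidate
  expect_identical(nrow(screen_candidate_genes(
    regions, rec(8, "C", 0.9, 0.85, 0.05), fx$models, fx$genome)), 0L)
  # qualifying site in a gene outside all significant regions
  expect_identical(nrow(screen_candidate_genes(
    regions, rec(26, "G", 0.9, 0.85, 0.05), fx$models, fx$genome)), 0L)
})

test_that("the screen is monotone in its thresholds", {
  fx <- tiny_fixture()
  regions <- data.frame(chrom = "chr1", start = 0, end = 33)
  set.seed(83)
  recs <- data.frame(chrom = "chr1",
                     pos = sample(c(3:14, 18:29), 20, replace = TRUE),
                     alt_base = NA, fst_RI = stats::runif(20),
                     fst_RJ = stats::runif(20), fst_IJ = stats::runif(20),
                     stringsAsFactors = FALSE)
  recs$alt_base <- vapply(recs$pos, function(p) {
    r <- as.character(Biostrings::subseq(fx$genome[[1]], p + 1, p + 1))
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, "")
  base <- screen_candidate_genes(regions, recs, fx$models, fx$genome,
                                 thr_high = 0.6, thr_low = 0.3)
  wider <- screen_candidate_genes(regions, recs, fx$models, fx$genome,
                                  thr_high = 0.4, thr_low = 0.5)
  expect_true(all(base$gene_id %in% wider$gene_id))
})

test_that("single-candidate accounting matches a planted fixture", {
  regions <- data.frame(chrom = "chr1", start = (0:4) * 100,
                        end = (1:5) * 100)
  none <- single_candidate_regions(
    data.frame(gene_id = character(), region = integer(),
               n_sites = integer()), regions)
  expect_identical(none$per_region, rep(0L, 5))
  # plant exactly one candidate in regions 1, 3, 4 and two in region 5
  cand <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     region = c(1L, 3L, 4L, 5L, 5L), n_sites = 1L)
  rep_out <- single_candidate_regions(cand, regions)
  expect_identical(rep_out$single_candidate_regions, 3L)
  expect_setequal(rep_out$single_candidate_genes, c("a", "b", "c"))
  expect_identical(rep_out$regions_with_candidates, 4L)
})
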
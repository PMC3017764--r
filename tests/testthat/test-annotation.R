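test_that("interval overlap classifies exon vs intron on half-open coords", {
  genes <- data.frame(gene_name = "KRT5", accession = "NM_1",
                      species = "bovine", chrom = "chr1",
                      start = c(0, 200), end = c(90, 500))
  probe <- data.frame(probe_id = "p", chrom = "chr1", start = 100, end = 160)
  ov <- probe_overlap(probe, genes)
  expect_equal(ov$overlap_kind, "intron")   # inside span, between exons

  probe2 <- data.frame(probe_id = "p", chrom = "chr1", start = 100, end = 210)
  expect_equal(probe_overlap(probe2, genes)$overlap_kind, "exon")

  # exon starting exactly at the probe end does not overlap (half-open)
  genes2 <- data.frame(gene_name = "X", accession = "NM_2",
                       species = "bovine", chrom = "chr1",
                       start = 160, end = 300)
  expect_equal(nrow(probe_overlap(probe, genes2)), 0L)

  # wrong chromosome never overlaps
  probe3 <- data.frame(probe_id = "p", chrom = "chr9", start = 100, end = 160)
  expect_equal(nrow(probe_overlap(probe3, genes)), 0L)
})

test_that("nearest gene minimises interval distance with accession ties", {
  genes <- data.frame(gene_name = c("A", "B"),
                      accession = c("NM_20", "NM_10"),
                      species = "bovine", chrom = "chr1",
                      start = c(0, 200), end = c(90, 400))
  probe <- data.frame(probe_id = "p", chrom = "chr1", start = 100, end = 160)
  ng <- nearest_gene(probe, genes)
  expect_equal(ng$gene_name, "A")       # distance 10 beats 40
  expect_equal(ng$distance, 10L)

  # equidistant: lowest accession number wins
  genes$end[1] <- 60; genes$start[2] <- 200   # distances 40 and 40
  expect_equal(nearest_gene(probe, genes)$gene_name, "B")

  # an overlapping gene always wins at distance zero
  genes2 <- rbind(genes, data.frame(gene_name = "C", accession = "NM_99",
                                    species = "bovine", chrom = "chr1",
                                    start = 150, end = 300))
  expect_equal(nearest_gene(probe, genes2)$gene_name, "C")

  empty <- nearest_gene(data.frame(probe_id = "p", chrom = "chr7",
                                   start = 1, end = 2), genes)
  expect_equal(nrow(empty), 0L)
})

test_that("accession ordering is numeric within a prefix", {
  acc <- c("NM_001008663", "NM_000200", "XM_000510", "NM_000300")
  expect_equal(acc[accession_order(acc)[1]], "NM_000200")
  expect_equal(accession_order(c("ABC", "AAA")), c(2L, 1L))
})

test_that("the assignment cascade follows the four documented steps", {
  fx <- generate_annotation_fixtures(n_probes = 9)
  bov <- fx$genes[fx$genes$species == "bovine", ]
  hum <- fx$genes[fx$genes$species == "human", ]
  one <- function(id) assign_gene(fx$probes[fx$probes$probe_id == id, ],
                                  bov, hum, fx$blast)
  # step 1: informative bovine exon overlap, concordant blast
  r1 <- one("AGI001")
  expect_equal(r1[, c("gene_name", "decision_step")],
               data.frame(gene_name = "KRT5", decision_step = "1"),
               ignore_attr = TRUE)
  expect_false(r1$flagged)
  # step 1 with two candidates: lowest accession; discordant blast flags
  r3 <- one("AGI003")
  expect_equal(r3$gene_name, "DSG1")
  expect_true(r3$flagged)
  # step 2: provisional bovine name, single human overlap
  r9 <- one("AGI009")
  expect_equal(r9[, c("gene_name", "decision_step")],
               data.frame(gene_name = "DSC1", decision_step = "2"),
               ignore_attr = TRUE)
  # step 2 with two human overlaps: lowest accession
  expect_equal(one("AGI004")$gene_name, "IVL")
  # intron-only overlap falls through to the nearest-gene rule
  r2 <- one("AGI002")
  expect_equal(r2$decision_step, "3")
  expect_equal(r2$gene_name, "KRT5")
  expect_equal(r2$overlap_kind, "intron")
  # no overlap at all: nearest gene
  r7 <- one("AGI007")
  expect_equal(r7[, c("gene_name", "decision_step", "overlap_kind")],
               data.frame(gene_name = "CLDN8", decision_step = "3",
                          overlap_kind = "none"), ignore_attr = TRUE)
  # empty chromosome: unassigned
  r8 <- one("AGI008")
  expect_equal(r8$decision_step, "unassigned")
  expect_true(is.na(r8$gene_name))
})

test_that("rule engine matches the brute-force oracle on all fixtures", {
  fx <- generate_annotation_fixtures(n_probes = 40, seed = 17)
  res <- annotate_probes(fx$probes, fx$genes, fx$blast)
  for (i in seq_len(nrow(fx$probes))) {
    orc <- oracle_annotate_one(fx$probes[i, ], fx$genes, fx$blast)
    expect_identical(res$gene_name[i], orc$name)
    expect_identical(res$decision_step[i], orc$step)
    expect_identical(res$flagged[i], orc$flagged)
  }
})

test_that("annotation is order-invariant and counts conserve probes", {
  fx <- generate_annotation_fixtures(n_probes = 20, seed = 2)
  res <- annotate_probes(fx$probes, fx$genes, fx$blast)
  shuf <- function(df) df[sample(nrow(df)), ]
  set.seed(9)
  res2 <- annotate_probes(fx$probes, shuf(fx$genes), shuf(fx$blast))
  expect_equal(res, res2)

  counts <- summarise_annotation(res)
  expect_equal(sum(counts), nrow(fx$probes))
  fx_small <- generate_annotation_fixtures(n_probes = 9)
  cs <- summarise_annotation(annotate_probes(fx_small$probes, fx_small$genes,
                                             fx_small$blast))
  expect_equal(unname(cs["none"]), 1L)        # the empty-chromosome probe
  expect_equal(summarise_annotation(annotate_probes(fx$probes[0, ],
                                                    fx$genes, fx$blast)),
               c(LOC = 0L, MGC = 0L, named = 0L, none = 0L))
})

test_that("annotation tables round-trip through their file formats", {
  fx <- generate_annotation_fixtures(n_probes = 12, seed = 3)
  dir <- file.path(tempdir(), "annot_io")
  paths <- write_annotation_tables(fx, dir)
  probes <- read_probe_bed(paths[["probes"]])
  genes <- read_gene_models(paths[["genes"]])
  blast <- read_blast_hits(paths[["blast"]])
  expect_equal(probes, fx$probes, ignore_attr = TRUE)
  expect_equal(genes, fx$genes, ignore_attr = TRUE)
  expect_equal(blast, fx$blast, ignore_attr = TRUE)
  # identical assignments from files and from memory
  expect_equal(annotate_probes(probes, genes, blast),
               annotate_probes(fx$probes, fx$genes, fx$blast))
  # malformed intervals rejected at load
  bad <- fx
  bad$probes$end[1] <- bad$probes$start[1]
  p2 <- write_annotation_tables(bad, file.path(tempdir(), "annot_bad"))
  expect_error(read_probe_bed(p2[["probes"]]), "malformed")
})
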
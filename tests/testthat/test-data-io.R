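test_that("gene order is sorted by start with dense per-chromosome indices", {
  g <- as_genome_index(data.frame(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    start = c(500L, 100L, 900L), end = c(600L, 200L, 950L)
  ))
  expect_equal(g$order_index[match(c("a", "b", "c"), g$gene_id)], c(1L, 0L, 2L))

  two <- as_genome_index(data.frame(
    gene_id = letters[1:4], chrom = rep(c("chr1", "chr2"), each = 2),
    start = c(10L, 5L, 7L, 2L), end = c(20L, 6L, 9L, 4L)
  ))
  expect_equal(sort(two$order_index[two$chrom == "chr1"]), 0:1)
  expect_equal(sort(two$order_index[two$chrom == "chr2"]), 0:1)
})

test_that("ties on start are broken by (end, gene_id) independent of row order", {
  rows <- data.frame(
    gene_id = c("gx", "ga", "gm"), chrom = "chr1",
    start = c(100L, 100L, 100L), end = c(300L, 200L, 200L)
  )
  ref <- as_genome_index(rows)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(as_genome_index(rows[perm, ]), ref)
  }
  # (end, gene_id) ordering: ga (end 200) < gm (end 200, id later) < gx (end 300)
  expect_equal(ref$gene_id[order(ref$order_index)], c("ga", "gm", "gx"))
})

test_that("gene order round-trips through the TSV dialect", {
  fix <- random_fixture(11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_order(fix$genome, path)
  expect_equal(read_gene_order(path, "tsv"), fix$genome)
})

test_that("annotation dialects agree on the same genes", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "gene_id\tchrom\tstart\tend",
    "gA\tchr1\t100\t200", "gB\tchr1\t400\t600", "gC\tchr2\t0\t50"
  ), tsv)
  writeLines(c(
    "chr1\t100\t200\tgA", "chr1\t400\t600\tgB", "chr2\t0\t50\tgC"
  ), bed)
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=tA;Parent=gA",
    "chr1\tsrc\tgene\t401\t600\t.\t-\t.\tID=gB",
    "chr2\tsrc\tgene\t1\t50\t.\t+\t.\tID=gC"
  ), gff)
  g_tsv <- read_gene_order(tsv, "tsv")
  expect_equal(read_gene_order(bed, "bed"), g_tsv)
  # GFF3 1-based inclusive converts to the same 0-based half-open coords
  expect_equal(read_gene_order(gff, "gff3"), g_tsv)
})

test_that("empty and duplicated annotations are fatal", {
  expect_error(
    as_genome_index(data.frame(gene_id = character(), chrom = character(), start = integer())),
    "no gene records"
  )
  expect_error(
    as_genome_index(data.frame(
      gene_id = c("a", "a"), chrom = "c", start = c(1L, 5L), end = c(2L, 6L)
    )),
    "duplicate gene_id: a"
  )
})

test_that("network filtering applies score, self-edge and dedup rules", {
  genome <- as_genome_index(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "c", start = c(0L, 10L, 20L),
    end = c(5L, 15L, 25L)
  ))
  net <- as_network_edges(data.frame(
    gene_a = c("g1", "g1", "g1", "g2", "g1", "gX"),
    gene_b = c("g2", "g1", "g2", "g1", "g3", "g2"),
    score = c(149L, 900L, 400L, 700L, 151L, 500L)
  ), genome)
  # (g1,g2,149) below threshold; (g1,g1) self; (g1,g2,400)/(g2,g1,700) -> 700;
  # (gX,g2) unknown endpoint dropped
  expect_equal(nrow(net), 2L)
  expect_equal(net$score[net$gene_a == "g1" & net$gene_b == "g2"], 700L)
  expect_equal(attr(net, "n_dropped_score"), 1L)
  expect_equal(attr(net, "n_dropped_self"), 1L)
  expect_equal(attr(net, "n_dropped_unknown"), 1L)

  # dedup-keep-max agrees with a naive pairwise scan on a random fixture
  fix <- random_fixture(5)
  raw <- data.frame(
    gene_a = c(fix$network$gene_a, fix$network$gene_b),
    gene_b = c(fix$network$gene_b, fix$network$gene_a),
    score = rep(fix$network$score, 2)
  )
  redone <- as_network_edges(raw, fix$genome)
  for (i in seq_len(nrow(redone))) {
    naive <- max(raw$score[(raw$gene_a == redone$gene_a[i] & raw$gene_b == redone$gene_b[i]) |
      (raw$gene_a == redone$gene_b[i] & raw$gene_b == redone$gene_a[i])])
    expect_identical(redone$score[i], as.integer(naive))
  }
})

test_that("network loading is idempotent and the partner map symmetric", {
  fix <- random_fixture(7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(fix$network, path)
  again <- read_network(path, fix$genome)
  expect_equal(
    as.data.frame(again)[c("gene_a", "gene_b", "score")],
    as.data.frame(fix$network)[c("gene_a", "gene_b", "score")]
  )
  # symmetry: a in partners[b] <=> b in partners[a], checked exhaustively
  for (i in seq_len(nrow(fix$network))) {
    a <- fix$network$gene_a[i]
    b <- fix$network$gene_b[i]
    expect_true(b %in% or_partners(fix$network, a))
    expect_true(a %in% or_partners(fix$network, b))
  }
})

test_that("non-integer scores are fatal with a line number", {
  genome <- as_genome_index(data.frame(gene_id = c("a", "b"), chrom = "c", start = 0:1, end = 2:3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t500", "a\tb\tx"), path)
  expect_error(read_network(path, genome), "non-integer score at line 2")
})

test_that("alias harmonization rewrites, drops and counts rows", {
  aliases <- data.frame(
    alias = c("9606.ENSP0001", "9606.ENSP0002"),
    gene_id = c("GENE_A", "GENE_B")
  )
  rows <- data.frame(
    gene_a = c("9606.ENSP0001", "9606.ENSP0001", "UNKNOWN"),
    gene_b = c("9606.ENSP0002", "GENE_B", "GENE_A"),
    score = c(500L, 400L, 300L)
  )
  out <- harmonize_ids(rows, aliases, known = c("GENE_A", "GENE_B"))
  expect_equal(out$gene_a, c("GENE_A", "GENE_A"))
  expect_equal(out$gene_b, c("GENE_B", "GENE_B"))
  expect_equal(attr(out, "n_dropped"), 1L)

  # identity table leaves rows unchanged
  ident <- harmonize_ids(rows, data.frame(alias = "GENE_A", gene_id = "GENE_A"))
  expect_equal(ident$gene_a, rows$gene_a)

  expect_error(
    harmonize_ids(rows, data.frame(alias = c("x", "x"), gene_id = c("A", "B"))),
    "ambiguous alias"
  )
})

test_that("ortholog groups are total with auto-singletons and reject conflicts", {
  genome <- as_genome_index(data.frame(
    gene_id = paste0("g", 1:5), chrom = "c",
    start = seq(0L, 40L, 10L), end = seq(5L, 45L, 10L)
  ))
  grp <- as_ortholog_groups(
    data.frame(gene_id = c("g1", "g2", "g3"), group_id = c("K1", "K1", "K2")),
    genome
  )
  expect_equal(nrow(grp), 5L)
  expect_equal(sum(startsWith(grp$group_id, "singleton:")), 2L)
  expect_equal(length(unique(grp$group_id)), 4L)
  expect_error(
    as_ortholog_groups(
      data.frame(gene_id = c("g1", "g1"), group_id = c("K1", "K2")), genome
    ),
    "multiple groups"
  )
})

test_that("homolog map enforces one-to-one and network presence with reasons", {
  ga <- as_genome_index(data.frame(
    gene_id = paste0("a", 1:4), chrom = "c", start = seq(0L, 30L, 10L),
    end = seq(5L, 35L, 10L)
  ))
  gb <- as_genome_index(data.frame(
    gene_id = paste0("b", 1:4), chrom = "c", start = seq(0L, 30L, 10L),
    end = seq(5L, 35L, 10L)
  ))
  na <- as_network_edges(data.frame(gene_a = "a1", gene_b = "a2", score = 500L), ga)
  nb <- as_network_edges(data.frame(gene_a = "b1", gene_b = "b2", score = 500L), gb)
  hm <- read_homologs(
    data.frame(
      gene_a = c("a1", "a2", "a2", "a3", "a9"),
      gene_b = c("b1", "b2", "b3", "b4", "b9")
    ),
    ga, gb, na, nb
  )
  expect_equal(hm$gene_a, "a1")
  expect_equal(hm$gene_b, "b1")
  exc <- attr(hm, "excluded")
  expect_setequal(exc$reason[exc$gene_a == "a2"], "not one-to-one")
  expect_equal(exc$reason[exc$gene_a == "a9"], "missing annotation")
  # a3-b4: annotated both sides but b4 has no edges
  expect_equal(exc$reason[exc$gene_a == "a3"], "missing network data")
})
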
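chrom_genome <- function(n, prefix = "g") {
  as_genome_index(data.frame(
    gene_id = sprintf("%s%03d", prefix, 1:n), chrom = "chr1",
    start = as.integer((0:(n - 1)) * 1000), end = as.integer((0:(n - 1)) * 1000 + 500)
  ))
}

edge_df <- function(pairs, score = 500L) {
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], score = score)
}

test_that("worked single-chromosome example matches the analytic fold-change", {
  genome <- chrom_genome(100)
  focal <- genome$gene_id[genome$order_index == 50]
  # 4 partners: 2 inside +/-10 (offsets +3, -7), 2 far away
  partners <- genome$gene_id[genome$order_index %in% c(53, 43, 5, 90)]
  net <- as_network_edges(edge_df(cbind(focal, partners)), genome)
  res <- gene_stats(focal, genome, net, window = 10)
  expect_equal(res$T, 4L)
  expect_equal(res$L, 2L)
  expect_equal(res$n_window, 20L)
  expect_equal(res$genome_likelihood, 4 / 99)
  expect_equal(res$local_likelihood, 2 / 20)
  expect_equal(res$FC, (2 / 20) / (4 / 99)) # = 2.475
  expect_equal(res$bin, "2≤FC<5")
})

test_that("genes without partners or window genes are excluded, never NaN", {
  genome <- chrom_genome(30)
  net <- as_network_edges(
    edge_df(cbind(genome$gene_id[1], genome$gene_id[2])), genome
  )
  res <- coloc_stats(genome, net, window = 5)
  lonely <- res[res$T == 0, ]
  expect_true(all(lonely$excluded_reason == "no partners"))
  expect_true(all(is.na(lonely$FC)))
  expect_false(any(is.nan(res$FC)))

  # a gene alone on its chromosome has no window genes
  g2 <- as_genome_index(rbind(
    as.data.frame(genome)[, 1:4],
    data.frame(gene_id = "solo", chrom = "chrX", start = 0L, end = 10L)
  ))
  net2 <- as_network_edges(edge_df(cbind("solo", genome$gene_id[1])), g2)
  solo <- gene_stats("solo", g2, net2, window = 5)
  expect_equal(solo$excluded_reason, "no window genes")
  expect_true(is.na(solo$FC))
})

test_that("FC = 1 when the window spans the whole chromosome", {
  W <- 5
  genome <- chrom_genome(2 * W + 1)
  focal <- genome$gene_id[genome$order_index == W]
  others <- setdiff(genome$gene_id, focal)
  net <- as_network_edges(edge_df(cbind(focal, sample(others, 4))), genome)
  res <- gene_stats(focal, genome, net, window = W)
  expect_equal(res$n_window, nrow(genome) - 1L)
  expect_equal(res$L, res$T)
  expect_equal(res$FC, 1)
})

test_that("same-ortholog-group window genes are removed from L and n_window", {
  genome <- chrom_genome(50)
  focal <- genome$gene_id[genome$order_index == 25]
  dup <- genome$gene_id[genome$order_index == 26] # offset +1, same KO group
  far <- genome$gene_id[genome$order_index == 30]
  net <- as_network_edges(edge_df(cbind(focal, c(dup, far))), genome)
  groups <- as_ortholog_groups(
    data.frame(gene_id = c(focal, dup), group_id = "KO7"), genome
  )
  with_grp <- gene_stats(focal, genome, net, groups = groups, window = 10)
  no_grp <- gene_stats(focal, genome, net, window = 10)
  expect_equal(no_grp$L, 2L)
  expect_equal(no_grp$n_window, 20L)
  expect_equal(with_grp$L, 1L)
  expect_equal(with_grp$n_window, 19L)
  # genome-wide T is untouched by the exclusion
  expect_equal(with_grp$T, 2L)
})

test_that("FC classes use left-closed bins with FC >= 2 called non-random", {
  expect_equal(fc_bin(2.0), "2≤FC<5")
  expect_equal(fc_bin(1.99), "FC<2")
  expect_equal(fc_bin(50.0), "50≤FC")
  expect_equal(fc_bin(c(0.5, 5, 19.99, 20, 49.9)),
    c("FC<2", "5≤FC<20", "5≤FC<20", "20≤FC<50", "20≤FC<50"))

  fix <- random_fixture(3)
  res <- coloc_stats(fix$genome, fix$network, window = 5)
  tab <- classify_fc(res)
  frac <- tab$fraction[tab$bin != "excluded"]
  expect_equal(sum(frac), 1)
  expect_equal(sum(tab$n[tab$bin != "excluded"]) + tab$n[tab$bin == "excluded"], nrow(res))
})

test_that("gene_stats and distance_decay match the brute-force oracle", {
  for (seed in 1:3) {
    fix <- random_fixture(seed, with_groups = seed == 3)
    res <- coloc_stats(fix$genome, fix$network, groups = fix$groups, window = 6)
    orc <- oracle_gene_stats(fix$genome, fix$network, fix$groups, W = 6)
    m <- match(orc$gene_id, res$gene_id)
    expect_identical(res$T[m], orc$T)
    expect_identical(res$L[m], orc$L)
    expect_identical(res$n_window[m], orc$n_window)
    expect_equal(res$FC[m], orc$FC)

    dec <- distance_decay(fix$genome, fix$network, window = 6)
    odec <- oracle_decay(fix$genome, fix$network, W = 6)
    expect_identical(dec$eligible, odec$eligible)
    expect_identical(dec$hits, odec$hits)
    expect_equal(dec$likelihood, odec$likelihood)
  }
})

test_that("windows truncate at chromosome ends with no wraparound", {
  genome <- as_genome_index(data.frame(
    gene_id = sprintf("t%02d", 1:30), chrom = rep(c("c1", "c2"), each = 15),
    start = as.integer(rep((0:14) * 100, 2)), end = as.integer(rep((0:14) * 100 + 50, 2))
  ))
  fix_net <- as_network_edges(
    edge_df(cbind(genome$gene_id[1:29], genome$gene_id[2:30])), genome
  )
  W <- 10
  res <- coloc_stats(genome, fix_net, window = W)
  for (i in seq_len(nrow(res))) {
    idx <- res$order_index[i]
    n_chr <- 15
    expect_equal(res$n_window[i], min(idx, W) + min(n_chr - 1 - idx, W))
  }
  expect_true(all(res$n_window < 2 * W))
})

test_that("FC is invariant under chromosome relabeling and order reversal", {
  fix <- random_fixture(9)
  base <- coloc_stats(fix$genome, fix$network, window = 5)

  relab <- fix$genome
  relab$chrom <- paste0("Z_", relab$chrom)
  relab <- as_genome_index(as.data.frame(relab)[, 1:4])
  res_relab <- coloc_stats(relab, as_network_edges(as.data.frame(fix$network), relab), window = 5)
  m <- match(base$gene_id, res_relab$gene_id)
  expect_equal(res_relab$FC[m], base$FC)

  # reverse gene order on every chromosome by mirroring start coordinates
  rev_df <- as.data.frame(fix$genome)
  rev_df$width <- rev_df$end - rev_df$start
  mx <- max(rev_df$end)
  rev_df$start <- as.integer(mx - rev_df$end)
  rev_df$end <- as.integer(rev_df$start + rev_df$width)
  revg <- as_genome_index(rev_df[, c("gene_id", "chrom", "start", "end")])
  res_rev <- coloc_stats(revg, as_network_edges(as.data.frame(fix$network), revg), window = 5)
  m <- match(base$gene_id, res_rev$gene_id)
  expect_equal(res_rev$FC[m], base$FC)
})

test_that("invariant 0 <= L <= min(T, n_window) holds on random fixtures", {
  for (seed in 4:6) {
    fix <- random_fixture(seed)
    res <- coloc_stats(fix$genome, fix$network, window = 8)
    expect_true(all(res$L >= 0))
    expect_true(all(res$L <= pmin(res$T, res$n_window)))
    ok <- res[is.na(res$excluded_reason), ]
    expect_true(all(ok$genome_likelihood >= 0 & ok$genome_likelihood <= 1))
    expect_true(all(ok$local_likelihood >= 0 & ok$local_likelihood <= 1))
  }
})

test_that("distance decay reproduces forced nearest-neighbor structure", {
  genome <- chrom_genome(20)
  # every gene's only partners are its immediate neighbors
  adj <- cbind(genome$gene_id[-nrow(genome)], genome$gene_id[-1])
  net <- as_network_edges(edge_df(adj), genome)
  dec <- distance_decay(genome, net, window = 4)
  expect_equal(dec$likelihood[1], 1)
  expect_equal(dec$likelihood[2:4], rep(0, 3))

  # 5-gene chromosome with edges {g0-g1, g0-g3}: oracle agreement
  g5 <- chrom_genome(5, prefix = "q")
  n5 <- as_network_edges(
    edge_df(rbind(c("q001", "q002"), c("q001", "q004"))), g5
  )
  dec5 <- distance_decay(g5, n5, window = 2)
  o5 <- oracle_decay(g5, n5, W = 2)
  expect_equal(dec5$likelihood, o5$likelihood)
  expect_equal(dec5$eligible, o5$eligible)
  empty_net <- suppressWarnings(
    as_network_edges(edge_df(cbind("q001", "q002"))[0, ], g5)
  )
  expect_error(distance_decay(g5, empty_net), "no partnered genes")
})
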
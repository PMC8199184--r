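# deterministic sub-seeds so adding a generator never perturbs existing
# streams; kept below 2^31
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic genome index
#'
#' Lays out `genes_per_chrom` non-overlapping genes per chromosome with
#' exponentially distributed gene spans and inter-gene gaps. Pure function
#' of its parameters and `seed`.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param genes_per_chrom Genes per chromosome (>= 2).
#' @param mean_gene_span_bp Mean gene length in bp (default 2000).
#' @param seed Integer seed.
#' @return A `genome_index` with gene ids `g<chrom>_<rank>`.
#' @export
generate_genome <- function(n_chrom, genes_per_chrom, mean_gene_span_bp = 2000,
                            seed = 1) {
  if (n_chrom < 1 || genes_per_chrom < 2 || mean_gene_span_bp <= 0) {
    abort("generate_genome parameters must be positive (>= 2 genes per chromosome)")
  }
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n_chrom), function(ch) {
    spans <- pmax(100L, as.integer(round(rexp(genes_per_chrom, 1 / mean_gene_span_bp))))
    gaps <- pmax(1L, as.integer(round(rexp(genes_per_chrom, 1 / (2 * mean_gene_span_bp)))))
    start <- cumsum(as.numeric(gaps)) + c(0, cumsum(as.numeric(spans)))[seq_len(genes_per_chrom)]
    tibble(
      gene_id = sprintf("g%d_%03d", ch, seq_len(genes_per_chrom)),
      chrom = paste0("chr", ch),
      start = as.integer(start),
      end = as.integer(start) + spans
    )
  })
  as_genome_index(rows)
}

# decode 1-based unordered-pair indices k (pairs (i,j), 0 <= i < j < n,
# ordered by i then j) into endpoint indices; exact integer correction after
# the floating-point root
decode_pairs <- function(k, n) {
  k0 <- k - 1
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * k0)) / 2)
  S <- function(i) i * (2 * n - i - 1) / 2
  i <- pmax(0, pmin(i, n - 2))
  for (step in 1:3) {
    i <- i - (S(i) > k0) + (S(i + 1) <= k0)
    i <- pmax(0, pmin(i, n - 2))
  }
  j <- i + 1 + (k0 - S(i))
  cbind(i + 1, j + 1) # 1-based gene indices
}

#' Generate a synthetic interaction network
#'
#' Draws background edges independently at probability `p_bg` over all gene
#' pairs, then superimposes either planted clusters — runs of
#' `cluster_span` consecutive genes whose internal pairs gain an extra edge
#' at probability `min(1, f * p_bg)` — or a distance-decay kernel in which a
#' same-chromosome pair at gene-order distance `d` gains an edge at
#' probability `a * exp(-d / lambda)`. Edge scores are drawn uniformly on
#' `[min_score, 1000]` (the analysis only thresholds scores).
#'
#' @param genome A `genome_index`.
#' @param p_bg Background edge probability per gene pair.
#' @param clusters Optional list `list(n_clusters, span, f)` planting
#'   clusters of consecutive genes (span default 5) with enrichment factor
#'   `f`; an explicit `p_within` overrides the within-cluster edge
#'   probability `min(1, f * p_bg)` (needed e.g. when `p_bg = 0`).
#' @param decay Optional list `list(a, lambda)` for the geometric
#'   rank-decay kernel. At most one of `clusters` / `decay`.
#' @param min_score Score floor for generated edges (default 150).
#' @param seed Integer seed.
#' @return A list with elements `network` (a `network_edges`) and `truth`
#'   (a `sim_truth` list: `planted_cluster_members`, `enrichment_factor`,
#'   `p_bg`, `lambda`, `seed`, ...).
#' @export
generate_network <- function(genome, p_bg, clusters = NULL, decay = NULL,
                             min_score = 150, seed = 1) {
  stopifnot(p_bg >= 0, p_bg <= 1, is.null(clusters) || is.null(decay))
  seeds <- substream_seeds(seed, 3)
  n <- nrow(genome)
  ids <- genome$gene_id

  set.seed(seeds[1])
  M <- n * (n - 1) / 2
  m <- rbinom(1, M, p_bg)
  bg <- if (m > 0) {
    pk <- decode_pairs(sort(sample(M, m)), n)
    tibble(gene_a = ids[pk[, 1]], gene_b = ids[pk[, 2]])
  } else {
    tibble(gene_a = character(), gene_b = character())
  }

  planted <- character()
  f <- NA_real_
  lambda <- NA_real_
  extra <- tibble(gene_a = character(), gene_b = character())

  if (!is.null(clusters)) {
    set.seed(seeds[2])
    span <- clusters$span %||% 5
    f <- clusters$f %||% NA_real_
    p_in <- clusters$p_within %||% (f * p_bg)
    if (p_in > 1) {
      warn("cluster edge probability f * p_bg > 1; clamped to 1")
      p_in <- 1
    }
    per_chrom <- split(genome$gene_id, genome$chrom)
    sizes <- vapply(per_chrom, length, 1L)
    if (span > max(sizes)) abort("cluster span exceeds chromosome length")
    chroms <- names(per_chrom)[sizes >= span]
    extra_list <- vector("list", clusters$n_clusters)
    for (cl in seq_len(clusters$n_clusters)) {
      ch <- sample(chroms, 1)
      s <- sample(length(per_chrom[[ch]]) - span + 1, 1)
      members <- per_chrom[[ch]][s:(s + span - 1)]
      planted <- union(planted, members)
      pr <- t(utils::combn(members, 2))
      hit <- runif(nrow(pr)) < p_in
      extra_list[[cl]] <- tibble(gene_a = pr[hit, 1], gene_b = pr[hit, 2])
    }
    extra <- bind_rows(extra_list)
  } else if (!is.null(decay)) {
    set.seed(seeds[2])
    lambda <- decay$lambda
    a <- decay$a
    per_chrom <- split(seq_len(n), genome$chrom)
    extra_list <- list()
    for (ch in names(per_chrom)) {
      rows <- per_chrom[[ch]]
      len <- length(rows)
      ord <- rows[order(genome$order_index[rows])]
      for (d in seq_len(len - 1)) {
        p_d <- a * exp(-d / lambda)
        if (p_d < 1e-8) break
        i1 <- ord[seq_len(len - d)]
        i2 <- ord[seq_len(len - d) + d]
        hit <- runif(len - d) < p_d
        if (any(hit)) {
          extra_list[[length(extra_list) + 1]] <-
            tibble(gene_a = ids[i1[hit]], gene_b = ids[i2[hit]])
        }
      }
    }
    extra <- bind_rows(extra_list)
  }

  set.seed(seeds[3])
  edges <- bind_rows(bg, extra) |>
    mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b)
    ) |>
    distinct(.data$lo, .data$hi) |>
    rename(gene_a = "lo", gene_b = "hi")
  edges$score <- as.integer(round(runif(nrow(edges), min_score, 1000)))
  truth <- structure(
    list(
      planted_cluster_members = planted, enrichment_factor = f,
      p_bg = p_bg, lambda = lambda, seed = seed
    ),
    class = "sim_truth"
  )
  list(network = as_network_edges(edges, genome, min_score = min_score), truth = truth)
}

#' Derive a rearranged second species
#'
#' Species B starts as a renamed exact copy of species A (identity homolog
#' map). Each gene is then relocated to a uniformly random genomic position
#' with probability `shuffle_rate`; `n_inversions` random non-overlapping
#' segments of `inversion_span` genes are reversed in place; and each A edge
#' is retained in B with probability `edge_retention`. This emulates the
#' divergence of gene order and interaction data between two related
#' genomes while keeping the ground truth known.
#'
#' @param genome A species-A `genome_index`.
#' @param network A species-A `network_edges`.
#' @param shuffle_rate Per-gene relocation probability in \[0,1\].
#' @param n_inversions Number of inverted segments (default 0).
#' @param inversion_span Genes per inverted segment (default 5).
#' @param edge_retention Probability an A edge survives in B (default 1).
#' @param seed Integer seed.
#' @return A list: `genome_b`, `homologs` (a `homolog_map`), `network_b`,
#'   `truth` (`sim_truth` with the rearrangement parameters).
#' @export
generate_species_pair <- function(genome, network, shuffle_rate = 0,
                                  n_inversions = 0, inversion_span = 5,
                                  edge_retention = 1, seed = 1) {
  stopifnot(
    shuffle_rate >= 0, shuffle_rate <= 1,
    edge_retention >= 0, edge_retention <= 1
  )
  seeds <- substream_seeds(seed, 3)
  rename_b <- setNames(paste0(genome$gene_id, "_B"), genome$gene_id)

  # per-chromosome gene orders of species B, as A ids
  orders <- genome |>
    arrange(.data$chrom, .data$order_index) |>
    (\(d) split(d$gene_id, d$chrom))()

  set.seed(seeds[1])
  if (shuffle_rate > 0) {
    move <- runif(nrow(genome)) < shuffle_rate
    moved <- genome$gene_id[move]
    orders <- lapply(orders, function(v) setdiff(v, moved))
    for (g in moved) {
      ch <- sample(names(orders), 1)
      pos <- sample(length(orders[[ch]]) + 1, 1)
      orders[[ch]] <- append(orders[[ch]], g, after = pos - 1)
    }
  }

  set.seed(seeds[2])
  if (n_inversions > 0) {
    if (inversion_span > max(lengths(orders))) {
      abort("inversion_span exceeds chromosome length")
    }
    used <- lapply(orders, function(v) integer())
    placed <- 0
    tries <- 0
    while (placed < n_inversions && tries < 1000 * n_inversions) {
      tries <- tries + 1
      eligible <- names(orders)[lengths(orders) >= inversion_span]
      ch <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      s <- sample(length(orders[[ch]]) - inversion_span + 1, 1)
      seg <- s:(s + inversion_span - 1)
      if (length(intersect(seg, used[[ch]])) > 0) next
      orders[[ch]][seg] <- rev(orders[[ch]][seg])
      used[[ch]] <- c(used[[ch]], seg)
      placed <- placed + 1
    }
    if (placed < n_inversions) abort("could not place non-overlapping inversions")
  }

  genome_b <- as_genome_index(purrr::map_dfr(names(orders), function(ch) {
    v <- orders[[ch]]
    tibble(
      gene_id = unname(rename_b[v]), chrom = ch,
      start = (seq_along(v) - 1L) * 1000L,
      end = (seq_along(v) - 1L) * 1000L + 500L
    )
  }))

  set.seed(seeds[3])
  keep <- runif(nrow(network)) < edge_retention | edge_retention == 1
  edges_b <- tibble(
    gene_a = unname(rename_b[network$gene_a[keep]]),
    gene_b = unname(rename_b[network$gene_b[keep]]),
    score = network$score[keep]
  )
  network_b <- as_network_edges(edges_b, genome_b)

  homologs <- tibble(gene_a = genome$gene_id, gene_b = unname(rename_b[genome$gene_id]))
  attr(homologs, "excluded") <- tibble(
    gene_a = character(), gene_b = character(), reason = character()
  )
  class(homologs) <- c("homolog_map", class(homologs))

  truth <- structure(
    list(
      shuffle_rate = shuffle_rate, n_inversions = n_inversions,
      inversion_span = inversion_span, edge_retention = edge_retention,
      seed = seed
    ),
    class = "sim_truth"
  )
  list(genome_b = genome_b, homologs = homologs, network_b = network_b, truth = truth)
}

#' Generate a phased haplotype panel under a founder-copying model
#'
#' Each haplotype copies one of `n_founders` founder haplotypes, switching
#' to a different founder between adjacent sites with probability `c` (the
#' recombination parameter). With the default two complementary founders,
#' `c` tunes two-locus LD continuously: `c -> 0` gives complete linkage
#' (D' = 1), `c = 0.5` makes adjacent sites independent.
#'
#' @param n_haplotypes Number of haplotypes.
#' @param n_snps Number of variant sites.
#' @param n_founders Number of founders (default 2: all-0 and all-1, which
#'   keeps every site polymorphic in expectation; further founders are
#'   random). All-identical founders are rejected.
#' @param c Per-interval founder-switch probability in \[0, 1\].
#' @param seed Integer seed.
#' @param chrom Chromosome label (default `"1"`).
#' @param spacing_bp Distance between adjacent sites (default 1000).
#' @return A `haplotype_panel`.
#' @export
generate_haplotype_panel <- function(n_haplotypes, n_snps, n_founders = 2,
                                     c = 0.01, seed = 1, chrom = "1",
                                     spacing_bp = 1000) {
  stopifnot(n_haplotypes >= 2, n_snps >= 1, c >= 0, c <= 1, n_founders >= 2)
  set.seed(seed)
  founders <- rbind(
    matrix(0L, 1, n_snps),
    matrix(1L, 1, n_snps)
  )
  if (n_founders > 2) {
    founders <- rbind(
      founders,
      matrix(as.integer(runif((n_founders - 2) * n_snps) < 0.5), n_founders - 2, n_snps)
    )
  }
  if (nrow(unique(founders)) == 1) abort("all-identical founders give a monomorphic panel")
  H <- matrix(0L, n_haplotypes, n_snps)
  for (h in seq_len(n_haplotypes)) {
    fidx <- integer(n_snps)
    fidx[1] <- sample(n_founders, 1)
    if (n_snps > 1) {
      switches <- runif(n_snps - 1) < c
      for (s in 2:n_snps) {
        fidx[s] <- if (switches[s - 1]) {
          # switch to a *different* founder, so with two founders c = 0.5
          # makes adjacent sites independent and c -> 0 gives complete LD
          others <- setdiff(seq_len(n_founders), fidx[s - 1])
          others[sample.int(length(others), 1)]
        } else {
          fidx[s - 1]
        }
      }
    }
    H[h, ] <- founders[cbind(fidx, seq_len(n_snps))]
  }
  haplotype_panel(
    H,
    tibble(
      variant_id = sprintf("snp%04d", seq_len(n_snps)),
      chrom = chrom, pos = seq_len(n_snps) * spacing_bp
    )
  )
}

#' Build an exact two-site haplotype panel from class counts
#'
#' Constructs the panel containing `n_AB` haplotypes of class A-B, `n_Ab`
#' of A-b, `n_aB` of a-B and `n_ab` of a-b (allele A/B coded 1, a/b coded
#' 0), for analytic LD checks: complete linkage (only AB and ab present)
#' gives D' = 1; equal counts of all four classes give D' = 0.
#'
#' @param n_AB,n_Ab,n_aB,n_ab Non-negative haplotype class counts; at least
#'   two classes must be non-zero.
#' @return A `haplotype_panel` with two variants.
#' @examples
#' pairwise_ld(two_site_panel(30, 0, 0, 20), 1, 2)$D_prime # 1
#' pairwise_ld(two_site_panel(25, 25, 25, 25), 1, 2)$D_prime # 0
#' @export
two_site_panel <- function(n_AB, n_Ab, n_aB, n_ab) {
  counts <- c(n_AB, n_Ab, n_aB, n_ab)
  stopifnot(all(counts >= 0))
  if (sum(counts > 0) < 2) abort("at least two haplotype classes must be non-zero")
  classes <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  H <- classes[rep(1:4, counts), , drop = FALSE]
  haplotype_panel(
    H,
    tibble(variant_id = c("site_A", "site_B"), chrom = "1", pos = c(1000L, 2000L))
  )
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A `sim_truth` list.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, null = "null")
  invisible(file)
}
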
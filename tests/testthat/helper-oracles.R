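# Quadratic brute-force reimplementations used as independent oracles.
# They enumerate every gene pair and order distance with plain loops and
# share no code with the package internals.

or_is_edge <- function(edges, a, b) {
  any((edges$gene_a == a & edges$gene_b == b) |
    (edges$gene_a == b & edges$gene_b == a))
}

or_partners <- function(edges, g) {
  unique(c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g]))
}

# per-gene T, L, n_window, FC by scanning all genes
oracle_gene_stats <- function(genome, edges, groups = NULL, W = 10) {
  N <- nrow(genome)
  grp <- function(g) {
    if (is.null(groups)) {
      paste0("s:", g)
    } else {
      groups$group_id[match(g, groups$gene_id)]
    }
  }
  out <- lapply(genome$gene_id, function(g) {
    row <- genome[genome$gene_id == g, ]
    partners <- or_partners(edges, g)
    T_ <- length(partners)
    win <- character()
    for (i in seq_len(N)) {
      other <- genome[i, ]
      if (other$gene_id == g) next
      if (other$chrom != row$chrom) next
      d <- abs(other$order_index - row$order_index)
      if (d >= 1 && d <= W && grp(other$gene_id) != grp(g)) {
        win <- c(win, other$gene_id)
      }
    }
    L <- sum(win %in% partners)
    n_window <- length(win)
    FC <- if (T_ > 0 && n_window > 0) {
      (L / n_window) / (T_ / (N - 1))
    } else {
      NA_real_
    }
    data.frame(
      gene_id = g, T = T_, L = L, n_window = n_window, FC = FC,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# likelihood at each rank k by scanning every gene/rank pair
oracle_decay <- function(genome, edges, W = 10) {
  out <- data.frame(k = seq_len(W), eligible = 0L, hits = 0L)
  for (g in genome$gene_id) {
    if (length(or_partners(edges, g)) == 0) next
    row <- genome[genome$gene_id == g, ]
    for (k in seq_len(W)) {
      nb <- genome$gene_id[genome$chrom == row$chrom &
        abs(genome$order_index - row$order_index) == k]
      if (length(nb) == 0) next
      out$eligible[k] <- out$eligible[k] + 1L
      if (any(vapply(nb, function(p) or_is_edge(edges, g, p), TRUE))) {
        out$hits[k] <- out$hits[k] + 1L
      }
    }
  }
  out$likelihood <- ifelse(out$eligible > 0, out$hits / out$eligible, NA_real_)
  out
}

# occupant of a window slot, NA beyond the chromosome end
or_occupant <- function(genome, g, o) {
  row <- genome[genome$gene_id == g, ]
  hit <- genome$gene_id[genome$chrom == row$chrom &
    genome$order_index == row$order_index + o]
  if (length(hit) == 1) hit else NA_character_
}

# per-homolog-pair events and overlaps by scanning all offset pairs
oracle_overlaps <- function(genome_a, genome_b, edges_a, edges_b, hom,
                            groups_a = NULL, W = 10) {
  grp <- function(groups, g) {
    if (is.null(groups)) paste0("s:", g) else groups$group_id[match(g, groups$gene_id)]
  }
  b_of <- function(a) hom$gene_b[match(a, hom$gene_a)]
  offsets <- setdiff(-W:W, 0)
  out <- lapply(seq_len(nrow(hom)), function(i) {
    gA <- hom$gene_a[i]
    gB <- hom$gene_b[i]
    events <- 0L
    overlaps <- 0L
    for (o in offsets) {
      p <- or_occupant(genome_a, gA, o)
      if (is.na(p)) next
      if (grp(groups_a, p) == grp(groups_a, gA)) next
      if (!or_is_edge(edges_a, gA, p)) next
      events <- events + 1L
      ph <- b_of(p)
      if (is.na(ph)) next
      hit <- FALSE
      for (ob in c(o, -o)) {
        q <- or_occupant(genome_b, gB, ob)
        if (!is.na(q) && q == ph && or_is_edge(edges_b, gB, q)) hit <- TRUE
      }
      if (hit) overlaps <- overlaps + 1L
    }
    data.frame(gene_a = gA, gene_b = gB, events = events, overlaps = overlaps)
  })
  do.call(rbind, out)
}

# small random fixture: genome + uniform random network (+ optional groups)
random_fixture <- function(seed, n_chrom = 2, genes_per_chrom = 40,
                           n_edges = 120, with_groups = FALSE) {
  set.seed(seed)
  genome <- as_genome_index(data.frame(
    gene_id = sprintf("f%02d_%03d", seed, 1:(n_chrom * genes_per_chrom)),
    chrom = rep(paste0("c", 1:n_chrom), each = genes_per_chrom),
    start = as.integer(rep(seq(0, by = 1000, length.out = genes_per_chrom), n_chrom)),
    end = as.integer(rep(seq(500, by = 1000, length.out = genes_per_chrom), n_chrom))
  ))
  n <- nrow(genome)
  a <- sample(genome$gene_id, n_edges, replace = TRUE)
  b <- sample(genome$gene_id, n_edges, replace = TRUE)
  keep <- a != b
  edges <- data.frame(
    gene_a = a[keep], gene_b = b[keep],
    score = sample(150:1000, sum(keep), replace = TRUE)
  )
  network <- as_network_edges(edges, genome)
  groups <- NULL
  if (with_groups) {
    # a few multi-gene groups over consecutive genes, rest singletons
    gdf <- data.frame(
      gene_id = genome$gene_id[1:10],
      group_id = rep(c("KO1", "KO2"), each = 5)
    )
    groups <- as_ortholog_groups(gdf, genome)
  }
  list(genome = genome, network = network, groups = groups)
}
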
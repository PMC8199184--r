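#' Default fold-change bin labels
#'
#' Bins FC values into the standard classes: `FC<2` (random placement) and
#' the non-random classes `2<=FC<5`, `5<=FC<20`, `20<=FC<50`, `50<=FC`.
#'
#' @param fc Numeric vector of fold-changes (NA allowed).
#' @param breaks Ascending bin lower bounds above the random class
#'   (default `c(2, 5, 20, 50)`).
#' @return A character vector of bin labels (NA where `fc` is NA).
#' @export
fc_bin <- function(fc, breaks = c(2, 5, 20, 50)) {
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  labs <- c(
    paste0("FC<", breaks[1]),
    if (length(breaks) > 1) {
      paste0(breaks[-length(breaks)], "\u2264FC<", breaks[-1])
    },
    paste0(breaks[length(breaks)], "\u2264FC")
  )
  idx <- findInterval(fc, breaks) + 1L
  out <- labs[idx]
  out[is.na(fc)] <- NA_character_
  out
}

# Long table of window slots: one row per (focal gene, offset) with the
# occupant gene. Offsets run -W..-1, +1..+W; slots beyond chromosome ends
# are absent (truncation, no wraparound).
window_table <- function(genome, window) {
  stopifnot(window >= 1)
  offsets <- setdiff(seq(-window, window), 0L)
  occupants <- genome |>
    select(occupant = "gene_id", "chrom", occ_index = "order_index")
  tidyr::expand_grid(
    genome |> select(gene_id = "gene_id", "chrom", "order_index"),
    offset = as.integer(offsets)
  ) |>
    mutate(occ_index = .data$order_index + .data$offset) |>
    inner_join(occupants, by = c("chrom", "occ_index")) |>
    select("gene_id", "offset", "occupant")
}

# window_table with same-ortholog-group occupants removed (the exclusion of
# homolog/duplicated genes within the window)
window_table_excluded <- function(genome, groups, window) {
  wt <- window_table(genome, window)
  if (is.null(groups)) {
    return(wt)
  }
  glk <- group_lookup(groups)
  wt[glk[wt$gene_id] != glk[wt$occupant], , drop = FALSE]
}

#' Per-gene co-localization statistics
#'
#' For every gene, compares the likelihood of finding its network partners
#' within the +/-`window` gene-order neighborhood against the genome-wide
#' likelihood. With `N` annotated genes, a focal gene with `T` partners
#' genome-wide and `L` partners among its `n_window` eligible window genes
#' has
#' \deqn{FC = \frac{L / n_{window}}{T / (N - 1)}}
#' FC near 1 indicates random placement of the partners along the genome;
#' FC >= 2 is conventionally called non-random (positive selection for
#' co-localization).
#'
#' The window consists of the genes at order offsets `-window..-1` and
#' `+1..+window` on the focal gene's chromosome, truncated at chromosome
#' ends. Window genes belonging to the focal gene's ortholog group are
#' removed from both `L` and `n_window`, so tandem duplicates are not
#' counted as co-localization; the genome-wide `T` is left untouched.
#' Genes with `T = 0` or `n_window = 0` get an `excluded_reason` and an
#' undefined (NA) FC.
#'
#' @param genome A `genome_index`.
#' @param network A `network_edges` object on the same gene universe.
#' @param groups Optional `ortholog_groups`; `NULL` treats every gene as its
#'   own singleton group (no exclusion).
#' @param window Window half-width in genes (default 10).
#' @param fc_breaks Bin bounds passed to [fc_bin()].
#' @return A tibble of class `coloc_result`, one row per genome gene:
#'   `gene_id`, `chrom`, `order_index`, `T`, `L`, `n_window`,
#'   `genome_likelihood`, `local_likelihood`, `FC`, `bin`,
#'   `excluded_reason` (NA for analyzable genes).
#' @examples
#' genome <- generate_genome(n_chrom = 1, genes_per_chrom = 50, seed = 1)
#' net <- generate_network(genome, p_bg = 0.05, seed = 2)$network
#' coloc_stats(genome, net, window = 5)
#' @export
coloc_stats <- function(genome, network, groups = NULL, window = 10,
                        fc_breaks = c(2, 5, 20, 50)) {
  N <- nrow(genome)
  wt <- window_table_excluded(genome, groups, window)
  nw <- wt |> count(.data$gene_id, name = "n_window")
  de <- directed_edges(network)
  lw <- wt |>
    semi_join(de, by = c(gene_id = "gene", occupant = "partner")) |>
    count(.data$gene_id, name = "L")
  out <- genome |>
    select("gene_id", "chrom", "order_index") |>
    left_join(partner_counts(network, genome), by = c(gene_id = "gene")) |>
    left_join(nw, by = "gene_id") |>
    left_join(lw, by = "gene_id") |>
    mutate(
      n_window = if_else(is.na(.data$n_window), 0L, as.integer(.data$n_window)),
      L = if_else(is.na(.data$L), 0L, as.integer(.data$L)),
      excluded_reason = dplyr::case_when(
        .data$T == 0L ~ "no partners",
        .data$n_window == 0L ~ "no window genes",
        TRUE ~ NA_character_
      ),
      genome_likelihood = if (N > 1) .data$T / (N - 1) else NA_real_,
      local_likelihood = if_else(.data$n_window > 0, .data$L / .data$n_window, NA_real_),
      FC = if_else(
        is.na(.data$excluded_reason),
        .data$local_likelihood / .data$genome_likelihood,
        NA_real_
      ),
      bin = fc_bin(.data$FC, fc_breaks)
    )
  attr(out, "params") <- list(window = window, fc_breaks = fc_breaks, n_genes = N)
  class(out) <- c("coloc_result", class(out))
  out
}

#' Co-localization statistics for a single gene
#'
#' Convenience wrapper around [coloc_stats()] returning the focal gene's
#' single row. Errors on an unknown gene.
#'
#' @param gene_id The focal gene.
#' @inheritParams coloc_stats
#' @return A one-row `coloc_result` tibble.
#' @export
gene_stats <- function(gene_id, genome, network, groups = NULL, window = 10,
                       fc_breaks = c(2, 5, 20, 50)) {
  stopifnot_gene(genome, gene_id)
  res <- coloc_stats(genome, network, groups, window, fc_breaks)
  res[res$gene_id == gene_id, , drop = FALSE]
}

#' Tabulate genes by fold-change class
#'
#' Counts and fractions of analyzable genes per FC bin, with excluded genes
#' reported separately. Fractions sum to 1 over non-excluded genes.
#'
#' @param results A `coloc_result` tibble.
#' @return A tibble with columns `bin`, `n`, `fraction` (excluded genes get
#'   `bin = "excluded"` and `fraction = NA`).
#' @export
classify_fc <- function(results) {
  params <- attr(results, "params")
  breaks <- params$fc_breaks %||% c(2, 5, 20, 50)
  labs <- fc_bin(c(breaks[1] - 1, breaks), breaks) # all labels in order
  ok <- results[is.na(results$excluded_reason), , drop = FALSE]
  tab <- tibble(bin = labs) |>
    left_join(count(ok, .data$bin), by = "bin") |>
    mutate(
      n = if_else(is.na(.data$n), 0L, as.integer(.data$n)),
      fraction = if (nrow(ok) > 0) .data$n / nrow(ok) else NA_real_
    )
  n_exc <- sum(!is.na(results$excluded_reason))
  bind_rows(tab, tibble(bin = "excluded", n = n_exc, fraction = NA_real_))
}

#' Co-localization likelihood across inter-loci distances
#'
#' For each gene-order rank `k = 1..window`, computes the fraction of genes
#' for which at least one of the (up to two) neighbors at order distance `k`
#' is a network partner. Only genes with `T > 0` (participating in the
#' network) that have at least one existing neighbor at rank `k` are
#' eligible at that rank. In real genomes this likelihood declines with
#' rank, reflecting the preference of co-expressed and co-interacting genes
#' for close co-localization.
#'
#' @inheritParams coloc_stats
#' @return A tibble of class `decay_curve` with one row per rank `k`:
#'   `k`, `eligible` (genes contributing), `hits` (genes with a partner at
#'   that rank), `likelihood` (`hits / eligible`, NA when no gene is
#'   eligible).
#' @export
distance_decay <- function(genome, network, window = 10) {
  if (nrow(network) == 0) abort("no partnered genes")
  pc <- partner_counts(network, genome)
  in_net <- pc$gene[pc$T > 0]
  wt <- window_table(genome, window) |>
    filter(.data$gene_id %in% in_net) |>
    mutate(k = abs(.data$offset))
  de <- directed_edges(network)
  hits <- wt |>
    semi_join(de, by = c(gene_id = "gene", occupant = "partner")) |>
    distinct(.data$gene_id, .data$k)
  out <- wt |>
    distinct(.data$gene_id, .data$k) |>
    count(.data$k, name = "eligible") |>
    left_join(count(hits, .data$k, name = "hits"), by = "k") |>
    mutate(hits = if_else(is.na(.data$hits), 0L, as.integer(.data$hits)))
  out <- tibble(k = seq_len(window)) |>
    left_join(out, by = "k") |>
    mutate(
      eligible = if_else(is.na(.data$eligible), 0L, as.integer(.data$eligible)),
      hits = if_else(is.na(.data$hits), 0L, as.integer(.data$hits)),
      likelihood = if_else(.data$eligible > 0, .data$hits / .data$eligible, NA_real_)
    )
  class(out) <- c("decay_curve", class(out))
  out
}
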
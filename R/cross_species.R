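#' Gene-order neighborhood profile of a focal gene
#'
#' Lists the occupants of the focal gene's +/-`window` gene-order slots and
#' flags which of them are network partners. Same-ortholog-group occupants
#' are kept as occupants but never flagged as partner events, identically to
#' the exclusion applied by [coloc_stats()].
#'
#' @inheritParams coloc_stats
#' @param gene_id The focal gene.
#' @return A tibble with columns `offset` (ordered, -window..+window without
#'   0; absent beyond chromosome ends), `occupant`, `is_partner`.
#' @export
neighborhood_profile <- function(gene_id, genome, network, groups = NULL,
                                 window = 10) {
  stopifnot_gene(genome, gene_id)
  all_profiles(genome, network, groups, window) |>
    filter(.data$gene_id == !!gene_id) |>
    select("offset", "occupant", "is_partner") |>
    arrange(.data$offset)
}

# profiles for every gene at once: gene_id, offset, occupant, is_partner
all_profiles <- function(genome, network, groups, window) {
  wt <- window_table(genome, window)
  de <- directed_edges(network)
  wt$is_partner <- !is.na(
    dplyr::left_join(
      wt,
      mutate(de, .hit = TRUE),
      by = c(gene_id = "gene", occupant = "partner")
    )$.hit
  )
  if (!is.null(groups)) {
    glk <- group_lookup(groups)
    same <- glk[wt$gene_id] == glk[wt$occupant]
    wt$is_partner[same] <- FALSE
  }
  wt
}

#' Conserved neighborhood partner events between two species
#'
#' For each one-to-one homolog pair `(gA, gB)`, every partner event of `gA`
#' (a partner gene `p` occupying window offset `o`) is checked for
#' conservation in species B: the event is an *overlap* when `p`'s homolog
#' `p'` is a partner of `gB` sitting at the same offset `o` — or at the
#' mirrored offset `-o`, which absorbs segmental inversions and opposite
#' chromosome orientations ("inverted but exactly the same" events). Each
#' event is counted at most once.
#'
#' @param genome_a,genome_b `genome_index` objects for the two species.
#' @param network_a,network_b `network_edges` for the two species.
#' @param homologs A `homolog_map` (columns `gene_a`, `gene_b`).
#' @param groups_a,groups_b Optional `ortholog_groups` per species.
#' @param window Window half-width in genes (default 10).
#' @return A tibble of class `overlap_result`, one row per usable homolog
#'   pair: `gene_a`, `gene_b`, `events` (partner events in A's window),
#'   `overlaps` (events conserved in B), `offsets_matched` (comma list of
#'   matched offsets, mirrored matches flagged `m`). Pairs skipped because a
#'   side is missing from its genome are recorded in the `skipped`
#'   attribute.
#' @examples
#' genome <- generate_genome(2, 60, seed = 1)
#' net <- generate_network(genome, p_bg = 0.03, seed = 2)$network
#' sp <- generate_species_pair(genome, net, shuffle_rate = 0, seed = 3)
#' ov <- overlap_events(genome, sp$genome_b, net, sp$network_b, sp$homologs)
#' summarize_overlaps(ov)$fraction_not_overlapped # 0 for an exact copy
#' @export
overlap_events <- function(genome_a, genome_b, network_a, network_b, homologs,
                           groups_a = NULL, groups_b = NULL, window = 10) {
  hom <- as_tibble(homologs)[, c("gene_a", "gene_b")]
  usable <- hom$gene_a %in% genome_a$gene_id & hom$gene_b %in% genome_b$gene_id
  skipped <- mutate(hom[!usable, ], reason = "missing annotation")
  hom <- hom[usable, , drop = FALSE]

  prof_a <- all_profiles(genome_a, network_a, groups_a, window) |>
    filter(.data$is_partner) |>
    select(gene_a = "gene_id", offset = "offset", partner_a = "occupant")
  prof_b <- all_profiles(genome_b, network_b, groups_b, window) |>
    filter(.data$is_partner) |>
    select(gene_b = "gene_id", offset_b = "offset", partner_b = "occupant")

  # events of the A-side focal genes in the homolog set
  events <- inner_join(hom, prof_a, by = "gene_a", relationship = "many-to-many")
  # homolog of the partner gene (events whose partner has no homolog cannot overlap)
  hom_all <- setNames(homologs$gene_b, homologs$gene_a)
  events$partner_hom <- unname(hom_all[events$partner_a])

  matched <- events |>
    left_join(prof_b,
      by = c(gene_b = "gene_b", partner_hom = "partner_b"),
      relationship = "many-to-many"
    ) |>
    mutate(
      same = !is.na(.data$offset_b) & .data$offset_b == .data$offset,
      mirror = !is.na(.data$offset_b) & .data$offset_b == -.data$offset
    ) |>
    group_by(.data$gene_a, .data$gene_b, .data$offset, .data$partner_a) |>
    summarise(
      hit = any(.data$same | .data$mirror),
      mirrored_only = any(.data$mirror) && !any(.data$same),
      .groups = "drop"
    )

  out <- hom |>
    left_join(
      matched |>
        group_by(.data$gene_a) |>
        summarise(
          events = n(),
          overlaps = sum(.data$hit),
          offsets_matched = paste0(
            .data$offset[.data$hit],
            if_else(.data$mirrored_only[.data$hit], "m", ""),
            collapse = ","
          ),
          .groups = "drop"
        ),
      by = "gene_a"
    ) |>
    mutate(
      events = if_else(is.na(.data$events), 0L, as.integer(.data$events)),
      overlaps = if_else(is.na(.data$overlaps), 0L, as.integer(.data$overlaps)),
      offsets_matched = if_else(is.na(.data$offsets_matched), "", .data$offsets_matched)
    )
  attr(out, "skipped") <- skipped
  attr(out, "window") <- window
  class(out) <- c("overlap_result", class(out))
  out
}

#' Summarize cross-species overlap records
#'
#' Aggregates per-homolog-pair overlap records into the histogram of
#' per-gene overlap counts, event totals, and the fraction of neighborhood
#' partner events not conserved between the species.
#'
#' @param records An `overlap_result` tibble from [overlap_events()].
#' @return A list of class `overlap_summary`:
#'   `histogram` (tibble `overlaps`, `n_genes`), `total_events`,
#'   `total_overlaps`, `fraction_not_overlapped`, `n_pairs`,
#'   `n_completely_overlapped` (genes with >= 1 event, all conserved).
#' @export
summarize_overlaps <- function(records) {
  stopifnot(nrow(records) >= 1)
  total_events <- sum(records$events)
  total_overlaps <- sum(records$overlaps)
  out <- list(
    histogram = count(as_tibble(records), overlaps = .data$overlaps, name = "n_genes"),
    total_events = total_events,
    total_overlaps = total_overlaps,
    fraction_not_overlapped =
      if (total_events > 0) 1 - total_overlaps / total_events else NA_real_,
    n_pairs = nrow(records),
    n_completely_overlapped =
      sum(records$events > 0 & records$overlaps == records$events)
  )
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Cross-species neighborhood overlap summary\n")
  cat("  homolog pairs analyzed: ", x$n_pairs, "\n", sep = "")
  cat("  total neighbor partner events: ", x$total_events, "\n", sep = "")
  cat("  conserved (overlap) events:    ", x$total_overlaps, "\n", sep = "")
  cat(sprintf("  fraction not overlapped:       %.3f\n", x$fraction_not_overlapped))
  cat("  genes with all events conserved: ", x$n_completely_overlapped, "\n", sep = "")
  invisible(x)
}
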
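#' Read ortholog (KO-style) group assignments
#'
#' Ortholog groups identify homologous / tandemly duplicated genes; partner
#' events between same-group genes inside a focal gene's window are excluded
#' from the local counts so that duplicate runs are not mistaken for
#' co-localization. The mapping is made total over the genome: every gene
#' absent from the file receives a unique singleton group id.
#'
#' @param file Path to a 2-column TSV (`gene_id`, `group_id`), header
#'   optional, gzip accepted. May be `NULL` for an all-singleton grouping.
#' @param genome A `genome_index`.
#' @return A tibble of class `ortholog_groups` with columns `gene_id`,
#'   `group_id`, one row per genome gene.
#' @export
read_groups <- function(file, genome) {
  if (is.null(file)) {
    return(as_ortholog_groups(NULL, genome))
  }
  df <- readr::read_tsv(file,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(df) < 2) abort("group table needs 2 columns: gene_id, group_id")
  names(df)[1:2] <- c("gene_id", "group_id")
  if (nrow(df) > 0 && df$gene_id[1] %in% c("gene_id", "gene")) df <- df[-1, , drop = FALSE]
  as_ortholog_groups(df[, c("gene_id", "group_id")], genome)
}

#' Coerce a gene-to-group table to a total ortholog grouping
#'
#' @param groups A data frame with columns `gene_id`, `group_id`, or `NULL`
#'   for an all-singleton grouping.
#' @inheritParams read_groups
#' @return An `ortholog_groups` tibble covering every genome gene.
#' @export
as_ortholog_groups <- function(groups, genome) {
  if (is.null(groups)) {
    groups <- tibble(gene_id = character(), group_id = character())
  }
  groups <- as_tibble(groups) |>
    mutate(gene_id = as.character(.data$gene_id), group_id = as.character(.data$group_id)) |>
    distinct()
  multi <- groups |>
    count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("gene assigned to multiple groups: ", paste(multi$gene_id, collapse = ", ")))
  }
  out <- tibble(gene_id = genome$gene_id) |>
    left_join(groups, by = "gene_id") |>
    mutate(group_id = if_else(
      is.na(.data$group_id),
      paste0("singleton:", .data$gene_id),
      .data$group_id
    ))
  class(out) <- c("ortholog_groups", class(out))
  out
}

group_lookup <- function(groups) setNames(groups$group_id, groups$gene_id)

#' Read and validate a two-species homolog map
#'
#' Reads one-to-one homolog pairs between species A and B. Pairs violating
#' the one-to-one requirement, or whose gene is missing from its species'
#' genome annotation or has no network edges, are moved to the `excluded`
#' attribute with a reason code — mirroring the exclusion of homologs with
#' missing data from cross-species overlap analyses.
#'
#' @param file Path to a 2-column TSV (`gene_a`, `gene_b`), or a data frame
#'   with those columns.
#' @param genome_a,genome_b `genome_index` objects for the two species.
#' @param network_a,network_b Optional `network_edges` for the two species;
#'   when supplied, genes without any edge are excluded with reason
#'   `"missing network data"`.
#' @return A tibble of class `homolog_map` with columns `gene_a`, `gene_b`
#'   (strictly one-to-one), and attribute `excluded`: a tibble
#'   (`gene_a`, `gene_b`, `reason`).
#' @export
read_homologs <- function(file, genome_a, genome_b,
                          network_a = NULL, network_b = NULL) {
  if (is.data.frame(file)) {
    df <- as_tibble(file)
  } else {
    df <- readr::read_tsv(file,
      col_names = FALSE, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    if (ncol(df) < 2) abort("homolog table needs 2 columns: gene_a, gene_b")
    names(df)[1:2] <- c("gene_a", "gene_b")
    if (nrow(df) > 0 && df$gene_a[1] %in% c("gene_a", "gene_A")) df <- df[-1, , drop = FALSE]
  }
  df <- df |>
    mutate(gene_a = as.character(.data$gene_a), gene_b = as.character(.data$gene_b)) |>
    select("gene_a", "gene_b") |>
    distinct()

  excluded <- tibble(gene_a = character(), gene_b = character(), reason = character())
  flag <- function(rows, reason) {
    if (nrow(rows) > 0) {
      excluded <<- bind_rows(excluded, mutate(rows, reason = reason))
    }
  }

  multi_a <- df$gene_a[duplicated(df$gene_a) | duplicated(df$gene_a, fromLast = TRUE)]
  multi_b <- df$gene_b[duplicated(df$gene_b) | duplicated(df$gene_b, fromLast = TRUE)]
  not_one2one <- df$gene_a %in% multi_a | df$gene_b %in% multi_b
  flag(df[not_one2one, ], "not one-to-one")
  df <- df[!not_one2one, , drop = FALSE]

  missing_anno <- !(df$gene_a %in% genome_a$gene_id) | !(df$gene_b %in% genome_b$gene_id)
  flag(df[missing_anno, ], "missing annotation")
  df <- df[!missing_anno, , drop = FALSE]

  if (!is.null(network_a) || !is.null(network_b)) {
    in_net <- function(ids, network) {
      if (is.null(network)) rep(TRUE, length(ids)) else ids %in% c(network$gene_a, network$gene_b)
    }
    missing_net <- !in_net(df$gene_a, network_a) | !in_net(df$gene_b, network_b)
    flag(df[missing_net, ], "missing network data")
    df <- df[!missing_net, , drop = FALSE]
  }

  attr(df, "excluded") <- excluded
  class(df) <- c("homolog_map", class(df))
  df
}
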
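#' Rewrite network gene aliases to canonical identifiers
#'
#' Interaction databases (e.g. STRING) key their edges by protein or
#' database-specific identifiers that must be reconciled with the gene ids of
#' the annotation before any positional analysis. Every alias appearing in
#' the alias table is replaced by its canonical id; rows in which either
#' endpoint cannot be resolved to a known id are dropped and counted.
#'
#' @param rows A data frame with columns `gene_a`, `gene_b` (and any others,
#'   carried through).
#' @param alias_table A data frame with columns `alias`, `gene_id` mapping
#'   each alias to exactly one canonical id. An alias mapped to two distinct
#'   canonical ids is an error.
#' @param known Optional character vector of ids considered resolvable
#'   post-mapping (e.g. the genome's gene ids). When supplied, rows with an
#'   endpoint outside `known` after mapping are dropped and counted.
#' @return The rewritten tibble, with attribute `n_dropped` giving the number
#'   of rows dropped for unresolvable endpoints.
#' @export
harmonize_ids <- function(rows, alias_table, known = NULL) {
  rows <- as_tibble(rows)
  alias_table <- as_tibble(alias_table)
  stopifnot(all(c("alias", "gene_id") %in% names(alias_table)))
  amb <- alias_table |>
    distinct(.data$alias, .data$gene_id) |>
    count(.data$alias) |>
    filter(.data$n > 1)
  if (nrow(amb) > 0) {
    abort(paste0("ambiguous alias: ", paste(amb$alias, collapse = ", ")))
  }
  map <- setNames(alias_table$gene_id, alias_table$alias)
  translate <- function(x) if_else(x %in% names(map), unname(map[x]), x)
  out <- rows |>
    mutate(gene_a = translate(.data$gene_a), gene_b = translate(.data$gene_b))
  if (!is.null(known)) {
    keep <- out$gene_a %in% known & out$gene_b %in% known
    dropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  } else {
    dropped <- 0L
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Build a filtered undirected network edge set
#'
#' Applies the standard cleaning of a STRING-style scored edge list:
#' edges below `min_score` are excluded (the combined-score scale runs
#' 0-1000 and scores below 150 are conventionally low-confidence), self
#' edges are removed, `(a,b)` / `(b,a)` duplicates are collapsed keeping the
#' maximum score, and edges with either endpoint absent from the genome are
#' dropped and counted.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `score`
#'   (integer 0-1000).
#' @param genome A `genome_index`; edges must connect annotated genes.
#' @param min_score Minimal combined score retained (default 150).
#' @return A tibble of class `network_edges` with columns `gene_a`,
#'   `gene_b`, `score`, one row per unordered pair with `gene_a < gene_b`.
#'   Attributes `n_dropped_score`, `n_dropped_self`, `n_dropped_unknown`
#'   report the filter counts.
#' @export
as_network_edges <- function(edges, genome, min_score = 150) {
  edges <- as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  if (!is.numeric(edges$score) || any(is.na(edges$score)) ||
    any(edges$score != as.integer(edges$score))) {
    bad <- which(is.na(suppressWarnings(as.integer(edges$score))) |
      edges$score != floor(edges$score))[1]
    abort(paste0("non-integer score at row ", bad %||% NA))
  }
  edges <- edges |>
    mutate(
      gene_a = as.character(.data$gene_a), gene_b = as.character(.data$gene_b),
      score = as.integer(.data$score)
    )
  n0 <- nrow(edges)
  edges <- filter(edges, .data$score >= min_score)
  n_score <- n0 - nrow(edges)
  n1 <- nrow(edges)
  edges <- filter(edges, .data$gene_a != .data$gene_b)
  n_self <- n1 - nrow(edges)
  n2 <- nrow(edges)
  edges <- filter(edges, .data$gene_a %in% genome$gene_id & .data$gene_b %in% genome$gene_id)
  n_unknown <- n2 - nrow(edges)
  out <- edges |>
    mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b)
    ) |>
    group_by(.data$lo, .data$hi) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    rename(gene_a = "lo", gene_b = "hi") |>
    arrange(.data$gene_a, .data$gene_b)
  if (nrow(out) == 0) warn("no edges remain after filtering")
  attr(out, "n_dropped_score") <- n_score
  attr(out, "n_dropped_self") <- n_self
  attr(out, "n_dropped_unknown") <- n_unknown
  attr(out, "min_score") <- as.integer(min_score)
  class(out) <- c("network_edges", class(out))
  out
}

#' Read a scored edge list
#'
#' Reads a 3-column TSV (`gene_a`, `gene_b`, `score`; header optional when
#' the first row parses as an edge; gzip accepted), optionally harmonizes
#' aliases, and applies [as_network_edges()] filtering.
#'
#' @inheritParams as_network_edges
#' @param file Path to the edge list.
#' @param alias_table Optional alias table passed to [harmonize_ids()].
#' @return A `network_edges` tibble.
#' @export
read_network <- function(file, genome, min_score = 150, alias_table = NULL) {
  df <- readr::read_tsv(file,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(df) < 3) abort("edge list needs 3 columns: gene_a, gene_b, score")
  names(df)[1:3] <- c("gene_a", "gene_b", "score")
  # tolerate a header row
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df$score[1])))) {
    df <- df[-1, , drop = FALSE]
  }
  score_num <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score_num) || any(score_num != floor(score_num))) {
    bad <- which(is.na(score_num) | score_num != floor(score_num))[1]
    abort(paste0("non-integer score at line ", bad))
  }
  df$score <- as.integer(score_num)
  if (!is.null(alias_table)) {
    df <- harmonize_ids(df, alias_table)
  }
  as_network_edges(df[, c("gene_a", "gene_b", "score")], genome, min_score = min_score)
}

#' Write a network edge set as TSV
#' @param network A `network_edges` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network <- function(network, file) {
  readr::write_tsv(network[, c("gene_a", "gene_b", "score")], file,
    col_names = FALSE, progress = FALSE
  )
  invisible(file)
}

# symmetric partner map: named list gene_id -> character vector of partners
partner_map <- function(network) {
  both <- c(network$gene_a, network$gene_b)
  other <- c(network$gene_b, network$gene_a)
  split(other, both)
}

# tibble with one row per directed partner relation (both directions)
directed_edges <- function(network) {
  tibble(
    gene = c(network$gene_a, network$gene_b),
    partner = c(network$gene_b, network$gene_a)
  )
}

# per-gene total partner count over the whole genome (genes absent from the
# network get T = 0)
partner_counts <- function(network, genome) {
  directed_edges(network) |>
    count(.data$gene, name = "T") |>
    (\(d) left_join(tibble(gene = genome$gene_id), d, by = "gene"))() |>
    mutate(T = if_else(is.na(.data$T), 0L, as.integer(.data$T)))
}
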
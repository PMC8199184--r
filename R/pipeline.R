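#' Read a pipeline run configuration
#'
#' The configuration is a flat YAML key/value file. Recognized keys:
#' input paths `annotation` (+ `annotation_dialect`), `network`, `aliases`,
#' `groups`, `homologs`, `annotation_b`, `network_b`, `vcf`; analysis
#' parameters `window`, `min_score`, `fc_breaks`; `out_dir`; `seed`; and
#' stage toggles `run_coloc`, `run_decay`, `run_overlap`, `run_ld`
#' (each defaults to on when its inputs are present).
#'
#' @param file Path to a YAML config, or a named list already in memory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(file) {
  cfg <- if (is.list(file)) file else yaml::read_yaml(file)
  defaults <- list(
    annotation_dialect = "tsv", window = 10, min_score = 150,
    fc_breaks = c(2, 5, 20, 50), out_dir = "colocnet_out", seed = 1
  )
  cfg <- utils::modifyList(defaults, cfg)
  # [[ ]] avoids partial matching (e.g. $annotation hitting annotation_dialect)
  if (is.null(cfg[["annotation"]])) abort("config lacks 'annotation'")
  if (is.null(cfg[["network"]])) abort("config lacks 'network'")
  path_keys <- c(
    "annotation", "network", "aliases", "groups", "homologs",
    "annotation_b", "network_b", "vcf"
  )
  for (k in path_keys) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      abort(paste0("input file for '", k, "' does not exist: ", cfg[[k]]))
    }
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Run the full co-localization pipeline
#'
#' Executes the stages in dependency order — input parsing, per-gene
#' co-localization statistics, distance decay, optional cross-species
#' overlap (when B-species inputs are configured), optional LD matrix (when
#' a VCF is configured) — and writes TSV/JSON outputs, a run log narrating
#' every filter count, the echoed config, and a MANIFEST with md5 checksums.
#' Identical config and seed produce a byte-identical output tree.
#'
#' @param config A `run_config`, a path to one, or a named list.
#' @return The output directory path, invisibly. Written files:
#'   `config.yaml`, `coloc.tsv`, `fc_classes.tsv`, `decay.tsv`,
#'   `overlap_pairs.tsv` + `overlap_summary.json` (when configured),
#'   `ld_matrix.tsv` (when configured), `run.log`, `MANIFEST.tsv`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0("INFO ", paste0(...))
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }

  say("reading annotation: ", cfg$annotation)
  genome <- read_gene_order(cfg$annotation, dialect = cfg$annotation_dialect)
  say("genes loaded: ", nrow(genome))

  aliases <- if (!is.null(cfg$aliases)) {
    readr::read_tsv(cfg$aliases,
      col_names = c("alias", "gene_id"),
      show_col_types = FALSE, progress = FALSE
    )
  }
  network <- read_network(cfg$network, genome,
    min_score = cfg$min_score, alias_table = aliases
  )
  say(
    "edges kept: ", nrow(network),
    " (dropped: score ", attr(network, "n_dropped_score"),
    ", self ", attr(network, "n_dropped_self"),
    ", unknown gene ", attr(network, "n_dropped_unknown"), ")"
  )
  groups <- read_groups(cfg$groups, genome)

  outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(cfg$out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      readr::write_tsv(obj, path, progress = FALSE)
    }
    outputs <<- c(outputs, path)
  }

  if (cfg$run_coloc %||% TRUE) {
    res <- coloc_stats(genome, network,
      groups = groups,
      window = cfg$window, fc_breaks = cfg$fc_breaks
    )
    emit(res, "coloc.tsv")
    emit(classify_fc(res), "fc_classes.tsv")
    say(
      "coloc: ", sum(is.na(res$excluded_reason)), " genes analyzable, ",
      sum(!is.na(res$excluded_reason)), " excluded"
    )
  }
  if (cfg$run_decay %||% TRUE) {
    emit(distance_decay(genome, network, window = cfg$window), "decay.tsv")
    say("distance decay computed to rank ", cfg$window)
  }

  if ((cfg$run_overlap %||% !is.null(cfg$homologs)) && !is.null(cfg$homologs)) {
    genome_b <- read_gene_order(cfg$annotation_b, dialect = cfg$annotation_dialect)
    network_b <- read_network(cfg$network_b, genome_b, min_score = cfg$min_score)
    homologs <- read_homologs(cfg$homologs, genome, genome_b, network, network_b)
    say(
      "homolog pairs: ", nrow(homologs), " usable, ",
      nrow(attr(homologs, "excluded")), " excluded"
    )
    ov <- overlap_events(genome, genome_b, network, network_b, homologs,
      groups_a = groups, window = cfg$window
    )
    emit(ov, "overlap_pairs.tsv")
    sm <- summarize_overlaps(ov)
    emit(unclass(sm), "overlap_summary.json")
    say(
      "overlap events: ", sm$total_events, " total, ",
      sm$total_overlaps, " conserved"
    )
  }

  if ((cfg$run_ld %||% !is.null(cfg$vcf)) && !is.null(cfg$vcf)) {
    panel <- read_vcf_haplotypes(cfg$vcf, region = cfg$ld_region)
    say("haplotype panel: ", panel$n_haplotypes, " haplotypes, ", nrow(panel$variants), " variants")
    emit(ld_matrix(panel), "ld_matrix.tsv")
  }

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "class")], cfg_path)
  outputs <- c(outputs, cfg_path)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  outputs <- c(outputs, file.path(cfg$out_dir, "run.log"))
  md5 <- tools::md5sum(sort(outputs))
  readr::write_tsv(
    tibble(file = basename(names(md5)), md5 = unname(md5)),
    file.path(cfg$out_dir, "MANIFEST.tsv"),
    progress = FALSE
  )
  invisible(cfg$out_dir)
}

#' Candidate-gene neighborhood report
#'
#' A human-readable view of a focal gene's +/-`window` neighborhood — the
#' genomic-block inspection used for candidate-gene calling: each window
#' gene with its offset, ortholog group, partner flag and edge score,
#' together with the focal gene's co-localization statistics.
#'
#' @inheritParams coloc_stats
#' @param gene_id The focal gene (unknown ids error with nearest-id
#'   suggestions).
#' @return A tibble of class `neighborhood_report`, rows ordered by offset:
#'   `offset`, `gene_id`, `group_id`, `is_partner`, `score` (NA when not a
#'   partner). Attribute `focal` carries the gene's `coloc_result` row;
#'   attribute `has_partner_neighbors` is TRUE when any window gene is a
#'   partner.
#' @export
neighborhood_report <- function(gene_id, genome, network, groups = NULL,
                                window = 10) {
  stopifnot_gene(genome, gene_id)
  grp <- if (is.null(groups)) as_ortholog_groups(NULL, genome) else groups
  prof <- neighborhood_profile(gene_id, genome, network, groups = grp, window = window)
  glk <- group_lookup(grp)
  scores <- network |>
    filter(.data$gene_a == !!gene_id | .data$gene_b == !!gene_id) |>
    mutate(other = if_else(.data$gene_a == !!gene_id, .data$gene_b, .data$gene_a)) |>
    select("other", "score")
  out <- prof |>
    rename(gene_id = "occupant") |>
    mutate(group_id = unname(glk[.data$gene_id])) |>
    left_join(scores, by = c(gene_id = "other")) |>
    mutate(score = if_else(.data$is_partner, .data$score, NA_integer_)) |>
    select("offset", "gene_id", "group_id", "is_partner", "score") |>
    arrange(.data$offset)
  attr(out, "focal") <- gene_stats(gene_id, genome, network, grp, window)
  attr(out, "has_partner_neighbors") <- any(out$is_partner)
  class(out) <- c("neighborhood_report", class(out))
  out
}

#' @export
print.neighborhood_report <- function(x, ...) {
  focal <- attr(x, "focal")
  cat("Neighborhood report for ", focal$gene_id,
    " (", focal$chrom, ", order index ", focal$order_index, ")\n",
    sep = ""
  )
  if (is.na(focal$excluded_reason)) {
    cat(sprintf(
      "  T = %d, L = %d, n_window = %d, FC = %.3f (%s)\n",
      focal$T, focal$L, focal$n_window, focal$FC, focal$bin
    ))
  } else {
    cat("  excluded: ", focal$excluded_reason, "\n", sep = "")
  }
  NextMethod()
  invisible(x)
}
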
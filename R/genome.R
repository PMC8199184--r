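#' Build a genome index from a gene table
#'
#' A genome index is the package's ordered gene model: one row per gene with
#' its chromosome, 0-based half-open coordinates, and a dense `order_index`
#' (0-based rank along the chromosome). All window-based statistics operate
#' on `order_index`, never on bp distance or strand.
#'
#' Genes are sorted within each chromosome by `(start, end, gene_id)` — a
#' stable, deterministic order — and `order_index` is assigned densely from
#' 0, so the result is independent of input row order.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `start` and
#'   optionally `end` (defaults to `start + 1`). Coordinates must already be
#'   0-based half-open.
#' @return A tibble of class `genome_index` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `order_index`, sorted by `(chrom, order_index)`.
#' @examples
#' as_genome_index(data.frame(
#'   gene_id = c("g1", "g2", "g3"), chrom = "chr1",
#'   start = c(500L, 100L, 900L), end = c(600L, 200L, 950L)
#' ))
#' @export
as_genome_index <- function(genes) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "chrom", "start")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) == 0) abort("no gene records")
  if (!"end" %in% names(genes)) genes$end <- genes$start + 1L
  genes <- genes |>
    mutate(
      gene_id = as.character(.data$gene_id),
      chrom = as.character(.data$chrom),
      start = as.integer(.data$start),
      end = as.integer(.data$end)
    )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(genes$end <= genes$start)) {
    bad <- genes$gene_id[genes$end <= genes$start]
    abort(paste0("end <= start for gene(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  idx <- genes |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(order_index = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "chrom", "start", "end", "order_index")
  class(idx) <- c("genome_index", class(idx))
  idx
}

#' Read gene order from an annotation file
#'
#' Parses a gene annotation into a [as_genome_index()] genome index. Three
#' dialects are supported and must be declared (no sniffing):
#'
#' * `"tsv"`: 3+ columns `gene_id`, `chrom`, `start`\[, `end`\] with a header
#'   line; coordinates 0-based half-open.
#' * `"bed"`: BED (first 4 columns used: chrom, start, end, name), 0-based
#'   half-open, no header.
#' * `"gff3"`: rows with feature type `gene`; the gene identifier is taken
#'   from the `ID` attribute (falling back to `gene_id` / `Name`). GFF3
#'   1-based inclusive coordinates are converted to 0-based half-open.
#'
#' All dialects accept gzip-compressed files.
#'
#' @param file Path to the annotation file.
#' @param dialect One of `"tsv"`, `"bed"`, `"gff3"`.
#' @return A `genome_index` tibble.
#' @seealso [as_genome_index()] for the sorting and indexing rules.
#' @export
read_gene_order <- function(file, dialect = c("tsv", "bed", "gff3")) {
  dialect <- match.arg(dialect)
  genes <- switch(dialect,
    tsv = {
      df <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
      names(df)[1:3] <- c("gene_id", "chrom", "start")
      if (ncol(df) >= 4 && !"end" %in% names(df)) names(df)[4] <- "end"
      df
    },
    bed = {
      df <- readr::read_tsv(file,
        col_names = FALSE, show_col_types = FALSE, progress = FALSE
      )
      if (ncol(df) < 4) abort("BED input needs at least 4 columns (chrom, start, end, name)")
      tibble(
        gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
        start = as.integer(df[[2]]), end = as.integer(df[[3]])
      )
    },
    gff3 = {
      gr <- as.data.frame(rtracklayer::import(file, format = "gff3"))
      gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene", , drop = FALSE]
      if (nrow(gr) == 0) abort("no gene records")
      ids <- if ("ID" %in% names(gr)) as.character(gr$ID) else rep(NA_character_, nrow(gr))
      for (alt in c("gene_id", "Name")) {
        if (anyNA(ids) && alt %in% names(gr)) {
          ids[is.na(ids)] <- as.character(gr[[alt]])[is.na(ids)]
        }
      }
      if (anyNA(ids)) abort("GFF3 gene records without an ID attribute")
      tibble(
        gene_id = ids,
        chrom = as.character(gr$seqnames),
        # GFF3 is 1-based inclusive; convert to 0-based half-open
        start = as.integer(gr$start) - 1L,
        end = as.integer(gr$end)
      )
    }
  )
  if (nrow(genes) == 0) abort("no gene records")
  as_genome_index(genes)
}

#' Write a genome index as TSV
#'
#' Writes the `gene_id`, `chrom`, `start`, `end` columns in the `"tsv"`
#' dialect that [read_gene_order()] accepts, so a genome index round-trips.
#'
#' @param genome A `genome_index`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gene_order <- function(genome, file) {
  readr::write_tsv(genome[, c("gene_id", "chrom", "start", "end")], file, progress = FALSE)
  invisible(file)
}

n_genes <- function(genome) nrow(genome)

# order_index lookup vector keyed by gene_id
genome_lookup <- function(genome) {
  setNames(genome$order_index, genome$gene_id)
}

stopifnot_gene <- function(genome, gene_id) {
  if (!gene_id %in% genome$gene_id) {
    near <- genome$gene_id[order(utils::adist(gene_id, genome$gene_id))][1:min(3, nrow(genome))]
    abort(paste0(
      "unknown gene '", gene_id, "'; nearest ids: ",
      paste(near, collapse = ", ")
    ))
  }
  invisible(TRUE)
}
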
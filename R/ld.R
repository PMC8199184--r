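#' Construct a phased haplotype panel
#'
#' A haplotype panel holds a complete 0/1 allele matrix (haplotypes in rows,
#' biallelic variants in columns) together with the variant map. Phasing is
#' required: all linkage-disequilibrium statistics are computed from
#' haplotype frequencies, never reconstructed from genotypes.
#'
#' @param haplotypes Integer/logical matrix of 0/1 alleles, one row per
#'   haplotype, one column per variant. No missing values.
#' @param variants A data frame with columns `variant_id`, `chrom`, `pos`
#'   (bp positions strictly increasing within chromosome), one row per
#'   matrix column.
#' @return An object of class `haplotype_panel` (list with elements
#'   `haplotypes`, `variants`, `n_haplotypes`).
#' @export
haplotype_panel <- function(haplotypes, variants) {
  haplotypes <- as.matrix(haplotypes)
  variants <- as_tibble(variants)
  stopifnot(
    all(c("variant_id", "chrom", "pos") %in% names(variants)),
    nrow(variants) == ncol(haplotypes)
  )
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
    abort("haplotype matrix must be complete with 0/1 alleles")
  }
  storage.mode(haplotypes) <- "integer"
  ok <- variants |>
    group_by(.data$chrom) |>
    summarise(sorted = !is.unsorted(.data$pos, strictly = TRUE))
  if (!all(ok$sorted)) abort("variant positions must be strictly increasing within chromosome")
  colnames(haplotypes) <- variants$variant_id
  structure(
    list(
      haplotypes = haplotypes, variants = variants,
      n_haplotypes = nrow(haplotypes)
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(
    "Phased haplotype panel: ", x$n_haplotypes, " haplotypes x ",
    nrow(x$variants), " variants\n",
    sep = ""
  )
  invisible(x)
}

#' Read phased haplotypes from a VCF
#'
#' Keeps phased (`|`-separated), biallelic SNP records with complete
#' genotypes; multiallelic, unphased, or incomplete records are dropped and
#' counted. Each diploid sample contributes two haplotypes.
#'
#' @param file Path to a VCF (plain or gzip).
#' @param region Optional region filter `"chrom"` or `"chrom:start-end"`
#'   (1-based bp, inclusive).
#' @return A `haplotype_panel`; attribute `n_dropped` reports the records
#'   removed, by reason.
#' @export
read_vcf_haplotypes <- function(file, region = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- stringr::str_match(region, "^([^:]+)(?::(\\d+)-(\\d+))?$")
    if (is.na(m[1, 1])) abort("region must be 'chrom' or 'chrom:start-end'")
    keep <- fix$CHROM == m[1, 2]
    if (!is.na(m[1, 3])) {
      keep <- keep & pos >= as.integer(m[1, 3]) & pos <= as.integer(m[1, 4])
    }
  }
  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  phased <- apply(gt, 1, function(g) {
    all(!is.na(g)) && all(grepl("^[01]\\|[01]$", g))
  })
  n_dropped <- c(
    region = sum(!keep),
    not_biallelic_snp = sum(keep & !snp),
    unphased_or_missing = sum(keep & snp & !phased)
  )
  use <- keep & snp & phased
  if (!any(use)) abort("no usable variants")
  gt <- gt[use, , drop = FALSE]
  a1 <- apply(gt, c(1, 2), function(g) as.integer(substr(g, 1, 1)))
  a2 <- apply(gt, c(1, 2), function(g) as.integer(substr(g, 3, 3)))
  # haplotypes: for each sample, two rows (hap1, hap2)
  haps <- rbind(t(a1), t(a2))
  ids <- fix$ID[use]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[use], ":", pos[use])[is.na(ids) | ids == "."]
  panel <- haplotype_panel(
    haps,
    tibble(variant_id = ids, chrom = fix$CHROM[use], pos = pos[use])
  )
  attr(panel, "n_dropped") <- n_dropped
  panel
}

#' Select SNPs flanking a gene
#'
#' Picks up to `n_max` variants nearest the gene body from its 5'- and
#' 3'-flanking regions, balanced between the two flanks as supply allows
#' (standard practice is to take 60-100 flanking SNPs per gene). If fewer
#' than `n_min` variants are available a warning is emitted and the
#' analysis proceeds with what exists.
#'
#' @param panel A `haplotype_panel`.
#' @param gene A one-row data frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. a `genome_index` row.
#' @param n_min,n_max Minimal / maximal number of SNPs (defaults 60 / 100).
#' @param flank_bp Flank width scanned on each side (default 50000).
#' @return Character vector of selected `variant_id`s, ordered by position.
#' @export
select_flanking_snps <- function(panel, gene, n_min = 60, n_max = 100,
                                 flank_bp = 50000) {
  v <- panel$variants
  # VCF positions are 1-based; gene coords 0-based half-open
  gene_start1 <- gene$start + 1
  gene_end1 <- gene$end
  left <- v |>
    filter(
      .data$chrom == gene$chrom,
      .data$pos < gene_start1, .data$pos >= gene_start1 - flank_bp
    ) |>
    mutate(dist = gene_start1 - .data$pos)
  right <- v |>
    filter(
      .data$chrom == gene$chrom,
      .data$pos > gene_end1, .data$pos <= gene_end1 + flank_bp
    ) |>
    mutate(dist = .data$pos - gene_end1)
  n_avail <- nrow(left) + nrow(right)
  if (n_avail == 0) abort("zero flanking variants")
  half <- ceiling(n_max / 2)
  take_l <- min(nrow(left), max(half, n_max - nrow(right)))
  take_r <- min(nrow(right), n_max - take_l)
  sel <- bind_rows(
    left |> arrange(.data$dist) |> head(take_l),
    right |> arrange(.data$dist) |> head(take_r)
  )
  if (nrow(sel) < n_min) {
    warn(paste0("only ", nrow(sel), " flanking SNPs available (< ", n_min, ")"))
  }
  sel |>
    arrange(.data$pos) |>
    pull(.data$variant_id)
}

# exact integer-count arithmetic: D' and r2 are ratios of integer products,
# so the single final division cannot push them past 1
ld_from_counts <- function(n, n_A, n_B, n_AB) {
  n <- as.numeric(n)
  n_A <- as.numeric(n_A)
  n_B <- as.numeric(n_B)
  n_AB <- as.numeric(n_AB)
  D_num <- n * n_AB - n_A * n_B # n^2 * D
  D <- D_num / n^2
  D_max_num <- if (D_num > 0) { # n^2 * D_max
    min(n_A * (n - n_B), (n - n_A) * n_B)
  } else {
    min(n_A * n_B, (n - n_A) * (n - n_B))
  }
  D_prime <- if (D_num == 0) 0 else abs(D_num) / D_max_num
  r2 <- D_num^2 / (n_A * (n - n_A) * n_B * (n - n_B))
  tibble(
    D = D, D_prime = D_prime, r2 = r2,
    p_A = n_A / n, p_B = n_B / n
  )
}

#' Pairwise linkage disequilibrium between two variants
#'
#' Computes the classical two-locus LD statistics from phased haplotype
#' frequencies. With `p_AB` the frequency of the haplotype carrying the
#' "1" allele at both sites and `p_A`, `p_B` the allele frequencies:
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` where `D_max` is
#' `min(p_A (1-p_B), (1-p_A) p_B)` for `D > 0` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` for `D < 0` (`D' = 0` when `D = 0`);
#' `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`. Complete linkage gives
#' `D' = 1`, random segregation `D' = 0`.
#'
#' @param panel A `haplotype_panel`.
#' @param i,j Variant ids or column indices. Both must be polymorphic.
#' @return A one-row tibble: `variant_i`, `variant_j`, `D`, `D_prime`,
#'   `r2`, `p_A`, `p_B`.
#' @examples
#' pan <- two_site_panel(30, 0, 0, 20)
#' pairwise_ld(pan, 1, 2) # complete linkage: D' = 1
#' @export
pairwise_ld <- function(panel, i, j) {
  H <- panel$haplotypes
  resolve <- function(x) if (is.character(x)) match(x, colnames(H)) else as.integer(x)
  ii <- resolve(i)
  jj <- resolve(j)
  if (is.na(ii) || is.na(jj)) abort("unknown variant")
  a <- H[, ii]
  b <- H[, jj]
  n <- length(a)
  n_A <- sum(a)
  n_B <- sum(b)
  if (n_A %in% c(0L, n) || n_B %in% c(0L, n)) {
    abort("undefined LD: monomorphic variant")
  }
  stat <- ld_from_counts(n, n_A, n_B, sum(a == 1L & b == 1L))
  bind_cols(
    tibble(
      variant_i = colnames(H)[ii] %||% as.character(ii),
      variant_j = colnames(H)[jj] %||% as.character(jj)
    ),
    stat
  )
}

#' Pairwise LD over a variant set
#'
#' Computes [pairwise_ld()] for every unordered pair of the selected
#' variants, excluding monomorphic variants up front. Variant order follows
#' genomic position as stored in the panel.
#'
#' @param panel A `haplotype_panel`.
#' @param variants Variant ids or indices; default all panel variants.
#' @return A tibble of class `ld_matrix` (long upper-triangular form), one
#'   row per pair, columns as in [pairwise_ld()]. Attribute
#'   `monomorphic_dropped` lists excluded variant ids.
#' @export
ld_matrix <- function(panel, variants = NULL) {
  H <- panel$haplotypes
  if (is.null(variants)) variants <- colnames(H)
  idx <- if (is.character(variants)) match(variants, colnames(H)) else as.integer(variants)
  if (anyNA(idx)) abort("unknown variant in selection")
  freq <- colMeans(H[, idx, drop = FALSE])
  mono <- colnames(H)[idx][freq %in% c(0, 1)]
  idx <- idx[!(freq %in% c(0, 1))]
  if (length(idx) < 2) abort("fewer than 2 polymorphic variants")
  pairs <- utils::combn(idx, 2)
  out <- purrr::map_dfr(
    seq_len(ncol(pairs)),
    function(k) pairwise_ld(panel, pairs[1, k], pairs[2, k])
  )
  attr(out, "monomorphic_dropped") <- mono
  class(out) <- c("ld_matrix", class(out))
  out
}
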
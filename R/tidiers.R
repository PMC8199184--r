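#' Tidy a co-localization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return The per-gene tibble, without the result class.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a co-localization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_analyzable`, `n_excluded`,
#'   `mean_FC`, `median_FC`, `frac_fc_ge_2` (fraction of analyzable genes
#'   with FC at or above the first bin bound), `window`.
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  params <- attr(x, "params")
  thr <- (params$fc_breaks %||% c(2, 5, 20, 50))[1]
  ok <- x[is.na(x$excluded_reason), , drop = FALSE]
  tibble(
    n_genes = nrow(x),
    n_analyzable = nrow(ok),
    n_excluded = nrow(x) - nrow(ok),
    mean_FC = mean(ok$FC),
    median_FC = median(ok$FC),
    frac_fc_ge_2 = mean(ok$FC >= thr),
    window = params$window
  )
}

#' @rdname tidy.coloc_result
#' @method tidy decay_curve
#' @export
tidy.decay_curve <- function(x, ...) as_tibble(x)

#' @rdname tidy.coloc_result
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) as_tibble(x)

#' One-row summary of cross-species overlap records
#'
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return A one-row tibble with the [summarize_overlaps()] totals.
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  s <- summarize_overlaps(x)
  tibble(
    n_pairs = s$n_pairs,
    total_events = s$total_events,
    total_overlaps = s$total_overlaps,
    fraction_not_overlapped = s$fraction_not_overlapped,
    n_completely_overlapped = s$n_completely_overlapped
  )
}

#' @rdname tidy.coloc_result
#' @method tidy ld_matrix
#' @export
tidy.ld_matrix <- function(x, ...) as_tibble(x)

#' One-row summary of an LD matrix
#'
#' @param x An `ld_matrix`.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `mean_D_prime`, `mean_r2`,
#'   `frac_complete_linkage` (pairs with D' = 1).
#' @method glance ld_matrix
#' @export
glance.ld_matrix <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    mean_D_prime = mean(x$D_prime),
    mean_r2 = mean(x$r2),
    frac_complete_linkage = mean(x$D_prime == 1)
  )
}
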
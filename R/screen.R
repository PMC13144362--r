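#' Filter screen cells to one class
#'
#' Retains cells of `keep_class` (interphase by default) and computes the
#' per-gene apoptotic fraction on the pre-filter set, which feeds the
#' gene-exclusion rule.
#'
#' @param records Per-cell tibble with at least `gene` and `class`
#'   columns (see [generate_screen_table()]).
#' @param keep_class Cell class to retain.
#' @return List with `cells` (filtered tibble) and `class_fractions`
#'   (per-gene tibble with `apoptotic_fraction` and `n_cells`); genes with
#'   no remaining cells are flagged in `empty_genes`.
#' @export
filter_cells <- function(records, keep_class = "interphase") {
  stopifnot(all(c("gene", "class") %in% names(records)))
  fractions <- records |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      apoptotic_fraction = mean(.data$class == "apoptotic"),
      .groups = "drop"
    )
  cells <- dplyr::filter(records, .data$class == keep_class)
  empty <- setdiff(fractions$gene, unique(cells$gene))
  if (length(empty)) {
    warning("gene(s) with no '", keep_class, "' cells after filtering: ",
            paste(empty, collapse = ", "))
  }
  list(cells = cells, class_fractions = fractions, empty_genes = empty)
}

#' Summarise a screen to per-gene values
#'
#' Computes the per-well median of the per-cell value, then the per-gene
#' mean of its wells' medians. Control wells (gene `"control"`) are kept
#' as per-well medians — not pooled — and their median is the control
#' reference; per-gene deltas are taken against it.
#'
#' @param records Per-cell tibble (`well`, `gene`, `sirna`, value column).
#' @param value_col Name of the per-cell value column.
#' @return A `"screen_summary"` list: `genes` tibble (`gene`, `n_wells`,
#'   `value`, `delta`, `excluded`, `reason`), `control_wells` tibble, and
#'   `control_reference` scalar.
#' @export
summarize_screen <- function(records, value_col = "aspect_ratio") {
  stopifnot(all(c("well", "gene", value_col) %in% names(records)))
  if (!any(records$gene == "control")) stop("at least one control well required")
  well_medians <- records |>
    dplyr::group_by(.data$gene, .data$well) |>
    dplyr::summarise(median_value = stats::median(.data[[value_col]]),
                     n_cells = dplyr::n(), .groups = "drop")
  control_wells <- well_medians |>
    dplyr::filter(.data$gene == "control") |>
    dplyr::select("well", "median_value", "n_cells") |>
    dplyr::arrange(.data$well)
  control_reference <- stats::median(control_wells$median_value)
  genes <- well_medians |>
    dplyr::filter(.data$gene != "control") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_wells = dplyr::n(), value = mean(.data$median_value),
                     .groups = "drop") |>
    dplyr::mutate(delta = .data$value - control_reference,
                  excluded = FALSE, reason = NA_character_) |>
    dplyr::arrange(.data$gene)
  structure(list(genes = genes, control_wells = control_wells,
                 control_reference = control_reference,
                 value_col = value_col),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary> %d gene(s), %d control well(s), control reference %.3f\n",
              nrow(x$genes), nrow(x$control_wells), x$control_reference))
  invisible(x)
}

#' Exclude genes with excess apoptosis
#'
#' Genes whose apoptotic fraction is strictly greater than `threshold`
#' (more than 20% by default) are marked excluded with reason
#' `"apoptosis"`; a fraction of exactly the threshold is retained.
#'
#' @param summary A [summarize_screen()] result.
#' @param class_fractions Per-gene fractions from [filter_cells()].
#' @param threshold Exclusion threshold on the apoptotic fraction.
#' @return The updated `"screen_summary"`.
#' @export
exclude_genes <- function(summary, class_fractions, threshold = 0.2) {
  stopifnot(inherits(summary, "screen_summary"),
            all(class_fractions$apoptotic_fraction >= 0),
            all(class_fractions$apoptotic_fraction <= 1))
  frac <- stats::setNames(class_fractions$apoptotic_fraction,
                          class_fractions$gene)
  g <- summary$genes
  hit <- !is.na(frac[g$gene]) & frac[g$gene] > threshold
  g$excluded <- g$excluded | unname(hit)
  g$reason <- ifelse(unname(hit) & is.na(g$reason), "apoptosis", g$reason)
  summary$genes <- g
  summary
}

#' Rank genes inducing nucleolar rounding
#'
#' Orders non-excluded genes by ascending per-gene value (aspect ratios
#' closer to 1 mean rounder nucleoli) and returns the top `k` with their
#' deltas versus the control reference. Ties are broken by gene
#' identifier, making the ranking deterministic.
#'
#' @param summary A [summarize_screen()] (optionally
#'   [exclude_genes()]-filtered) result.
#' @param k Number of top genes.
#' @return Tibble (`rank`, `gene`, `value`, `delta`).
#' @export
rank_rounding_hits <- function(summary, k = 20L) {
  stopifnot(inherits(summary, "screen_summary"))
  pool <- dplyr::filter(summary$genes, !.data$excluded)
  if (nrow(pool) < k) {
    stop("only ", nrow(pool), " non-excluded gene(s); cannot rank top ", k)
  }
  pool |>
    dplyr::arrange(.data$value, .data$gene) |>
    utils::head(k) |>
    dplyr::transmute(rank = dplyr::row_number(), gene = .data$gene,
                     value = .data$value, delta = .data$delta)
}
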
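# Efficiency-corrected Ct arithmetic for qPCR expression of the symbiont's
# RIP toxin genes.

#' Efficiency-correct Ct values
#'
#' A primer pair with fractional efficiency E amplifies by a factor (1 + E)
#' per cycle, so Ct values measured at different efficiencies are put on a
#' common doubling scale as `ct * log2(1 + E)`; at perfect efficiency
#' (E = 1) the correction is the identity. The `literal` flag instead
#' applies `ct * log2(E)` — the form sometimes printed in methods sections —
#' which collapses to ~0 at E near 1 and exists only for auditability.
#'
#' @param data tibble with columns `ct` and `efficiency`; an `efficiency`
#'   of NA for gene `RIP1` (when a `gene` column is present) defaults to
#'   0.995
#' @param literal use the literal `log2(E)` form (default `FALSE`)
#' @return `data` with a `corrected_ct` column appended
#' @export
#' @examples
#' correct_ct(tibble::tibble(ct = 20, efficiency = 0.995))
correct_ct <- function(data, literal = FALSE) {
  eff <- data$efficiency
  if ("gene" %in% names(data)) {
    eff[is.na(eff) & data$gene == "RIP1"] <- 0.995
  }
  if (anyNA(eff)) abort("missing efficiencies (only RIP1 has a default)")
  if (any(eff <= 0 | eff > 1.2)) abort("efficiencies must lie in (0, 1.2]")
  fac <- if (literal) log2(eff) else log2(1 + eff)
  mutate(data, efficiency = eff, corrected_ct = .data$ct * fac)
}

#' Reference-corrected delta-Ct per sample and target gene
#'
#' Computes `delta = corrected Ct(reference) - corrected Ct(target)` for
#' every non-reference gene of every sample, so larger deltas mean higher
#' target expression relative to the reference (the symbiont housekeeping
#' gene rpoB by default). Ct values are efficiency-corrected first via
#' [correct_ct()].
#'
#' @param data tibble with columns `sample_id`, `gene`, `ct`, `efficiency`
#' @param reference_gene reference gene name (default `"rpoB"`)
#' @param literal passed to [correct_ct()]
#' @return tibble: `sample_id`, `gene`, `corrected_ct_gene`,
#'   `corrected_ct_reference`, `delta`
#' @export
delta_ct <- function(data, reference_gene = "rpoB", literal = FALSE) {
  corr <- correct_ct(data, literal = literal)
  refs <- corr |>
    filter(.data$gene == reference_gene) |>
    select("sample_id", corrected_ct_reference = "corrected_ct")
  if (anyDuplicated(refs$sample_id)) {
    abort("multiple reference-gene rows for one sample; average Cts upstream")
  }
  targets <- corr # the reference row itself yields delta = 0
  missing_ref <- setdiff(unique(targets$sample_id), refs$sample_id)
  if (length(missing_ref)) {
    abort(paste("no", reference_gene, "row for sample(s):",
                paste(missing_ref, collapse = ", ")))
  }
  targets |>
    left_join(refs, by = "sample_id") |>
    mutate(delta = .data$corrected_ct_reference - .data$corrected_ct) |>
    select("sample_id", "gene", corrected_ct_gene = "corrected_ct",
           "corrected_ct_reference", "delta")
}
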
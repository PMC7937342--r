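# Direction-stratified set logic over the blue/red/green contrasts, and the
# expression-shape classifiers for the "restored" (A/B), symbiont-boosted
# (C) and male-gonad patterns.

.region_levels <- c("blue", "red", "green", "blue_red", "blue_green",
                    "red_green", "blue_red_green")

#' Direction-stratified Venn partition of three DE contrasts
#'
#' Builds SEPARATE membership partitions for up- and down-regulated genes
#' over the blue/red/green contrasts. A gene may legitimately occupy regions
#' in both partitions — e.g. down-exclusive in green while up-exclusive in
#' red, the signature of a "restored" gene — which a single gene-level Venn
#' cannot represent. Thresholds are applied via [de_filter()] before
#' partitioning.
#'
#' @param blue,red,green DE tibbles (`gene_id`, `log2fc`, `fdr`)
#' @param lfc_min,fdr_max significance thresholds passed to [de_filter()]
#' @return tibble of class `venn_partition` with `gene_id`, `direction`
#'   (`up`/`down`), `region` (one of blue, red, green, blue_red, blue_green,
#'   red_green, blue_red_green)
#' @export
venn_partition <- function(blue, red, green, lfc_min = 0.58, fdr_max = 0.05) {
  sets <- list(blue = blue, red = red, green = green)
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]]$gene_id)) {
      abort(sprintf("duplicate gene ids in the %s contrast", nm))
    }
  }
  sig <- purrr::map(sets, de_filter, lfc_min = lfc_min, fdr_max = fdr_max)
  one_direction <- function(dir) {
    members <- purrr::map(sig, function(d) d$gene_id[d$direction == dir])
    genes <- unique(unlist(members))
    if (!length(genes)) {
      return(tibble(gene_id = character(), direction = character(), region = character()))
    }
    inb <- genes %in% members$blue
    inr <- genes %in% members$red
    ing <- genes %in% members$green
    region <- paste0(ifelse(inb, "blue", ""),
                     ifelse(inr, "_red", ""),
                     ifelse(ing, "_green", ""))
    region <- sub("^_", "", region)
    tibble(gene_id = genes, direction = dir, region = region)
  }
  out <- bind_rows(one_direction("up"), one_direction("down"))
  out$region <- factor(out$region, levels = .region_levels)
  class(out) <- c("venn_partition", class(out))
  out
}

#' Region counts of a Venn partition
#'
#' @param partition a [venn_partition()] result
#' @return tibble with one row per direction x region and its gene count
#' @export
venn_counts <- function(partition) {
  as_tibble(partition) |>
    dplyr::count(.data$direction, .data$region, .drop = FALSE, name = "n_genes")
}

# per-gene z-scores of log2(TMM CPM + 1) and treatment means for the four
# relevant treatments at one time point
.treatment_zmeans <- function(expr, design, wasp = "lh", time = "T2") {
  d <- design[design$time == time & design$wasp %in% c("none", wasp), , drop = FALSE]
  d$treatment <- dplyr::case_when(
    d$spiroplasma == "absent" & d$wasp == "none" ~ "S-W-",
    d$spiroplasma == "present" & d$wasp == "none" ~ "S+W-",
    d$spiroplasma == "absent" ~ "S-wasp",
    TRUE ~ "S+wasp"
  )
  needed <- c("S-W-", "S+W-", "S-wasp", "S+wasp")
  if (!all(needed %in% d$treatment)) {
    abort(paste("expression design must cover the four treatments:",
                paste(setdiff(needed, d$treatment), collapse = ", "), "missing"))
  }
  sub <- expr[, d$sample_id, drop = FALSE]
  lg <- log2(sub + 1)
  mu <- rowMeans(lg)
  s <- apply(lg, 1, sd)
  z <- sweep(sweep(lg, 1, mu), 1, pmax(s, 1e-8), "/")
  zm <- vapply(needed, function(tr) {
    rowMeans(z[, d$sample_id[d$treatment == tr], drop = FALSE])
  }, numeric(nrow(z)))
  colnames(zm) <- c("z_swm", "z_spwm", "z_swasp", "z_spwasp")
  zm
}

#' Classify genes into the interaction expression groups
#'
#' Combines Venn-region membership with the expression shape over the four
#' treatments (symbiont absent/present x wasp absent/present):
#' * **A** — exclusively down in green and exclusively up in red: the wasp
#'   induces the gene, the symbiont restores it to control levels.
#' * **B** — exclusively up in green and exclusively down in red: the
#'   mirror-image restored pattern. Genes up in blue-and-green whose red set
#'   is exclusively down are annotated `B_like` rather than merged into B.
#' * **C** — up in green (green-only or red-and-green) with the highest
#'   z-mean in the symbiont+wasp treatment, exceeding every other treatment
#'   mean by at least `delta`, the other three means within `epsilon` of
#'   each other.
#' * **male_gonad_pattern** — optional, see [male_gonad_pattern()].
#'
#' z-scores are computed per gene over all samples of the time point from
#' `log2(normalized expression + 1)`.
#'
#' @param partition a [venn_partition()] result
#' @param expr normalized expression matrix (e.g. `cpm(counts, tmm_factors(counts))`)
#' @param design design tibble
#' @param wasp,time treatment slice to classify on
#' @param delta minimum z-unit separation (default 0.5)
#' @param epsilon maximum z-unit spread for "levels similar to each other"
#'   (default 0.75)
#' @param include_male_gonad also flag the male-gonad ordering pattern
#' @return tibble: `gene_id`, `group` (`A`, `B`, `B_like`, `C`,
#'   `male_gonad_pattern`, `unclassified`), `up_region`, `down_region`, the
#'   four treatment z-means
#' @export
classify_groups <- function(partition, expr, design, wasp = "lh", time = "T2",
                            delta = 0.5, epsilon = 0.75,
                            include_male_gonad = TRUE) {
  part <- as_tibble(partition) |> mutate(region = as.character(.data$region))
  up <- part[part$direction == "up", c("gene_id", "region")]
  dn <- part[part$direction == "down", c("gene_id", "region")]
  names(up)[2] <- "up_region"; names(dn)[2] <- "down_region"
  genes <- tibble(gene_id = rownames(expr)) |>
    left_join(up, by = "gene_id") |>
    left_join(dn, by = "gene_id")

  zm <- .treatment_zmeans(expr, design, wasp = wasp, time = time)
  genes <- bind_cols(genes, as_tibble(zm))

  up_reg <- genes$up_region
  dn_reg <- genes$down_region

  others_max <- pmax(genes$z_swm, genes$z_spwm, genes$z_swasp)
  others_min <- pmin(genes$z_swm, genes$z_spwm, genes$z_swasp)
  c_shape <- (genes$z_spwasp - others_max >= delta) &
    (others_max - others_min <= epsilon)

  group <- dplyr::case_when(
    !is.na(dn_reg) & dn_reg == "green" & !is.na(up_reg) & up_reg == "red" ~ "A",
    !is.na(up_reg) & up_reg == "green" & !is.na(dn_reg) & dn_reg == "red" ~ "B",
    !is.na(up_reg) & up_reg == "blue_green" & !is.na(dn_reg) & dn_reg == "red" ~ "B_like",
    !is.na(up_reg) & up_reg %in% c("green", "red_green") & c_shape ~ "C",
    TRUE ~ "unclassified"
  )
  genes$group <- group

  if (include_male_gonad) {
    mg <- male_gonad_pattern(expr, design, wasp = wasp, time = time,
                             delta = delta, epsilon = epsilon)
    genes$group[genes$group == "unclassified" &
                  genes$gene_id %in% mg$gene_id] <- "male_gonad_pattern"
  }
  dplyr::relocate(genes, "gene_id", "group")
}

#' Flag the male-gonad expression ordering
#'
#' Detects genes whose treatment means follow `S-W- > S-wasp > S+W- = S+wasp`
#' in z-units: the pattern expected of male-biased transcripts when the
#' symbiont kills males outright and the wasp depletes them partially. The
#' inequalities require a gap of at least `delta`; the "=" tolerates a
#' difference up to `epsilon`.
#'
#' @inheritParams classify_groups
#' @param expr normalized expression matrix
#' @return tibble of flagged genes with their treatment z-means
#' @export
male_gonad_pattern <- function(expr, design, wasp = "lh", time = "T2",
                               delta = 0.5, epsilon = 0.75) {
  zm <- as_tibble(.treatment_zmeans(expr, design, wasp = wasp, time = time))
  zm$gene_id <- rownames(expr)
  flag <- (zm$z_swm - zm$z_swasp >= delta) &
    (zm$z_swasp - pmax(zm$z_spwm, zm$z_spwasp) >= delta) &
    (abs(zm$z_spwm - zm$z_spwasp) <= epsilon)
  dplyr::relocate(zm[flag, , drop = FALSE], "gene_id")
}

#' Merge rows of nucleotide-identical genes
#'
#' Multi-copy genes that are identical at the nucleotide level (e.g. the
#' RIP3/RIP4/RIP5 toxin copies) cannot be quantified separately; their
#' counts are summed into a single labelled row (`"RIP3-5"`-style). All
#' other rows pass through untouched; the matrix total is conserved.
#'
#' @param counts gene-by-sample count matrix
#' @param groups named list: label -> character vector of gene ids to merge
#' @return count matrix with merged rows (merged labels appended last)
#' @export
#' @examples
#' m <- matrix(c(2, 3, 1, 0, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("RIP3", "RIP4", "RIP5"), c("s1", "s2")))
#' aggregate_identical_genes(m, list("RIP3-5" = c("RIP3", "RIP4", "RIP5")))
aggregate_identical_genes <- function(counts, groups = list()) {
  if (!length(groups)) return(counts)
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) abort("gene groups must be disjoint")
  missing <- setdiff(all_ids, rownames(counts))
  if (length(missing)) {
    abort(paste("genes not in matrix:", paste(missing, collapse = ", ")))
  }
  merged <- do.call(rbind, lapply(groups, function(ids) {
    colSums(counts[ids, , drop = FALSE])
  }))
  rownames(merged) <- names(groups)
  rest <- counts[!rownames(counts) %in% all_ids, , drop = FALSE]
  rbind(rest, merged)
}
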
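# Built-in differential-expression stage: a per-gene negative-binomial
# likelihood-ratio test at a single common dispersion. The set-logic stage
# accepts DE tables from any external tool; this stage exists so the whole
# pipeline is testable end to end without external software.

#' Samples entering one of the three interaction contrasts
#'
#' The three contrasts of the factorial design, named as in the study's
#' colour scheme: `blue` = symbiont effect without wasp (S-W- vs S+W-),
#' `red` = wasp effect without symbiont (S-W- vs S-wasp), `green` = symbiont
#' effect within wasp-parasitised hosts (S-wasp vs S+wasp). Fold-changes are
#' oriented second-group-over-first, so `log2fc > 0` means higher expression
#' in the symbiont-infected (blue, green) or parasitised (red) group.
#'
#' @param design design tibble (see [read_design()])
#' @param contrast `"blue"`, `"red"` or `"green"`
#' @param wasp which wasp treatment defines the parasitised groups
#' @param time time point to use
#' @return list with character vectors `group1`, `group2` of sample ids
#' @export
contrast_samples <- function(design, contrast = c("blue", "red", "green"),
                             wasp = "lh", time = "T2") {
  contrast <- match.arg(contrast)
  d <- design[design$time == time, , drop = FALSE]
  pick <- function(sp, wa) d$sample_id[d$spiroplasma == sp & d$wasp == wa]
  out <- switch(contrast,
    blue = list(group1 = pick("absent", "none"), group2 = pick("present", "none")),
    red = list(group1 = pick("absent", "none"), group2 = pick("absent", wasp)),
    green = list(group1 = pick("absent", wasp), group2 = pick("present", wasp))
  )
  if (!length(out$group1) || !length(out$group2)) {
    abort(sprintf("contrast '%s' has an empty group for wasp='%s', time='%s'",
                  contrast, wasp, time))
  }
  out
}

# maximum-likelihood NB mean per gene for one sample set, at fixed
# dispersion phi and per-sample size factors s; Newton iterations on log(m),
# vectorised over genes. Returns the per-gene mean and total log-likelihood.
.nb_group_fit <- function(Y, s, phi, iter = 50L) {
  A <- rowSums(Y)
  S <- sum(s)
  m <- A / S # exact MLE when phi = 0
  if (phi > 0) {
    k <- 1 / phi
    pos <- A > 0
    t <- log(m[pos])
    Yp <- Y[pos, , drop = FALSE]
    for (i in seq_len(iter)) {
      Mm <- exp(t) %o% s * phi
      den <- 1 + Mm
      g <- A[pos] - rowSums((Yp + k) * Mm / den)
      gp <- -rowSums((Yp + k) * Mm / den^2)
      step <- g / gp
      step[!is.finite(step)] <- 0
      t <- t - pmax(pmin(step, 5), -5)
      if (max(abs(g)) < 1e-10 * (max(A) + 1)) break
    }
    m[pos] <- exp(t)
  }
  mu <- pmax(m %o% s, 1e-300)
  dens <- if (phi > 0) {
    stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE)
  } else {
    stats::dpois(Y, mu, log = TRUE)
  }
  list(mean = m, loglik = rowSums(matrix(dens, nrow = nrow(Y))))
}

# pooled method-of-moments common dispersion on counts scaled to a common
# library size: phi = sum(var - mean) / sum(mean^2) over genes, pooled
# within groups, truncated at zero.
.common_dispersion <- function(norm_counts, group) {
  num <- 0; den <- 0
  for (gl in unique(group)) {
    sub <- norm_counts[, group == gl, drop = FALSE]
    if (ncol(sub) < 2L) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ok <- m > 1
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  max(num / max(den, 1e-12), 0)
}

#' Negative-binomial likelihood-ratio differential expression for one contrast
#'
#' Applies the <1-CPM-in-all-replicates filter, computes TMM factors over
#' the comparison's samples, estimates a single common dispersion by pooled
#' moment matching on normalized counts, then tests each gene with a
#' likelihood-ratio chi-square (df 1) between intercept-only and two-group
#' NB GLMs with effective-library-size offsets. FDR is Benjamini-Hochberg.
#'
#' @param counts gene-by-sample count matrix
#' @param design design tibble with `sample_id`, `spiroplasma`, `wasp`,
#'   `time`
#' @param contrast `"blue"`, `"red"` or `"green"`
#' @param wasp,time passed to [contrast_samples()]
#' @param allow_no_replication fit anyway with one replicate per side
#'   (dispersion cannot be estimated; Poisson is assumed). Default `FALSE`.
#' @return tibble with `gene_id`, `log2fc`, `lrt`, `p_value`, `fdr`,
#'   `direction`, `contrast`; the dispersion used is attached as attribute
#'   `"dispersion"`
#' @export
reference_de <- function(counts, design, contrast = c("blue", "red", "green"),
                         wasp = "lh", time = "T2",
                         allow_no_replication = FALSE) {
  contrast <- match.arg(contrast)
  cs <- contrast_samples(design, contrast, wasp = wasp, time = time)
  if ((length(cs$group1) < 2L || length(cs$group2) < 2L) && !allow_no_replication) {
    abort("a contrast side has fewer than 2 replicates; set allow_no_replication = TRUE to force")
  }
  samples <- c(cs$group1, cs$group2)
  grp <- factor(rep(c("g1", "g2"), c(length(cs$group1), length(cs$group2))),
                levels = c("g1", "g2"))
  keep <- cpm_filter(counts, samples)
  sub <- counts[keep, samples, drop = FALSE]
  f <- tmm_factors(sub)
  eff_lib <- colSums(sub) * f
  norm <- sweep(sub, 2, eff_lib / mean(eff_lib), "/")
  phi <- .common_dispersion(norm, grp)

  s <- eff_lib / mean(eff_lib)
  g1 <- grp == "g1"
  fit1 <- .nb_group_fit(sub[, g1, drop = FALSE], s[g1], phi)
  fit2 <- .nb_group_fit(sub[, !g1, drop = FALSE], s[!g1], phi)
  fit0 <- .nb_group_fit(sub, s, phi)
  lrt <- pmax(0, 2 * (fit1$loglik + fit2$loglik - fit0$loglik))
  # fold-change reported with a small continuity prior so all-zero groups
  # stay finite; the LRT itself uses the exact MLEs
  pseudo <- 0.125
  m1 <- (rowSums(sub[, g1, drop = FALSE]) + pseudo) / sum(s[g1])
  m2 <- (rowSums(sub[, !g1, drop = FALSE]) + pseudo) / sum(s[!g1])
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  out <- tibble(
    gene_id = rownames(sub),
    log2fc = log2(m2 / m1),
    lrt = lrt,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
  ) |>
    mutate(direction = ifelse(.data$log2fc >= 0, "up", "down"),
           contrast = contrast)
  attr(out, "dispersion") <- phi
  out
}

#' Apply the DE significance thresholds
#'
#' A gene is differentially expressed when `|log2fc| >= lfc_min` and
#' `fdr < fdr_max` (defaults 0.58, i.e. 1.5-fold, and 0.05). Relaxing either
#' threshold never removes a previously DE gene.
#'
#' @param de DE tibble (`gene_id`, `log2fc`, `fdr`)
#' @param lfc_min minimum absolute log2 fold-change
#' @param fdr_max FDR cutoff (exclusive)
#' @return the DE rows passing both thresholds
#' @export
de_filter <- function(de, lfc_min = 0.58, fdr_max = 0.05) {
  de[abs(de$log2fc) >= lfc_min & de$fdr < fdr_max, , drop = FALSE]
}
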
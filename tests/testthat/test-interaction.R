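# Expression-shape classification over the four treatments.

# build a 16-sample design and an expression matrix with specified
# per-treatment log2 means (+ small deterministic jitter)
shape_fixture <- function(means_by_gene, noise = 0.05) {
  design <- tidyr::crossing(
    tibble::tibble(spiroplasma = c("absent", "present", "absent", "present"),
                   wasp = c("none", "none", "lh", "lh")),
    replicate = 1:4
  ) |>
    dplyr::mutate(time = "T2",
                  sample_id = paste0(spiroplasma, "_", wasp, "_", replicate))
  treat <- paste0(design$spiroplasma, "_", design$wasp)
  key <- c(absent_none = 1, present_none = 2, absent_lh = 3, present_lh = 4)
  expr <- t(vapply(means_by_gene, function(mu4) {
    jit <- rep(c(-1, 1, -0.5, 0.5) * noise, times = 4)
    2^(mu4[key[treat]] + jit)
  }, numeric(nrow(design))))
  colnames(expr) <- design$sample_id
  rownames(expr) <- names(means_by_gene)
  list(expr = expr, design = design)
}

test_that("the restored and boosted expression patterns are classified", {
  # means in order (S-W-, S+W-, S-lh, S+lh), log2 scale
  fx <- shape_fixture(list(
    gA = c(5, 5, 8, 5),      # wasp-induced, symbiont-restored
    gB = c(8, 8, 5, 8),      # wasp-suppressed, symbiont-restored
    gC = c(5, 5, 5, 8),      # boosted only with symbiont AND wasp
    gFlat = c(6, 6, 6, 6)
  ))
  de <- list(
    blue = tibble::tibble(gene_id = character(0), log2fc = numeric(0),
                          fdr = numeric(0), direction = character(0)),
    red = tibble::tibble(gene_id = c("gA", "gB"), log2fc = c(3, -3),
                         fdr = 1e-6, direction = c("up", "down")),
    green = tibble::tibble(gene_id = c("gA", "gB", "gC"), log2fc = c(-3, 3, 3),
                           fdr = 1e-6, direction = c("down", "up", "up"))
  )
  part <- venn_partition(de$blue, de$red, de$green)
  cls <- classify_groups(part, fx$expr, fx$design)
  got <- setNames(cls$group, cls$gene_id)
  expect_equal(unname(got["gA"]), "A")
  expect_equal(unname(got["gB"]), "B")
  expect_equal(unname(got["gC"]), "C")
  expect_equal(unname(got["gFlat"]), "unclassified")
})

test_that("a gene up in red only stays unclassified", {
  fx <- shape_fixture(list(gRed = c(5, 5, 8, 8), gNull = c(6, 6, 6, 6)))
  de_red <- tibble::tibble(gene_id = "gRed", log2fc = 3, fdr = 1e-6,
                           direction = "up")
  empty <- de_red[0, ]
  part <- venn_partition(empty, de_red, empty)
  cls <- classify_groups(part, fx$expr, fx$design)
  expect_true(all(cls$group == "unclassified"))
})

test_that("blue-and-green upregulated genes with the B shape are B-like", {
  fx <- shape_fixture(list(gFbp = c(8, 9, 5, 9), gPad = c(6, 6, 6, 6)))
  de <- list(
    blue = tibble::tibble(gene_id = "gFbp", log2fc = 1, fdr = 1e-6, direction = "up"),
    red = tibble::tibble(gene_id = "gFbp", log2fc = -3, fdr = 1e-6, direction = "down"),
    green = tibble::tibble(gene_id = "gFbp", log2fc = 4, fdr = 1e-6, direction = "up")
  )
  part <- venn_partition(de$blue, de$red, de$green)
  cls <- classify_groups(part, fx$expr, fx$design)
  expect_equal(cls$group[cls$gene_id == "gFbp"], "B_like")
})

test_that("group C requires the boosted-only expression shape", {
  # up in green but S+W- is also high: 'others similar' fails
  fx <- shape_fixture(list(gNotC = c(5, 8, 5, 9), gPad = c(6, 6, 6, 6)))
  de_green <- tibble::tibble(gene_id = "gNotC", log2fc = 3, fdr = 1e-6,
                             direction = "up")
  empty <- de_green[0, ]
  part <- venn_partition(empty, empty, de_green)
  cls <- classify_groups(part, fx$expr, fx$design)
  expect_equal(cls$group[cls$gene_id == "gNotC"], "unclassified")
})

test_that("the male-gonad ordering is flagged and its violations are not", {
  fx <- shape_fixture(list(
    gMale = c(8, 3, 6, 3),     # S-W- > S-lh > S+W- = S+lh
    gEqual = c(6, 6, 6, 6),    # all equal
    gWrong = c(6, 3, 8, 3)     # S-lh highest: ordering violated
  ))
  mg <- male_gonad_pattern(fx$expr, fx$design)
  expect_true("gMale" %in% mg$gene_id)
  expect_false("gEqual" %in% mg$gene_id)
  expect_false("gWrong" %in% mg$gene_id)
})

test_that("classification is invariant to per-sample rescaling", {
  sim <- simulate_counts(n_genes = 600, seed = 17)
  de <- lapply(c("blue", "red", "green"), function(ctr)
    reference_de(sim$counts, sim$design, ctr))
  part <- venn_partition(de[[1]], de[[2]], de[[3]])
  expr1 <- cpm(sim$counts, tmm_factors(sim$counts))
  cls1 <- classify_groups(part, expr1, sim$design)

  scaled <- sweep(sim$counts, 2, c(rep(3, 8), rep(1, 8)), "*")
  expr2 <- cpm(scaled, tmm_factors(scaled))
  cls2 <- classify_groups(part, expr2, sim$design)
  expect_equal(cls1$group, cls2$group)
})

test_that("a missing treatment is a configuration error", {
  fx <- shape_fixture(list(g1 = c(5, 5, 5, 5)))
  broken <- fx$design[fx$design$wasp == "none", ]
  empty <- tibble::tibble(gene_id = character(0), log2fc = numeric(0),
                          fdr = numeric(0), direction = character(0))
  part <- venn_partition(empty, empty, empty)
  expect_error(
    classify_groups(part, fx$expr[, broken$sample_id, drop = FALSE], broken),
    "four treatments")
})
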
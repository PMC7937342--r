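test_that("the synthetic reference embeds the motif exactly once", {
  for (seed in c(1, 2, 99)) {
    ref <- srl_reference(seed = seed)
    expect_equal(nchar(ref$sequence), 400)
    hits <- gregexpr("TACGAGAGGAACC", ref$sequence, fixed = TRUE)[[1]]
    expect_equal(length(hits), 1)
    expect_false(hits[1] == -1)
  }
})

test_that("noise-free limits: no depurination shows all A, saturation all T", {
  rd0 <- simulate_reads(n_reads = 500, depurination_rate = 0, error_rate = 0,
                        seed = 3)
  cb0 <- count_bases(assign_reads(rd0), "s")
  expect_equal(cb0$a, cb0$total_ungapped)
  expect_gt(cb0$total_ungapped, 0)

  rd1 <- simulate_reads(n_reads = 500, depurination_rate = 1, error_rate = 0,
                        seed = 3)
  cb1 <- count_bases(assign_reads(rd1), "s")
  expect_equal(cb1$t, cb1$total_ungapped)
})

test_that("read simulation is byte-identical for a fixed seed", {
  a <- simulate_reads(n_reads = 100, depurination_rate = 0.2,
                      error_rate = 0.01, seed = 42, replicates = 2)
  b <- simulate_reads(n_reads = 100, depurination_rate = 0.2,
                      error_rate = 0.01, seed = 42, replicates = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_reads(n_reads = 100, depurination_rate = 0.2,
                      error_rate = 0.01, seed = 43, replicates = 2)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("the truth table is sufficient to score the caller", {
  rd <- simulate_reads(n_reads = 1000, depurination_rate = 0.25,
                       error_rate = 0, seed = 10)
  truth <- attr(rd, "truth")
  expect_equal(truth$depurination_rate, 0.25)
  # reads marked depurinated carry T at the target; others carry A
  calls <- assign_reads(rd)
  joined <- dplyr::left_join(calls, rd, by = c(read_id = "id"))
  retained <- joined[joined$retained, ]
  expect_true(all(retained$base[retained$depurinated] == "T"))
  expect_true(all(retained$base[!retained$depurinated] == "A"))
})

test_that("count simulation matches its negative-binomial moments", {
  sim <- simulate_counts(n_genes = 3000, bcv = 0.35, seed = 19,
                         classes = list(none = list(n = 0L, effect = 0)))
  # pooled moment estimate of phi across genes within one treatment
  sub <- sim$counts[, sim$design$sample_id[sim$design$spiroplasma == "absent" &
                                             sim$design$wasp == "none"]]
  m <- rowMeans(sub)
  v <- apply(sub, 1, var)
  ok <- m > 20
  phi_hat <- sum(v[ok] - m[ok]) / sum(m[ok]^2)
  expect_equal(phi_hat, 0.1225, tolerance = 0.25)

  # bcv = 0 reduces to Poisson: variance ~ mean
  simp <- simulate_counts(n_genes = 3000, bcv = 0, seed = 20,
                          classes = list(none = list(n = 0L, effect = 0)))
  subp <- simp$counts[, 1:4]
  mp <- rowMeans(subp); vp <- apply(subp, 1, var)
  okp <- mp > 20
  expect_equal(sum(vp[okp] - mp[okp]) / sum(mp[okp]^2), 0, tolerance = 0.02)
})

test_that("planted classes land in the promised contrasts", {
  sim <- simulate_counts(seed = 23)
  tr <- sim$truth
  expect_true(all(tr$log2fc_red[tr$class == "group_A"] == 2))
  expect_true(all(tr$log2fc_green[tr$class == "group_A"] == -2))
  expect_true(all(tr$log2fc_blue[tr$class == "group_A"] == 0))
  expect_true(all(tr$log2fc_green[tr$class == "group_C"] == 3))
  expect_true(all(tr$log2fc_red[tr$class == "group_C"] == 0))
  expect_true(all(tr$log2fc_blue[tr$class == "male_biased"] == -5))
  expect_true(all(tr$class[tr$log2fc_blue == 0 & tr$log2fc_red == 0 &
                             tr$log2fc_green == 0] %in%
                    c("null")))
  # truth, design and counts are mutually consistent
  expect_equal(rownames(sim$counts), tr$gene_id)
  expect_equal(colnames(sim$counts), sim$design$sample_id)
})

test_that("simulated studies write and read back from disk", {
  sim <- simulate_counts(n_genes = 400, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_sim_counts(sim, dir)
  expect_equal(read_count_matrix(paths["counts"]), sim$counts + 0)
  expect_equal(read_design(paths["design"])$sample_id, sim$design$sample_id)
})

test_that("estimated adenine fraction is unbiased for (1-d)(1-eps)", {
  d <- 0.3; eps <- 0.005
  ref <- srl_reference(seed = 55)
  af <- vapply(1:60, function(r) {
    rd <- simulate_reads(n_reads = 800, depurination_rate = d, error_rate = eps,
                         seed = 1000 + r, reference = ref)
    estimate_depurination(count_bases(assign_reads(rd), "s"))$adenine_fraction
  }, numeric(1))
  truth <- (1 - d) * (1 - eps)
  n_eff <- 800 * 0.4 # ~fraction of reads covering the target
  mc_se <- sqrt(truth * (1 - truth) / n_eff) / sqrt(60)
  expect_lt(abs(mean(af) - truth), 4 * mc_se)
})
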
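# Synthetic-data generators emulating the study's inputs: stranded 125 bp
# reads over an SRL-bearing rRNA fragment with a controllable A->T shift,
# factorial negative-binomial count matrices with planted gene classes, and
# qPCR Ct tables. Every generator emits a truth table sufficient to score
# recovery without re-reading its configuration.

#' Synthetic rRNA fragment containing the SRL motif once
#'
#' Random flanks around the conserved 13-mer, rejected and resampled until
#' the motif — and its target-wildcarded anchor pattern — occur exactly once
#' on the forward strand and never on the reverse complement, so raw-read
#' anchoring is unambiguous. The true wasp 28S flanking sequence is not used;
#' only the motif context is real.
#'
#' @param length fragment length in bases (default 400)
#' @param target an [srl_target()]
#' @param seed RNG seed
#' @return one-row reference tibble (`id`, `sequence`)
#' @export
srl_reference <- function(length = 400L, target = srl_target(), seed = 1L) {
  motif <- target$motif
  if (length < nchar(motif) + 2L) abort("reference too short for the motif")
  off <- target$target_offset
  anchor <- paste0(substr(motif, 1, off), "[ACGTN]",
                   substr(motif, off + 2, nchar(motif)))
  with_seed(seed, {
    repeat {
      flank_n <- length - nchar(motif)
      left_n <- flank_n %/% 2
      bases <- c("A", "C", "G", "T")
      seq <- paste0(
        paste(sample(bases, left_n, replace = TRUE), collapse = ""),
        motif,
        paste(sample(bases, flank_n - left_n, replace = TRUE), collapse = "")
      )
      fwd <- gregexpr(anchor, seq)[[1]]
      rev <- gregexpr(anchor, reverse_complement(seq))[[1]]
      if (length(fwd) == 1L && fwd[1] != -1L && rev[1] == -1L) break
    }
    tibble(id = "synthetic_28S_fragment", sequence = seq)
  })
}

#' Simulate stranded reads with RIP depurination signal
#'
#' Each read starts uniformly on the reference; a read covering the target
#' adenine carries `T` there with probability `depurination_rate` (the
#' rRNA-sense signature of reverse transcriptase inserting adenine opposite
#' the abasic site). Independent per-base sequencing errors at `error_rate`
#' substitute a uniform choice of the three alternative bases, applied after
#' the depurination substitution and never at the target position of a
#' depurinated read. Reads on the reverse strand are emitted
#' reverse-complemented.
#'
#' @param n_reads reads per replicate
#' @param depurination_rate probability d that a target-covering read is
#'   depurinated; may be a vector of length `replicates`
#' @param error_rate per-base error rate
#' @param seed base seed; replicate r uses the sub-stream `seed + 7919 * r`
#' @param replicates number of replicates to generate
#' @param reference one-row reference tibble (default [srl_reference()]
#'   seeded from `seed`)
#' @param read_length read length in bases (default 125)
#' @param strand_fraction_forward fraction of reads on the forward strand
#' @param target an [srl_target()]
#' @return tibble with `replicate`, `id`, `sequence`, `orientation`, and the
#'   truth columns `covers_target`, `depurinated`. Attributes: `"reference"`
#'   (the reference tibble), `"truth"` (per-replicate tibble of true rates).
#' @export
simulate_reads <- function(n_reads = 2000L, depurination_rate = 0,
                           error_rate = 0.001, seed = 1L, replicates = 1L,
                           reference = NULL, read_length = 125L,
                           strand_fraction_forward = 0.5,
                           target = srl_target()) {
  assert_scalar_number(depurination_rate, "depurination_rate", lower = 0, upper = 1)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.1)
  assert_scalar_number(strand_fraction_forward, "strand_fraction_forward",
                       lower = 0, upper = 1)
  if (is.null(reference)) reference <- srl_reference(seed = seed, target = target)
  refseq <- reference$sequence[[1]]
  L <- nchar(refseq)
  if (read_length > L) abort("read_length exceeds reference length")
  span <- locate_srl(reference, target)
  tpos1 <- span$target_pos + 1L # 1-based target position
  d_vec <- rep_len(depurination_rate, replicates)

  reps <- purrr::map(seq_len(replicates), function(r) {
    d <- d_vec[r]
    with_seed(seed + 7919L * r, {
      starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
      ends <- starts + read_length - 1L
      covers <- starts <= tpos1 & tpos1 <= ends
      depur <- covers & runif(n_reads) < d

      chars <- matrix(strsplit(paste(substring(refseq, starts, ends), collapse = ""),
                               "")[[1]],
                      nrow = n_reads, ncol = read_length, byrow = TRUE)
      tcol <- tpos1 - starts + 1L # per-read column of the target (when covered)
      if (any(depur)) chars[cbind(which(depur), tcol[depur])] <- "T"

      err <- matrix(runif(n_reads * read_length) < error_rate,
                    nrow = n_reads, ncol = read_length)
      if (any(depur)) err[cbind(which(depur), tcol[depur])] <- FALSE
      if (any(err)) {
        bases <- c("A", "C", "G", "T")
        alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                     c("A", "C", "T"), c("A", "C", "G"))
        cur <- match(chars[err], bases)
        chars[err] <- alt[cbind(cur, sample.int(3L, sum(err), replace = TRUE))]
      }
      seqs <- apply(chars, 1, paste, collapse = "")
      fwd <- runif(n_reads) < strand_fraction_forward
      seqs[!fwd] <- reverse_complement(seqs[!fwd])
      tibble(
        replicate = r,
        id = sprintf("rep%d_read%d", r, seq_len(n_reads)),
        sequence = seqs,
        orientation = ifelse(fwd, "forward", "reverse"),
        covers_target = covers,
        depurinated = depur
      )
    })
  })
  out <- bind_rows(reps)
  attr(out, "reference") <- reference
  attr(out, "truth") <- tibble(
    replicate = seq_len(replicates),
    depurination_rate = d_vec,
    error_rate = error_rate
  )
  out
}

#' Default planted-class layout for [simulate_counts()]
#'
#' Class sizes and log2 effects of the planted gene classes. Most effects
#' default to 4-fold (log2 effect 2), comfortably inside the detectable
#' range for four replicates at BCV 0.35; group C defaults to 8-fold
#' (`effect_c = 3`), emulating the strongly induced Turandot-like stress
#' effectors that define that class. The male-gonad profile plants log2 offsets
#' (0, -5, -2, -5) for (S-W-, S+W-, S-wasp, S+wasp): strong silencing when
#' the male-killing symbiont is present, partial depletion under wasp attack
#' alone.
#'
#' @param effect log2 effect size for the planted classes
#' @param effect_c log2 effect size for the symbiont-boosted group C class
#' @return named list of class definitions
#' @export
count_sim_classes <- function(effect = 2, effect_c = 3) {
  list(
    group_A = list(n = 20L, effect = effect),
    group_B = list(n = 20L, effect = effect),
    group_C = list(n = 20L, effect = effect_c),
    male_gonad_pattern = list(n = 20L, profile = c(0, -5, -2, -5)),
    male_biased = list(n = 80L, effect = -5),
    wasp_up = list(n = 60L, effect = effect),
    wasp_down = list(n = 60L, effect = -effect),
    spiroplasma_responsive = list(n = 60L, effect = effect)
  )
}

#' Simulate a factorial negative-binomial count matrix with planted classes
#'
#' Gene-wise negative-binomial draws with mean `mu` and variance
#' `mu + bcv^2 mu^2` over a 2x2 factorial design (symbiont absent/present x
#' wasp none/`wasp`) with `replicates` replicates per treatment. Planted
#' classes: wasp-responsive genes shift in both parasitised treatments
#' (red); symbiont-responsive genes shift in S+W- (blue); "restored" groups
#' A/B shift only in S-wasp, so the symbiont+wasp treatment returns to
#' control levels (opposite-signed red and green effects); group C genes
#' rise only in S+wasp (green); male-biased genes are silenced whenever the
#' male-killing symbiont is present; male-gonad-pattern genes follow
#' S-W- > S-wasp > S+W- = S+wasp.
#'
#' @param n_genes total genes (planted plus null)
#' @param bcv biological coefficient of variation (default 0.35)
#' @param replicates replicates per treatment (default 4)
#' @param seed RNG seed
#' @param classes planted-class layout from [count_sim_classes()]
#' @param baseline_log2_mean,baseline_log2_sd log2-normal distribution of
#'   per-gene baseline mean counts for null genes
#' @param planted_log2_mean,planted_log2_sd baseline distribution for
#'   planted-class genes; narrower and higher than the null background,
#'   since the expression classes the generator emulates were identified
#'   among well-detected genes in the first place
#' @param wasp,time design labels for the parasitised treatments
#' @return list with `counts` (matrix), `design` (tibble), `truth` (tibble:
#'   `gene_id`, `class`, `log2fc_blue`, `log2fc_red`, `log2fc_green`)
#' @export
simulate_counts <- function(n_genes = 2000L, bcv = 0.35, replicates = 4L,
                            seed = 1L, classes = count_sim_classes(),
                            baseline_log2_mean = 6.5, baseline_log2_sd = 1.8,
                            planted_log2_mean = 7.5, planted_log2_sd = 1.2,
                            wasp = "lh", time = "T2") {
  n_planted <- sum(vapply(classes, function(cl) cl$n, integer(1)))
  if (n_planted > n_genes) abort("planted classes exceed n_genes")
  treatments <- tibble(
    spiroplasma = c("absent", "present", "absent", "present"),
    wasp = c("none", "none", wasp, wasp)
  )
  design <- tidyr::crossing(treatments, replicate = seq_len(replicates)) |>
    mutate(
      time = time,
      sample_id = sprintf("S%s%s_%d",
                          ifelse(.data$spiroplasma == "present", "p", "m"),
                          ifelse(.data$wasp == "none", "Wm", .data$wasp),
                          .data$replicate)
    ) |>
    select("sample_id", "spiroplasma", "wasp", "time", "replicate")

  with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    class_lab <- rep("null", n_genes)
    i <- 1L
    for (nm in names(classes)) {
      n <- classes[[nm]]$n
      if (n > 0L) class_lab[i:(i + n - 1L)] <- nm
      i <- i + n
    }
    # log2 effect per gene x treatment; column order S-W-, S+W-, S-wasp, S+wasp
    E <- matrix(0, n_genes, 4,
                dimnames = list(gene_id, c("SmWm", "SpWm", "Smwasp", "Spwasp")))
    for (nm in names(classes)) {
      idx <- class_lab == nm
      cl <- classes[[nm]]
      if (nm == "male_gonad_pattern") {
        E[idx, ] <- matrix(cl$profile, sum(idx), 4, byrow = TRUE)
      } else if (nm == "male_biased") {
        E[idx, c("SpWm", "Spwasp")] <- cl$effect
      } else if (nm %in% c("wasp_up", "wasp_down")) {
        E[idx, c("Smwasp", "Spwasp")] <- cl$effect
      } else if (nm == "spiroplasma_responsive") {
        E[idx, "SpWm"] <- cl$effect
      } else if (nm == "group_A") {
        E[idx, "Smwasp"] <- cl$effect
      } else if (nm == "group_B") {
        E[idx, "Smwasp"] <- -cl$effect
      } else if (nm == "group_C") {
        E[idx, "Spwasp"] <- cl$effect
      }
    }
    planted <- class_lab != "null"
    mu0 <- numeric(n_genes)
    mu0[!planted] <- 2^rnorm(sum(!planted), baseline_log2_mean, baseline_log2_sd)
    mu0[planted] <- 2^rnorm(sum(planted), planted_log2_mean, planted_log2_sd)
    treat_col <- match(
      paste0(ifelse(design$spiroplasma == "present", "Sp", "Sm"),
             ifelse(design$wasp == "none", "Wm", "wasp")),
      colnames(E)
    )
    libfac <- runif(nrow(design), 0.85, 1.15)
    counts <- matrix(0L, n_genes, nrow(design),
                     dimnames = list(gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu <- mu0 * 2^E[, treat_col[j]] * libfac[j]
      counts[, j] <- if (bcv > 0) rnbinom(n_genes, mu = mu, size = 1 / bcv^2)
                     else stats::rpois(n_genes, mu)
    }
    truth <- tibble(
      gene_id = gene_id,
      class = class_lab,
      log2fc_blue = E[, "SpWm"] - E[, "SmWm"],
      log2fc_red = E[, "Smwasp"] - E[, "SmWm"],
      log2fc_green = E[, "Spwasp"] - E[, "Smwasp"]
    )
    list(counts = counts, design = design, truth = truth)
  })
}

#' Simulate a qPCR Ct table with known delta-Ct truth
#'
#' Builds raw Ct values whose efficiency-corrected delta-Ct equals the
#' requested `delta` for each (sample, gene), then adds Gaussian replicate
#' noise on the raw Ct scale. With `noise_sd = 0`, [delta_ct()] recovers the
#' requested deltas exactly.
#'
#' @param deltas tibble with `sample_id`, `gene`, `delta` and optionally
#'   `efficiency` (default 1)
#' @param noise_sd Gaussian sd added to raw Ct values
#' @param seed RNG seed
#' @param reference_gene,reference_efficiency the reference gene row added
#'   per sample
#' @param reference_corrected_ct corrected-scale Ct of the reference
#' @return tibble (`sample_id`, `gene`, `ct`, `efficiency`) with the
#'   requested deltas attached as attribute `"truth"`
#' @export
simulate_ct <- function(deltas, noise_sd = 0, seed = 1L,
                        reference_gene = "rpoB", reference_efficiency = 1,
                        reference_corrected_ct = 25) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  eff <- if ("efficiency" %in% names(deltas)) deltas$efficiency else rep(1, nrow(deltas))
  with_seed(seed, {
    target_ct <- (reference_corrected_ct - deltas$delta) / log2(1 + eff) +
      rnorm(nrow(deltas), 0, noise_sd)
    ref_rows <- deltas |>
      distinct(.data$sample_id) |>
      mutate(gene = reference_gene,
             ct = reference_corrected_ct / log2(1 + reference_efficiency) +
               rnorm(dplyr::n(), 0, noise_sd),
             efficiency = reference_efficiency)
    out <- bind_rows(
      tibble(sample_id = deltas$sample_id, gene = deltas$gene,
             ct = target_ct, efficiency = eff),
      ref_rows
    )
    attr(out, "truth") <- deltas
    out
  })
}

#' Write a simulated count study to disk
#'
#' @param sim output of [simulate_counts()]
#' @param dir output directory (created if needed); writes `counts.tsv`,
#'   `design.tsv`, `truth.tsv`
#' @return named vector of paths, invisibly
#' @export
write_sim_counts <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_count_matrix(sim$counts, paths["counts"])
  readr::write_tsv(sim$design, paths["design"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
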
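#' Define the sarcin-ricin loop target
#'
#' The sarcin-ricin loop (SRL) of the 28S rRNA carries the adenine that
#' ribosome-inactivating proteins (RIPs) depurinate. The default motif is the
#' conserved 13-mer `TACGAGAGGAACC` with the target adenine at 0-based offset
#' 4; in cDNA-derived reads depurination shows up as an A-to-T shift at that
#' position, because reverse transcriptase preferentially inserts adenine
#' opposite the abasic site.
#'
#' @param motif nucleotide string containing the target adenine
#' @param target_offset 0-based offset of the target adenine within `motif`
#' @return an object of class `srl_target`
#' @export
#' @examples
#' srl_target()
srl_target <- function(motif = "TACGAGAGGAACC", target_offset = 4L) {
  motif <- toupper(motif)
  if (nchar(motif) < 5L) abort("motif must be at least 5 bases")
  if (grepl("[^ACGT]", motif)) abort("motif must contain only A/C/G/T")
  if (target_offset < 0L || target_offset >= nchar(motif)) {
    abort("`target_offset` must index a position inside the motif")
  }
  if (substr(motif, target_offset + 1L, target_offset + 1L) != "A") {
    abort("the base at `target_offset` must be the target adenine 'A'")
  }
  structure(list(motif = motif, target_offset = as.integer(target_offset)),
            class = "srl_target")
}

#' @export
print.srl_target <- function(x, ...) {
  marked <- paste0(substr(x$motif, 1, x$target_offset), "[",
                   substr(x$motif, x$target_offset + 1, x$target_offset + 1), "]",
                   substr(x$motif, x$target_offset + 2, nchar(x$motif)))
  cat("<srl_target> ", marked, " (target offset ", x$target_offset, ", 0-based)\n", sep = "")
  invisible(x)
}

#' Run configuration for the depurination caller
#'
#' @param min_reads_per_replicate replicates with fewer ungapped reads at the
#'   target are flagged and excluded from group tests (default 10)
#' @param max_mismatch_fraction maximum per-read mismatch fraction for
#'   retention (default 0.02); the target site itself is exempt
#' @param subsample_reads optional cap on reads analysed per sample
#' @param seed seed echoed into reports and used for subsampling
#' @return an `srl_config` list
#' @export
srl_config <- function(min_reads_per_replicate = 10L,
                       max_mismatch_fraction = 0.02,
                       subsample_reads = NULL,
                       seed = 1L) {
  assert_scalar_number(min_reads_per_replicate, "min_reads_per_replicate", lower = 0)
  assert_scalar_number(max_mismatch_fraction, "max_mismatch_fraction", lower = 0, upper = 1)
  if (!is.null(subsample_reads)) assert_scalar_number(subsample_reads, "subsample_reads", lower = 0)
  structure(list(
    min_reads_per_replicate = as.integer(min_reads_per_replicate),
    max_mismatch_fraction = max_mismatch_fraction,
    subsample_reads = subsample_reads,
    seed = as.integer(seed)
  ), class = "srl_config")
}

#' Locate the SRL motif on a reference sequence
#'
#' Requires exactly one exact occurrence; zero occurrences or several are
#' errors (in the ambiguous case the caller must supply coordinates
#' explicitly). Coordinates are 0-based, half-open.
#'
#' @param reference one-row tibble (or list) with `id` and `sequence`
#' @param target an [srl_target()]
#' @return tibble with `reference_id`, `start`, `end` (0-based half-open span
#'   of the motif) and `target_pos` (absolute 0-based position of the adenine)
#' @export
#' @examples
#' ref <- tibble::tibble(id = "r", sequence = paste0("GG", "TACGAGAGGAACC", "CC"))
#' locate_srl(ref, srl_target())
locate_srl <- function(reference, target = srl_target()) {
  seq <- toupper(reference$sequence[[1]])
  hits <- gregexpr(target$motif, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    abort(sprintf("motif %s absent from reference '%s'", target$motif, reference$id[[1]]))
  }
  if (length(hits) > 1L) {
    abort(sprintf("motif %s occurs %d times in reference '%s'; supply coordinates explicitly",
                  target$motif, length(hits), reference$id[[1]]))
  }
  start0 <- as.integer(hits[1]) - 1L
  tibble(
    reference_id = reference$id[[1]],
    start = start0,
    end = start0 + nchar(target$motif),
    target_pos = start0 + target$target_offset
  )
}

# map every reference position in [start, end) to the read base ("-" for a
# deletion), or NULL if the alignment does not fully cover the span.
# Also returns the mismatch count over aligned (M/=/X) bases, excluding
# `exempt_pos`, and the aligned length.
.walk_cigar_span <- function(pos0, cigar, seq, refseq, start, end, exempt_pos) {
  ops <- strsplit(gsub("(\\d+)([MIDNSHP=X])", "\\1 \\2 ", cigar), " +")[[1]]
  lens <- as.integer(ops[c(TRUE, FALSE)])
  typs <- ops[c(FALSE, TRUE)]
  rpos <- pos0          # current reference pos (0-based)
  qpos <- 0L            # current read pos (0-based)
  span_base <- rep(NA_character_, end - start)
  mism <- 0L
  aligned <- 0L
  for (k in seq_along(typs)) {
    op <- typs[k]; L <- lens[k]
    if (op %in% c("M", "=", "X")) {
      idx <- seq_len(L)
      refp <- rpos + idx - 1L
      qb <- substring(seq, qpos + idx, qpos + idx)
      rb <- substring(refseq, refp + 1L, refp + 1L)
      is_mm <- qb != rb & refp != exempt_pos
      mism <- mism + sum(is_mm)
      aligned <- aligned + L
      inside <- refp >= start & refp < end
      if (any(inside)) span_base[refp[inside] - start + 1L] <- qb[inside]
      rpos <- rpos + L; qpos <- qpos + L
    } else if (op %in% c("D", "N")) {
      refp <- rpos + seq_len(L) - 1L
      inside <- refp >= start & refp < end
      if (any(inside)) span_base[refp[inside] - start + 1L] <- "-"
      rpos <- rpos + L
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + L
    } # H, P consume nothing we track
  }
  if (anyNA(span_base)) return(NULL)
  list(span_base = span_base, mismatches = mism, aligned = aligned)
}

#' Call the base at the SRL target adenine for each read
#'
#' A read is retained only if it fully covers the motif span. In alignment
#' mode, retained reads whose mismatch fraction (substitutions over aligned
#' length, the target site exempt) exceeds `max_mismatch_fraction` are
#' dropped; a deletion at the target yields the call `"-"` (gap). In raw-read
#' mode reads are anchored by an exact match of the motif with the target
#' position wildcarded, searched on the read and its reverse complement.
#'
#' @param x alignments from [read_alignments()] (columns `read_id`, `pos`,
#'   `cigar`, `seq`) or raw reads (columns `id`/`read_id` and `sequence`)
#' @param reference one-row tibble with `id`, `sequence` (alignment mode)
#' @param span span tibble from [locate_srl()]; in raw-read mode only the
#'   motif is used
#' @param target an [srl_target()]
#' @param config an [srl_config()]
#' @return tibble with `read_id`, `retained`, `reason` (`"retained"`,
#'   `"partial_coverage"`, `"mismatch_excess"`, `"no_anchor"`), `base`
#'   (A/C/G/T/N or `"-"`; NA for dropped reads). Drop-reason counts are
#'   attached as attribute `"drops"`.
#' @export
assign_reads <- function(x, reference = NULL, span = NULL,
                         target = srl_target(), config = srl_config()) {
  if (!is.null(config$subsample_reads)) {
    x <- subsample_reads(x, config$subsample_reads, seed = config$seed)
  }
  if ("cigar" %in% names(x)) {
    if (is.null(reference) || is.null(span)) {
      abort("alignment mode needs `reference` and `span`")
    }
    calls <- .assign_from_alignments(x, reference, span, config)
  } else {
    calls <- .assign_from_reads(x, target)
  }
  drops <- table(factor(calls$reason,
                        levels = c("retained", "partial_coverage", "mismatch_excess", "no_anchor")))
  attr(calls, "drops") <- as.integer(drops) |> setNames(names(drops))
  calls
}

.assign_from_alignments <- function(aln, reference, span, config) {
  refseq <- toupper(reference$sequence[[1]])
  start <- span$start[[1]]; end <- span$end[[1]]; tpos <- span$target_pos[[1]]
  out <- purrr::pmap(
    list(aln$pos, aln$cigar, aln$seq, aln$read_id),
    function(pos0, cigar, seq, id) {
      w <- .walk_cigar_span(pos0, cigar, toupper(seq), refseq, start, end, tpos)
      if (is.null(w)) {
        return(tibble(read_id = id, retained = FALSE,
                      reason = "partial_coverage", base = NA_character_))
      }
      frac <- if (w$aligned > 0) w$mismatches / w$aligned else 0
      if (frac > config$max_mismatch_fraction) {
        return(tibble(read_id = id, retained = FALSE,
                      reason = "mismatch_excess", base = NA_character_))
      }
      tibble(read_id = id, retained = TRUE, reason = "retained",
             base = w$span_base[tpos - start + 1L])
    }
  )
  bind_rows(out)
}

.assign_from_reads <- function(reads, target) {
  id_col <- if ("read_id" %in% names(reads)) "read_id" else "id"
  off <- target$target_offset
  left <- substr(target$motif, 1L, off)
  right <- substr(target$motif, off + 2L, nchar(target$motif))
  pat <- paste0(left, "[ACGTN]", right)
  seqs <- toupper(reads$sequence)

  # vectorised two-pass anchor: forward first, then reverse complement for
  # the remainder; the wildcarded base sits nchar(left) into the match
  base <- rep(NA_character_, length(seqs))
  m_fwd <- regexpr(pat, seqs)
  hit <- m_fwd != -1L
  base[hit] <- substr(seqs[hit], m_fwd[hit] + off, m_fwd[hit] + off)
  if (any(!hit)) {
    rc <- reverse_complement(seqs[!hit])
    m_rev <- regexpr(pat, rc)
    hit_rc <- m_rev != -1L
    idx <- which(!hit)[hit_rc]
    base[idx] <- substr(rc[hit_rc], m_rev[hit_rc] + off, m_rev[hit_rc] + off)
  }
  tibble(
    read_id = as.character(reads[[id_col]]),
    retained = !is.na(base),
    reason = ifelse(is.na(base), "no_anchor", "retained"),
    base = base
  )
}

#' Tally base calls at the target position for one sample
#'
#' Gapped reads (deletion at the target) are counted separately and never
#' contribute to base counts; ambiguous `N` counts as `other`.
#'
#' @param calls output of [assign_reads()]
#' @param sample_id sample label for the output row
#' @return one-row tibble: `sample_id`, `a`, `c`, `g`, `t`, `other`,
#'   `gapped`, `total_ungapped`
#' @export
#' @examples
#' calls <- tibble::tibble(read_id = as.character(1:5), retained = TRUE,
#'                         reason = "retained", base = c("A", "A", "A", "T", "-"))
#' count_bases(calls, "s1")
count_bases <- function(calls, sample_id = "sample") {
  b <- calls$base[calls$retained & !is.na(calls$base)]
  n <- function(x) sum(b == x)
  a <- n("A"); cc <- n("C"); g <- n("G"); t <- n("T")
  gapped <- n("-")
  other <- length(b) - a - cc - g - t - gapped
  tibble(
    sample_id = sample_id,
    a = a, c = cc, g = g, t = t, other = other,
    gapped = gapped,
    total_ungapped = a + cc + g + t + other
  )
}

#' Wilson score interval for a binomial proportion
#'
#' Behaves sensibly at the 0/1 boundaries where the Wald interval collapses,
#' which matters here because unattacked samples sit at adenine fraction 1.
#'
#' @param x successes
#' @param n trials
#' @param conf confidence level
#' @return tibble with `lower`, `upper`
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Estimate the depurination fraction for one sample
#'
#' The adenine fraction is `a / total_ungapped`, the depurination fraction
#' its complement, with a 95% Wilson interval on the adenine fraction.
#' Replicates with fewer than `min_reads_per_replicate` ungapped reads fail
#' QC and are excluded from group tests downstream.
#'
#' @param counts one-row tibble from [count_bases()] (or several rows; one
#'   estimate per row)
#' @param config an [srl_config()]
#' @return tibble: `sample_id`, `n_reads`, `adenine_fraction`,
#'   `depurination_fraction`, `t_fraction`, `ci_low`, `ci_high`, `passed_qc`
#' @export
estimate_depurination <- function(counts, config = srl_config()) {
  n <- counts$total_ungapped
  af <- ifelse(n > 0, counts$a / n, NA_real_)
  ci <- wilson_interval(counts$a, pmax(n, 1L))
  out <- tibble(
    sample_id = counts$sample_id,
    n_reads = n,
    adenine_fraction = af,
    depurination_fraction = 1 - af,
    t_fraction = ifelse(n > 0, counts$t / n, NA_real_),
    ci_low = ifelse(n > 0, ci$lower, NA_real_),
    ci_high = ifelse(n > 0, ci$upper, NA_real_),
    passed_qc = n >= config$min_reads_per_replicate
  )
  class(out) <- c("srl_estimates", class(out))
  out
}
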
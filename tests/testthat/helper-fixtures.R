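# Shared fixture builders and independent oracles.

MOTIF <- "TACGAGAGGAACC"

# a small deterministic reference: 30 nt flanks around the SRL motif
fixture_reference <- function() {
  left <- "GATTACCAGGATCCGTTAGCCGGATTCAGA"
  right <- "CCTAGGATTCCGAGATTACAGGCCTTAGGA"
  tibble::tibble(id = "ref28S", sequence = paste0(left, MOTIF, right))
}

# write a SAM file over fixture_reference(); records = list of lists with
# qname, flag, pos (1-based), cigar, seq, and optional nm
write_fixture_sam <- function(records, path, ref = fixture_reference(),
                              extra_refs = character()) {
  sq <- c(sprintf("@SQ\tSN:%s\tLN:%d", ref$id, nchar(ref$sequence)),
          sprintf("@SQ\tSN:%s\tLN:%d", extra_refs, 1000L))
  lines <- c("@HD\tVN:1.6\tSO:unsorted", sq)
  for (r in records) {
    opt <- if (!is.null(r$nm)) sprintf("\tNM:i:%d", r$nm) else ""
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*%s",
                              r$qname, r$flag %||% 0L, r$rname %||% ref$id,
                              r$pos, r$cigar, r$seq, opt))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pure-string brute-force oracle for base counting: slide the
# target-wildcarded motif over each read and its reverse complement, and
# tally the base at the wildcard position of the first anchor found
oracle_count_bases <- function(sequences, motif = MOTIF, offset = 4L) {
  left <- substr(motif, 1, offset)
  right <- substr(motif, offset + 2, nchar(motif))
  mlen <- nchar(motif)
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  find_base <- function(s) {
    for (cand in c(s, revcomp(s))) {
      n <- nchar(cand)
      if (n < mlen) next
      for (i in seq_len(n - mlen + 1L)) {
        win <- substr(cand, i, i + mlen - 1L)
        if (substr(win, 1, offset) == left &&
            substr(win, offset + 2, mlen) == right) {
          return(substr(win, offset + 1, offset + 1))
        }
      }
    }
    NA_character_
  }
  bases <- vapply(toupper(sequences), find_base, character(1), USE.NAMES = FALSE)
  bases <- bases[!is.na(bases)]
  c(a = sum(bases == "A"), c = sum(bases == "C"), g = sum(bases == "G"),
    t = sum(bases == "T"),
    other = sum(!bases %in% c("A", "C", "G", "T")))
}

# brute-force set-algebra oracle for the direction-stratified Venn
oracle_venn <- function(blue, red, green, lfc_min = 0.58, fdr_max = 0.05) {
  sig <- lapply(list(blue = blue, red = red, green = green), function(d) {
    d[abs(d$log2fc) >= lfc_min & d$fdr < fdr_max, ]
  })
  out <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(sig, function(d) d$gene_id[d$direction == dir])
    b <- sets$blue; r <- sets$red; g <- sets$green
    regions <- list(
      blue = setdiff(b, union(r, g)),
      red = setdiff(r, union(b, g)),
      green = setdiff(g, union(b, r)),
      blue_red = setdiff(intersect(b, r), g),
      blue_green = setdiff(intersect(b, g), r),
      red_green = setdiff(intersect(r, g), b),
      blue_red_green = intersect(intersect(b, r), g)
    )
    for (nm in names(regions)) {
      if (length(regions[[nm]])) {
        out[[paste(dir, nm)]] <- tibble::tibble(
          gene_id = regions[[nm]], direction = dir, region = nm)
      }
    }
  }
  dplyr::bind_rows(out)
}

# random DE-table triple for oracle comparisons
random_de_tables <- function(n_genes = 40, seed = 1) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    mk <- function() {
      tibble::tibble(
        gene_id = genes,
        log2fc = round(runif(n_genes, -3, 3), 2),
        fdr = round(runif(n_genes)^2, 4)
      ) |>
        dplyr::mutate(direction = ifelse(log2fc >= 0, "up", "down"))
    }
    list(blue = mk(), red = mk(), green = mk())
  })
}

# per-replicate base-count table builder for group tests
make_group_counts <- function(a_by_rep, t_by_rep, groups) {
  n <- length(a_by_rep)
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    a = a_by_rep, c = 0L, g = 0L, t = t_by_rep, other = 0L, gapped = 0L,
    total_ungapped = a_by_rep + t_by_rep,
    group = groups
  )
}
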
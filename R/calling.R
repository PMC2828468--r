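#' Default caller thresholds
#'
#' Strict and relaxed LogR cutoffs used throughout the pipeline.  The strict
#' threshold (-0.52) is calibrated, together with the default [logr_noise()]
#' emission, so that the strict caller detects deletions spanning >= 3 SNPs
#' with per-genome sensitivity about 0.75 while producing fewer than 0.05
#' false calls per deletion-free genome.  The relaxed threshold (-0.20) is
#' used only for targeted re-scans of a locus already implicated in the
#' other member of a parent/child pair; because every true deletion keeps a
#' discernible intensity deficit, a re-scan of a genome that really carries
#' the deletion essentially always confirms it, so a transmitted deletion
#' is almost never mistaken for a de novo event.
#'
#' @name caller-thresholds
#' @keywords internal
NULL

DELHOT_STRICT_THRESHOLD <- -0.523
DELHOT_RELAXED_THRESHOLD <- -0.20

#' Call heterozygous deletions on LogR tracks
#'
#' Implements the run rule: a deletion call is a maximal run of at least
#' `min_run` consecutive array SNPs (adjacent on the SNP map, never crossing
#' a chromosome boundary) whose LogR lies below `threshold`.  Runs are not
#' merged across any intervening SNP above threshold, calls within a sample
#' never overlap, and the call's bp interval is reported half-open as
#' [pos(first SNP), pos(last SNP) + 1) — on an array the true breakpoints
#' between SNPs are unknowable.
#'
#' @param logr Numeric vector of per-SNP LogR values aligned to `map`, or a
#'   samples x SNPs matrix with sample ids as rownames.
#' @param map A `genome_model` or a SNP table with columns `chrom`, `pos`
#'   (sorted; row number = global SNP index).
#' @param threshold LogR cutoff; SNPs strictly below it count as low.
#' @param min_run Minimum run length (>= 2).
#' @param sample Optional sample id attached to vector input.
#' @return Tibble of calls: `sample`, `chrom`, `first_snp`, `last_snp`
#'   (global SNP indices, inclusive), `start`, `end` (bp, half-open),
#'   `n_snps`, `mean_logr`, `provenance` (`"called"`), sorted by position.
#' @examples
#' gm <- build_genome_model()
#' x <- rep(0, nrow(gm$snps)); x[101:105] <- -0.7
#' call_deletions(x, gm)
#' @export
call_deletions <- function(logr, map, threshold = DELHOT_STRICT_THRESHOLD,
                           min_run = 3L, sample = NULL) {
  snps <- as_snp_map(map)
  stop_not(min_run >= 2, "`min_run` must be >= 2")
  if (is.matrix(logr)) {
    ids <- rownames(logr) %||% as.character(seq_len(nrow(logr)))
    return(purrr::map_dfr(seq_len(nrow(logr)), function(i) {
      call_deletions(logr[i, ], snps, threshold, min_run, sample = ids[i])
    }))
  }
  stop_not(length(logr) == nrow(snps),
           "track length does not match the SNP map")
  stop_not(all(is.finite(logr)), "LogR values must be finite")

  low <- logr < threshold
  grp <- match(snps$chrom, unique(snps$chrom))
  n <- length(low)
  prev_ok <- c(FALSE, low[-n] & diff(grp) == 0)
  next_ok <- c(low[-1] & diff(grp) == 0, FALSE)
  starts <- which(low & !prev_ok)
  ends <- which(low & !next_ok)
  len <- ends - starts + 1L
  keep <- len >= min_run
  starts <- starts[keep]; ends <- ends[keep]; len <- len[keep]

  if (!length(starts)) {
    return(tibble(sample = character(), chrom = character(),
                  first_snp = integer(), last_snp = integer(),
                  start = double(), end = double(), n_snps = integer(),
                  mean_logr = double(), provenance = character()))
  }
  cs <- cumsum(logr)
  tibble(
    sample = sample %||% NA_character_,
    chrom = snps$chrom[starts],
    first_snp = as.integer(starts),
    last_snp = as.integer(ends),
    start = snps$pos[starts],
    end = snps$pos[ends] + 1,
    n_snps = as.integer(len),
    mean_logr = (cs[ends] - cs[starts] + logr[starts]) / len,
    provenance = "called"
  )
}

#' Sample-level QC on call counts
#'
#' Flags samples generating more than `max_calls` deletion calls — a sign of
#' a noisy intensity track rather than genuine variation.  The bound is
#' exclusive: a sample with exactly `max_calls` calls is kept.  When a
#' pedigree is supplied, exclusion of any trio member removes the whole trio
#' (incomplete trios are useless for cross-verification).
#'
#' @param calls Call tibble (from [call_deletions()]) for the whole cohort.
#' @param samples Character vector of all sample ids (so samples with zero
#'   calls are reported too).
#' @param max_calls QC bound, default 20.
#' @param pedigree Optional pedigree tibble; triggers trio-wise removal.
#' @return List with `report` (tibble `sample`, `n_calls`, `excluded`),
#'   `kept_samples`, `calls` (calls of kept samples only) and, if a pedigree
#'   was given, `pedigree` (kept trios).
#' @export
qc_filter_samples <- function(calls, samples, max_calls = 20L, pedigree = NULL) {
  counts <- calls |>
    count(.data$sample, name = "n_calls") |>
    right_join(tibble(sample = samples), by = "sample") |>
    mutate(n_calls = as.integer(replace_na(.data$n_calls, 0L)),
           excluded = .data$n_calls > max_calls) |>
    arrange(match(.data$sample, samples))
  kept <- counts$sample[!counts$excluded]
  out <- list(report = counts)
  if (!is.null(pedigree)) {
    ok <- pedigree$child %in% kept & pedigree$father %in% kept &
      pedigree$mother %in% kept
    pedigree <- pedigree[ok, ]
    kept <- intersect(kept, c(pedigree$child, pedigree$father, pedigree$mother))
    out$pedigree <- pedigree
  }
  out$kept_samples <- kept
  out$calls <- dplyr::filter(calls, .data$sample %in% kept)
  out
}

#' Targeted re-scan of a locus at a relaxed threshold
#'
#' Stands in for visual re-examination of an intensity image: given a locus
#' implicated by a call in the other member of a parent/child pair, re-apply
#' the run caller restricted to that region, with a relaxed threshold and a
#' shorter minimum run.  Returns at most one call (the longest qualifying
#' run, ties broken by lower mean LogR), tagged `provenance = "rescued"`.
#'
#' @param logr Per-SNP LogR vector for one sample, aligned to `map`.
#' @param map A `genome_model` or SNP table.
#' @param chrom,start,end The locus to re-scan (0-based half-open bp).
#' @param threshold Relaxed LogR cutoff.
#' @param min_run Minimum run, default 2 (a rescued call may have fewer SNPs
#'   than a strict call).
#' @param sample Optional sample id.
#' @return One-row call tibble, or a zero-row tibble if no qualifying run.
#' @export
rescan_locus <- function(logr, map, chrom, start, end,
                         threshold = DELHOT_RELAXED_THRESHOLD, min_run = 2L,
                         sample = NULL) {
  snps <- as_snp_map(map)
  stop_not(is.numeric(start) && is.numeric(end) && end > start,
           "empty region: end must be > start")
  stop_not(chrom %in% snps$chrom, "region chromosome not on the SNP map")
  idx <- which(snps$chrom == chrom & snps$pos >= start & snps$pos < end)
  empty <- call_deletions(numeric(0), snps[0, ], threshold, min_run)
  if (!length(idx)) return(empty)
  sub <- call_deletions(logr[idx], snps[idx, ], threshold, min_run,
                        sample = sample)
  if (!nrow(sub)) return(empty)
  sub <- sub |>
    mutate(first_snp = .data$first_snp + idx[1] - 1L,
           last_snp = .data$last_snp + idx[1] - 1L,
           provenance = "rescued") |>
    arrange(desc(.data$n_snps), .data$mean_logr)
  sub[1, ]
}
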
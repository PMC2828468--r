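#' Caller configuration for trio verification
#'
#' Bundles the thresholds used by the two-round cross-verification.
#'
#' @param threshold Strict LogR cutoff for [call_deletions()].
#' @param relaxed_threshold Relaxed cutoff for [rescan_locus()].
#' @param min_run Strict minimum run (>= 3 for a primary call).
#' @param rescue_min_run Minimum run for rescued calls (default 2).
#' @param tolerance Boundary-match tolerance in SNPs (default 0: exact
#'   first/last SNP agreement).
#' @param max_calls Sample QC bound for [qc_filter_samples()].
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(threshold = DELHOT_STRICT_THRESHOLD,
                          relaxed_threshold = DELHOT_RELAXED_THRESHOLD,
                          min_run = 3L, rescue_min_run = 2L,
                          tolerance = 0L, max_calls = 20L) {
  stop_not(relaxed_threshold > threshold,
           "`relaxed_threshold` must be above (less negative than) `threshold`")
  structure(list(threshold = threshold, relaxed_threshold = relaxed_threshold,
                 min_run = as.integer(min_run),
                 rescue_min_run = as.integer(rescue_min_run),
                 tolerance = as.integer(tolerance),
                 max_calls = as.integer(max_calls)),
            class = "caller_config")
}

#' Do two deletion calls share boundaries?
#'
#' Two calls match when they sit on the same chromosome and their first and
#' last deleted SNP indices each agree within `tolerance` SNPs.  The
#' relation is symmetric.  Vectorised over rows (shorter input recycled).
#'
#' @param a,b Call tibbles (columns `chrom`, `first_snp`, `last_snp`).
#' @param tolerance Allowed per-boundary difference in SNPs, default 0.
#' @return Logical vector.
#' @export
match_boundaries <- function(a, b, tolerance = 0L) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(logical(0))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] &
    abs(a$first_snp[ia] - b$first_snp[ib]) <= tolerance &
    abs(a$last_snp[ia] - b$last_snp[ib]) <= tolerance
}

# any call in `set` matching the single call `x`?
any_match <- function(x, set, tolerance) {
  if (!nrow(set)) return(FALSE)
  any(set$chrom == x$chrom &
        abs(set$first_snp - x$first_snp) <= tolerance &
        abs(set$last_snp - x$last_snp) <= tolerance)
}

# any call in `set` overlapping the bp interval of `x` on the same chromosome?
any_overlap <- function(x, set) {
  if (!nrow(set)) return(FALSE)
  any(set$chrom == x$chrom & set$start < x$end & set$end > x$start)
}

#' Round 1: classify offspring calls as transmitted or de novo
#'
#' For each affirmed offspring call, look for a parental call with matching
#' boundaries; failing that, re-scan the locus in both parental tracks at
#' the relaxed threshold (the computational stand-in for visual
#' re-examination of the parental images).  A call is `de_novo` only when
#' both parents show no qualifying signal at either threshold.
#'
#' @param offspring_calls Affirmed (QC-passed) strict calls of the children.
#' @param parent_calls Affirmed strict calls of the parents.
#' @param tracks LogR matrix containing at least the parental rows.
#' @param map A `genome_model` or SNP table.
#' @param pedigree Pedigree tibble.  Trios whose parental tracks are missing
#'   from `tracks` are skipped with a warning.
#' @param config A [caller_config()].
#' @return List with `labels` (offspring calls plus `label`, `matched`,
#'   `support_parent`) and `parent_rescues` (rescued parental calls).
#' @export
classify_round1 <- function(offspring_calls, parent_calls, tracks, map,
                            pedigree, config = caller_config()) {
  snps <- as_snp_map(map)
  have <- rownames(tracks)
  bad <- !(pedigree$father %in% have & pedigree$mother %in% have)
  if (any(bad)) {
    rlang::warn(sprintf("skipping %d trio(s) with missing parent tracks", sum(bad)))
    pedigree <- pedigree[!bad, ]
  }
  fam <- pedigree
  offspring_calls <- dplyr::filter(offspring_calls, .data$sample %in% fam$child)
  pc_by_sample <- split(parent_calls, parent_calls$sample)
  father_of <- setNames(fam$father, fam$child)
  mother_of <- setNames(fam$mother, fam$child)

  n <- nrow(offspring_calls)
  label <- character(n); matched <- logical(n); support <- rep(NA_character_, n)
  rescues <- vector("list", n)
  for (i in seq_len(n)) {
    x <- offspring_calls[i, ]
    fa <- father_of[[x$sample]]; mo <- mother_of[[x$sample]]
    hit_fa <- any_match(x, pc_by_sample[[fa]] %||% parent_calls[0, ], config$tolerance)
    hit_mo <- any_match(x, pc_by_sample[[mo]] %||% parent_calls[0, ], config$tolerance)
    if (hit_fa || hit_mo) {
      label[i] <- "transmitted"; matched[i] <- TRUE
      support[i] <- if (hit_fa) fa else mo
      next
    }
    r_fa <- rescan_locus(tracks[fa, ], snps, x$chrom, x$start, x$end,
                         config$relaxed_threshold, config$rescue_min_run,
                         sample = fa)
    r_mo <- rescan_locus(tracks[mo, ], snps, x$chrom, x$start, x$end,
                         config$relaxed_threshold, config$rescue_min_run,
                         sample = mo)
    if (nrow(r_fa) || nrow(r_mo)) {
      label[i] <- "transmitted"
      support[i] <- if (nrow(r_fa)) fa else mo
      rescues[[i]] <- bind_rows(r_fa, r_mo)
    } else {
      label[i] <- "de_novo"
    }
  }
  list(labels = mutate(offspring_calls, label = label, matched = matched,
                       support_parent = support),
       parent_rescues = bind_rows(rescues))
}

#' Round 2: recover uncalled offspring deletions from parental calls
#'
#' For each affirmed parental call with no boundary-matched offspring call,
#' re-scan the child's track at the locus.  A successful re-scan adds a
#' rescued transmitted offspring call; a silent child labels the parental
#' deletion non-transmitted.  Parental calls whose locus already carries an
#' affirmed offspring call with (merely) shifted boundaries are marked
#' `requeried` and add nothing — the event was already counted in round 1.
#'
#' @param parent_calls Affirmed strict parental calls.
#' @param offspring_calls Affirmed strict offspring calls (round-1 input).
#' @param tracks LogR matrix containing the child rows.
#' @param map A `genome_model` or SNP table.
#' @param pedigree Pedigree tibble.
#' @param config A [caller_config()].
#' @return List with `parent_status` (parental calls plus `status` in
#'   matched / requeried / recovered / nontransmitted), `recovered` (new
#'   rescued offspring calls) and `nontransmitted` (parental calls).
#' @export
classify_round2 <- function(parent_calls, offspring_calls, tracks, map,
                            pedigree, config = caller_config()) {
  snps <- as_snp_map(map)
  child_of <- c(setNames(pedigree$child, pedigree$father),
                setNames(pedigree$child, pedigree$mother))
  parent_calls <- dplyr::filter(parent_calls, .data$sample %in% names(child_of))
  oc_by_sample <- split(offspring_calls, offspring_calls$sample)

  n <- nrow(parent_calls)
  status <- character(n)
  recovered <- vector("list", n)
  for (i in seq_len(n)) {
    x <- parent_calls[i, ]
    ch <- child_of[[x$sample]]
    oc <- oc_by_sample[[ch]] %||% offspring_calls[0, ]
    if (any_match(x, oc, config$tolerance)) {
      status[i] <- "matched"
    } else if (any_overlap(x, oc)) {
      status[i] <- "requeried"
    } else {
      r <- rescan_locus(tracks[ch, ], snps, x$chrom, x$start, x$end,
                        config$relaxed_threshold, config$rescue_min_run,
                        sample = ch)
      if (nrow(r)) {
        status[i] <- "recovered"
        recovered[[i]] <- mutate(r, label = "transmitted",
                                 support_parent = x$sample)
      } else {
        status[i] <- "nontransmitted"
      }
    }
  }
  parent_status <- mutate(parent_calls, status = status)
  list(parent_status = parent_status,
       recovered = bind_rows(recovered),
       nontransmitted = dplyr::filter(parent_status, .data$status == "nontransmitted"))
}

#' Run the full two-round trio cross-verification
#'
#' Convenience pipeline: sample QC, round 1 (offspring against parents with
#' targeted parental rescue), round 2 (parents against offspring with
#' targeted offspring rescue), and ledger compilation.
#'
#' @param calls Strict cohort calls for all samples (see [call_deletions()]).
#' @param tracks LogR matrix for all samples.
#' @param map A `genome_model` or SNP table.
#' @param pedigree Pedigree tibble.
#' @param config A [caller_config()].
#' @return Object of class `trio_verification`: list with `round1`,
#'   `round2`, `ledger` (a [trio_ledger()]), `offspring_final` (all final
#'   offspring deletion calls with labels) and `qc` (the QC report).
#' @export
verify_trios <- function(calls, tracks, map, pedigree,
                         config = caller_config()) {
  samples <- rownames(tracks)
  qc <- qc_filter_samples(calls, samples, config$max_calls, pedigree)
  ped <- qc$pedigree
  oc <- dplyr::filter(qc$calls, .data$sample %in% ped$child)
  pc <- dplyr::filter(qc$calls, .data$sample %in% c(ped$father, ped$mother))
  r1 <- classify_round1(oc, pc, tracks, map, ped, config)
  r2 <- classify_round2(pc, oc, tracks, map, ped, config)
  ledger <- compile_ledger(r1, r2, tolerance = config$tolerance)
  offspring_final <- bind_rows(
    select(r1$labels, -dplyr::any_of("matched")),
    select(r2$recovered, dplyr::any_of(names(r1$labels)))
  )
  structure(list(round1 = r1, round2 = r2, ledger = ledger,
                 offspring_final = offspring_final, qc = qc$report),
            class = "trio_verification")
}

#' @export
print.trio_verification <- function(x, ...) {
  cat("<trio_verification>\n")
  print(x$ledger)
  invisible(x)
}
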
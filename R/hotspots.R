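#' Count events in fixed genome bins
#'
#' Tiles each chromosome with non-overlapping bins of `unit` bp starting at
#' 0 (the last, partial bin is kept and flagged) and assigns every event to
#' exactly one bin by its interval midpoint, so an event straddling a bin
#' boundary is counted once.
#'
#' @param events Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome A `genome_model` or tibble with `chrom`, `length`.
#' @param unit Bin width in bp (> 0), default 0.6 Mb.
#' @param offset Tiling phase offset in bp (used by the optional half-offset
#'   scan pass); default 0.
#' @return Tibble: `chrom`, `bin_start`, `bin_end`, `partial`, `count`.
#' @export
bin_counts <- function(events, genome, unit = 6e5, offset = 0) {
  stop_not(unit > 0, "`unit` must be > 0")
  g <- as_genome_tbl(genome)
  stop_not(all(events$chrom %in% g$chrom), "events on chromosomes not in the genome")
  bins <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    len <- g$length[i]
    edges <- unique(c(0, seq(offset %% unit, len, by = unit), len))
    edges <- sort(edges[edges >= 0 & edges <= len])
    tibble(chrom = g$chrom[i],
           bin_start = edges[-length(edges)], bin_end = edges[-1])
  }) |>
    mutate(partial = (.data$bin_end - .data$bin_start) != unit)
  if (nrow(events)) {
    mid <- interval_mid(events$start, events$end)
    counts <- purrr::map_int(seq_len(nrow(bins)), function(j) {
      sum(events$chrom == bins$chrom[j] &
            mid >= bins$bin_start[j] & mid < bins$bin_end[j])
    })
    bins$count <- counts
  } else {
    bins$count <- 0L
  }
  bins
}

#' Poisson expectation for bin occupancy
#'
#' Under a homogeneous placement of `N` independent events across `B` equal
#' bins, the count in one bin is Poisson with mean `lambda = N / B`, and the
#' expected number of bins holding exactly `k` events is `B * e^-lambda *
#' lambda^k / k!`.  Observing far more high-occupancy bins than this
#' expectation is the evidence that deletion hotspots exist.
#'
#' @param N Total number of independent events (>= 0).
#' @param B Number of bins (>= 1).
#' @param k Occupancy (vectorised, each >= 0).
#' @return Tibble with `k`, `expected` (bins with exactly `k` events) and
#'   `p_ge` (per-bin upper tail P(X >= k)).
#' @examples
#' poisson_expectation(368, 4400, 2:4)   # ~14, 0.39, 0.008
#' @export
poisson_expectation <- function(N, B, k) {
  stop_not(N >= 0 && B >= 1, "need N >= 0 and B >= 1")
  stop_not(all(k >= 0), "`k` must be >= 0")
  lambda <- N / B
  tibble(k = k,
         expected = B * dpois(k, lambda),
         p_ge = ppois(k - 1, lambda, lower.tail = FALSE))
}

#' Call hotspots from binned counts
#'
#' Bins holding at least `min_events` independent events are hotspot bins;
#' adjacent qualifying bins on a chromosome merge into one region.
#'
#' @param bins Tibble from [bin_counts()].
#' @param min_events Minimum independent events per bin, default 3.
#' @return Tibble of regions: `chrom`, `bin_start`, `bin_end` (merged bin
#'   span), `n_bins`, `n_independent`.
#' @export
call_hotspots <- function(bins, min_events = 3L) {
  hot <- bins |>
    dplyr::filter(.data$count >= min_events) |>
    arrange(.data$chrom, .data$bin_start)
  if (!nrow(hot)) {
    return(tibble(chrom = character(), bin_start = double(),
                  bin_end = double(), n_bins = integer(),
                  n_independent = integer()))
  }
  new_run <- hot$chrom != dplyr::lag(hot$chrom, default = "") |
    hot$bin_start != dplyr::lag(hot$bin_end, default = -1)
  hot$region <- cumsum(new_run)
  hot |>
    group_by(.data$region) |>
    summarise(chrom = .data$chrom[1],
              bin_start = min(.data$bin_start), bin_end = max(.data$bin_end),
              n_bins = dplyr::n(),
              n_independent = as.integer(sum(.data$count)),
              .groups = "drop") |>
    select(-"region")
}

#' Per-unit-length enrichment of events in regions
#'
#' The enrichment fold of a region is its event density (events per bp,
#' assigned by midpoint) divided by the genome-wide background density
#' computed over the genome *excluding* all supplied regions.  The average
#' fold is weighted by region length.
#'
#' @param events Event tibble (`chrom`, `start`, `end`).
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genome A `genome_model` or `chrom`/`length` tibble.
#' @return List with `regions` (input plus `n_events`, `fold`) and
#'   `average` (length-weighted mean fold).
#' @export
enrichment_fold <- function(events, regions, genome) {
  stop_not(nrow(regions) >= 1, "need at least one region")
  g <- as_genome_tbl(genome)
  mid <- interval_mid(events$start, events$end)
  n_in <- purrr::map_int(seq_len(nrow(regions)), function(j) {
    sum(events$chrom == regions$chrom[j] &
          mid >= regions$start[j] & mid < regions$end[j])
  })
  len_in <- regions$end - regions$start
  n_out <- nrow(events) - sum(n_in)
  len_out <- sum(g$length) - sum(len_in)
  stop_not(len_out > 0 && n_out > 0,
           "background density is zero: cannot compute enrichment")
  bg <- n_out / len_out
  fold <- (n_in / len_in) / bg
  list(regions = mutate(regions, n_events = n_in, fold = fold),
       average = weighted.mean(fold, len_in))
}

#' Scan a genome for deletion hotspots
#'
#' Full Poisson enrichment scan: fixed `unit`-bp tiling, midpoint bin
#' counts, homogeneous-Poisson occupancy expectations, hotspot calling at
#' `min_events`, per-region enrichment folds and Poisson tail p-values.
#' Region limits are reported both as the merged bin span (used for density
#' and enrichment) and as the extremal bp bounds of the member events (the
#' descriptive "limits of region" convention).  An optional second pass with
#' the tiling shifted by half a unit reduces sensitivity to bin phase.
#'
#' @param events Independent-event tibble (`chrom`, `start`, `end`).
#' @param genome A `genome_model` or `chrom`/`length` tibble.
#' @param unit Bin width (bp), default 0.6 Mb.
#' @param min_events Hotspot threshold, default 3 independent events.
#' @param half_offset Also scan a half-unit-shifted tiling and union the
#'   qualifying regions?  Default `FALSE`.
#' @return Object of class `hotspot_scan`: list with `bins`, `expected`
#'   (occupancy table with observed and expected bin counts), `hotspots`
#'   (regions with `n_independent`, `limits_start`, `limits_end`, `fold`,
#'   `p_poisson`, `p_bonferroni`), `average_fold`, and scalars `N`, `B`,
#'   `lambda`, `unit`, `min_events`.
#' @export
scan_hotspots <- function(events, genome, unit = 6e5, min_events = 3L,
                          half_offset = FALSE) {
  g <- as_genome_tbl(genome)
  bins <- bin_counts(events, g, unit)
  N <- nrow(events)
  B <- nrow(bins)
  lambda <- N / B
  kmax <- max(bins$count, 0L)
  expected <- poisson_expectation(N, B, 0:max(kmax, min_events)) |>
    mutate(observed = purrr::map_int(.data$k, ~ sum(bins$count == .x)))

  regions <- call_hotspots(bins, min_events)
  if (half_offset) {
    bins2 <- bin_counts(events, g, unit, offset = unit / 2)
    regions <- bind_rows(regions, call_hotspots(bins2, min_events)) |>
      merge_regions()
    # re-count events inside merged spans
    mid <- interval_mid(events$start, events$end)
    regions$n_independent <- purrr::map_int(seq_len(nrow(regions)), function(j) {
      sum(events$chrom == regions$chrom[j] & mid >= regions$bin_start[j] &
            mid < regions$bin_end[j])
    })
    regions$n_bins <- as.integer(round((regions$bin_end - regions$bin_start) / unit))
  }

  hotspots <- regions
  average_fold <- NA_real_
  if (nrow(regions)) {
    mid <- interval_mid(events$start, events$end)
    lim <- purrr::map_dfr(seq_len(nrow(regions)), function(j) {
      inside <- events$chrom == regions$chrom[j] &
        mid >= regions$bin_start[j] & mid < regions$bin_end[j]
      tibble(limits_start = min(events$start[inside]),
             limits_end = max(events$end[inside]))
    })
    ef <- enrichment_fold(events,
                          regions |> transmute(.data$chrom, start = .data$bin_start,
                                               end = .data$bin_end),
                          g)
    hotspots <- bind_cols(regions, lim) |>
      mutate(fold = ef$regions$fold,
             p_poisson = ppois(.data$n_independent - 1, lambda * .data$n_bins,
                               lower.tail = FALSE),
             p_bonferroni = pmin(1, .data$p_poisson * B))
    average_fold <- ef$average
  }

  structure(list(bins = bins, expected = expected, hotspots = hotspots,
                 average_fold = average_fold, N = N, B = B, lambda = lambda,
                 unit = unit, min_events = as.integer(min_events)),
            class = "hotspot_scan")
}

# merge overlapping/adjacent candidate regions (same chromosome)
merge_regions <- function(regions) {
  if (!nrow(regions)) return(regions)
  regions <- arrange(regions, .data$chrom, .data$bin_start)
  new_run <- regions$chrom != dplyr::lag(regions$chrom, default = "") |
    regions$bin_start > dplyr::lag(cummax_by(regions$bin_end, regions$chrom), default = -1)
  regions$.r <- cumsum(new_run)
  regions |>
    group_by(.data$.r) |>
    summarise(chrom = .data$chrom[1],
              bin_start = min(.data$bin_start), bin_end = max(.data$bin_end),
              n_bins = NA_integer_, n_independent = NA_integer_,
              .groups = "drop") |>
    select(-".r")
}

cummax_by <- function(x, g) {
  unlist(lapply(split(x, factor(g, levels = unique(g))), cummax), use.names = FALSE)
}

#' @export
print.hotspot_scan <- function(x, ...) {
  cat(sprintf("<hotspot_scan> N = %d events, B = %d bins of %g Mb, lambda = %.4f\n",
              x$N, x$B, x$unit / 1e6, x$lambda))
  cat(sprintf("  %d hotspot region(s) at >= %d independent events",
              nrow(x$hotspots), x$min_events))
  if (nrow(x$hotspots)) cat(sprintf(", average fold %.1f", x$average_fold))
  cat("\n")
  invisible(x)
}

#' @export
tidy.hotspot_scan <- function(x, ...) x$hotspots

#' @export
glance.hotspot_scan <- function(x, ...) {
  tibble(N = x$N, B = x$B, lambda = x$lambda, unit = x$unit,
         n_hotspots = nrow(x$hotspots), average_fold = x$average_fold)
}
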
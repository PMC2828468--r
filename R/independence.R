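#' Collapse boundary-identical calls into independent events
#'
#' Deletions sharing their first and last deleted array SNP are treated as
#' one mutational event carried by several individuals; deletions with any
#' boundary difference are independent events.  Calls are partitioned by the
#' transitive closure of [match_boundaries()] at the given tolerance; each
#' class becomes one event, so class sizes sum to the input call count and
#' collapsing an already-collapsed set changes nothing.
#'
#' @param calls Call tibble with columns `chrom`, `first_snp`, `last_snp`,
#'   `sample`, optionally `cohort` (defaults to a single cohort) and bp
#'   bounds `start`, `end`.
#' @param tolerance Boundary tolerance in SNPs (default 0, exact identity).
#' @return Tibble of events: `event_id`, `chrom`, `first_snp`, `last_snp`,
#'   `start`, `end` (boundaries of the first member call), `n_carriers`,
#'   and `carriers` (list-column of per-member `cohort`, `sample`).
#' @export
collapse_identical <- function(calls, tolerance = 0L) {
  calls <- tibble::as_tibble(calls)
  if (!"cohort" %in% names(calls)) calls$cohort <- "cohort1"
  if (!nrow(calls)) {
    return(tibble(event_id = integer(), chrom = character(),
                  first_snp = integer(), last_snp = integer(),
                  start = double(), end = double(),
                  n_carriers = integer(), carriers = list()))
  }
  ord <- order(calls$chrom, calls$first_snp, calls$last_snp)
  calls <- calls[ord, ]
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (tolerance == 0) {
    key <- paste(calls$chrom, calls$first_snp, calls$last_snp)
    grp <- match(key, unique(key))
  } else {
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && calls$chrom[j] == calls$chrom[i] &&
             calls$first_snp[j] - calls$first_snp[i] <= tolerance) {
        if (abs(calls$last_snp[j] - calls$last_snp[i]) <= tolerance) {
          parent[find(j)] <- find(i)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    grp <- match(roots, unique(roots))
  }
  calls$.grp <- grp
  calls |>
    group_by(.data$.grp) |>
    summarise(chrom = .data$chrom[1],
              first_snp = .data$first_snp[1], last_snp = .data$last_snp[1],
              start = if ("start" %in% names(calls)) .data$start[1] else NA_real_,
              end = if ("end" %in% names(calls)) .data$end[1] else NA_real_,
              n_carriers = dplyr::n(),
              carriers = list(tibble(cohort = cohort, sample = sample)),
              .groups = "drop") |>
    arrange(.data$chrom, .data$first_snp) |>
    mutate(event_id = dplyr::row_number(), .before = 1) |>
    select(-".grp")
}

#' Restrict events to rare ones
#'
#' Keeps only events carried by at most `max_carriers` individuals within
#' any single cohort — the rarity restriction that removes common
#' population deletions and recurrent repeat-mediated events.  The bound is
#' an absolute carrier count (the reference screens applied "1 or 2
#' individuals" to cohorts of roughly 440-640 alike); set
#' `scale_by_cohort = TRUE` to scale it by `cohort_size / cohort_size_ref`.
#' Recurrence across different cohorts never drops an event: rarity is
#' judged within each cohort.
#'
#' @param events Event tibble from [collapse_identical()].
#' @param max_carriers Maximum carriers per cohort (default 2).
#' @param scale_by_cohort Scale the bound by cohort size? Default `FALSE`.
#' @param cohort_sizes Named vector of cohort sizes (required when scaling).
#' @param cohort_size_ref Reference cohort size for scaling, default 500.
#' @return List with `kept` (events, flagged `rare = TRUE`) and `dropped`.
#' @export
frequency_filter <- function(events, max_carriers = 2L,
                             scale_by_cohort = FALSE, cohort_sizes = NULL,
                             cohort_size_ref = 500) {
  if (!nrow(events)) {
    return(list(kept = mutate(events, rare = logical(0)), dropped = events))
  }
  per_cohort <- events |>
    select("event_id", "carriers") |>
    unnest("carriers") |>
    count(.data$event_id, .data$cohort, name = "n_in_cohort")
  if (scale_by_cohort) {
    stop_not(!is.null(cohort_sizes), "`cohort_sizes` needed when scaling")
    per_cohort$bound <- pmax(1, round(max_carriers *
      cohort_sizes[per_cohort$cohort] / cohort_size_ref))
  } else {
    per_cohort$bound <- max_carriers
  }
  common <- per_cohort |>
    dplyr::filter(.data$n_in_cohort > .data$bound) |>
    dplyr::pull(.data$event_id) |>
    unique()
  list(kept = events |>
         dplyr::filter(!.data$event_id %in% common) |>
         mutate(rare = TRUE),
       dropped = dplyr::filter(events, .data$event_id %in% common))
}
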
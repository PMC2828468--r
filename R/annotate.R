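#' Deletion length statistics by hotspot status
#'
#' Splits events into hotspot and background groups by interval midpoint,
#' summarises lengths (mean, median, SD, fraction inside a reference length
#' window, default 20-200 kb) and tests whether the in-window fractions
#' differ with a 2x2 chi-square.  Both the uncorrected statistic and the
#' Yates-corrected one are reported, the uncorrected being the headline
#' (the test variant used in older CNV literature is typically unstated).
#'
#' @param events Tibble with `chrom`, `start`, `end` and (optionally)
#'   `length`; lengths default to `end - start`.
#' @param hotspot_regions Regions tibble (`chrom`, `start`, `end`).
#' @param range Length window in bp, default `c(2e4, 2e5)`.
#' @return Object of class `length_stats`: list with `stats` (one row per
#'   group) and `test` (chi-square with and without continuity correction).
#' @export
length_statistics <- function(events, hotspot_regions, range = c(2e4, 2e5)) {
  events <- tibble::as_tibble(events)
  if (!"length" %in% names(events)) events$length <- events$end - events$start
  grp <- ifelse(point_in_regions(events$chrom,
                                 interval_mid(events$start, events$end),
                                 hotspot_regions),
                "hotspot", "background")
  stop_not(all(c("hotspot", "background") %in% grp) &&
             min(table(grp)) >= 2,
           "need at least 2 events in each of the hotspot and background groups")
  events$group <- factor(grp, levels = c("hotspot", "background"))
  stats <- events |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              mean = mean(.data$length), median = median(.data$length),
              sd = sd(.data$length),
              fraction_in_range = mean(.data$length >= range[1] &
                                         .data$length <= range[2]),
              .groups = "drop")
  tab <- events |>
    mutate(in_range = .data$length >= range[1] & .data$length <= range[2]) |>
    count(.data$group, .data$in_range) |>
    pivot_wider(names_from = "in_range", values_from = "n", values_fill = 0L)
  m <- as.matrix(tab[, setdiff(names(tab), "group")])
  test <- purrr::map_dfr(c(FALSE, TRUE), function(corr) {
    ct <- suppressWarnings(chisq.test(m, correct = corr))
    tibble(correction = corr, statistic = unname(ct$statistic),
           df = unname(ct$parameter), p_value = ct$p.value)
  })
  structure(list(stats = stats, test = test, range = range),
            class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("<length_stats> window %g-%g kb\n", x$range[1] / 1e3, x$range[2] / 1e3))
  print(x$stats)
  print(x$test)
  invisible(x)
}

#' @export
tidy.length_stats <- function(x, ...) x$stats

#' @export
glance.length_stats <- function(x, ...) {
  un <- x$test[!x$test$correction, ]
  tibble(statistic = un$statistic, df = un$df, p_value = un$p_value,
         statistic_yates = x$test$statistic[x$test$correction])
}

#' Flag events that disrupt coding exons
#'
#' An event is coding-affected when its half-open interval intersects at
#' least one annotated exon interval; an event merely abutting an exon
#' (end-to-end touch) does not intersect it.  Overlap is computed with
#' IRanges.
#'
#' @param events Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes Exon models: tibble with `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. `genome_model$genes` or
#'   [read_gene_models()].
#' @return `events` with added `coding_affected` (logical) and `genes_hit`
#'   (comma-separated gene names, `NA` when none).
#' @export
exon_overlap <- function(events, genes) {
  events <- tibble::as_tibble(events)
  stop_not(is.data.frame(genes) &&
             all(c("gene", "chrom", "start", "end") %in% names(genes)),
           "malformed gene model: need columns gene, chrom, start, end")
  stop_not(all(genes$end > genes$start),
           "malformed gene model: exon end must be > start")
  events$coding_affected <- FALSE
  events$genes_hit <- NA_character_
  if (!nrow(events) || !nrow(genes)) return(events)
  for (ch in unique(events$chrom)) {
    ei <- which(events$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    # half-open -> 1-based closed
    hits <- findOverlaps(IRanges(events$start[ei] + 1, events$end[ei]),
                         IRanges(genes$start[gi] + 1, genes$end[gi]))
    if (!length(hits)) next
    q <- queryHits(hits); s <- subjectHits(hits)
    hit_genes <- tapply(genes$gene[gi][s], q,
                        function(g) paste(sort(unique(g)), collapse = ","))
    rows <- ei[as.integer(names(hit_genes))]
    events$coding_affected[rows] <- TRUE
    events$genes_hit[rows] <- as.character(hit_genes)
  }
  events
}

#' Per-hotspot cohort summary table
#'
#' One row per hotspot region with its limits in Mb, the gene(s) whose
#' exons fall in the region (or `"none"`), and one cell per cohort holding
#' the independent-event count with the coding-affected count in
#' parentheses — `"n (n_coding)"`, or `"n (na)"` for gene-less regions.
#'
#' @param events Independent events with columns `chrom`, `start`, `end`,
#'   `cohort` and `coding_affected` (see [exon_overlap()]).
#' @param hotspots Regions tibble (`chrom`, `start`, `end`).
#' @param genes Exon model tibble, or `NULL`.
#' @param cohorts Cohort column order; defaults to the cohorts present.
#' @return Tibble: `region`, `limits_mb`, `gene`, one character column per
#'   cohort.
#' @export
cohort_table <- function(events, hotspots, genes = NULL, cohorts = NULL) {
  events <- tibble::as_tibble(events)
  if (!"cohort" %in% names(events)) events$cohort <- "cohort1"
  cohorts <- cohorts %||% unique(events$cohort)
  if (!"coding_affected" %in% names(events)) events$coding_affected <- NA
  mid <- interval_mid(events$start, events$end)
  purrr::map_dfr(seq_len(nrow(hotspots)), function(j) {
    h <- hotspots[j, ]
    gene <- "none"
    if (!is.null(genes) && nrow(genes)) {
      gi <- genes$chrom == h$chrom & genes$start < h$end & genes$end > h$start
      if (any(gi)) gene <- paste(sort(unique(genes$gene[gi])), collapse = ",")
    }
    inside <- events$chrom == h$chrom & mid >= h$start & mid < h$end
    cells <- vapply(cohorts, function(co) {
      i <- inside & events$cohort == co
      if (gene == "none") sprintf("%d (na)", sum(i))
      else sprintf("%d (%d)", sum(i), sum(i & events$coding_affected %in% TRUE))
    }, character(1))
    out <- tibble(region = sprintf("%s:%s-%s Mb", h$chrom,
                                   fmt_mb(h$start), fmt_mb(h$end)),
                  limits_mb = sprintf("%s-%s", fmt_mb(h$start), fmt_mb(h$end)),
                  gene = gene)
    out[cohorts] <- as.list(cells)
    out
  })
}
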
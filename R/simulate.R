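#' Trio cohort design parameters
#'
#' Captures the study-level quantities of a trio cohort: its size, the
#' per-genome call sensitivity the intensity model is calibrated to, and the
#' de novo deletion process.  The defaults are the conditions of the study
#' the pipeline models: 440 trios, standalone caller sensitivity about 0.75,
#' a de novo rate chosen so that 440 offspring over 7 Mb of hotspot sequence
#' yield 5 expected de novo deletions, and a 3/5 maternal fraction.
#'
#' @param n_trios Number of parent-parent-child trios (>= 1; 0 allowed for
#'   degenerate empty cohorts).
#' @param sensitivity Designed per-genome strict-caller sensitivity in (0, 1]
#'   for deletions spanning >= 3 SNPs.  Declarative: the emission noise and
#'   caller thresholds shipped as defaults are calibrated to realise it.
#' @param denovo_rate De novo deletions per child per Mb of hotspot sequence.
#'   The default, 5 / (440 * 7), is equivalent to 4.87e-4 per generation per
#'   chromosome per 0.6 Mb with two contributing parental chromosomes.
#' @param maternal_fraction Probability a de novo event arises on the
#'   maternal chromosome.
#' @param denovo_in_hotspots If `TRUE` (default) de novo events are placed
#'   only inside hotspot intervals; `denovo_background_rate` (per child per
#'   background Mb) adds genome-wide events when positive.
#' @param denovo_background_rate See above; default 0.
#' @return An object of class `trio_design`.
#' @export
trio_design <- function(n_trios = 440, sensitivity = 0.75,
                        denovo_rate = 5 / (440 * 7),
                        maternal_fraction = 0.6,
                        denovo_in_hotspots = TRUE,
                        denovo_background_rate = 0) {
  stop_not(n_trios >= 0, "`n_trios` must be >= 0")
  stop_not(sensitivity > 0 && sensitivity <= 1, "`sensitivity` must be in (0, 1]")
  stop_not(denovo_rate >= 0, "`denovo_rate` must be >= 0")
  stop_not(maternal_fraction >= 0 && maternal_fraction <= 1,
           "`maternal_fraction` must be in [0, 1]")
  structure(list(n_trios = as.integer(n_trios), sensitivity = sensitivity,
                 denovo_rate = denovo_rate,
                 maternal_fraction = maternal_fraction,
                 denovo_in_hotspots = denovo_in_hotspots,
                 denovo_background_rate = denovo_background_rate),
            class = "trio_design")
}

#' @export
print.trio_design <- function(x, ...) {
  cat(sprintf("<trio_design> %d trios, s = %.2f, de novo %.3g / child / hotspot-Mb, maternal %.2f\n",
              x$n_trios, x$sensitivity, x$denovo_rate, x$maternal_fraction))
  invisible(x)
}

#' LogR emission noise model
#'
#' LogR at a diploid SNP is N(0, `sd_diploid`).  Inside a heterozygous
#' deletion the dominant variation is event-level, not SNP-level: each
#' (sample, deletion) draws one intensity deficit
#' `delta = mu_del + event_sd * Z`, with `Z` standard normal truncated above
#' at `event_zmax`, and its SNPs scatter tightly around it with SD
#' `snp_sd`.  Whole events therefore hybridise bright or dim — the way real
#' HMM callers miss entire events — while every true deletion retains a
#' discernible deficit (at least `mu_del + event_sd * event_zmax`, -0.31
#' at the defaults), so a targeted re-examination of a genome known to
#' carry a deletion essentially never comes up empty.  This is the regime
#' the two-generation sensitivity arithmetic `S = 1 - (1 - s)^2` assumes:
#' per-genome misses are event-level coin flips, independent between parent
#' and child.  The defaults are calibrated so the default strict caller
#' detects deletions spanning >= 3 SNPs with per-genome sensitivity ~0.75.
#'
#' @param mu_del Centre of the event-level LogR deficit (< 0).
#' @param event_sd Scale of the event-level deficit distribution.
#' @param event_zmax Upper truncation (in SDs) of the deficit: no true
#'   deletion is dimmer than `mu_del + event_sd * event_zmax` (< 0 required).
#' @param snp_sd Within-event per-SNP SD.
#' @param sd_diploid Per-SNP SD at copy number 2.
#' @return An object of class `logr_noise`.
#' @export
logr_noise <- function(mu_del = -0.66, event_sd = 0.25, event_zmax = 1.4,
                       snp_sd = 0.04, sd_diploid = 0.20) {
  stop_not(event_sd > 0 && snp_sd > 0 && sd_diploid > 0, "noise SDs must be > 0")
  stop_not(mu_del < 0, "`mu_del` must be < 0")
  stop_not(mu_del + event_sd * event_zmax < 0,
           "`event_zmax` must keep the deficit below 0")
  structure(list(mu_del = mu_del, event_sd = event_sd,
                 event_zmax = event_zmax, snp_sd = snp_sd,
                 sd_diploid = sd_diploid), class = "logr_noise")
}

# Piecewise-constant deletion intensity segments for one genome model.
# weight = Mb * multiplier; used for site sampling and total rates.
intensity_segments <- function(model) {
  purrr::map_dfr(seq_len(nrow(model$autosomes)), function(i) {
    chrom <- model$autosomes$chrom[i]
    len <- model$autosomes$length[i]
    hs <- dplyr::filter(model$hotspots, .data$chrom == !!chrom)
    cuts <- sort(unique(c(0, len, hs$start, hs$end)))
    seg <- tibble(chrom = chrom, start = cuts[-length(cuts)], end = cuts[-1])
    seg$multiplier <- 1
    if (nrow(hs)) {
      for (j in seq_len(nrow(hs))) {
        inside <- seg$start >= hs$start[j] & seg$end <= hs$end[j]
        seg$multiplier[inside] <- hs$multiplier[j]
      }
    }
    seg
  }) |>
    mutate(weight = (.data$end - .data$start) / 1e6 * .data$multiplier)
}

#' Simulate founder deletion events
#'
#' Draws deletion sites from an inhomogeneous point process whose intensity
#' is `base_rate` per Mb per genome outside hotspots and `base_rate *
#' multiplier` inside.  Lengths are truncated lognormal, with the hotspot
#' median (default 54 kb) about twice the background median; deletions are
#' centred on their site and clipped to the chromosome.  Overlapping
#' deletions within one genome are dropped (greedy, earlier kept), so no
#' genome carries more than one deletion at a locus.
#'
#' @param model A [build_genome_model()] object.
#' @param n_genomes Number of founder genomes (0 gives an empty truth set).
#' @param base_rate Background deletion intensity per Mb per genome (> 0).
#'   The default yields about 1.3 deletions per founder genome on the
#'   default mini genome, of which about 0.85 span >= 3 SNPs — the scale of
#'   the true per-genome counts implied by the study's sensitivity-corrected
#'   totals.
#' @param sample_ids Optional character vector of genome ids (length
#'   `n_genomes`).
#' @param length_median_hotspot,length_median_background Median deletion
#'   length (bp) for events whose site lies inside / outside a hotspot.
#' @param length_sdlog Lognormal shape; the default 1.15 puts ~68% of
#'   hotspot deletion lengths in 20-200 kb.
#' @param length_range Truncation bounds in bp (array resolution to
#'   sub-chromosomal).
#' @param seed Integer seed; the truth set is deterministic given it.
#' @return Tibble with columns `sample`, `chrom`, `start`, `end`, `length`,
#'   `in_hotspot`, `origin` (`"founder"`).
#' @export
simulate_deletion_events <- function(model, n_genomes,
                                     base_rate = 4.9e-3,
                                     sample_ids = NULL,
                                     length_median_hotspot = 54e3,
                                     length_median_background = 27e3,
                                     length_sdlog = 1.15,
                                     length_range = c(3e3, 2e6),
                                     seed = 1L) {
  stop_not(inherits(model, "genome_model"), "`model` must be a genome_model")
  stop_not(base_rate > 0, "`base_rate` must be > 0")
  if (is.null(sample_ids)) sample_ids <- sprintf("G%05d", seq_len(n_genomes))
  stop_not(length(sample_ids) == n_genomes, "`sample_ids` length mismatch")
  empty <- tibble(sample = character(), chrom = character(), start = double(),
                  end = double(), length = double(), in_hotspot = logical(),
                  origin = character())
  if (n_genomes == 0) return(empty)

  seg <- intensity_segments(model)
  lambda <- base_rate * sum(seg$weight)
  chrom_len <- setNames(model$autosomes$length, model$autosomes$chrom)

  withr::with_seed(as.integer(seed), {
    counts <- rpois(n_genomes, lambda)
    m <- sum(counts)
    if (m == 0) return(empty)
    idx <- sample.int(nrow(seg), m, replace = TRUE, prob = seg$weight)
    site <- seg$start[idx] + runif(m) * (seg$end[idx] - seg$start[idx])
    in_hot <- point_in_regions(seg$chrom[idx], site, model$hotspots)
    len <- numeric(m)
    if (any(in_hot)) {
      len[in_hot] <- rlnorm_trunc(sum(in_hot), length_median_hotspot,
                                  length_sdlog, length_range)
    }
    if (any(!in_hot)) {
      len[!in_hot] <- rlnorm_trunc(sum(!in_hot), length_median_background,
                                   length_sdlog, length_range)
    }
    del <- tibble(
      sample = rep(sample_ids, counts),
      chrom = seg$chrom[idx],
      start = pmax(0, round(site - len / 2)),
      in_hotspot = in_hot
    )
    del$end <- unname(pmin(chrom_len[del$chrom], round(site + len / 2)))
    del <- del |>
      filter(.data$end > .data$start) |>
      arrange(.data$sample, .data$chrom, .data$start)
    keep <- drop_overlaps(paste(del$sample, del$chrom), del$start, del$end)
    del[keep, ] |>
      mutate(length = .data$end - .data$start, origin = "founder") |>
      select("sample", "chrom", "start", "end", "length", "in_hotspot", "origin")
  })
}

#' Standard pedigree table for n trios
#'
#' @param n_trios Number of trios.
#' @return Tibble with columns `family`, `child`, `father`, `mother`.
#' @export
make_pedigree <- function(n_trios) {
  fam <- sprintf("F%04d", seq_len(n_trios))
  tibble(family = fam, child = paste0(fam, "_ch"),
         father = paste0(fam, "_fa"), mother = paste0(fam, "_mo"))
}

#' Transmit founder deletions to offspring and add de novo events
#'
#' Each parental deletion is transmitted independently with probability 1/2
#' (its `transmitted` flag is set accordingly).  De novo deletions are added
#' to each child at rate `design$denovo_rate` per hotspot Mb, restricted to
#' hotspot intervals by default, maternal with probability
#' `design$maternal_fraction`; an optional genome-wide component uses
#' `design$denovo_background_rate` per background Mb.
#'
#' @param founder_truth Truth tibble from [simulate_deletion_events()], with
#'   samples named as in `pedigree`'s `father`/`mother` columns.
#' @param model A `genome_model`.
#' @param design A [trio_design()].
#' @param pedigree Pedigree tibble (see [make_pedigree()]).
#' @param seed Integer seed.
#' @return Truth tibble covering parents and offspring.  Parental rows carry
#'   `transmitted` (logical); offspring rows carry `inherited_from` (the
#'   parental sample, `NA` for de novo) and `origin` in
#'   `founder` / `de_novo_maternal` / `de_novo_paternal`.
#' @export
transmit_to_offspring <- function(founder_truth, model, design, pedigree,
                                  seed = 1L) {
  stop_not(inherits(design, "trio_design"), "`design` must be a trio_design")
  parent_of <- c(setNames(pedigree$family, pedigree$father),
                 setNames(pedigree$family, pedigree$mother))
  unknown <- setdiff(unique(founder_truth$sample), names(parent_of))
  stop_not(length(unknown) == 0,
           paste0("founder samples not in pedigree: ", paste(unknown, collapse = ", ")))

  hs <- model$hotspots
  hot_mb <- sum(hs$end - hs$start) / 1e6
  bg_mb <- sum(model$autosomes$length) / 1e6 - hot_mb

  withr::with_seed(as.integer(seed), {
    founders <- founder_truth
    founders$transmitted <- if (nrow(founders)) rbinom(nrow(founders), 1, 0.5) == 1 else logical()

    child_of <- setNames(pedigree$child, pedigree$family)
    inherited <- founders |>
      filter(.data$transmitted) |>
      mutate(inherited_from = .data$sample,
             sample = unname(child_of[parent_of[.data$sample]]),
             transmitted = NA)

    # de novo events, hotspot-restricted (plus optional genome-wide term)
    lam_hot <- if (design$denovo_in_hotspots && hot_mb > 0) design$denovo_rate * hot_mb else 0
    lam_bg <- design$denovo_background_rate * bg_mb
    n_dn <- if (nrow(pedigree)) rpois(nrow(pedigree), lam_hot + lam_bg) else integer()
    m <- sum(n_dn)
    denovo <- NULL
    if (m > 0) {
      from_hot <- runif(m) < lam_hot / (lam_hot + lam_bg)
      chrom <- character(m); site <- numeric(m)
      if (any(from_hot)) {
        w <- hs$end - hs$start
        i <- sample.int(nrow(hs), sum(from_hot), replace = TRUE, prob = w)
        chrom[from_hot] <- hs$chrom[i]
        site[from_hot] <- hs$start[i] + runif(sum(from_hot)) * w[i]
      }
      if (any(!from_hot)) {
        a <- model$autosomes
        i <- sample.int(nrow(a), sum(!from_hot), replace = TRUE, prob = a$length)
        chrom[!from_hot] <- a$chrom[i]
        site[!from_hot] <- runif(sum(!from_hot)) * a$length[i]
      }
      len <- rlnorm_trunc(m, 54e3, 1.15, c(3e3, 2e6))
      chrom_len <- setNames(model$autosomes$length, model$autosomes$chrom)
      maternal <- runif(m) < design$maternal_fraction
      denovo <- tibble(
        sample = rep(pedigree$child, n_dn),
        chrom = chrom,
        start = pmax(0, round(site - len / 2)),
        end = unname(pmin(chrom_len[chrom], round(site + len / 2))),
        in_hotspot = from_hot,
        origin = ifelse(maternal, "de_novo_maternal", "de_novo_paternal"),
        transmitted = NA,
        inherited_from = NA_character_
      ) |>
        filter(.data$end > .data$start) |>
        mutate(length = .data$end - .data$start)
    }

    offspring <- bind_rows(inherited, denovo) |>
      arrange(.data$sample, .data$chrom, .data$start)
    if (nrow(offspring)) {
      keep <- drop_overlaps(paste(offspring$sample, offspring$chrom),
                            offspring$start, offspring$end)
      offspring <- offspring[keep, ]
    }
    bind_rows(founders, offspring) |>
      select("sample", "chrom", "start", "end", "length", "in_hotspot",
             "origin", "transmitted", dplyr::any_of("inherited_from"))
  })
}

#' Render LogR intensity tracks for a set of samples
#'
#' Produces one LogR value per SNP per sample under [logr_noise()]: diploid
#' SNPs draw N(0, sd_diploid); SNPs inside a heterozygous deletion draw the
#' shifted law with a shared per-event component.  Deletions covering fewer
#' than 3 SNPs are rendered like any other — whether they are callable is
#' the caller's problem.
#'
#' @param truth Truth tibble (rows for samples not in `samples` are ignored).
#' @param model A `genome_model`; truth deletions must lie on its chromosomes.
#' @param samples Character vector of samples to render (rows of the output).
#' @param noise A [logr_noise()] object.
#' @param seed Integer seed.
#' @return Numeric matrix, samples x SNPs, with `rownames` the sample ids
#'   and `colnames` the SNP names of `model$snps`.
#' @export
render_logr <- function(truth, model, samples, noise = logr_noise(), seed = 1L) {
  stop_not(inherits(noise, "logr_noise"), "`noise` must be a logr_noise object")
  stop_not(all(truth$chrom %in% model$autosomes$chrom),
           "truth deletions must lie on the model's chromosomes")
  snps <- model$snps
  n <- length(samples); p <- nrow(snps)
  truth <- dplyr::filter(truth, .data$sample %in% samples)
  pmax_z <- stats::pnorm(noise$event_zmax)

  # per-chromosome position vectors for fast interval -> SNP-run lookup
  pos_by_chrom <- split(seq_len(p), snps$chrom)

  withr::with_seed(as.integer(seed), {
    x <- matrix(rnorm(n * p, 0, noise$sd_diploid), n, p,
                dimnames = list(samples, snps$snp))
    if (nrow(truth)) {
      row_of <- setNames(seq_len(n), samples)
      for (i in seq_len(nrow(truth))) {
        idx <- pos_by_chrom[[truth$chrom[i]]]
        pos <- snps$pos[idx]
        lo <- findInterval(truth$start[i] - 0.5, pos) + 1L
        hi <- findInterval(truth$end[i] - 0.5, pos)
        if (hi >= lo) {
          cols <- idx[lo:hi]
          delta <- noise$mu_del +
            noise$event_sd * stats::qnorm(runif(1, 0, pmax_z))
          x[row_of[truth$sample[i]], cols] <-
            delta + rnorm(length(cols), 0, noise$snp_sd)
        }
      }
    }
    x
  })
}

#' Simulate a complete trio cohort
#'
#' Convenience wrapper chaining [simulate_deletion_events()] (founders),
#' [transmit_to_offspring()] and [render_logr()] with deterministic
#' stage-specific seeds derived from one master seed.
#'
#' @param design A [trio_design()].
#' @param model A `genome_model`, default [default_genome_model()].
#' @param base_rate Background founder deletion intensity per Mb per genome.
#' @param noise A [logr_noise()].
#' @param seed Master seed.
#' @param render If `FALSE`, skip track rendering (truth only; `tracks` is
#'   `NULL`).  Useful for event-level studies at large scale.
#' @return An object of class `trio_cohort`: list with `model`, `design`,
#'   `pedigree`, `truth`, `tracks`, `noise`, `seed`.
#' @export
simulate_trio_cohort <- function(design = trio_design(), model = NULL,
                                 base_rate = 4.9e-3, noise = logr_noise(),
                                 seed = 1L, render = TRUE) {
  seeds <- derive_seeds(seed, 4)
  if (is.null(model)) model <- default_genome_model(seed = seeds[1])
  pedigree <- make_pedigree(design$n_trios)
  parents <- c(rbind(pedigree$father, pedigree$mother))
  founders <- simulate_deletion_events(model, length(parents),
                                       base_rate = base_rate,
                                       sample_ids = parents, seed = seeds[2])
  truth <- transmit_to_offspring(founders, model, design, pedigree,
                                 seed = seeds[3])
  samples <- c(pedigree$father, pedigree$mother, pedigree$child)
  tracks <- if (render) render_logr(truth, model, samples, noise, seed = seeds[4])
  structure(list(model = model, design = design, pedigree = pedigree,
                 truth = truth, tracks = tracks, noise = noise, seed = seed),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d trios, %d truth deletions, %s\n",
              nrow(x$pedigree), nrow(x$truth),
              if (is.null(x$tracks)) "tracks not rendered"
              else sprintf("%d x %d LogR matrix", nrow(x$tracks), ncol(x$tracks))))
  invisible(x)
}
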
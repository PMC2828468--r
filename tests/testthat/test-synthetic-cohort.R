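test_that("founder deletions under multiplier 1 are spatially homogeneous", {
  gm <- build_genome_model(hotspots = NULL, seed = 3)
  # dispersion test per seed: chi-square GOF of per-bin counts against a
  # common mean; at alpha = 0.01 over 20 seeds, at most ~1 failure expected
  fails <- 0L
  for (s in 1:20) {
    ev <- simulate_deletion_events(gm, n_genomes = 400, base_rate = 4e-3,
                                   seed = s)
    bins <- bin_counts(ev, gm, unit = 6e5)
    x <- bins$count[!bins$partial]
    stat <- sum((x - mean(x))^2) / mean(x)
    p <- stats::pchisq(stat, df = length(x) - 1, lower.tail = FALSE)
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 2L)
})

test_that("hotspot intensity multiplier is reproduced in event density", {
  hs <- tibble::tibble(chrom = "chr1", start = 12e6, end = 12.6e6,
                       multiplier = 100)
  gm <- build_genome_model(hotspots = hs, seed = 1)
  ev <- simulate_deletion_events(gm, n_genomes = 1500, base_rate = 5e-3,
                                 seed = 5)
  mid <- (ev$start + ev$end) / 2
  n_in <- sum(ev$chrom == "chr1" & mid >= 12e6 & mid < 12.6e6)
  n_out <- nrow(ev) - n_in
  dens_ratio <- (n_in / 0.6e6) / (n_out / (sum(gm$autosomes$length) - 0.6e6))
  # ~100x within generous sampling error
  expect_gt(dens_ratio, 70)
  expect_lt(dens_ratio, 140)
})

test_that("degenerate generator inputs behave", {
  gm <- build_genome_model()
  expect_equal(nrow(simulate_deletion_events(gm, 0)), 0)
  expect_error(simulate_deletion_events(gm, 10, base_rate = 0), "base_rate")
  expect_error(logr_noise(sd_diploid = 0), "SD")
  expect_error(logr_noise(event_zmax = 5), "deficit")
})

test_that("hotspot deletion lengths hit the 20-200 kb mass target", {
  gm <- default_genome_model()
  ev <- simulate_deletion_events(gm, n_genomes = 2500, seed = 11)
  hot <- ev[ev$in_hotspot, ]
  expect_gte(nrow(hot), 500)
  frac <- mean(hot$length >= 2e4 & hot$length <= 2e5)
  expect_gt(frac, 0.63)
  expect_lt(frac, 0.73)
  # background deletions are about half as long
  expect_lt(median(ev$length[!ev$in_hotspot]), 0.75 * median(hot$length))
  expect_true(all(ev$length >= 3e3 & ev$length <= 2e6))
  # no founder carries overlapping deletions
  ovl <- ev |>
    dplyr::arrange(sample, chrom, start) |>
    dplyr::group_by(sample, chrom) |>
    dplyr::summarise(bad = any(start < dplyr::lag(end, default = -1)),
                     .groups = "drop")
  expect_false(any(ovl$bad))
})

test_that("transmission is Mendelian and de novo events are offspring-only", {
  gm <- default_genome_model()
  design <- trio_design(n_trios = 400, denovo_rate = 0)
  ped <- make_pedigree(400)
  founders <- simulate_deletion_events(
    gm, 800, base_rate = 2e-2,
    sample_ids = c(rbind(ped$father, ped$mother)), seed = 2)
  truth <- transmit_to_offspring(founders, gm, design, ped, seed = 3)
  par_rows <- truth[!is.na(truth$transmitted), ]
  kid_rows <- truth[is.na(truth$transmitted), ]
  # conservation: every founder deletion is transmitted or not
  expect_equal(nrow(par_rows), nrow(founders))
  # transmitted founder rows == offspring inherited rows + overlap-dropped
  expect_lte(nrow(kid_rows), sum(par_rows$transmitted))
  expect_gt(nrow(kid_rows), 0.95 * sum(par_rows$transmitted))
  # Mendelian coin: 0.5 within 3 SE
  p <- mean(par_rows$transmitted)
  se <- sqrt(0.25 / nrow(par_rows))
  expect_lt(abs(p - 0.5), 3 * se)
  # with denovo_rate = 0, no de novo rows anywhere
  expect_true(all(truth$origin == "founder"))
  # de novo appear only in offspring and only in hotspots by default
  design2 <- trio_design(n_trios = 400, denovo_rate = 0.5)
  truth2 <- transmit_to_offspring(founders, gm, design2, ped, seed = 3)
  dn <- truth2[grepl("de_novo", truth2$origin), ]
  expect_gt(nrow(dn), 0)
  expect_true(all(dn$sample %in% ped$child))
  expect_true(all(dn$in_hotspot))
})

test_that("de novo parent-of-origin follows the maternal fraction", {
  gm <- default_genome_model()
  ped <- make_pedigree(300)
  founders <- simulate_deletion_events(gm, 0)
  design <- trio_design(n_trios = 300, denovo_rate = 5, maternal_fraction = 0.6)
  truth <- transmit_to_offspring(founders, gm, design, ped, seed = 9)
  dn <- truth[grepl("de_novo", truth$origin), ]
  expect_gt(nrow(dn), 1000)
  m <- mean(dn$origin == "de_novo_maternal")
  expect_lt(abs(m - 0.6), 3 * sqrt(0.24 / nrow(dn)))
})

test_that("rendered LogR tracks follow the emission model", {
  map <- tiny_map(n = 200)
  gm <- structure(list(autosomes = tiny_genome(n = 200),
                       snp_spacing = 1e4,
                       hotspots = tibble::tibble(
                         chrom = character(), start = double(),
                         end = double(), multiplier = double()),
                       genes = NULL, snps = map),
                  class = "genome_model")
  # clean sample: mean ~ 0
  x0 <- render_logr(tibble::tibble(sample = character(), chrom = character(),
                                   start = double(), end = double()),
                    gm, samples = "s1", seed = 4)
  expect_equal(dim(x0), c(1, 400))
  expect_lt(abs(mean(x0)), 4 * 0.20 / sqrt(400))

  # a 10-SNP deletion: every true event keeps a clear deficit, and the
  # event-level law sets how often the mean drops below -0.4
  truth <- tibble::tibble(sample = sprintf("s%03d", 1:300), chrom = "chr1",
                          start = 50e3, end = 150e3)
  x <- render_logr(truth, gm, samples = truth$sample, seed = 5)
  idx <- which(map$chrom == "chr1" & map$pos >= 50e3 & map$pos < 150e3)
  expect_length(idx, 10)
  ms <- rowMeans(x[, idx])
  expect_true(all(ms < -0.25))            # bounded deficit: never signal-free
  p_deep <- stats::pnorm((-0.4 + 0.66) / 0.25) / stats::pnorm(1.4)
  expect_lt(abs(mean(ms < -0.4) - p_deep), 3 * sqrt(p_deep * (1 - p_deep) / 300))

  # sub-3-SNP deletions are still rendered
  t2 <- tibble::tibble(sample = "s1", chrom = "chr1", start = 54e3, end = 70e3)
  x2 <- render_logr(t2, gm, samples = "s1", seed = 6)
  expect_true(all(x2[1, 6:7] < -0.15))
  expect_error(render_logr(t2, gm, samples = "s1",
                           noise = logr_noise(sd_diploid = -1)), "SD")
  expect_error(render_logr(dplyr::mutate(t2, chrom = "chrX"), gm,
                           samples = "s1"), "chromosome")
})

test_that("cohort simulation is deterministic given the master seed", {
  a <- simulate_trio_cohort(trio_design(n_trios = 5), seed = 123)
  b <- simulate_trio_cohort(trio_design(n_trios = 5), seed = 123)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_trio_cohort(trio_design(n_trios = 5), seed = 124)
  expect_false(identical(a$tracks, c$tracks))
})
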
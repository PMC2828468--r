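test_that("the de novo rate calculator does the per-unit arithmetic", {
  r <- de_novo_rate(5, 440, 7e6, 6e5)
  expect_equal(r$rate, 5 / (2 * 440) * (6e5 / 7e6), tolerance = 1e-12)
  expect_equal(r$rate, 3 / 6160, tolerance = 1e-12)     # = 4.870e-4
  expect_equal(de_novo_rate(0, 440, 7e6)$rate, 0)
  expect_equal(de_novo_rate(2, 100, 1.2e6, 6e5)$rate, 5e-3, tolerance = 1e-12)
  # linearity in d and in u
  expect_equal(de_novo_rate(10, 440, 7e6)$rate, 2 * r$rate)
  expect_equal(de_novo_rate(5, 440, 7e6, 3e5)$rate, r$rate / 2)
  expect_error(de_novo_rate(5, 440, 0), "hotspot_length")
})

test_that("the incidence-based projection reproduces the DMD-style arithmetic", {
  r <- incidence_hotspot_rate(1 / 3500, 1 / 3, 0.60, 2 / 3)
  expect_equal(r$ascertainable, (1 / 3500) * (1 / 3) * 0.6 * (2 / 3),
               tolerance = 1e-12)
  expect_equal(r$ascertainable_1sf, 4e-5)
  expect_equal(r$projected, 2 * r$ascertainable)
  expect_equal(r$projected_1sf, 8e-5)
  expect_equal(incidence_hotspot_rate(0, 1 / 3, 0.6, 2 / 3)$projected, 0)
  expect_error(incidence_hotspot_rate(1 / 3500, 1.2, 0.6, 2 / 3), "fraction")
})

test_that("rate ratios are normalised per unit length", {
  r1 <- de_novo_rate(5, 440, 7e6, 6e5)
  r2 <- incidence_hotspot_rate(1 / 3500, 1 / 3, 0.60, 2 / 3)
  fold <- rate_ratio(r1, r2)
  expect_equal(fold, (r1$rate / 6e5) / (r2$projected / 7e5), tolerance = 1e-12)
  expect_gte(fold, 5)
  # identical rates over identical units give 1
  expect_equal(rate_ratio(1e-4, 1e-4, 6e5, 6e5), 1)
  # same quoted rate over a doubled unit is half the per-bp rate,
  # so the normalised ratio doubles
  expect_equal(rate_ratio(1e-4, 1e-4, 6e5, 1.2e6), 2)
  expect_error(rate_ratio(1e-4, 0, 6e5, 6e5), "zero")
})

test_that("length statistics split by hotspot status and test the window mass", {
  hs <- tibble::tibble(chrom = "chr1", start = 10e6, end = 10.6e6)
  mk <- function(n, len, inside) {
    mid <- if (inside) 10.3e6 else 20e6
    tibble::tibble(chrom = "chr1", start = mid - len / 2 + seq_len(n) * 0,
                   end = mid + len / 2)
  }
  events <- dplyr::bind_rows(
    purrr::map_dfr(c(54e3, 94e3, 20e3), ~ mk(1, .x, TRUE)),
    purrr::map_dfr(c(10e3, 300e3, 25e3), ~ mk(1, .x, FALSE)))
  ls <- length_statistics(events, hs)
  hot <- ls$stats[ls$stats$group == "hotspot", ]
  expect_equal(hot$median, 54e3)
  expect_equal(hot$n, 3)
  expect_equal(hot$fraction_in_range, 1)
  bg <- ls$stats[ls$stats$group == "background", ]
  expect_equal(bg$fraction_in_range, 1 / 3)
  expect_error(length_statistics(events[1:3, ], hs), "background")

  # 2x2 chi-square equals the hand formula, with and without correction
  grp <- rep(c("in", "out"), c(135, 322))
  lens <- c(rep(5e4, 92), rep(5e5, 43), rep(5e4, 162), rep(5e5, 160))
  ev2 <- tibble::tibble(chrom = "chr1",
                        start = ifelse(grp == "in", 10.2e6, 20e6),
                        end = ifelse(grp == "in", 10.2e6, 20e6) + lens)
  ls2 <- length_statistics(ev2, hs)
  a <- 92; b <- 43; c <- 162; d <- 160; N <- a + b + c + d
  by_hand <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(ls2$test$statistic[!ls2$test$correction], by_hand,
               tolerance = 1e-9)
  expect_lt(ls2$test$p_value[!ls2$test$correction], 0.05)
  expect_lt(ls2$test$statistic[ls2$test$correction], by_hand)
})

test_that("exon overlap uses half-open interval intersection", {
  genes <- tibble::tibble(gene = c("PARK-like", "PARK-like", "other"),
                          chrom = c("chr1", "chr1", "chr2"),
                          start = c(1e6, 2e6, 5e6), end = c(1.01e6, 2.02e6, 5.1e6))
  events <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1.5e6, 1.99e6, 0.5e6, 4e6),
    end = c(1.6e6, 2.5e6, 1e6, 5.05e6))   # intronic; exon hit; abutting; hit
  out <- exon_overlap(events, genes)
  expect_equal(out$coding_affected, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$genes_hit, c(NA, "PARK-like", NA, "other"))
  expect_error(exon_overlap(events, dplyr::mutate(genes, end = start)),
               "malformed")

  # brute-force pairwise intersection oracle on random fixtures
  set.seed(7)
  for (rep in 1:40) {
    ev <- tibble::tibble(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                         start = sample(1e5, 30))
    ev$end <- ev$start + sample(5e3, 30)
    gn <- tibble::tibble(gene = paste0("g", 1:12),
                         chrom = sample(c("c1", "c2"), 12, replace = TRUE),
                         start = sample(1e5, 12))
    gn$end <- gn$start + sample(5e3, 12)
    got <- exon_overlap(ev, gn)$coding_affected
    want <- vapply(seq_len(nrow(ev)), function(i) {
      any(gn$chrom == ev$chrom[i] & gn$start < ev$end[i] & gn$end > ev$start[i])
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("the cohort table formats per-region counts Table-1 style", {
  hs <- tibble::tibble(chrom = c("chr1", "chr2"),
                       start = c(14.5e6, 5.4e6), end = c(15.1e6, 6.0e6))
  genes <- tibble::tibble(gene = "MACRO-like", chrom = "chr1",
                          start = 14.6e6, end = 14.62e6)
  events <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = 14.55e6 + (0:7) * 5e4,
                   end = 14.58e6 + (0:7) * 5e4, cohort = "ADHD",
                   coding_affected = FALSE),
    tibble::tibble(chrom = "chr2", start = 5.5e6, end = 5.6e6,
                   cohort = "EN", coding_affected = FALSE))
  tab <- cohort_table(events, hs, genes, cohorts = c("ADHD", "EN"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$gene, c("MACRO-like", "none"))
  expect_equal(tab$ADHD[1], "8 (0)")        # 8 events, none exon-disrupting
  expect_equal(tab$EN[1], "0 (0)")
  expect_equal(tab$EN[2], "1 (na)")         # gene-less region
  expect_equal(tab$limits_mb[1], "14.5-15.1")
  # empty cohort column zero-fills
  tab2 <- cohort_table(events[0, ], hs, genes, cohorts = "LG")
  expect_equal(tab2$LG, c("0 (0)", "0 (na)"))
})
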
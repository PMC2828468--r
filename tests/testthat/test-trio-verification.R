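test_that("boundary matching is exact, tolerant and symmetric", {
  a <- mk_call("c1", "chr1", 10, 20)
  b <- mk_call("p1", "chr1", 10, 20)
  expect_true(match_boundaries(a, b))
  # one-SNP boundary shift: rejected at tolerance 0, accepted at 1
  b1 <- mk_call("p1", "chr1", 11, 20)
  expect_false(match_boundaries(a, b1, tolerance = 0))
  expect_true(match_boundaries(a, b1, tolerance = 1))
  # disjoint calls never match below their span
  expect_false(match_boundaries(a, mk_call("p1", "chr1", 40, 50), tolerance = 5))
  # different chromosome never matches
  expect_false(match_boundaries(a, mk_call("p1", "chr2", 10, 20)))
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:200) {
    f1 <- sample(100, 1); l1 <- f1 + sample(0:5, 1)
    f2 <- f1 + sample(-3:3, 1); l2 <- l1 + sample(-3:3, 1)
    tol <- sample(0:2, 1)
    x <- mk_call("a", "chr1", f1, l1); y <- mk_call("b", "chr1", f2, l2)
    expect_equal(match_boundaries(x, y, tol), match_boundaries(y, x, tol))
  }
})

test_that("round 1 labels constructed trios correctly", {
  map <- tiny_map()
  ped <- tibble::tibble(family = "f1", child = "ch", father = "fa", mother = "mo")
  # child deletion at SNPs 11-15; three parental scenarios
  child_call <- mk_call("ch", "chr1", 11, 15, map)

  # (1) father carries a called deletion with identical boundaries
  tracks <- rbind(ch = make_track(map, 11:15), fa = make_track(map, 11:15),
                  mo = make_track(map))
  pc <- mk_call("fa", "chr1", 11, 15, map)
  r1 <- classify_round1(child_call, pc, tracks, map, ped)
  expect_equal(r1$labels$label, "transmitted")
  expect_true(r1$labels$matched)
  expect_equal(r1$labels$support_parent, "fa")

  # (2) parents called nothing; mother has sub-threshold signal -> rescued
  tracks2 <- rbind(ch = make_track(map, 11:15),
                   fa = make_track(map),
                   mo = make_track(map, 11:15, value = -0.35))
  r2 <- classify_round1(child_call, pc[0, ], tracks2, map, ped)
  expect_equal(r2$labels$label, "transmitted")
  expect_false(r2$labels$matched)
  expect_equal(r2$labels$support_parent, "mo")
  expect_equal(r2$parent_rescues$provenance, "rescued")

  # (3) both parents flat at the locus -> de novo
  tracks3 <- rbind(ch = make_track(map, 11:15), fa = make_track(map),
                   mo = make_track(map))
  r3 <- classify_round1(child_call, pc[0, ], tracks3, map, ped)
  expect_equal(r3$labels$label, "de_novo")

  # missing parent track -> trio skipped with a warning
  expect_warning(
    r4 <- classify_round1(child_call, pc, tracks[c("ch", "fa"), ], map, ped),
    "missing parent")
  expect_equal(nrow(r4$labels), 0)
})

test_that("round 2 recovers uncalled offspring deletions and labels the rest", {
  map <- tiny_map()
  ped <- tibble::tibble(family = "f1", child = "ch", father = "fa", mother = "mo")
  pc <- dplyr::bind_rows(
    mk_call("fa", "chr1", 11, 15, map),   # child has weak signal -> recovered
    mk_call("mo", "chr1", 30, 34, map),   # child flat -> non-transmitted
    mk_call("fa", "chr2", 60, 64, map))   # child called & matched -> no action
  oc <- mk_call("ch", "chr2", 60, 64, map)
  tracks <- rbind(
    ch = make_track(map, 11:15, value = -0.35) + make_track(map, 60:64) - 0,
    fa = make_track(map, c(11:15, 60:64)),
    mo = make_track(map, 30:34))
  tracks["ch", 60:64] <- -0.7
  r2 <- classify_round2(pc, oc, tracks, map, ped)
  expect_equal(r2$parent_status$status, c("recovered", "nontransmitted", "matched"))
  expect_equal(nrow(r2$recovered), 1)
  expect_equal(r2$recovered$sample, "ch")
  expect_equal(r2$recovered$provenance, "rescued")
  expect_equal(r2$recovered$label, "transmitted")
  expect_equal(nrow(r2$nontransmitted), 1)
  expect_equal(r2$nontransmitted$sample, "mo")
})

test_that("the ledger arithmetic reproduces the worked bookkeeping", {
  # 274 matched + 85 rescued -> 359 transmitted; +7 de novo +33 recovered -> 399
  l <- trio_ledger(matched_in_parent = 274, rescued_in_parent = 85,
                   de_novo = 7, rescued_in_offspring = 33)
  expect_equal(l$transmitted_total, 359)
  expect_equal(l$offspring_affirmed_total, 366)
  expect_equal(l$offspring_total_final, 399)

  # explicit totals that contradict the parts are rejected
  expect_error(trio_ledger(matched_in_parent = 274, rescued_in_parent = 85,
                           transmitted_total = 358), "invariant")
  expect_error(trio_ledger(matched_in_parent = -1), ">= 0")

  # an empty verification compiles to an all-zero ledger
  empty_r1 <- list(labels = mk_call("x", "chr1", 1, 3)[0, ] |>
                     dplyr::mutate(label = character(), matched = logical()),
                   parent_rescues = mk_call("x", "chr1", 1, 3)[0, ])
  empty_r2 <- list(parent_status = mk_call("x", "chr1", 1, 3)[0, ] |>
                     dplyr::mutate(status = character()),
                   recovered = mk_call("x", "chr1", 1, 3)[0, ],
                   nontransmitted = mk_call("x", "chr1", 1, 3)[0, ])
  l0 <- compile_ledger(empty_r1, empty_r2)
  expect_equal(l0$offspring_total_final, 0)
  expect_equal(l0$nontransmitted_total, 0)
})

test_that("sensitivity algebra links standalone and combined detection", {
  expect_equal(combined_sensitivity(0.75), 0.9375)
  expect_equal(combined_sensitivity(1), 1)
  expect_equal(combined_sensitivity(0.5), 0.75)
  est <- estimate_sensitivity(274, 366)
  expect_equal(est$standalone, 274 / 366, tolerance = 1e-12)
  expect_equal(round(est$standalone, 2), 0.75)
  expect_equal(round(est$combined, 2), 0.94)
  # from a compiled ledger
  l <- trio_ledger(matched_in_parent = 274, rescued_in_parent = 85,
                   de_novo = 7, rescued_in_offspring = 33)
  est2 <- estimate_sensitivity(l)
  expect_equal(est2$standalone, 274 / 366)
  expect_error(estimate_sensitivity(10, 0), "denominator")
})

test_that("true counts are detected counts scaled by sensitivity", {
  tc <- estimate_true_counts(c(270, 368, 100), c(0.75, 0.94, 1))
  expect_equal(tc$estimate, c(360, 368 / 0.94, 100))
  expect_equal(tc$estimate_rounded, c(360, 390, 100))
  expect_error(estimate_true_counts(100, 0), "sensitivity")
})

test_that("every affirmed offspring call gets exactly one label", {
  co <- simulate_trio_cohort(trio_design(n_trios = 60), seed = 31)
  calls <- call_deletions(co$tracks, co$model)
  v <- verify_trios(calls, co$tracks, co$model, co$pedigree)
  lab <- v$round1$labels
  expect_true(all(lab$label %in% c("transmitted", "de_novo")))
  l <- v$ledger
  expect_equal(l$transmitted_total + l$de_novo, l$offspring_affirmed_total)
  expect_equal(l$offspring_total_final,
               l$transmitted_total + l$de_novo + l$rescued_in_offspring)
  expect_equal(l$matched_in_parent + l$rescued_in_parent, l$transmitted_total)
  # ledger counts are consistent with the returned tibbles
  expect_equal(nrow(v$round2$nontransmitted), l$nontransmitted_total)
  expect_equal(nrow(v$offspring_final), l$offspring_total_final)
})
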
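ledger_fields <- c(
  "offspring_affirmed_independent", "offspring_affirmed_total",
  "matched_in_parent", "rescued_in_parent",
  "transmitted_total", "transmitted_independent", "de_novo",
  "parent_affirmed_independent", "parent_affirmed_total",
  "matched_in_offspring", "rescued_in_offspring", "rescued_already_known",
  "offspring_total_final", "offspring_independent_final",
  "nontransmitted_independent", "nontransmitted_total"
)

#' Construct a trio-verification ledger
#'
#' The ledger is the bookkeeping of the two-round cross-verification: how
#' many offspring calls were affirmed, how many were matched or rescued in a
#' parent, how many were de novo, how many parental calls were matched,
#' recovered or non-transmitted in the offspring, and the final totals.
#' Derived fields are computed when omitted and validated when supplied:
#' `transmitted_total = matched_in_parent + rescued_in_parent` and
#' `offspring_total_final = transmitted_total + de_novo +
#' rescued_in_offspring`.
#'
#' @param ... Named counts among the ledger fields (see
#'   [tidy.trio_ledger()] for the full list).  Unsupplied independent-event
#'   counts default to `NA`.
#' @return Object of class `trio_ledger`.
#' @examples
#' # the worked arithmetic of a real 440-trio screen:
#' trio_ledger(matched_in_parent = 274, rescued_in_parent = 85,
#'             de_novo = 7, rescued_in_offspring = 33)
#' @export
trio_ledger <- function(...) {
  given <- list(...)
  bad <- setdiff(names(given), ledger_fields)
  stop_not(length(bad) == 0,
           paste0("unknown ledger field(s): ", paste(bad, collapse = ", ")))
  x <- setNames(as.list(rep(NA_real_, length(ledger_fields))), ledger_fields)
  x[names(given)] <- given

  derive <- function(field, value) {
    if (is.na(x[[field]])) x[[field]] <<- value
    else if (!is.na(value) && x[[field]] != value) {
      rlang::abort(sprintf("ledger invariant violated: %s is %s but parts sum to %s",
                           field, format(x[[field]]), format(value)))
    }
  }
  derive("transmitted_total", x$matched_in_parent + x$rescued_in_parent)
  derive("offspring_affirmed_total", x$transmitted_total + x$de_novo)
  derive("offspring_total_final",
         x$transmitted_total + x$de_novo + x$rescued_in_offspring)
  vals <- unlist(x)
  stop_not(all(is.na(vals) | vals >= 0), "ledger counts must be >= 0")
  structure(x, class = "trio_ledger")
}

#' Compile the ledger from the two verification rounds
#'
#' @param round1 Result of [classify_round1()].
#' @param round2 Result of [classify_round2()].
#' @param tolerance Boundary tolerance used when collapsing to independent
#'   events.
#' @return A [trio_ledger()].
#' @export
compile_ledger <- function(round1, round2, tolerance = 0L) {
  lab <- round1$labels
  n_indep <- function(calls) {
    if (!nrow(calls)) return(0L)
    nrow(collapse_identical(calls, tolerance))
  }
  transmitted <- dplyr::filter(lab, .data$label == "transmitted")
  recovered <- round2$recovered
  if (!nrow(recovered)) recovered <- lab[0, ]
  # recovered events whose boundary class already appeared among round-1
  # offspring events (necessarily in another trio: same-trio re-detections
  # were marked `requeried` and never reach the recovered set)
  known <- if (nrow(recovered)) {
    purrr::map_lgl(seq_len(nrow(recovered)),
                   function(i) any_match(recovered[i, ], lab, tolerance))
  } else logical(0)

  trio_ledger(
    offspring_affirmed_total = nrow(lab),
    offspring_affirmed_independent = n_indep(lab),
    matched_in_parent = sum(lab$label == "transmitted" & lab$matched),
    rescued_in_parent = sum(lab$label == "transmitted" & !lab$matched),
    transmitted_total = nrow(transmitted),
    transmitted_independent = n_indep(transmitted),
    de_novo = sum(lab$label == "de_novo"),
    parent_affirmed_total = nrow(round2$parent_status),
    parent_affirmed_independent = n_indep(round2$parent_status),
    matched_in_offspring = sum(round2$parent_status$status %in%
                                 c("matched", "requeried")),
    rescued_in_offspring = nrow(round2$recovered),
    rescued_already_known = sum(known),
    offspring_independent_final = n_indep(bind_rows(lab, recovered)),
    nontransmitted_total = nrow(round2$nontransmitted),
    nontransmitted_independent = n_indep(round2$nontransmitted)
  )
}

#' @export
print.trio_ledger <- function(x, ...) {
  cat("<trio_ledger>\n")
  df <- tidy(x)
  cat(sprintf("  %-32s %s\n", df$metric, format(df$count)), sep = "")
  invisible(x)
}

#' Tidy a trio ledger into a metric/count tibble
#'
#' @param x A `trio_ledger`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `count`.
#' @export
tidy.trio_ledger <- function(x, ...) {
  tibble(metric = ledger_fields, count = unlist(x[ledger_fields]))
}

#' @export
glance.trio_ledger <- function(x, ...) {
  tibble::as_tibble(x[ledger_fields])
}

#' Estimate caller sensitivity from trio concordance
#'
#' The standalone sensitivity `s` is the probability that the strict caller
#' detects a deletion known to be present in a genome.  From a compiled
#' ledger it is estimated as the fraction of affirmed offspring deletions
#' whose parent carried a *called* deletion at the same boundaries
#' (`matched_in_parent / offspring_affirmed_total`): every affirmed
#' offspring deletion that proved transmitted marks a parental genome known
#' to carry it, and the parental strict call either fired or did not.  The
#' combined sensitivity of the two-round procedure, in which a call in
#' either generation triggers a targeted rescue in the other, is
#' `S = 1 - (1 - s)^2`.
#'
#' @param x A `trio_ledger`, or the number of called carrier genomes.
#' @param n_present When `x` is a count: the number of genomes known to
#'   carry the deletion (> 0).
#' @param ... Unused.
#' @return Object of class `sensitivity_estimate` with fields `standalone`,
#'   `combined`, `method`.
#' @examples
#' estimate_sensitivity(274, 366)   # ~0.75, combined ~0.94
#' @export
estimate_sensitivity <- function(x, n_present = NULL, ...) {
  if (inherits(x, "trio_ledger")) {
    stop_not(!is.na(x$offspring_affirmed_total) && x$offspring_affirmed_total > 0,
             "ledger has no affirmed offspring deletions")
    s <- x$matched_in_parent / x$offspring_affirmed_total
    method <- "matched fraction of affirmed offspring deletions"
  } else {
    stop_not(is.numeric(x) && !is.null(n_present), "supply (n_called, n_present)")
    stop_not(n_present > 0, "zero denominator")
    s <- x / n_present
    method <- "direct fraction"
  }
  stop_not(s > 0 && s <= 1, "estimated sensitivity outside (0, 1]")
  structure(list(standalone = s, combined = combined_sensitivity(s),
                 method = method),
            class = "sensitivity_estimate")
}

#' Combined sensitivity of two-generation cross-verification
#'
#' A deletion present in both a parent and a child is found unless the
#' strict caller misses it in *both* genomes, since a call in either genome
#' triggers a targeted rescue in the other: `S = 1 - (1 - s)^2`.
#'
#' @param s Standalone per-genome sensitivity in (0, 1].
#' @return Combined sensitivity `S >= s`.
#' @examples
#' combined_sensitivity(0.75)  # 0.9375
#' @export
combined_sensitivity <- function(s) {
  stop_not(all(s > 0 & s <= 1), "`s` must be in (0, 1]")
  1 - (1 - s)^2
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("<sensitivity_estimate> standalone %.4f, combined %.4f (%s)\n",
              x$standalone, x$combined, x$method))
  invisible(x)
}

#' @export
tidy.sensitivity_estimate <- function(x, ...) {
  tibble(standalone = x$standalone, combined = x$combined, method = x$method)
}

#' Correct a detected count for imperfect sensitivity
#'
#' @param detected Detected (independent) event count(s).
#' @param sensitivity Detection sensitivity in (0, 1].
#' @return Tibble with `detected`, `sensitivity`, `estimate`
#'   (`detected / sensitivity`) and `estimate_rounded` (nearest 10, the
#'   presentation used for cohort-scale totals).
#' @examples
#' estimate_true_counts(c(368, 270), c(0.94, 0.75))
#' @export
estimate_true_counts <- function(detected, sensitivity) {
  stop_not(all(sensitivity > 0 & sensitivity <= 1),
           "`sensitivity` must be in (0, 1]")
  stop_not(all(detected >= 0), "`detected` must be >= 0")
  est <- detected / sensitivity
  tibble(detected = detected, sensitivity = sensitivity,
         estimate = est, estimate_rounded = round(est / 10) * 10)
}
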
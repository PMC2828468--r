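#' De novo deletion rate per generation per chromosome per unit length
#'
#' From `d` de novo events observed among `n_individuals` offspring over a
#' total hotspot length `L`, with two parental chromosomes able to
#' contribute at an autosomal locus, the rate per generation per chromosome
#' per `unit` of sequence is `r = d / (2 n) * (unit / L)`.  The rate is
#' linear in `d` and in `unit`.
#'
#' @param d De novo event count (>= 0).
#' @param n_individuals Number of offspring screened (> 0).
#' @param hotspot_length Total length surveyed, bp (> 0).
#' @param unit Reporting unit length, bp (default 0.6 Mb).
#' @param chromosomes Contributing chromosomes per locus (default 2).
#' @return One-row tibble: inputs plus `rate` (full precision) and
#'   `rate_1sf` (presented to one significant figure, the convention for
#'   quoting such rates).
#' @examples
#' de_novo_rate(5, 440, 7e6)        # 4.87e-4 per generation/chromosome/0.6 Mb
#' @export
de_novo_rate <- function(d, n_individuals, hotspot_length, unit = 6e5,
                         chromosomes = 2L) {
  stop_not(d >= 0, "`d` must be >= 0")
  stop_not(n_individuals > 0, "`n_individuals` must be > 0")
  stop_not(hotspot_length > 0, "`hotspot_length` must be > 0")
  stop_not(unit > 0, "`unit` must be > 0")
  rate <- d / (chromosomes * n_individuals) * (unit / hotspot_length)
  tibble(d = d, n_individuals = n_individuals, chromosomes = chromosomes,
         hotspot_length = hotspot_length, unit = unit,
         rate = rate, rate_1sf = signif(rate, 1))
}

#' Project a hotspot de novo deletion rate from disease incidence
#'
#' Literature-style projection for a locus whose deletions are ascertained
#' through a disease phenotype: the ascertainable de novo deletion
#' frequency is `incidence * f_denovo * f_deletion * f_hotspot`, and the
#' projected total (including exon-sparing deletions that are never
#' ascertained clinically) multiplies it by `intronic_multiplier`.
#'
#' @param incidence Disease incidence per birth (> 0).
#' @param f_denovo Fraction of cases due to de novo mutation.
#' @param f_deletion Fraction of de novo mutations that are deletions.
#' @param f_hotspot Fraction of deletions falling in the major hotspot.
#' @param intronic_multiplier Factor accounting for never-ascertained
#'   intron-only deletions, default 2.
#' @param unit Unit length the rate refers to, bp (default 0.7 Mb, the
#'   major-hotspot length of the X-linked dystrophin locus).
#' @return One-row tibble with `ascertainable`, `projected`, their
#'   one-significant-figure presentations and `unit`.
#' @examples
#' incidence_hotspot_rate(1 / 3500, 1 / 3, 0.60, 2 / 3)  # ~4e-5, ~8e-5
#' @export
incidence_hotspot_rate <- function(incidence, f_denovo, f_deletion, f_hotspot,
                                   intronic_multiplier = 2, unit = 7e5) {
  stop_not(incidence >= 0, "`incidence` must be >= 0")
  fr <- c(f_denovo, f_deletion, f_hotspot)
  stop_not(all(fr >= 0 & fr <= 1), "fractions must be in [0, 1]")
  asc <- incidence * f_denovo * f_deletion * f_hotspot
  proj <- asc * intronic_multiplier
  tibble(ascertainable = asc, projected = proj,
         ascertainable_1sf = signif(asc, 1), projected_1sf = signif(proj, 1),
         unit = unit)
}

#' Unit-normalised ratio of two per-unit-length rates
#'
#' Rates quoted per different unit lengths are first normalised per bp:
#' `(r1 / u1) / (r2 / u2)`.
#'
#' @param rate1,rate2 Rates, either bare numbers or one-row tibbles carrying
#'   `rate` (or `ascertainable`/`projected`) and `unit` columns.
#' @param unit1,unit2 Unit lengths in bp (taken from the tibbles when
#'   omitted).
#' @param which2 Column to use from a `rate2` tibble produced by
#'   [incidence_hotspot_rate()] (default `"projected"`).
#' @return The fold by which `rate1` exceeds `rate2` per bp.
#' @examples
#' r1 <- de_novo_rate(5, 440, 7e6)
#' r2 <- incidence_hotspot_rate(1 / 3500, 1 / 3, 0.60, 2 / 3)
#' rate_ratio(r1, r2)   # >= 5
#' @export
rate_ratio <- function(rate1, rate2, unit1 = NULL, unit2 = NULL,
                       which2 = "projected") {
  pick <- function(r, u, col) {
    if (is.data.frame(r)) {
      u <- u %||% r$unit
      r <- if ("rate" %in% names(r)) r$rate else r[[col]]
    }
    stop_not(!is.null(u), "unit length missing")
    c(r, u)
  }
  a <- pick(rate1, unit1, which2)
  b <- pick(rate2, unit2, which2)
  stop_not(b[1] > 0, "division by zero: `rate2` must be > 0")
  (a[1] / a[2]) / (b[1] / b[2])
}
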
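# Internal helpers shared across modules.

# Derive independent child seeds from one master seed without touching the
# caller's RNG state.  Keeps all derived seeds in 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

stop_not <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# Accept a genome_model or a plain chrom/length table; return tibble(chrom, length).
as_genome_tbl <- function(genome) {
  if (inherits(genome, "genome_model")) return(genome$autosomes)
  stop_not(is.data.frame(genome) && all(c("chrom", "length") %in% names(genome)),
           "`genome` must be a genome_model or a data frame with columns chrom, length")
  tibble::as_tibble(genome[, c("chrom", "length")])
}

# Accept a genome_model or a SNP table; return tibble(snp, chrom, pos) sorted,
# with the global row index used as the SNP index everywhere.
as_snp_map <- function(map) {
  if (inherits(map, "genome_model")) return(map$snps)
  stop_not(is.data.frame(map) && all(c("chrom", "pos") %in% names(map)),
           "`map` must be a genome_model or a data frame with columns chrom, pos")
  tibble::as_tibble(map)
}

# Truncated lognormal sampler parameterised by its median (exact inverse-CDF).
rlnorm_trunc <- function(n, median, sdlog, range) {
  p <- plnorm(range, meanlog = log(median), sdlog = sdlog)
  qlnorm(runif(n, p[1], p[2]), meanlog = log(median), sdlog = sdlog)
}

# Greedy removal of intervals overlapping an earlier-kept interval, within
# groups defined by `key` (vectors must be pre-sorted by key, start).
drop_overlaps <- function(key, start, end) {
  keep <- logical(length(key))
  last_key <- NA_character_
  last_end <- -Inf
  for (i in seq_along(key)) {
    if (!identical(key[i], last_key) || start[i] >= last_end) {
      keep[i] <- TRUE
      last_key <- key[i]
      last_end <- end[i]
    }
  }
  keep
}

# Midpoint of a half-open interval, integer bp.
interval_mid <- function(start, end) (start + end) %/% 2L

# Is the point (chrom, pos) inside any half-open region?
point_in_regions <- function(chrom, pos, regions) {
  out <- logical(length(chrom))
  if (is.null(regions) || nrow(regions) == 0) return(out)
  for (j in seq_len(nrow(regions))) {
    out <- out | (chrom == regions$chrom[j] &
                    pos >= regions$start[j] & pos < regions$end[j])
  }
  out
}

fmt_mb <- function(x) sprintf("%.1f", x / 1e6)
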
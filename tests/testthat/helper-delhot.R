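# Shared fixtures, built in code.

# A tiny deterministic SNP map: `n` SNPs per chromosome, exactly `spacing`
# apart (no jitter), so tests can reason about indices and positions.
tiny_map <- function(chroms = c("chr1", "chr2"), n = 50, spacing = 1e4) {
  purrr::map_dfr(chroms, function(ch) {
    tibble::tibble(chrom = ch, pos = (seq_len(n) - 1) * spacing + 5e3)
  }) |>
    dplyr::mutate(snp = sprintf("s%04d", dplyr::row_number()), .before = 1)
}

tiny_genome <- function(chroms = c("chr1", "chr2"), n = 50, spacing = 1e4) {
  tibble::tibble(chrom = chroms, length = n * spacing)
}

# A flat track over `map` with LogR `value` at the given global SNP indices.
make_track <- function(map, idx = integer(), value = -0.7, base = 0) {
  x <- rep(base, nrow(map))
  x[idx] <- value
  x
}

# One-row call tibble from explicit boundaries (for matching tests).
mk_call <- function(sample, chrom, first_snp, last_snp, map = NULL,
                    provenance = "called") {
  start <- if (is.null(map)) first_snp * 1e4 else map$pos[first_snp]
  end <- if (is.null(map)) (last_snp + 1) * 1e4 else map$pos[last_snp] + 1
  tibble::tibble(sample = sample, chrom = chrom,
                 first_snp = as.integer(first_snp),
                 last_snp = as.integer(last_snp),
                 start = start, end = end,
                 n_snps = as.integer(last_snp - first_snp + 1),
                 mean_logr = -0.7, provenance = provenance)
}

# Independent O(n^2) enumeration of maximal qualifying runs: for every
# (i, j) window, check lowness, chromosome constancy and maximality
# directly.  Deliberately naive; used as the caller oracle.
brute_force_calls <- function(logr, map, threshold, min_run) {
  n <- length(logr)
  low <- logr < threshold
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_run) next
      if (!all(low[i:j])) next
      if (!all(map$chrom[i:j] == map$chrom[i])) next
      left_max <- i == 1 || !low[i - 1] || map$chrom[i - 1] != map$chrom[i]
      right_max <- j == n || !low[j + 1] || map$chrom[j + 1] != map$chrom[j]
      if (left_max && right_max) {
        out[[length(out) + 1]] <- c(first = i, last = j)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(first_snp = integer(), last_snp = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(first_snp = as.integer(m[, "first"]),
                 last_snp = as.integer(m[, "last"]))
}

# Count SNPs of `map` covered by the half-open interval.
snps_in <- function(map, chrom, start, end) {
  sum(map$chrom == chrom & map$pos >= start & map$pos < end)
}
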
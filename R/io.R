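# Readers and writers for the pipeline's plain-text interchange formats:
#  - per-sample intensity TSV: SNP_Name  Chr  Position  LogR  (1-based file
#    positions, converted to the package's 0-based convention on read)
#  - pedigree TSV: family  child  father  mother
#  - truth / call BED5: chrom  start  end  sample  origin (0-based half-open)
#  - genome TSV: chrom  length ; hotspot TSV: chrom start end multiplier

#' Write a simulated trio cohort to a directory
#'
#' Emits `genome.tsv`, `pedigree.tsv`, `hotspots.tsv`, `truth.bed` and one
#' Beadstudio-like intensity TSV per sample under `samples/`.  Positions in
#' the intensity files are 1-based; everything else is 0-based half-open.
#' The files round-trip losslessly through [read_cohort()].
#'
#' @param cohort A `trio_cohort` (with rendered tracks).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stop_not(inherits(cohort, "trio_cohort"), "`cohort` must be a trio_cohort")
  stop_not(!is.null(cohort$tracks), "cohort has no rendered tracks")
  samples <- rownames(cohort$tracks)
  stop_not(!anyDuplicated(samples), "duplicate sample id")
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$model$autosomes, file.path(dir, "genome.tsv"))
  readr::write_tsv(cohort$pedigree, file.path(dir, "pedigree.tsv"))
  readr::write_tsv(cohort$model$hotspots, file.path(dir, "hotspots.tsv"))
  truth <- cohort$truth |>
    select("chrom", "start", "end", "sample", "origin")
  readr::write_tsv(truth, file.path(dir, "truth.bed"), col_names = FALSE)
  snps <- cohort$model$snps
  for (s in samples) {
    readr::write_tsv(
      tibble(SNP_Name = snps$snp, Chr = snps$chrom,
             Position = snps$pos + 1, LogR = cohort$tracks[s, ]),
      file.path(dir, "samples", paste0(s, ".tsv"))
    )
  }
  invisible(dir)
}

#' Read a per-sample intensity table
#'
#' @param path Intensity TSV with columns `SNP_Name`, `Chr`, `Position`
#'   (1-based), `LogR`.
#' @return Tibble `snp`, `chrom`, `pos` (0-based), `logr`.
#' @export
read_intensity_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(SNP_Name = "c", Chr = "c",
                                          Position = "d", LogR = "d")) |>
    transmute(snp = .data$SNP_Name, chrom = .data$Chr,
              pos = .data$Position - 1, logr = .data$LogR)
}

#' Read a pedigree table
#'
#' @param path TSV with columns `family`, `child`, `father`, `mother`.
#' @return Pedigree tibble.
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Read a BED5 deletion table
#'
#' @param path Headerless BED5: `chrom start end sample origin`, 0-based
#'   half-open.
#' @return Tibble `chrom`, `start`, `end`, `sample`, `origin`.
#' @export
read_bed5 <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "sample", "origin"),
                  show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", start = "d", end = "d",
                                          sample = "c", origin = "c"))
}

#' Read back a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `genome` (autosome tibble), `pedigree`, `hotspots`,
#'   `truth`, `map` (SNP tibble `snp`, `chrom`, `pos`) and `tracks`
#'   (samples x SNPs LogR matrix).
#' @export
read_cohort <- function(dir) {
  genome <- readr::read_tsv(file.path(dir, "genome.tsv"), show_col_types = FALSE,
                            col_types = readr::cols(chrom = "c", length = "d"))
  pedigree <- read_pedigree(file.path(dir, "pedigree.tsv"))
  hotspots <- readr::read_tsv(file.path(dir, "hotspots.tsv"), show_col_types = FALSE,
                              col_types = readr::cols(chrom = "c", .default = "d"))
  truth <- read_bed5(file.path(dir, "truth.bed"))
  files <- list.files(file.path(dir, "samples"), full.names = TRUE)
  samples <- sub("\\.tsv$", "", basename(files))
  first <- read_intensity_tsv(files[1])
  map <- select(first, "snp", "chrom", "pos")
  tracks <- matrix(NA_real_, length(samples), nrow(map),
                   dimnames = list(samples, map$snp))
  tracks[1, ] <- first$logr
  for (i in seq_along(files)[-1]) {
    tracks[i, ] <- read_intensity_tsv(files[i])$logr
  }
  list(genome = genome, pedigree = pedigree, hotspots = hotspots,
       truth = truth, map = map, tracks = tracks)
}

#' Read gene/exon models from GFF3 or BED12
#'
#' Imports gene models via rtracklayer and reduces them to the exon tibble
#' used by [exon_overlap()] (0-based half-open coordinates).  GFF3 `exon`
#' features are grouped by their `gene` (or `Parent`/`ID`) attribute; BED12
#' blocks become exons of the record's `name`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED12 (`.bed`) file.
#' @param format Override format detection.
#' @return Tibble `gene`, `chrom`, `start`, `end`, one row per exon.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  stop_not(requireNamespace("rtracklayer", quietly = TRUE),
           "read_gene_models() needs the rtracklayer package")
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    meta <- S4Vectors::mcols(gr)
    gene <- if ("gene" %in% names(meta)) as.character(meta$gene)
      else if ("Parent" %in% names(meta)) vapply(meta$Parent, function(p) as.character(p)[1], character(1))
      else as.character(meta$ID)
    tibble(gene = gene, chrom = as.character(GenomicRanges::seqnames(gr)),
           start = BiocGenerics::start(gr) - 1, end = as.numeric(BiocGenerics::end(gr)))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    blocks <- if (!is.null(gr$blocks)) gr$blocks else methods::as(GenomicRanges::ranges(gr), "IRangesList")
    purrr::map_dfr(seq_along(gr), function(i) {
      b <- blocks[[i]]
      tibble(gene = gr$name[i],
             chrom = as.character(GenomicRanges::seqnames(gr[i])),
             start = BiocGenerics::start(gr[i]) - 1 + BiocGenerics::start(b) - 1,
             end = BiocGenerics::start(gr[i]) - 1 + as.numeric(BiocGenerics::end(b)))
    })
  }
}
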
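# Cohort bundle I/O and validation. Point variants use VCF-style 1-based
# inclusive coordinates; panel intervals and segments use BED-style 0-based
# half-open coordinates.

bundle_files <- c(samples = "samples.tsv", variants = "variants.tsv",
                  snps = "snps.tsv", panel_bed = "panel.bed",
                  panel_gc = "panel_gc.tsv", panel_depths = "panel_depths.tsv",
                  cn_segments = "cn_segments.tsv",
                  driver_genes = "driver_genes.txt")

#' Write a cohort bundle to a directory of TSV/BED files
#'
#' @param bundle A cohort bundle (e.g. from [generate_cohort()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(bundle$samples, "samples.tsv")
  v <- bundle$variants  # canonical order so write/load round-trips exactly
  tsv(v[order(v$patient_id, v$chrom, v$pos, v$sample_id), ], "variants.tsv")
  if (!is.null(bundle$snps)) tsv(bundle$snps, "snps.tsv")
  if (!is.null(bundle$panel)) {
    utils::write.table(bundle$panel[, c("chrom", "start", "end", "interval_id")],
                       file.path(dir, "panel.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    tsv(bundle$panel[, c("interval_id", "gc_fraction", "gene")], "panel_gc.tsv")
  }
  if (!is.null(bundle$panel_depths)) tsv(bundle$panel_depths, "panel_depths.tsv")
  if (!is.null(bundle$cn_segments)) tsv(bundle$cn_segments, "cn_segments.tsv")
  writeLines(bundle$driver_genes, file.path(dir, "driver_genes.txt"))
  invisible(dir)
}

#' Load and validate a cohort bundle
#'
#' Reads the bundle files written by [write_cohort()] (or prepared by hand),
#' checks schemas and referential integrity, and returns a validated
#' bundle. Variants are sorted by chromosome and position within patient.
#'
#' @param dir Directory containing the bundle files, or a named list of
#'   file paths overriding the defaults.
#' @return A `cohort_bundle` list: `samples`, `variants`, `snps`, `panel`,
#'   `panel_depths`, `cn_segments`, `driver_genes`.
#' @export
load_cohort <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1)
    setNames(file.path(dir, bundle_files), names(bundle_files))
  else unlist(dir)
  need <- function(p) { if (!file.exists(p)) stop("missing input file: ", p); p }
  rd <- function(p, classes = NA) utils::read.delim(need(p), colClasses = classes,
                                                    stringsAsFactors = FALSE)
  opt <- function(p, ...) if (file.exists(p)) rd(p, ...) else NULL

  samples <- rd(paths["samples"])
  variants <- rd(paths["variants"])
  snps <- opt(paths["snps"])
  panel <- NULL
  if (file.exists(paths["panel_bed"])) {
    bed <- utils::read.delim(paths["panel_bed"], header = FALSE,
                             col.names = c("chrom", "start", "end", "interval_id"),
                             stringsAsFactors = FALSE)
    gc <- rd(paths["panel_gc"])
    panel <- merge(bed, gc, by = "interval_id", sort = FALSE)
    panel <- panel[, c("interval_id", "chrom", "start", "end",
                       "gc_fraction", "gene")]
  }
  cn_segments <- opt(paths["cn_segments"])
  if (!is.null(cn_segments) && !is.null(cn_segments$genes)) {
    cn_segments$genes <- as.character(cn_segments$genes)
    cn_segments$genes[is.na(cn_segments$genes)] <- ""
  }
  bundle <- list(samples = samples, variants = variants, snps = snps,
                 panel = panel,
                 panel_depths = opt(paths["panel_depths"]),
                 cn_segments = cn_segments,
                 driver_genes = if (file.exists(paths["driver_genes"]))
                   readLines(paths["driver_genes"]) else DRIVER_GENES_15)
  class(bundle) <- c("cohort_bundle", "list")
  validate_bundle(bundle)
}

#' Validate a cohort bundle
#'
#' Fatal problems: a patient without exactly one normal sample, unknown
#' assay strings, table rows referencing unknown sample ids, duplicate
#' (site, sample) read-count rows. Rows with malformed (non-positive or
#' non-numeric) coordinates are rejected with row-numbered diagnostics.
#'
#' @param bundle A cohort bundle.
#' @return The validated bundle (variants sorted per patient/chromosome).
#' @export
validate_bundle <- function(bundle) {
  s <- bundle$samples
  req <- c("sample_id", "patient_id", "component", "assay",
           "median_capture_coverage")
  if (!all(req %in% names(s))) stop("samples table missing columns: ",
                                    paste(setdiff(req, names(s)), collapse = ", "))
  if (!all(s$assay %in% c("wes", "targeted")))
    stop("unknown assay: ", paste(unique(setdiff(s$assay,
                                                 c("wes", "targeted"))),
                                  collapse = ", "))
  n_normal <- tapply(s$component == "normal", s$patient_id, sum)
  bad <- names(n_normal)[n_normal != 1]
  if (length(bad)) stop("patients without exactly one normal sample: ",
                        paste(bad, collapse = ", "))
  if (any(s$median_capture_coverage <= 0))
    stop("median_capture_coverage must be positive")

  v <- bundle$variants
  unknown <- setdiff(v$sample_id, s$sample_id)
  if (length(unknown)) stop("variants reference unknown sample_id: ",
                            paste(unknown, collapse = ", "))
  badpos <- which(!is.finite(v$pos) | v$pos < 1 | v$pos != floor(v$pos))
  if (length(badpos))
    stop("malformed variant coordinates at rows: ",
         paste(utils::head(badpos, 10), collapse = ", "))
  key <- paste(v$patient_id, v$chrom, v$pos, v$ref, v$alt, v$sample_id)
  if (anyDuplicated(key))
    stop("duplicate (site, sample) rows at: ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "))
  bundle$variants <- v[order(v$patient_id, v$chrom, v$pos, v$sample_id), ]
  rownames(bundle$variants) <- NULL

  if (!is.null(bundle$snps)) {
    unknown <- setdiff(bundle$snps$sample_id, s$sample_id)
    if (length(unknown)) stop("snps reference unknown sample_id: ",
                              paste(unknown, collapse = ", "))
  }
  if (!is.null(bundle$panel) && any(bundle$panel$end <= bundle$panel$start))
    stop("panel intervals must satisfy end > start")
  bundle
}
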
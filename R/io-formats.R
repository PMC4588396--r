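#' Read per-sample copy-number segments (SEG-like TSV)
#'
#' Expects a tab-separated file with header
#' `sample, chrom, start, end, cn, rank`. Coordinates are stored internally
#' as 0-based half-open; files written in the common 1-based inclusive
#' dialect are converted on the way in by shifting `start` down by one.
#'
#' @param path File path.
#' @param dialect `"zero_based"` (half-open, default) or `"one_based"`
#'   (inclusive, converted on read).
#' @return Tibble with columns `sample`, `chrom`, `start`, `end`, `cn`,
#'   `rank`, 0-based half-open.
#' @export
read_seg <- function(path, dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  segs <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chrom = "c", start = "d", end = "d", cn = "i", rank = "i"
  ))
  if (dialect == "one_based") segs$start <- segs$start - 1
  validate_segments(segs)
  segs
}

#' @rdname read_seg
#' @param segs Segment tibble as returned by [read_seg()].
#' @export
write_seg <- function(segs, path) {
  validate_segments(segs)
  readr::write_tsv(segs, path)
  invisible(path)
}

validate_segments <- function(segs) {
  req <- c("sample", "chrom", "start", "end", "cn", "rank")
  if (!all(req %in% names(segs))) {
    abort(paste("segment table must have columns:", paste(req, collapse = ", ")))
  }
  if (any(segs$start >= segs$end)) abort("segments must satisfy start < end")
  if (any(segs$cn < 0)) abort("cn states must be >= 0")
  if (nrow(segs) > 1L) {
    bad <- segs |>
      arrange(.data$sample, .data$chrom, .data$start) |>
      group_by(.data$sample, .data$chrom) |>
      mutate(overlap = .data$start < dplyr::lag(.data$end, default = -Inf)) |>
      ungroup() |>
      filter(.data$overlap)
    if (nrow(bad)) {
      abort(sprintf(
        "overlapping segments within a sample: %s",
        paste(sprintf("%s %s:%d-%d", bad$sample, bad$chrom,
                      as.integer(bad$start), as.integer(bad$end)),
              collapse = "; ")
      ))
    }
  }
  invisible(segs)
}

#' Read gene annotation from a 6-column BED file
#'
#' BED coordinates are 0-based half-open and are kept that way internally.
#'
#' @param path BED file path (chrom, start, end, name, score, strand).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  ann <- tibble(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # back to BED 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  )
  ann$strand[ann$strand == "*"] <- "."
  if (anyDuplicated(ann$gene_id)) {
    abort(sprintf("duplicate gene ids in %s: %s", path,
                  paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", ")))
  }
  if (any(ann$start >= ann$end)) abort("annotation requires start < end")
  ann
}

#' @rdname read_bed
#' @param ann Annotation tibble.
#' @export
write_bed <- function(ann, path) {
  readr::write_tsv(
    tibble(ann$chrom, format(ann$start, scientific = FALSE, trim = TRUE),
           format(ann$end, scientific = FALSE, trim = TRUE),
           ann$gene_id, 0L, ann$strand),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a log2 expression matrix with probe annotation
#'
#' Expects a TSV whose first three columns are `feature_id`, `gene_id`,
#' `quality_flag` followed by one numeric column per sample.
#'
#' @param path File path.
#' @return List with `values` (numeric probe x sample matrix) and `features`
#'   (tibble of `feature_id`, `gene_id`, `quality_flag`).
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", gene_id = "c", quality_flag = "c", .default = "d"
  ))
  if (anyDuplicated(tab$feature_id)) {
    abort(sprintf("duplicate feature ids: %s",
                  paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
                        collapse = ", ")))
  }
  features <- tab |> select("feature_id", "gene_id", "quality_flag")
  values <- as.matrix(tab[setdiff(names(tab), names(features))])
  rownames(values) <- tab$feature_id
  if (!is.numeric(values)) abort("expression values must be numeric")
  list(values = values, features = features)
}

#' @rdname read_expression
#' @param expression List with `values` and `features` as returned by
#'   [read_expression()].
#' @export
write_expression <- function(expression, path) {
  stopifnot_matrix(expression$values, "expression$values")
  tab <- dplyr::bind_cols(
    expression$features,
    as_tibble(expression$values, .name_repair = "minimal")
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' One row per sample. Missing covariates are allowed (encoded as NA, the
#' analogue of "Unknown" entries in cohort tables) but an observed relapse
#' event must carry a time.
#'
#' @param path TSV path with columns `sample`, `tissue`, `cohort`, `batch`,
#'   `cellularity_pct`, `psa`, `gleason_primary`, `gleason_secondary`,
#'   `stage`, `ece`, `psm`, `time_to_bcr`, `bcr_event`.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", tissue = "c", cohort = "c", batch = "c",
    cellularity_pct = "d", psa = "d", gleason_primary = "i",
    gleason_secondary = "i", stage = "c", ece = "i", psm = "i",
    time_to_bcr = "d", bcr_event = "i"
  ))
  validate_clinical(cl)
  cl
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  readr::write_tsv(clinical, path)
  invisible(path)
}

validate_clinical <- function(cl) {
  if (anyDuplicated(cl$sample)) abort("duplicate sample ids in clinical table")
  if (!all(cl$tissue %in% c("tumour", "benign", "germline"))) {
    abort("tissue must be one of tumour, benign, germline")
  }
  bad_cell <- !is.na(cl$cellularity_pct) &
    (cl$cellularity_pct < 0 | cl$cellularity_pct > 100)
  if (any(bad_cell)) abort("cellularity_pct must lie in [0, 100]")
  bad_evt <- !is.na(cl$bcr_event) & cl$bcr_event == 1L & is.na(cl$time_to_bcr)
  if (any(bad_evt)) {
    abort(sprintf("bcr_event = 1 with missing time_to_bcr for: %s",
                  paste(cl$sample[bad_evt], collapse = ", ")))
  }
  if (any(!is.na(cl$time_to_bcr) & cl$time_to_bcr < 0)) {
    abort("time_to_bcr must be >= 0")
  }
  invisible(cl)
}

#' Report samples present in one table but not another
#'
#' @param expression Expression list (see [read_expression()]).
#' @param clinical Clinical tibble.
#' @return Tibble with columns `sample` and `where` ("expression_only" or
#'   "clinical_only"); zero rows when the cohorts agree.
#' @export
sample_mismatches <- function(expression, clinical) {
  ex <- colnames(expression$values)
  cl <- clinical$sample
  bind_rows(
    tibble(sample = setdiff(ex, cl), where = "expression_only"),
    tibble(sample = setdiff(cl, ex), where = "clinical_only")
  )
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}
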
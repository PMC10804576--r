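#' Read a beta-value matrix from TSV/CSV
#'
#' The file must have probe ids as row labels (first column) and sample
#' ids as column labels. Values are validated into `[0, 1]`; any
#' out-of-range cell raises an error naming the offending probe and
#' sample. Optional sample metadata is joined from a sidecar table keyed
#' by `sample_id`.
#'
#' @param path Path to a TSV (default) or CSV matrix file.
#' @param meta_path Optional path to a sample-metadata TSV/CSV with a
#'   `sample_id` column.
#' @param sep Field separator; inferred from the file extension when
#'   `NULL` (".csv" means comma, anything else tab).
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path, meta_path = NULL, sep = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE,
                              sep = infer_sep(meta_path, sep),
                              check.names = FALSE, stringsAsFactors = FALSE)
  }
  beta_matrix(m, sample_meta = meta)
}

#' Write a beta-value matrix to TSV/CSV
#'
#' @param x A [beta_matrix].
#' @param path Output matrix file.
#' @param meta_path Optional output path for the sample-metadata sidecar.
#' @param sep Field separator; inferred from extension when `NULL`.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(x, path, meta_path = NULL, sep = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  s <- infer_sep(path, sep)
  df <- data.frame(probe_id = rownames(x$beta), x$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = s, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(x$sample_meta, meta_path, sep = infer_sep(meta_path, sep),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a probe manifest from CSV/TSV
#'
#' Requires columns `probe_id`, `chrom`, `pos`, `design_type`; the
#' optional columns `snp_af`, `nonspecific`, `island_len_bp` default to
#' absent (`NA`/`FALSE`). The result is sorted by `(chrom, pos)`.
#'
#' @param path Manifest file path.
#' @param sep Field separator; inferred from extension when `NULL`.
#' @return A [probe_manifest].
#' @export
read_manifest <- function(path, sep = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                          check.names = FALSE, stringsAsFactors = FALSE)
  probe_manifest(df)
}

#' Write a probe manifest to CSV/TSV
#' @param x A [probe_manifest].
#' @param path Output path.
#' @param sep Field separator; inferred from extension when `NULL`.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(x, path, sep = NULL) {
  utils::write.table(as.data.frame(x), path, sep = infer_sep(path, sep),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region set as BED
#'
#' Regions are held 1-based closed internally; BED is 0-based half-open,
#' so a region `chr1:100-200` becomes the line `chr1 99 200`. Member
#' probe ids, when present, are written comma-joined in the BED name
#' column so that [read_regions_bed()] inverts exactly.
#'
#' @param regions A [region_set].
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  name <- vapply(regions$probes, function(p) {
    if (length(p)) paste(p, collapse = ",") else "."
  }, character(1))
  df <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                   end = regions$end, name = name, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region set from BED
#'
#' Inverse of [write_regions_bed()]: converts 0-based half-open BED lines
#' back to 1-based closed regions. A fourth column, when present and not
#' `"."`, is parsed as comma-joined member probe ids.
#'
#' @param path BED file path.
#' @return A [region_set].
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0) return(region_set())
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(nf < 3)[1]))
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  if (anyNA(start0) || anyNA(end0)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 which(is.na(start0) | is.na(end0))[1]))
  }
  probes <- lapply(seq_along(parts), function(i) {
    if (nf[i] >= 4 && parts[[i]][4] != ".") {
      strsplit(parts[[i]][4], ",", fixed = TRUE)[[1]]
    } else {
      character()
    }
  })
  region_set(chrom, start0 + 1L, end0, probes)
}

#' Serialize an evaluation report to JSON
#' @param report An [eval_report] (or a named list of them).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  strip <- function(r) lapply(unclass(r), function(v) if (is.na(v)) NULL else v)
  out <- if (inherits(report, "eval_report")) strip(report) else lapply(report, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
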
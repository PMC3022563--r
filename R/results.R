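#' Construct a scan result table
#'
#' The result of a two-locus scan: one row per SNP pair, with the first SNP
#' preceding the second in matrix order (each unordered pair at most once),
#' sorted by statistic descending with ties broken by (first, second) index
#' order. `significance` is an adjusted p-value or q-value depending on
#' `significance_kind`, or `NA` when no error control has been applied.
#'
#' @param ia,ib integer SNP indices (1-based, `ia < ib` rowwise).
#' @param statistic numeric test statistics (`>= 0`, may be `Inf`).
#' @param k integer count of non-empty joint-genotype groups per pair.
#' @param ids character vector of SNP ids the indices refer to.
#' @param significance numeric in `[0,1]` or `NA`.
#' @param significance_kind `"fwer_adjusted_p"`, `"fdr_q"` or `"none"`.
#' @return A `data.frame` of class `scan_result` with columns `snp_a`,
#'   `snp_b`, `statistic`, `k`, `significance`, `significance_kind`.
#' @export
scan_result <- function(ia, ib, statistic, k, ids,
                        significance = NA_real_,
                        significance_kind = "none") {
  stopifnot(length(ia) == length(ib), length(ia) == length(statistic),
            length(ia) == length(k))
  significance_kind <- match.arg(significance_kind,
                                 c("none", "fwer_adjusted_p", "fdr_q"))
  if (any(ia >= ib)) stop("pair indices must satisfy ia < ib", call. = FALSE)
  ord <- order(-rank(statistic), ia, ib) # rank() puts Inf above finite values
  df <- data.frame(
    snp_a = ids[ia][ord],
    snp_b = ids[ib][ord],
    statistic = statistic[ord],
    k = as.integer(k)[ord],
    significance = rep_len(as.numeric(significance), length(ia))[ord],
    significance_kind = rep_len(significance_kind, length(ia)),
    stringsAsFactors = FALSE
  )
  attr(df, "ia") <- as.integer(ia)[ord]
  attr(df, "ib") <- as.integer(ib)[ord]
  class(df) <- c("scan_result", "data.frame")
  df
}

#' @export
print.scan_result <- function(x, n = 10L, ...) {
  cat("scan_result: ", nrow(x), " SNP pair(s)\n", sep = "")
  print.data.frame(head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more row(s)\n", sep = "")
  invisible(x)
}

fmt_stat <- function(x) {
  out <- character(length(x))
  out[is.infinite(x)] <- "inf"
  fin <- is.finite(x)
  out[fin] <- formatC(x[fin], digits = 10L, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a scan result as TSV
#'
#' Writes a tab-separated table with header
#' `snp_a snp_b statistic k significance significance_kind`; statistics are
#' printed with 10 significant digits and `+Inf` prints as `inf`. Optional
#' metadata (engine, test, permutation count, seed, level) is written as
#' leading `# key=value` comment lines.
#'
#' @param r a [scan_result()].
#' @param path output file path.
#' @param meta optional named list written as `# name=value` header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(r, path, meta = NULL) {
  stopifnot(inherits(r, "scan_result"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), "=", vapply(meta, as.character, "")), con)
  }
  writeLines("snp_a\tsnp_b\tstatistic\tk\tsignificance\tsignificance_kind", con)
  if (nrow(r) > 0L) {
    writeLines(paste(r$snp_a, r$snp_b, fmt_stat(r$statistic), r$k,
                     fmt_stat(r$significance), r$significance_kind,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a scan result written by [write_results()]
#'
#' @param path file path.
#' @return A `data.frame` with the same columns ( `# key=value` metadata
#'   lines, if any, returned in attribute `"meta"`).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  lines <- lines[!grepl("^# ", lines)]
  if (length(lines) < 1L) stop("empty results file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  parse_num <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    out[x == "inf"] <- Inf
    out
  }
  df <- data.frame(
    snp_a = vapply(body, `[`, character(1), 1L),
    snp_b = vapply(body, `[`, character(1), 2L),
    statistic = parse_num(vapply(body, `[`, character(1), 3L)),
    k = as.integer(vapply(body, `[`, character(1), 4L)),
    significance = parse_num(vapply(body, `[`, character(1), 5L)),
    significance_kind = vapply(body, `[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
  if (length(body) == 0L) df <- df[0, , drop = FALSE]
  if (length(meta_lines) > 0L) {
    kv <- sub("^# ", "", meta_lines)
    pos <- regexpr("=", kv, fixed = TRUE)
    meta <- as.list(substring(kv, pos + 1L))
    names(meta) <- substring(kv, 1L, pos - 1L)
    attr(df, "meta") <- meta
  }
  df
}
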
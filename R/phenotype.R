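#' Construct a phenotype vector
#'
#' Per-individual trait values, either `quantitative` (finite reals with
#' nonzero variance) or `binary` (case/control, coded 1 = case,
#' 0 = control, both classes present). The kind is inferred when not given:
#' binary iff every value is 0 or 1.
#'
#' @param values numeric vector of trait values.
#' @param individual_ids character vector of unique ids, same length.
#' @param kind `"quantitative"`, `"binary"`, or `NULL` to infer.
#' @return An object of class `phenotype_vector`: list with `values`
#'   (named numeric) and `kind`.
#' @export
phenotype_vector <- function(values, individual_ids = names(values),
                             kind = NULL) {
  force(individual_ids)
  values <- as.numeric(values)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_along(values))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != length(values)) {
    stop("individual_ids length != values length", call. = FALSE)
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual id(s) in phenotype", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite phenotype value(s)", call. = FALSE)
  if (is.null(kind)) {
    kind <- if (all(values %in% c(0, 1))) "binary" else "quantitative"
  }
  kind <- match.arg(kind, c("quantitative", "binary"))
  if (kind == "binary") {
    if (!all(values %in% c(0, 1))) {
      stop("binary phenotype values must be 0 (control) or 1 (case)", call. = FALSE)
    }
    if (length(unique(values)) < 2L) {
      stop("phenotype has a single class", call. = FALSE)
    }
  } else {
    if (length(values) < 2L || var(values) == 0) {
      stop("quantitative phenotype has zero variance", call. = FALSE)
    }
  }
  names(values) <- individual_ids
  structure(list(values = values, kind = kind), class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat("phenotype_vector: ", length(x$values), " individuals, kind = ",
      x$kind, "\n", sep = "")
  invisible(x)
}

#' Read a phenotype table
#'
#' Two-column TSV `individual_id<TAB>value`; a header line is detected (and
#' skipped) when its second field is not numeric. Kind is inferred as in
#' [phenotype_vector()] unless overridden.
#'
#' @param path file path.
#' @param kind optional `"quantitative"` / `"binary"` override.
#' @return A [phenotype_vector()].
#' @export
read_phenotype <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("phenotype file must have exactly two tab-separated columns", call. = FALSE)
  }
  second <- vapply(fields, `[`, character(1), 2L)
  first_val <- suppressWarnings(as.numeric(second[1]))
  if (is.na(first_val)) { # header row
    fields <- fields[-1]
    second <- second[-1]
  }
  if (length(fields) == 0L) stop("phenotype file has no data rows", call. = FALSE)
  vals <- suppressWarnings(as.numeric(second))
  if (anyNA(vals)) {
    stop("non-numeric phenotype value(s): ",
         paste(unique(second[is.na(vals)]), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  phenotype_vector(vals, individual_ids = ids, kind = kind)
}

#' Write a phenotype vector as a two-column TSV
#'
#' @param y a [phenotype_vector()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(y, path) {
  stopifnot(inherits(y, "phenotype_vector"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("individual_id\tvalue", con)
  writeLines(paste(names(y$values), format(y$values, digits = 15, trim = TRUE,
                                           scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Align genotype and phenotype samples by individual id
#'
#' Both objects are reordered to the intersection of their individual ids,
#' in genotype-file order. Ids present in only one input are dropped with a
#' warning; an intersection smaller than 2 is an error.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype_vector()].
#' @return A list with elements `genotypes` and `phenotype`, aligned.
#' @export
align_samples <- function(G, y) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(y, "phenotype_vector"))
  gids <- individual_ids(G)
  pids <- names(y$values)
  common <- gids[gids %in% pids]
  dropped <- c(setdiff(gids, pids), setdiff(pids, gids))
  if (length(common) < 2L) {
    stop("fewer than 2 individuals shared between genotype and phenotype files",
         call. = FALSE)
  }
  if (length(dropped) > 0L) {
    warning(length(dropped), " individual(s) present in only one file dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  Ga <- genotype_matrix(G$codes[, common, drop = FALSE],
                        snp_ids = snp_ids(G), individual_ids = common,
                        alphabet = G$alphabet)
  ya <- phenotype_vector(y$values[common], individual_ids = common,
                         kind = y$kind)
  list(genotypes = Ga, phenotype = ya)
}
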
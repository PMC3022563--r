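#' Construct a genotype matrix
#'
#' A genotype matrix stores `m` SNPs by `n` individuals in SNP-major order
#' (one row per SNP) with a small integer code alphabet: `binary` codes
#' `{0,1}` (homozygous designs such as inbred crosses) or `triallelic`
#' codes `{0,1,2}` (human-style additive genotype coding, minor-allele
#' count). Missing genotypes are not supported: every downstream scan
#' assumes complete contingency tables, and silent imputation would change
#' every count, so incomplete data are rejected at construction.
#'
#' @param codes integer matrix, `m` SNPs x `n` individuals.
#' @param snp_ids character vector of `m` unique SNP identifiers; defaults
#'   to `rownames(codes)` or `snp1..snpm`.
#' @param individual_ids character vector of `n` unique individual
#'   identifiers; defaults to `colnames(codes)` or `ind1..indn`.
#' @param alphabet `"binary"`, `"triallelic"`, or `NULL` to infer:
#'   triallelic iff any code equals 2.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes` (integer matrix with ids as dimnames) and `alphabet`.
#' @seealso [read_genotypes()], [write_genotypes()]
#' @export
genotype_matrix <- function(codes, snp_ids = NULL, individual_ids = NULL,
                            alphabet = NULL) {
  codes <- as.matrix(codes)
  if (anyNA(codes)) {
    stop("missing genotype not supported (", sum(is.na(codes)),
         " NA cell(s))", call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  m <- nrow(codes)
  n <- ncol(codes)
  if (m < 2L || n < 2L) {
    stop("genotype matrix needs at least 2 SNPs and 2 individuals (got ",
         m, " x ", n, ")", call. = FALSE)
  }
  if (is.null(snp_ids)) {
    snp_ids <- rownames(codes)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  }
  if (is.null(individual_ids)) {
    individual_ids <- colnames(codes)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  }
  snp_ids <- as.character(snp_ids)
  individual_ids <- as.character(individual_ids)
  if (length(snp_ids) != m) stop("snp_ids length != number of rows", call. = FALSE)
  if (length(individual_ids) != n) stop("individual_ids length != number of columns", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP id(s): ",
                                   paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "),
                                   call. = FALSE)
  if (anyDuplicated(individual_ids)) stop("duplicate individual id(s): ",
                                          paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "),
                                          call. = FALSE)
  rng <- range(codes)
  if (rng[1] < 0L || rng[2] > 2L) {
    stop("genotype codes must be in {0,1,2}; found ",
         paste(setdiff(unique(as.vector(codes)), 0:2), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(alphabet)) {
    alphabet <- if (rng[2] == 2L) "triallelic" else "binary"
  }
  alphabet <- match.arg(alphabet, c("binary", "triallelic"))
  if (alphabet == "binary" && rng[2] > 1L) {
    stop("code 2 present but alphabet declared binary", call. = FALSE)
  }
  dimnames(codes) <- list(snp_ids, individual_ids)
  structure(list(codes = codes, alphabet = alphabet),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$codes), " SNPs x ", ncol(x$codes),
      " individuals, alphabet = ", x$alphabet, "\n", sep = "")
  invisible(x)
}

# cardinality of the code alphabet (2 or 3)
alphabet_card <- function(G) if (G$alphabet == "binary") 2L else 3L

n_snps <- function(G) nrow(G$codes)
n_individuals <- function(G) ncol(G$codes)
snp_ids <- function(G) rownames(G$codes)
individual_ids <- function(G) colnames(G$codes)

#' Read a genotype matrix from a text file
#'
#' Two dialects are supported. The native `tsv` format is SNP-major: a
#' header line `snp_id<TAB>id1<TAB>...`, then one row per SNP with cells in
#' `{0,1,2}`. The `plink_raw` format is the individual-major text export of
#' PLINK (`--recode A`): whitespace-separated, header
#' `FID IID PAT MAT SEX PHENOTYPE SNP1 ...`, additive 0/1/2 coding; it is
#' transposed on read and its PHENOTYPE column is ignored (the phenotype
#' comes from its own file, see [read_phenotype()]). Missing values
#' (`NA` cells) are rejected in both dialects.
#'
#' @param path file path.
#' @param format `"tsv"` (native SNP-major) or `"plink_raw"`.
#' @param alphabet optional override; by default triallelic iff any code 2.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype file has fewer than 2 lines", call. = FALSE)
  if (format == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1]]
    if (header[1] != "snp_id") {
      stop("native genotype TSV must start with a 'snp_id' header column", call. = FALSE)
    }
    ind_ids <- header[-1]
    widths <- lengths(fields[-1])
    if (any(widths != length(header))) {
      stop("ragged genotype rows: expected ", length(header),
           " fields, got ", paste(unique(widths[widths != length(header)]), collapse = ", "),
           call. = FALSE)
    }
    body <- fields[-1]
    snps <- vapply(body, `[`, character(1), 1L)
    cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
    codes <- parse_genotype_cells(cells)
    codes <- matrix(codes, nrow = length(body), ncol = length(ind_ids), byrow = TRUE)
    genotype_matrix(codes, snp_ids = snps, individual_ids = ind_ids,
                    alphabet = alphabet)
  } else {
    fields <- strsplit(trimws(lines), "[ \t]+")
    header <- fields[[1]]
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (length(header) < 7L || !identical(header[1:6], fixed)) {
      stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE ...)",
           call. = FALSE)
    }
    snps <- header[-(1:6)]
    body <- fields[-1]
    widths <- lengths(body)
    if (any(widths != length(header))) {
      stop("ragged PLINK .raw rows", call. = FALSE)
    }
    ind_ids <- vapply(body, `[`, character(1), 2L)
    cells <- unlist(lapply(body, `[`, -(1:6)), use.names = FALSE)
    codes <- parse_genotype_cells(cells)
    # individual-major on disk -> SNP-major in memory
    codes <- matrix(codes, nrow = length(snps), ncol = length(body))
    genotype_matrix(codes, snp_ids = snps, individual_ids = ind_ids,
                    alphabet = alphabet)
  }
}

parse_genotype_cells <- function(cells) {
  bad <- !cells %in% c("0", "1", "2")
  if (any(bad)) {
    if (any(cells[bad] %in% c("NA", "na", ".", ""))) {
      stop("missing genotype not supported (", sum(cells[bad] %in% c("NA", "na", ".", "")),
           " cell(s))", call. = FALSE)
    }
    stop("invalid genotype code(s): ",
         paste(unique(cells[bad])[seq_len(min(5, length(unique(cells[bad]))))], collapse = ", "),
         call. = FALSE)
  }
  as.integer(cells)
}

#' Write a genotype matrix in the native SNP-major TSV format
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("snp_id", individual_ids(G)), collapse = "\t"), con)
  body <- apply(G$codes, 1L, paste, collapse = "\t")
  writeLines(paste(snp_ids(G), body, sep = "\t"), con)
  invisible(path)
}
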
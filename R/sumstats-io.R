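## Reading and writing GWAS summary-statistics tables and LD matrices.
## Canonical dialect: UTF-8, tab-delimited, header row, '.' decimal
## separator, NA permitted for eaf only. Positions are 1-based.

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file into a validated [SumStats-class] object.
#' Foreign headers are renamed through `columnMap`. Rows violating the
#' record invariants (non-positive standard error, p-value outside (0, 1],
#' identical alleles, frequency outside \[0, 1\], ...) are rejected with a
#' row-numbered warning naming the offending field; valid rows are kept in
#' file order. A duplicated SNP identifier among the valid rows is an error.
#'
#' @param path path to a tab- (or `sep`-) delimited file with a header.
#' @param traitLabel trait name to attach.
#' @param traitType `"binary"` or `"continuous"`.
#' @param columnMap named character vector mapping file column names to
#'   canonical fields, e.g. `c(rsid = "snp_id", effect = "beta")`. Columns
#'   already canonically named need no entry.
#' @param sep field separator, tab by default.
#' @return A [SumStats-class] object.
#' @seealso [writeSumStats()], which this function inverts exactly.
#' @export
readSumStats <- function(path, traitLabel, traitType = c("binary", "continuous"),
                         columnMap = NULL, sep = "\t") {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    # a mapping that points at an absent column is a config error
    absent <- setdiff(names(columnMap), names(raw))
    if (length(absent))
      stop("columnMap names absent from header: ",
           paste(absent, collapse = ", "))
    hit <- names(raw) %in% names(columnMap)
    names(raw)[hit] <- unname(columnMap[names(raw)[hit]])
  }
  missing_cols <- setdiff(.SUMSTATS_COLS, names(raw))
  if (length(missing_cols))
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[, .SUMSTATS_COLS, drop = FALSE]

  numify <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "NA" & is.na(out))
    if (length(bad))
      stop(sprintf("unparseable numeric in column '%s' at data row(s) %s",
                   col, paste(bad, collapse = ", ")))
    out
  }
  tab <- data.frame(snp_id = raw$snp_id, chrom = raw$chrom,
                    pos = numify("pos"),
                    effect_allele = toupper(raw$effect_allele),
                    other_allele = toupper(raw$other_allele),
                    eaf = numify("eaf"), beta = numify("beta"),
                    se = numify("se"), pval = numify("pval"),
                    n = numify("n"), stringsAsFactors = FALSE)

  diagnostics <- .validateSumStatRows(tab)
  dup <- duplicated(tab$snp_id)
  if (any(dup))
    stop("duplicate snp_id: ", paste(unique(tab$snp_id[dup]), collapse = ", "))
  if (length(diagnostics)) {
    warning(sprintf("%s: rejected %d row(s):\n  %s", path,
                    length(unique(as.integer(sub("^row (\\d+):.*", "\\1",
                                                 diagnostics)))),
                    paste(diagnostics, collapse = "\n  ")),
            call. = FALSE)
    bad_rows <- unique(as.integer(sub("^row (\\d+):.*", "\\1", diagnostics)))
    tab <- tab[-bad_rows, , drop = FALSE]
  }
  tab$pos <- as.integer(tab$pos)
  SumStats(tab, traitLabel = traitLabel, traitType = traitType)
}

#' Write a GWAS summary-statistics table
#'
#' Writes the canonical tab-delimited dialect: header row with the canonical
#' column names, '.' decimal separator, `NA` for missing effect-allele
#' frequency, numerics at 17 significant digits so that [readSumStats()]
#' inverts the file exactly.
#'
#' @param x a [SumStats-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumStats <- function(x, path) {
  stopifnot(is(x, "SumStats"))
  tab <- x@table
  for (col in c("eaf", "beta", "se", "pval", "n"))
    tab[[col]] <- trimws(formatC(tab[[col]], digits = 17, format = "g"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an LD matrix
#'
#' Expects a tab-delimited file whose first column and header row both carry
#' SNP identifiers, followed by the square matrix of squared correlations.
#' Optionally a second column `pos` carries base-pair positions; otherwise
#' positions must be supplied.
#'
#' @param path path to the matrix file.
#' @param positions integer positions aligned to the matrix identifiers;
#'   required when the file has no `pos` column.
#' @return A validated [LDMatrix-class]. Asymmetry beyond 1e-8, a diagonal
#'   away from 1, values outside \[0, 1\] or a non-square matrix are errors.
#' @export
readLDMatrix <- function(path, positions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  raw <- raw[, -1, drop = FALSE]
  if ("pos" %in% names(raw)) {
    positions <- as.integer(raw[["pos"]])
    raw <- raw[, setdiff(names(raw), "pos"), drop = FALSE]
  }
  if (ncol(raw) != length(ids))
    stop("LD matrix is not square: ", length(ids), " rows, ",
         ncol(raw), " columns")
  if (!identical(names(raw), ids))
    stop("LD matrix header does not match row identifiers")
  if (is.null(positions))
    stop("positions required: no 'pos' column in ", path)
  m <- as.matrix(raw)
  if (any(is.na(m))) stop("non-numeric entries in LD matrix")
  if (any(m < 0 | m > 1)) stop("r2 values outside [0, 1]")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(m - t(m))) > 1e-8)
    stop("LD matrix asymmetric beyond tolerance 1e-8")
  LDMatrix(ids, m, positions)
}

#' Write an LD matrix
#'
#' Inverse of [readLDMatrix()]: identifiers in the first column and header,
#' positions in a `pos` column.
#'
#' @param ld an [LDMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(ld, path) {
  stopifnot(is(ld, "LDMatrix"))
  out <- data.frame(snp_id = ld@snpIds, pos = ld@positions,
                    formatC(ld@r2, digits = 17, format = "g"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- ld@snpIds
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
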
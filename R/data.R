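# Case-control genotype container.  Genotypes are categorical codes from a
# declared level set (default 0/1/2 = minor-allele counts); internally each
# column is re-coded to 0..L-1 so that multi-locus cells can be addressed by
# a single integer key.

#' Construct a case-control genotype dataset
#'
#' Bundles a binary case/control status vector with a matrix of categorical
#' genotype codes.  All non-missing genotype values must belong to the
#' declared level set; values equal to `missing` are treated as missing and
#' excluded row-wise for whichever locus combination is being evaluated.
#'
#' @param genotypes n x p matrix or data frame of genotype codes.
#' @param status vector of n binary labels (1 = case, 0 = control).
#' @param levels ordered vector of admissible genotype codes.
#' @param locus_names optional p identifiers; defaults to the column names
#'   of `genotypes`, or `"1" ... "p"` when absent.
#' @param missing sentinel value marking a missing genotype (default `NA`).
#' @return An object of class `mdr_data`: a list with elements `status`,
#'   `genotypes`, `code` (internal 0-based recoding), `levels`,
#'   `locus_names`, `n_cases` and `n_controls`.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3)
#' d <- mdr_data(g, status = c(1, 0, 1))
#' d$n_cases
#' @export
mdr_data <- function(genotypes, status, levels = 0:2, locus_names = NULL,
                     missing = NA) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (!is.matrix(genotypes)) genotypes <- matrix(genotypes, nrow = length(status))
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (n < 1L || p < 1L)
    stop("need at least one individual and one locus")
  status <- as.integer(status)
  if (length(status) != n)
    stop("length of 'status' (", length(status),
         ") does not match the number of rows (", n, ")")
  if (anyNA(status) || !all(status %in% c(0L, 1L)))
    stop("'status' must be coded 0 (control) / 1 (case) with no missing values")
  if (length(levels) < 2L || anyDuplicated(levels))
    stop("'levels' must be at least two distinct genotype codes")
  if (is.null(locus_names)) locus_names <- colnames(genotypes)
  if (is.null(locus_names)) locus_names <- as.character(seq_len(p))
  if (length(locus_names) != p)
    stop("'locus_names' must have one entry per locus")

  g <- genotypes
  if (!is.na(missing)) g[g == missing] <- NA
  code <- matrix(match(g, levels), nrow = n, ncol = p) - 1L
  bad <- !is.na(g) & is.na(matrix(match(g, levels), nrow = n))
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1L, ]
    stop("genotype value '", g[j[1L], j[2L]], "' at row ", j[1L], ", locus '",
         locus_names[j[2L]], "' is not in the declared level set {",
         paste(levels, collapse = ", "), "}")
  }
  structure(list(
    status      = status,
    genotypes   = genotypes,
    code        = code,
    levels      = levels,
    locus_names = as.character(locus_names),
    n_cases     = sum(status == 1L),
    n_controls  = sum(status == 0L)
  ), class = "mdr_data")
}

#' @export
print.mdr_data <- function(x, ...) {
  cat("Case-control genotype dataset:",
      nrow(x$code), "individuals x", ncol(x$code), "loci\n")
  cat("  cases:", x$n_cases, "  controls:", x$n_controls, "\n")
  cat("  genotype levels: {", paste(x$levels, collapse = ", "), "}\n")
  nm <- sum(is.na(x$code))
  if (nm > 0L) cat("  missing genotypes:", nm, "\n")
  invisible(x)
}

#' @export
dim.mdr_data <- function(x) dim(x$code)

#' Read a case-control genotype dataset from delimited text
#'
#' The first column is the binary status (1 = case, 0 = control) and the
#' remaining columns are genotype codes.  The field separator is
#' auto-detected (comma vs tab) unless given.
#'
#' @param file path to a delimited text file.
#' @param sep field separator; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @param header does the file carry a header row? Default `TRUE`.
#' @param levels admissible genotype codes (default `0:2`).
#' @param missing token marking a missing genotype (default `"NA"`).
#' @return An [mdr_data] object.
#' @export
read_mdr_data <- function(file, sep = NULL, header = TRUE, levels = 0:2,
                          missing = "NA") {
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(file, sep = sep, header = header,
                          na.strings = missing, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("expected a status column plus at least one genotype column")
  nm <- if (header) colnames(df)[-1L] else NULL
  mdr_data(as.matrix(df[, -1L, drop = FALSE]), status = df[[1L]],
           levels = levels, locus_names = nm)
}

#' Write a case-control genotype dataset to delimited text
#'
#' @param data an [mdr_data] object.
#' @param file output path.
#' @param sep field separator (default comma).
#' @return `file`, invisibly.
#' @export
write_mdr_data <- function(data, file, sep = ",") {
  stopifnot(inherits(data, "mdr_data"))
  df <- data.frame(status = data$status, data$genotypes, check.names = FALSE)
  colnames(df) <- c("status", data$locus_names)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Internal: 1-based integer cell key for a locus tuple; NA when any genotype
# at the tuple is missing.  Keys run over 1..L^k in locus-major order
# (first locus varies fastest).
.combo_key <- function(code, loci, L) {
  key <- code[, loci[1L]]
  if (length(loci) > 1L) {
    mult <- 1L
    for (j in 2L:length(loci)) {
      mult <- mult * L
      key <- key + mult * code[, loci[j]]
    }
  }
  key + 1L
}

# Internal: decode cell keys 1..L^k back to a k-column matrix of 0-based codes.
.decode_key <- function(keys, k, L) {
  out <- matrix(0L, nrow = length(keys), ncol = k)
  r <- keys - 1L
  for (j in seq_len(k)) {
    out[, j] <- r %% L
    r <- r %/% L
  }
  out
}
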
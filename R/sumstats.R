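# GWAS summary-statistics tables: construction, validation, I/O.
#
# A sumstats object is a data.frame with one row per SNP-trait association
# and canonical columns:
#   snp, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval,
#   n, n_case, n_control, trait_id, trait_type
# beta is the per-effect-allele change in the trait (log odds ratio for
# binary traits); positions are 1-based and only used for clumping windows.

.SUM_COLS <- c(
  "snp", "chrom", "pos", "effect_allele", "other_allele", "eaf",
  "beta", "se", "pval", "n", "n_case", "n_control", "trait_id", "trait_type"
)
.SUM_REQUIRED <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
.BASES <- c("A", "C", "G", "T")

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) ea == .complement(oa)

#' Assemble and validate a summary-statistics table
#'
#' Coerces a data.frame with canonical column names into a validated
#' `sumstats` object. Rows violating the invariants (non-ACGT alleles,
#' `se <= 0`, p-value outside (0, 1], effect-allele frequency outside
#' \[0, 1\], or inconsistent case/control counts) are dropped with a warning,
#' or raise an error when `strict = TRUE`.
#'
#' @param x data.frame carrying at least `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optionally `chrom`, `pos`, `eaf`,
#'   `n`, `n_case`, `n_control`.
#' @param trait_id Character label for the trait.
#' @param trait_type `"continuous"` or `"binary"`. For binary traits `beta`
#'   is interpreted as a log odds ratio.
#' @param strict If `TRUE`, any invalid row is an error instead of being
#'   skipped.
#' @param lines Optional integer vector of source line numbers used in
#'   validation messages (defaults to row numbers).
#' @return A `sumstats` data.frame with canonical columns. The rejected rows
#'   (with a `reason` column) are attached as attribute `"rejected"`.
#' @export
as_sumstats <- function(x, trait_id = "trait", trait_type = c("continuous", "binary"),
                        strict = FALSE, lines = NULL) {
  trait_type <- match.arg(trait_type)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SUM_REQUIRED, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.SUM_COLS, names(x))) x[[col]] <- NA
  x$snp <- as.character(x$snp)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$trait_id <- trait_id
  x$trait_type <- trait_type
  if (is.null(lines)) lines <- seq_len(nrow(x))

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(x$snp) | !nzchar(x$snp), "missing snp id")
  reason <- flag(!(x$effect_allele %in% .BASES), "effect_allele not A/C/G/T")
  reason <- flag(!(x$other_allele %in% .BASES), "other_allele not A/C/G/T")
  reason <- flag(x$effect_allele == x$other_allele, "effect_allele equals other_allele")
  reason <- flag(is.na(x$beta), "missing beta")
  reason <- flag(is.na(x$se) | x$se <= 0, "se not > 0")
  reason <- flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval not in (0,1]")
  reason <- flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf outside [0,1]")
  if (trait_type == "binary") {
    cc <- !is.na(x$n) & !is.na(x$n_case) & !is.na(x$n_control)
    reason <- flag(cc & (x$n_case + x$n_control != x$n), "n_case + n_control != n")
  }

  bad <- !is.na(reason)
  if (any(bad)) {
    msgs <- paste0("line ", lines[bad], ": ", reason[bad])
    if (strict) {
      stop("invalid summary-statistic row(s):\n", paste(msgs, collapse = "\n"))
    }
    warning(sum(bad), " row(s) rejected:\n", paste(msgs, collapse = "\n"), call. = FALSE)
  }
  rejected <- cbind(x[bad, .SUM_COLS, drop = FALSE],
                    line = lines[bad], reason = reason[bad])
  out <- x[!bad, .SUM_COLS, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row and maps its
#' columns onto the canonical summary-statistics fields.
#'
#' @param path Path to the file. The delimiter is taken from `sep`, or
#'   inferred from the header line (tab if it contains a tab, comma
#'   otherwise).
#' @param column_map Named character vector mapping canonical field names to
#'   the file's column names, e.g. `c(snp = "rsid", beta = "logOR")`.
#'   Canonical names already present in the file need not be listed.
#' @param sep Field separator; `NULL` to infer.
#' @inheritParams as_sumstats
#' @return A validated `sumstats` object; invalid rows are reported with
#'   their file line numbers (header = line 1).
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = "trait",
                          trait_type = c("continuous", "binary"),
                          sep = NULL, strict = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(raw))
    if (length(miss) > 0) {
      stop("column_map refers to absent column(s): ", paste(miss, collapse = ", "))
    }
    for (canon in names(column_map)) {
      raw[[canon]] <- raw[[column_map[[canon]]]]
    }
  }
  as_sumstats(raw, trait_id = trait_id, trait_type = trait_type,
              strict = strict, lines = seq_len(nrow(raw)) + 1L)
}

#' Write a summary-statistics table to tab-delimited text
#'
#' @param x A `sumstats` object (or compatible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  write.table(as.data.frame(x)[, .SUM_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d SNP(s), trait '%s' (%s)\n",
              nrow(x), x$trait_id[1], x$trait_type[1]))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}
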
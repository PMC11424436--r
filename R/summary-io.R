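#' Canonical column dialect for GWAS summary-statistics tables
#'
#' The package's on-disk dialect uses the column names `snp`, `chr`, `pos`,
#' `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`. Source files with arbitrary
#' headers are mapped onto these names through a dialect: a named character
#' vector whose names are the canonical columns and whose values are the
#' source headers.
#'
#' @param snp,chr,pos,ea,oa,eaf,beta,se,pval,n Source header for each
#'   canonical column.
#' @return Named character vector mapping canonical names to source headers.
#' @export
#' @examples
#' summary_dialect(snp = "rsid", pval = "p")
summary_dialect <- function(snp = "snp", chr = "chr", pos = "pos",
                            ea = "ea", oa = "oa", eaf = "eaf",
                            beta = "beta", se = "se", pval = "pval",
                            n = "n") {
  c(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
    beta = beta, se = se, pval = pval, n = n)
}

.canonical_cols <- c("snp", "chr", "pos", "ea", "oa", "eaf",
                     "beta", "se", "pval", "n")
.bases <- c("A", "C", "G", "T")

#' Construct a validated summary table
#'
#' Builds a `summary_table` from a data frame holding the canonical columns.
#' Rows violating the per-record invariants (positive SE, allele codes,
#' frequency and p-value ranges) are dropped with a warning; duplicate SNP
#' identifiers are an error. Rows whose p-value disagrees with the two-sided
#' normal p implied by `beta/se` by more than a factor of two are kept but
#' flagged with a warning, since rounding in published tables routinely
#' produces mild inconsistency.
#'
#' @param df Data frame with columns `snp`, `chr`, `pos`, `ea`, `oa`, `eaf`,
#'   `beta`, `se`, `pval`, `n` (`eaf` may be `NA`).
#' @param trait_id Character scalar naming the trait.
#' @return A `summary_table`: a data frame with canonical columns, attributes
#'   `trait_id` and `n_dropped`.
#' @export
summary_table <- function(df, trait_id = "trait") {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.canonical_cols, names(df))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[.canonical_cols]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$pos <- as.integer(df$pos)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)

  if (anyDuplicated(df$snp)) {
    stop("duplicate snp identifiers in table '", trait_id, "': ",
         paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))
  }

  ok <- !is.na(df$snp) & nzchar(df$snp) &
    !is.na(df$pos) & df$pos >= 1 &
    df$ea %in% .bases & df$oa %in% .bases & df$ea != df$oa &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    !is.na(df$beta) & is.finite(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
    !is.na(df$n) & df$n >= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(n_dropped, " row(s) dropped from '", trait_id,
            "' for failing validation", call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }

  if (nrow(df) > 0) {
    p_implied <- 2 * stats::pnorm(-abs(df$beta / df$se))
    inconsistent <- p_implied > 1e-290 & df$pval > 1e-290 &
      (df$pval / p_implied > 2 | p_implied / df$pval > 2) &
      df$pval < 0.99   # rounded p = 1 and underflowed rows are uninformative
    if (any(inconsistent, na.rm = TRUE)) {
      warning(sum(inconsistent, na.rm = TRUE), " row(s) in '", trait_id,
              "' have p-values inconsistent with beta/se by more than 2x",
              call. = FALSE)
    }
  }

  rownames(df) <- NULL
  structure(df, trait_id = trait_id, n_dropped = n_dropped,
            class = c("summary_table", "data.frame"))
}

# subset an already-validated table without re-running validation
.subset_summary <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = attr(table, "trait_id"),
            n_dropped = attr(table, "n_dropped"),
            class = c("summary_table", "data.frame"))
}

#' Trait identifier of a summary table
#' @param table A `summary_table`.
#' @return Character scalar.
#' @export
trait_id <- function(table) attr(table, "trait_id")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited summary-statistics file, maps source headers onto
#' the canonical dialect, and validates every row (see [summary_table()]).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param trait_id Trait name; defaults to the file name without extension.
#' @param dialect Column mapping from [summary_dialect()].
#' @return A validated `summary_table`.
#' @export
read_summary <- function(path, trait_id = NULL,
                         dialect = summary_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(trait_id)) {
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  df <- raw[unname(dialect)]
  names(df) <- names(dialect)
  summary_table(df, trait_id = trait_id)
}

#' Write a summary table in the canonical dialect
#'
#' Writes a tab-delimited file with the canonical header and 17 significant
#' digits for real-valued columns, so that [read_summary()] recovers the
#' table exactly.
#'
#' @param table A `summary_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(table, path) {
  stopifnot(inherits(table, "summary_table"))
  df <- as.data.frame(table)
  for (col in c("eaf", "beta", "se", "pval")) {
    df[[col]] <- trimws(formatC(df[[col]], digits = 17, format = "g"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set identifier, description, then one or more member
#' symbols, all tab-separated. Duplicate members within a line are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene sets, each a list with `set_id`, `description`,
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("GMT line ", i, " has no members")
    }
    ids[[i]] <- fields[[1]]
    sets[[i]] <- list(set_id = fields[[1]], description = fields[[2]],
                      members = members)
  }
  names(sets) <- ids
  sets
}

#' Read a SNP-by-SNP LD matrix
#'
#' Expects a tab-delimited square matrix with SNP identifiers as both the
#' header row and the first column. Values must lie in \[-1, 1\]; mild
#' asymmetry is repaired by averaging the two off-diagonal entries (with a
#' warning) and the diagonal is forced to 1.
#'
#' @param path Path to the LD matrix file.
#' @return Numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) {
    stop("LD matrix is not square: ", nrow(m), " x ", ncol(m))
  }
  mode(m) <- "numeric"
  if (any(is.na(m))) stop("LD matrix contains missing values")
  if (any(abs(m) > 1)) stop("LD matrix has entries outside [-1, 1]")
  if (!isTRUE(all.equal(m, t(m), tolerance = 0))) {
    if (max(abs(m - t(m))) > 0) {
      warning("asymmetric LD matrix symmetrized by averaging", call. = FALSE)
    }
    m <- (m + t(m)) / 2
  }
  diag(m) <- 1
  m
}

#' Read a SNP blocklist
#'
#' One SNP identifier per line; `#` starts a comment.
#'
#' @param path Path to the blocklist file.
#' @return Character vector of SNP ids (possibly empty).
#' @export
read_blocklist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' @export
print.summary_table <- function(x, ...) {
  cat("GWAS summary table '", trait_id(x), "': ", nrow(x), " SNP(s)\n",
      sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}
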
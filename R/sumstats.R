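# Summary-statistics tables: a data.frame subclass with canonical columns
#   marker_id, chrom, pos, effect_allele, other_allele, beta, se, p
# plus attributes `dialect` (input column convention) and `source_label`.

# recognized input dialects: canonical field -> header aliases (lower case)
.dialects <- list(
  canonical = c(marker_id = "marker_id", chrom = "chrom", pos = "pos",
                effect_allele = "effect_allele", other_allele = "other_allele",
                beta = "beta", se = "se", p = "p"),
  metal = c(marker_id = "markername", allele1 = "allele1", allele2 = "allele2",
            effect_allele = "allele1", other_allele = "allele2",
            chrom = "chromosome", pos = "position",
            beta = "effect", se = "stderr", p = "p-value"),
  plink = c(marker_id = "snp", effect_allele = "a1", other_allele = "a2",
            chrom = "chr", pos = "bp", beta = "beta", se = "se", p = "p")
)

.required_fields <- c("marker_id", "beta", "se")

#' Construct a summary-statistics table
#'
#' @param df A data.frame with at least `marker_id`, `beta`, `se` columns;
#'   optional `chrom`, `pos`, `effect_allele`, `other_allele`, `p`.
#' @param dialect Column-convention tag recorded on the object (the canonical
#'   columns themselves are always used internally).
#' @param source_label Free-text provenance label.
#' @return Object of class `c("sumstats", "data.frame")`.
#' @export
sumstats <- function(df, dialect = "canonical", source_label = "") {
  stopifnot(is.data.frame(df))
  for (col in c("chrom", "pos", "effect_allele", "other_allele", "p")) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  df <- df[, c("marker_id", "chrom", "pos", "effect_allele", "other_allele",
               "beta", "se", "p",
               setdiff(names(df), c("marker_id", "chrom", "pos",
                                    "effect_allele", "other_allele",
                                    "beta", "se", "p")))]
  df$marker_id <- as.character(df$marker_id)
  df$beta <- as.numeric(df$beta)
  df$se <- as.numeric(df$se)
  validate_sumstats(df)
  structure(df, dialect = dialect, source_label = source_label,
            class = c("sumstats", "data.frame"))
}

validate_sumstats <- function(df) {
  miss <- setdiff(.required_fields, names(df))
  if (length(miss)) {
    stop(invalid_input(paste("missing required column(s):",
                             paste(miss, collapse = ", "))))
  }
  dup <- unique(df$marker_id[duplicated(df$marker_id)])
  if (length(dup)) {
    stop(invalid_input(paste("duplicate marker ID(s):",
                             paste(utils::head(dup, 5L), collapse = ", "))))
  }
  bad <- !is.finite(df$se) | df$se <= 0 | !is.finite(df$beta)
  if (any(bad)) {
    stop(invalid_input(paste(
      "rows with missing/non-finite beta or non-positive se:",
      paste(utils::head(df$marker_id[bad], 5L), collapse = ", ")
    )))
  }
  invisible(df)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("Summary statistics [%s]%s: %d marker(s)\n",
              attr(x, "dialect"),
              if (nzchar(attr(x, "source_label")))
                paste0(" <", attr(x, "source_label"), ">") else "",
              nrow(x)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat(sprintf("... %d more row(s)\n", nrow(x) - 6L))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) {
    cat(sprintf("%d input row(s) were rejected at read time; see attr(x, \"rejected\")\n",
                nrow(rej)))
  }
  invisible(x)
}

detect_dialect <- function(header) {
  h <- tolower(header)
  for (d in names(.dialects)) {
    al <- .dialects[[d]]
    # an OR column may stand in for the beta column (log-transform is
    # gated behind read_sumstats(or_scale = TRUE))
    if (all(al[c("marker_id", "se")] %in% h) &&
        (al[["beta"]] %in% h || "or" %in% h)) {
      return(d)
    }
  }
  stop(invalid_input(paste0(
    "could not detect summary-statistics dialect from header [",
    paste(header, collapse = ", "), "]; recognized dialects: ",
    paste(names(.dialects), collapse = ", ")
  )))
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-delimited summary-statistics table (optionally
#' gzip-compressed) and maps its columns to the canonical fields. Three
#' header conventions are recognized, case-insensitively:
#' `canonical` (`marker_id/effect_allele/other_allele/beta/se/p`),
#' `metal` (`MarkerName/Allele1/Allele2/Effect/StdErr/P-value`) and
#' `plink` (`SNP/A1/A2/BETA/SE/P`). When `dialect` is omitted it is
#' auto-detected from the header.
#'
#' Rows whose standard error is missing or non-positive violate the table
#' invariant and are rejected individually; they are reported via a warning
#' and kept, with the reason, in `attr(result, "rejected")` — never silently
#' dropped without trace. Duplicated marker IDs are a hard error.
#'
#' Odds-ratio input (an `OR` column in place of `beta`) is refused unless
#' `or_scale = TRUE`, in which case `beta = log(OR)` and the file's SE must
#' already be on the log-odds scale (the universal convention in
#' logistic-regression GWAS output); silently mixing scales would corrupt
#' the meta-analysis algebra.
#'
#' @param path Path to the file (plain or `.gz`).
#' @param dialect Optional dialect tag (`"canonical"`, `"metal"`, `"plink"`);
#'   auto-detected when `NULL`.
#' @param or_scale Accept an odds-ratio effect column and log-transform it.
#' @param source_label Provenance label stored on the table; defaults to the
#'   file name.
#' @return A [sumstats] table.
#' @export
read_sumstats <- function(path, dialect = NULL, or_scale = FALSE,
                          source_label = basename(path)) {
  if (!file.exists(path)) {
    stop(invalid_input(paste("file not found:", path)))
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  header <- names(raw)
  if (is.null(dialect)) dialect <- detect_dialect(header)
  if (!dialect %in% names(.dialects)) {
    stop(invalid_input(paste0("unknown dialect '", dialect,
                              "'; recognized: ",
                              paste(names(.dialects), collapse = ", "))))
  }
  al <- .dialects[[dialect]]
  h <- tolower(header)
  pick <- function(field) {
    i <- match(al[[field]], h)
    if (is.na(i)) NULL else raw[[i]]
  }
  df <- data.frame(marker_id = as.character(pick("marker_id")),
                   stringsAsFactors = FALSE)
  for (field in c("chrom", "pos", "effect_allele", "other_allele", "p")) {
    v <- if (field %in% names(al)) pick(field) else NULL
    df[[field]] <- if (is.null(v)) NA else v
  }
  beta <- pick("beta")
  if (is.null(beta)) {
    i_or <- match("or", h)
    if (!is.na(i_or)) {
      if (!or_scale) {
        stop(invalid_input(
          "input carries an odds-ratio (OR) column; pass or_scale = TRUE to log-transform it (SE must already be on the log scale)"
        ))
      }
      beta <- log(as.numeric(raw[[i_or]]))
    } else {
      stop(invalid_input("no effect-size column found"))
    }
  }
  df$beta <- as.numeric(beta)
  df$se <- as.numeric(pick("se"))

  dup <- unique(df$marker_id[duplicated(df$marker_id)])
  if (length(dup)) {
    stop(invalid_input(paste("duplicate marker ID(s) in", path, ":",
                             paste(utils::head(dup, 5L), collapse = ", "))))
  }
  bad <- !is.finite(df$se) | df$se <= 0 | !is.finite(df$beta)
  rejected <- NULL
  if (any(bad)) {
    rejected <- data.frame(
      marker_id = df$marker_id[bad],
      reason = ifelse(!is.finite(df$se[bad]), "missing/non-finite se",
                      ifelse(df$se[bad] <= 0, "non-positive se",
                             "missing/non-finite beta")),
      stringsAsFactors = FALSE
    )
    warning(sprintf("%s: rejected %d row(s) with invalid beta/se (%s)",
                    basename(path), nrow(rejected),
                    paste(utils::head(rejected$marker_id, 5L), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  out <- sumstats(df, dialect = dialect, source_label = source_label)
  attr(out, "rejected") <- rejected
  out
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited dialect. Numeric fields are serialized
#' with 17 significant digits so that a read/write round trip reproduces
#' every `beta`/`se`/`p` bit for bit.
#'
#' @param table A [sumstats] table (a plain data.frame with the canonical
#'   columns is accepted).
#' @param path Output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- "NA"
      df[[col]] <- v
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
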
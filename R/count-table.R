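#' Construct a sample-by-OTU count table
#'
#' The raw community observation: a non-negative integer matrix with samples
#' as rows and OTUs as columns, plus a 7-rank taxonomy string per OTU
#' (`"k__...; p__...; c__...; o__...; f__...; g__...; s__..."`; trailing
#' ranks may be unclassified).
#'
#' @param counts integer matrix, samples x OTUs, with dimnames.
#' @param taxonomy named character vector mapping OTU id to taxonomy string.
#'   OTUs without an entry get an empty lineage.
#' @return An object of class `count_table` with elements `counts`,
#'   `sample_ids`, `otu_ids`, `taxonomy`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be non-negative integers; offending cell: sample '",
         rownames(counts)[bad[1, 1]], "', OTU '", colnames(counts)[bad[1, 2]],
         "' = ", counts[bad[1, 1], bad[1, 2]])
  }
  storage.mode(counts) <- "integer"
  tax <- setNames(rep("", ncol(counts)), colnames(counts))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be named by OTU id")
    tax[intersect(names(taxonomy), names(tax))] <-
      taxonomy[intersect(names(taxonomy), names(tax))]
  }
  structure(list(counts = counts,
                 sample_ids = rownames(counts),
                 otu_ids = colnames(counts),
                 taxonomy = tax),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", length(x$sample_ids), " samples x ",
      length(x$otu_ids), " OTUs; total reads ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

# Subset a count table by sample and/or OTU ids (internal).
subset_count_table <- function(table, samples = NULL, otus = NULL) {
  samples <- samples %||% table$sample_ids
  otus <- otus %||% table$otu_ids
  count_table(table$counts[samples, otus, drop = FALSE],
              table$taxonomy[otus])
}

TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

# Split one taxonomy string into its 7 rank fields (empty where absent).
parse_lineage <- function(s) {
  out <- setNames(rep("", 7L), TAX_RANKS)
  if (is.na(s) || !nzchar(s)) return(out)
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  for (p in parts) {
    hit <- which(startsWith(p, TAX_PREFIXES))
    if (length(hit) == 1L) out[hit] <- p
  }
  out
}

#' Read an OTU count table
#'
#' Supports the classic tab-delimited OTU-table dialect (OTU ids as rows,
#' samples as columns, a final `taxonomy` column, optional leading
#' `# Constructed from biom file` comment) and BIOM-JSON via the
#' \pkg{biomformat} package.
#'
#' @param path file path.
#' @param format `"classic_tsv"` or `"biom_json"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("classic_tsv", "biom_json")) {
  format <- match.arg(format)
  if (format == "biom_json") return(read_biom_table(path))
  lines <- readLines(path)
  # leading comment lines ("# Constructed from biom file") precede the header
  hdr <- which(startsWith(lines, "#OTU ID"))[1]
  if (is.na(hdr)) hdr <- which(!startsWith(lines, "#"))[1] - 1L
  if (is.na(hdr) || hdr < 1L) stop("no '#OTU ID' header found in ", path)
  df <- read.table(text = lines[hdr:length(lines)], sep = "\t", header = TRUE,
                   comment.char = "", check.names = FALSE,
                   colClasses = "character", quote = "")
  names(df)[1] <- "otu_id"
  has_tax <- tolower(names(df)[ncol(df)]) %in% c("taxonomy", "consensus lineage")
  if (!has_tax) {
    warning("no taxonomy column in ", path, "; lineages left empty")
    tax_col <- NULL
  } else {
    tax_col <- df[[ncol(df)]]
    df <- df[-ncol(df)]
  }
  otus <- df$otu_id
  if (anyDuplicated(otus)) stop("duplicate OTU ids in ", path)
  mat <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  if (anyNA(num)) stop("non-numeric count in ", path)
  counts <- t(num)                             # samples x OTUs
  colnames(counts) <- otus
  tax <- if (is.null(tax_col)) NULL else setNames(tax_col, otus)
  count_table(counts, tax)
}

read_biom_table <- function(path) {
  b <- biomformat::read_biom(path)
  mat <- as(biomformat::biom_data(b), "matrix")   # observations x samples
  counts <- t(mat)
  md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  tax <- NULL
  if (!is.null(md)) {
    if (is.data.frame(md)) {
      tax <- setNames(apply(md, 1L, paste, collapse = "; "), rownames(md))
    } else if (is.list(md)) {
      tax <- vapply(md, function(x) paste(unlist(x), collapse = "; "), character(1))
    }
  }
  if (is.null(tax)) warning("no observation metadata in ", path,
                            "; lineages left empty")
  count_table(counts, tax)
}

#' Write a count table in the classic tab-delimited dialect
#'
#' OTUs as rows, samples as columns, a final `taxonomy` column; round-trips
#' bit-exactly through [read_count_table()].
#'
#' @param table a [count_table()].
#' @param path output file.
#' @param biom_header write the conventional `# Constructed from biom file`
#'   first line.
#' @export
write_classic_otu_table <- function(table, path, biom_header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (biom_header) writeLines("# Constructed from biom file", con)
  writeLines(paste(c("#OTU ID", table$sample_ids, "taxonomy"), collapse = "\t"), con)
  m <- t(table$counts)                            # OTUs x samples
  body <- paste(rownames(m),
                apply(m, 1L, paste, collapse = "\t"),
                table$taxonomy[rownames(m)], sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Tab-delimited, keyed by a `sample_id` (or QIIME-style `#SampleID`) first
#' column.  Recognised columns: `ethnicity`, `sex`, `age`, `bmi`,
#' `body_site`, `country`; anything else rides along as an extra factor.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "",
                   check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  names(df)[1] <- sub("^#SampleID$", "sample_id", names(df)[1])
  names(df)[1] <- sub("^#sample_id$", "sample_id", names(df)[1])
  if (names(df)[1] != "sample_id") names(df)[1] <- "sample_id"
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  for (col in c("age", "bmi")) if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname read_metadata
#' @param metadata data.frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  names(out)[names(out) == "sample_id"] <- "#SampleID"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
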
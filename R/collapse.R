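#' Collapse an OTU table to a taxonomic rank
#'
#' OTUs sharing the lineage prefix through `rank` are summed; each sample
#' row is then closed to relative abundance.  An OTU unclassified at `rank`
#' (empty field or bare prefix such as `"g__"`) is kept as a distinct
#' "Unclassified-within-parent" taxon -- its label retains the classified
#' prefix, so unclassified genera of different families stay separate.  An
#' OTU with an entirely empty lineage lands in an `"Unassigned"` bucket.
#'
#' @param table a [count_table()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return Object of class `taxon_table`: `values` (samples x taxa relative
#'   abundances; rows sum to 1 unless a sample has zero reads, which is
#'   flagged), `counts` (the pre-closure collapsed counts), `rank`,
#'   `sample_ids`, `taxa`.
#' @export
collapse_taxonomy <- function(table, rank = c("phylum", "class", "order",
                                              "family", "genus")) {
  rank <- match.arg(rank)
  idx <- match(rank, TAX_RANKS)
  labels <- vapply(table$taxonomy, function(s) {
    lin <- parse_lineage(s)
    if (all(!nzchar(lin))) return("Unassigned")
    fields <- lin[seq_len(idx)]
    empty <- !nzchar(fields) | fields %in% TAX_PREFIXES[seq_len(idx)]
    fields[empty] <- paste0(TAX_PREFIXES[seq_len(idx)][empty], "Unclassified")
    paste(fields, collapse = "; ")
  }, character(1))
  collapsed <- t(rowsum(t(table$counts), labels))   # samples x taxa
  taxon_table(collapsed, rank)
}

#' Construct a taxon table from collapsed counts
#'
#' @param counts samples x taxa matrix of collapsed counts (or already
#'   relative abundances; rows are re-closed either way).
#' @param rank taxonomic rank of the columns.
#' @keywords internal
#' @export
taxon_table <- function(counts, rank) {
  counts <- as.matrix(counts)
  depths <- rowSums(counts)
  values <- counts / ifelse(depths > 0, depths, 1)
  zero_rows <- rownames(counts)[depths == 0]
  structure(list(values = values, counts = counts, rank = rank,
                 sample_ids = rownames(counts), taxa = colnames(counts),
                 zero_samples = zero_rows),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("<taxon_table> rank ", x$rank, ": ", length(x$sample_ids),
      " samples x ", length(x$taxa), " taxa\n", sep = "")
  invisible(x)
}

# Field of a collapsed label at a rank ("" if absent), internal.
label_rank_field <- function(label, rank) {
  lin <- parse_lineage(label)
  lin[[match(rank, TAX_RANKS)]]
}

# TRUE when a collapsed label is classified at its terminal rank.
label_is_classified <- function(label, rank) {
  f <- label_rank_field(label, rank)
  nzchar(f) && !grepl("Unclassified$", f) && !(f %in% TAX_PREFIXES)
}
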
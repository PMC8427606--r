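#' Read a miRNA target-prediction export table
#'
#' Expects TSV columns `mirna gene` and, for score-bearing sources, `score`
#' (miRDB prediction score, or TargetScan cumulative weighted context++
#' score; miRTarBase rows carry no score — presence is the evidence). Gene
#' symbols are upper-cased and trimmed so downstream matching is exact
#' normalized-string comparison.
#'
#' @param path TSV file.
#' @param source `"mirdb"`, `"targetscan"` or `"mirtarbase"`.
#' @return `data.frame` with `mirna_id`, `gene_symbol`, `source`, `score`
#'   (`NA` for miRTarBase when absent).
#' @export
read_target_table <- function(path, source = c("mirdb", "targetscan",
                                               "mirtarbase")) {
  source <- match.arg(source)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("mirna", "gene")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("target table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"score" %in% names(df)) {
    if (source != "mirtarbase") {
      stop("source '", source, "' requires a score column")
    }
    df$score <- NA_real_
  }
  data.frame(mirna_id = trimws(df$mirna),
             gene_symbol = toupper(trimws(df$gene)),
             source = source, score = as.numeric(df$score),
             stringsAsFactors = FALSE)
}

#' Apply the per-database target filter
#'
#' miRDB predictions are kept when `80 < score <= 100` (strict lower bound:
#' a score of exactly 80 is excluded); scores outside `(0, 100]` are not
#' valid miRDB scores and the rows are rejected with a warning. TargetScan
#' predictions are kept when the cumulative weighted context++ score is
#' `<= -0.2` (inclusive; more negative means stronger repression, no lower
#' bound). miRTarBase entries are experimentally supported interactions and
#' are all kept.
#'
#' @param rows `data.frame` as from [read_target_table()], all of one
#'   source.
#' @param source `"mirdb"`, `"targetscan"` or `"mirtarbase"`.
#' @return The filtered rows.
#' @export
filter_source <- function(rows, source = c("mirdb", "targetscan",
                                           "mirtarbase")) {
  source <- match.arg(source)
  if (source == "mirdb") {
    invalid <- is.na(rows$score) | rows$score <= 0 | rows$score > 100
    if (any(invalid)) {
      warning("rejecting ", sum(invalid),
              " row(s) with scores outside the miRDB range (0, 100]")
      rows <- rows[!invalid, , drop = FALSE]
    }
    return(rows[rows$score > 80 & rows$score <= 100, , drop = FALSE])
  }
  if (source == "targetscan") {
    invalid <- is.na(rows$score)
    if (any(invalid)) {
      warning("rejecting ", sum(invalid),
              " TargetScan row(s) without a context score")
      rows <- rows[!invalid, , drop = FALSE]
    }
    return(rows[rows$score <= -0.2, , drop = FALSE])
  }
  rows
}

#' Intersect filtered target predictions across the three databases
#'
#' A gene is a consensus target of a miRNA when it appears, after the
#' per-source filters, in miRDB, TargetScan and miRTarBase for that miRNA.
#' An empty intersection is a valid result (some miRNAs have no gene shared
#' by all three databases). Gene-symbol aliases are not resolved; matching
#' is exact on the normalized symbol.
#'
#' @param mirdb,targetscan,mirtarbase Already-filtered rows per source.
#' @param mirna Optional miRNA id to restrict to.
#' @return `data.frame` with `mirna_id`, `gene_symbol`, `mirdb_score`,
#'   `targetscan_score`, sorted by miRNA then gene symbol.
#' @export
intersect_targets <- function(mirdb, targetscan, mirtarbase, mirna = NULL) {
  if (!is.null(mirna)) {
    mirdb <- mirdb[mirdb$mirna_id %in% mirna, , drop = FALSE]
    targetscan <- targetscan[targetscan$mirna_id %in% mirna, , drop = FALSE]
    mirtarbase <- mirtarbase[mirtarbase$mirna_id %in% mirna, , drop = FALSE]
  }
  key <- function(d) paste(d$mirna_id, d$gene_symbol, sep = "\r")
  shared <- intersect(intersect(key(mirdb), key(targetscan)),
                      key(mirtarbase))
  i <- match(shared, key(mirdb))
  j <- match(shared, key(targetscan))
  out <- data.frame(mirna_id = mirdb$mirna_id[i],
                    gene_symbol = mirdb$gene_symbol[i],
                    mirdb_score = mirdb$score[i],
                    targetscan_score = targetscan$score[j],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter and intersect in one call
#'
#' Convenience wrapper: applies [filter_source()] to each table, then
#' [intersect_targets()].
#'
#' @param mirdb,targetscan,mirtarbase Unfiltered rows per source (as from
#'   [read_target_table()]).
#' @param mirna Optional miRNA id restriction.
#' @return Consensus targets, see [intersect_targets()].
#' @export
consensus_targets <- function(mirdb, targetscan, mirtarbase, mirna = NULL) {
  intersect_targets(filter_source(mirdb, "mirdb"),
                    filter_source(targetscan, "targetscan"),
                    filter_source(mirtarbase, "mirtarbase"),
                    mirna = mirna)
}
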
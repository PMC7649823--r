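#' Construct a PPI network object
#'
#' Undirected gene-level interaction network with STRING-style combined
#' confidence scores (0-1000). Self-loops are dropped; duplicate and
#' reciprocal pairs are collapsed keeping the maximum score; each edge is
#' stored once with endpoints in lexicographic order.
#'
#' @param gene1,gene2 character vectors of edge endpoints.
#' @param score numeric vector of confidence scores in \[0, 1000\].
#' @return an object of class `diffge_ppi`: a data.frame with columns
#'   `gene1`, `gene2`, `score`.
#' @export
ppi_network <- function(gene1 = character(), gene2 = character(),
                        score = numeric()) {
  stopifnot(length(gene1) == length(gene2), length(gene1) == length(score))
  if (any(is.na(score)) || any(score < 0) || any(score > 1000)) {
    stop("scores must be numeric in [0, 1000]")
  }
  keep <- gene1 != gene2
  gene1 <- gene1[keep]; gene2 <- gene2[keep]; score <- score[keep]
  a <- pmin(gene1, gene2)
  b <- pmax(gene1, gene2)
  df <- data.frame(gene1 = a, gene2 = b, score = score,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$gene1, df$gene2, sep = "\r")
    df <- df[order(key, -df$score), , drop = FALSE]
    df <- df[!duplicated(paste(df$gene1, df$gene2, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("diffge_ppi", "data.frame")
  df
}

#' @export
print.diffge_ppi <- function(x, ...) {
  cat(sprintf("<diffge_ppi> %d edges over %d genes\n",
              nrow(x), length(ppi_genes(x))))
  if (nrow(x)) print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Node set of a PPI network
#' @param ppi a [ppi_network()] object.
#' @return sorted character vector of gene identifiers with >= 1 edge.
#' @export
ppi_genes <- function(ppi) {
  sort(unique(c(ppi$gene1, ppi$gene2)))
}

#' Read a STRING-dialect protein links file
#'
#' Parses whitespace- or tab-delimited `protein1 protein2 combined_score`
#' files as distributed by STRING. A header row is auto-detected by a
#' non-numeric score field. Edges below `min_score` are discarded. When an
#' alias file is given, protein identifiers are translated to gene symbols
#' and edges with unmapped endpoints are dropped (their count is reported
#' in a message). Self-loops are removed and reciprocal duplicates
#' collapsed keeping the maximum score.
#'
#' @param links_path path to the links file (>= 3 columns).
#' @param alias_path optional two-column TSV mapping protein id -> gene
#'   symbol. A protein mapped to several genes keeps the first mapping
#'   (warning emitted).
#' @param min_score minimum combined score in \[0, 1000\] (STRING's
#'   "medium confidence" 400 by default).
#' @return a [ppi_network()] object.
#' @export
read_ppi <- function(links_path, alias_path = NULL, min_score = 400) {
  if (!file.exists(links_path)) stop("file not found: ", links_path)
  stopifnot(is.numeric(min_score), min_score >= 0, min_score <= 1000)
  raw <- utils::read.table(links_path, header = FALSE, sep = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 3L) stop("links file must have >= 3 columns")
  # header detection: first row's third field not numeric
  if (nrow(raw) && is.na(suppressWarnings(as.numeric(raw[1, 3])))) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0L) return(ppi_network())
  score <- suppressWarnings(as.numeric(raw[[3]]))
  if (any(is.na(score))) {
    stop("malformed score column at line ", which(is.na(score))[1])
  }
  p1 <- raw[[1]]; p2 <- raw[[2]]
  keep <- score >= min_score
  p1 <- p1[keep]; p2 <- p2[keep]; score <- score[keep]
  if (!is.null(alias_path)) {
    map <- read_alias(alias_path)
    m1 <- map[p1]; m2 <- map[p2]
    unmapped <- is.na(m1) | is.na(m2)
    if (any(unmapped)) {
      message(sum(unmapped), " edge(s) dropped with unmapped endpoint(s)")
    }
    p1 <- unname(m1[!unmapped]); p2 <- unname(m2[!unmapped])
    score <- score[!unmapped]
  }
  ppi_network(p1, p2, score)
}

read_alias <- function(alias_path) {
  if (!file.exists(alias_path)) stop("file not found: ", alias_path)
  df <- utils::read.table(alias_path, header = FALSE, sep = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("alias file must have >= 2 columns")
  dup <- duplicated(df[[1]])
  if (any(dup)) {
    warning("alias file maps ", sum(dup),
            " protein id(s) to multiple genes; keeping first mapping")
    df <- df[!dup, , drop = FALSE]
  }
  stats::setNames(df[[2]], df[[1]])
}
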
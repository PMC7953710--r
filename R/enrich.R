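# Pathway over-representation analysis and the pairwise pathway-difference
# statistic.
#
# Over-representation uses the one-sided ("greater") Fisher exact test on the
# 2x2 table (in query & in pathway | in query & not | not & in | not & not)
# within a fixed gene universe.  The pathway difference for two subnetwork
# gene sets S_i, S_k and a pathway P with P_i = P \cap S_i is
#   dP_{i,k} = |(P_i u P_k) \ (P_i n P_k)| / |P_i u P_k|,  defined only when
# |P_i u P_k| > 0; per pathway the median over all defined unordered pairs is
# reported.

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   \code{name<TAB>description<TAB>member...}.
#' @return object of class \code{gene_set_collection}: named list of unique
#'   member vectors, with a \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("%s: empty GMT file", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stopf("%s: line %d has fewer than 3 fields", path, bad[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stopf("%s: duplicate set names", path)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of member vectors (or a \code{gene_set_collection}).
#' @param path output path.
#' @param descriptions optional per-set description (default "na").
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Fisher exact over-representation test
#'
#' @param query character vector of query genes (e.g. a subnetwork gene set).
#' @param pathway character vector of pathway members.
#' @param universe_size total gene count N of the contingency table (must be
#'   at least \code{length(union(query, pathway))}).
#' @return one-row data.frame: \code{hits}, \code{set_size},
#'   \code{pathway_size}, \code{p} (one-sided "greater" Fisher exact p-value).
#' @export
fisher_enrichment <- function(query, pathway, universe_size) {
  query <- unique(query); pathway <- unique(pathway)
  n_union <- length(union(query, pathway))
  if (universe_size < n_union)
    stopf("universe size %d smaller than |query u pathway| = %d",
          universe_size, n_union)
  hits <- length(intersect(query, pathway))
  tab <- matrix(c(hits,
                  length(query) - hits,
                  length(pathway) - hits,
                  universe_size - length(query) - length(pathway) + hits),
                2L, 2L)
  p <- fisher.test(tab, alternative = "greater")$p.value
  data.frame(hits = hits, set_size = length(query),
             pathway_size = length(pathway), p = p)
}

#' Multiple-testing adjustment of enrichment rows
#'
#' @param rows data.frame with a \code{p} column (one row per pathway tested).
#' @param method \code{"BH"} (Benjamini-Hochberg, default) or
#'   \code{"bonferroni"}.
#' @return \code{rows} with an added \code{p_adj} column.
#' @export
adjust_pvalues <- function(rows, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L, "p" %in% names(rows))
  rows$p_adj <- p.adjust(rows$p, method = method)
  rows
}

#' Pathway difference between two subnetwork gene sets
#'
#' @param pathway pathway member genes P.
#' @param set_i,set_k two subnetwork gene sets S_i, S_k.
#' @return the symmetric-difference fraction of the matched pathway genes, in
#'   \code{[0, 1]}; \code{NA} when neither set matches the pathway (the
#'   statistic is undefined for an empty union, as per its side condition).
#' @export
pathway_difference <- function(pathway, set_i, set_k) {
  pi_ <- intersect(pathway, set_i)
  pk_ <- intersect(pathway, set_k)
  u <- union(pi_, pk_)
  if (length(u) == 0L) return(NA_real_)
  length(setdiff(u, intersect(pi_, pk_))) / length(u)
}

#' Median pairwise pathway difference
#'
#' @param pathway pathway member genes.
#' @param sets list of >= 2 subnetwork gene sets.
#' @return list with \code{median} (median of the defined pairwise
#'   differences; NA if every pair is undefined), \code{n_pairs} (defined
#'   pairs) and \code{n_skipped} (undefined pairs).
#' @export
median_pairwise_difference <- function(pathway, sets) {
  if (length(sets) < 2L) stopf("need at least 2 sets")
  pairs <- utils::combn(length(sets), 2L)
  d <- apply(pairs, 2L, function(ik)
    pathway_difference(pathway, sets[[ik[1]]], sets[[ik[2]]]))
  ok <- !is.na(d)
  list(median = if (any(ok)) median(d[ok]) else NA_real_,
       n_pairs = sum(ok), n_skipped = sum(!ok))
}

#' Enrichment of one or more gene sets against a collection
#'
#' Runs \code{\link{fisher_enrichment}} for every (query set, pathway) pair,
#' adjusts p-values (one family per query set by default, or one family across
#' all tests with \code{family = "global"}), and, when several query sets are
#' given, appends the per-pathway median pairwise difference.
#'
#' @param queries named list of query gene sets.
#' @param collection a \code{gene_set_collection} (or named list of pathways).
#' @param universe_size total contingency-table gene count; default the size
#'   of the union of all pathway and query genes.
#' @param method multiple-testing method, see \code{\link{adjust_pvalues}}.
#' @param family \code{"per_set"} (adjust within each query set) or
#'   \code{"global"}.
#' @return data.frame with columns query, pathway, pathway_size, set_size,
#'   hits, p, p_adj, dP_median.
#' @export
enrich_collection <- function(queries, collection, universe_size = NULL,
                              method = "BH",
                              family = c("per_set", "global")) {
  family <- match.arg(family)
  if (length(collection) == 0L) stopf("empty pathway collection")
  if (is.null(names(queries))) names(queries) <- paste0("set", seq_along(queries))
  if (is.null(universe_size))
    universe_size <- length(unique(c(unlist(collection), unlist(queries))))
  rows <- do.call(rbind, lapply(names(queries), function(qn) {
    do.call(rbind, lapply(names(collection), function(pn) {
      r <- fisher_enrichment(queries[[qn]], collection[[pn]], universe_size)
      cbind(data.frame(query = qn, pathway = pn), r)
    }))
  }))
  if (family == "global") {
    rows <- adjust_pvalues(rows, method)
  } else {
    rows <- do.call(rbind, lapply(split(rows, rows$query),
                                  adjust_pvalues, method = method))
    rownames(rows) <- NULL
  }
  if (length(queries) >= 2L) {
    med <- vapply(names(collection), function(pn)
      median_pairwise_difference(collection[[pn]], queries)$median, numeric(1))
    rows$dP_median <- med[rows$pathway]
  } else {
    rows$dP_median <- NA_real_
  }
  rows
}
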
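# Cross-species comparison layer: how well does one species' product
# predict the others'? Continuous products (suitability, current, corridor
# surfaces) are compared by Pearson correlation over jointly valid cells;
# binary corridor masks by percent overlap.

#' Pearson correlation between two raster maps
#'
#' Computed over jointly valid (non-nodata, finite) cells. A constant map
#' has no defined correlation; `NA` is returned with a warning.
#'
#' @param a,b grid-compatible `raster_grid` objects.
#' @return correlation in \[-1, 1\], or `NA` if undefined.
#' @export
map_correlation <- function(a, b) {
  stop_if_incompatible(a, b, "maps")
  ok <- valid_mask(a) & valid_mask(b)
  if (sum(ok) < 3) stop("need at least 3 jointly valid cells")
  va <- a$values[ok]; vb <- b$values[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("correlation undefined: at least one map is constant over the shared cells")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Percent overlap of two corridor masks
#'
#' Symmetric Jaccard percentage `100 * |A n B| / |A u B|` by default. With
#' equal-area corridor slices the masks have (almost) equal area, so this
#' nearly coincides with the asymmetric convention
#' (`mean(|A n B|/|A|, |A n B|/|B|) * 100`), available via `convention`.
#'
#' @param a,b logical corridor masks (matrices) of equal dimension, both
#'   nonempty.
#' @param convention `"jaccard"` (default) or `"mean_asymmetric"`.
#' @return overlap percentage in \[0, 100\].
#' @export
percent_overlap <- function(a, b, convention = c("jaccard", "mean_asymmetric")) {
  convention <- match.arg(convention)
  if (!identical(dim(a), dim(b))) stop("masks must share dimensions")
  if (!any(a) || !any(b)) stop("corridor masks must be nonempty")
  inter <- sum(a & b)
  if (convention == "jaccard") {
    100 * inter / sum(a | b)
  } else {
    100 * mean(c(inter / sum(a), inter / sum(b)))
  }
}

#' Pairwise comparison matrix across species products
#'
#' @param products named list of products, one per label: `raster_grid`
#'   objects (or `suitability_map`s) for `statistic = "pearson_r"`, logical
#'   mask matrices for `statistic = "percent_overlap"`.
#' @param statistic `"pearson_r"` or `"percent_overlap"`.
#' @param convention overlap convention, see [percent_overlap()].
#' @return a square matrix with dimnames = labels; diagonal 1 (correlation)
#'   or 100 (overlap). Class `comparison_matrix` with attributes
#'   `statistic` and `convention`.
#' @export
comparison_matrix <- function(products,
                              statistic = c("pearson_r", "percent_overlap"),
                              convention = "jaccard") {
  statistic <- match.arg(statistic)
  labels <- names(products)
  if (length(labels) < 2) stop("need at least two labelled products")
  products <- lapply(products, function(p) {
    if (inherits(p, "suitability_map")) p$grid else p
  })
  k <- length(labels)
  m <- matrix(if (statistic == "pearson_r") 1 else 100, k, k,
              dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- if (statistic == "pearson_r") {
        map_correlation(products[[i]], products[[j]])
      } else {
        percent_overlap(products[[i]], products[[j]],
                        convention = convention)
      }
    }
  }
  structure(m, statistic = statistic, convention = convention,
            class = c("comparison_matrix", "matrix"))
}

#' Rank species as connectivity proxies
#'
#' For each label, averages its pairwise statistic against all
#' single-species labels (the stacked multi-species label, if present, is
#' ranked itself but never counted among the averaging targets, and self-
#' comparisons are excluded). Labels are sorted by descending mean; exact
#' ties are broken alphabetically and flagged.
#'
#' @param m a `comparison_matrix` (or plain named square matrix).
#' @param stacked_label label of the stacked map (default `"stacked"`).
#' @return data frame with columns `label`, `mean_value`, `rank`, `tied`.
#' @export
proxy_ranking <- function(m, stacked_label = "stacked") {
  labels <- rownames(m)
  if (length(labels) < 3) stop("need at least three labels to rank")
  singles <- setdiff(labels, stacked_label)
  means <- vapply(labels, function(lb) {
    targets <- setdiff(singles, lb)
    mean(m[lb, targets])
  }, numeric(1))
  ord <- order(-means, labels)
  out <- data.frame(label = labels[ord], mean_value = unname(means[ord]),
                    rank = seq_along(ord),
                    tied = duplicated(means[ord]) |
                      duplicated(means[ord], fromLast = TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Write a comparison matrix as labelled CSV
#'
#' Rows and columns are labelled; the statistic (and overlap convention)
#' are recorded in `#`-prefixed header comments.
#'
#' @param m a `comparison_matrix`.
#' @param path CSV file path.
#' @param scaling optional scaling tag recorded in the header.
#' @export
write_comparison_csv <- function(m, path, scaling = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# statistic: %s", attr(m, "statistic")), con)
  if (!is.null(attr(m, "convention"))) {
    writeLines(sprintf("# convention: %s", attr(m, "convention")), con)
  }
  if (!is.null(scaling)) writeLines(sprintf("# scaling: %s", scaling), con)
  utils::write.csv(as.data.frame(unclass(m)), con, row.names = TRUE)
  invisible(path)
}
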
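#' Jaccard burst coincidence between two trains
#'
#' Intersection-over-union of two binary burst time courses:
#' `sum(a & b) / sum(a | b)`.  1 means perfect coincidence, 0 none.  If
#' the union is empty (neither region ever bursts) the value is 0 with
#' attribute `union_empty = TRUE` so group averaging stays well defined.
#'
#' @param a,b `burst_train` objects (or 0/1 vectors) on the same time
#'   base.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  av <- if (inherits(a, "burst_train")) a$b else as.integer(a != 0)
  bv <- if (inherits(b, "burst_train")) b$b else as.integer(b != 0)
  if (length(av) != length(bv)) stop("trains have different lengths")
  uni <- sum(av | bv)
  if (uni == 0) return(structure(0, union_empty = TRUE))
  sum(av & bv) / uni
}

#' Burst-coincidence connectome
#'
#' Computes the Jaccard coincidence for every unordered pair of regions.
#' The diagonal is fixed at 0 by convention (self-connections are
#' meaningless).
#'
#' @param trains list of aligned `burst_train` objects (one per region).
#' @return object of class `connectome`: list with `J` (R x R symmetric
#'   matrix), `labels`, `union_empty_mask` (logical R x R, pairs with an
#'   empty union).
#' @export
burst_connectome <- function(trains) {
  R <- length(trains)
  if (R < 2) stop("need at least two trains")
  lens <- vapply(trains, function(t) length(t$b), 0L)
  if (length(unique(lens)) != 1) stop("trains have inconsistent lengths")
  B <- do.call(rbind, lapply(trains, `[[`, "b"))
  labels <- vapply(trains, `[[`, "", "region_id")
  inter <- B %*% t(B)
  counts <- diag(inter)
  uni <- outer(counts, counts, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  mask <- uni == 0
  diag(J) <- 0; diag(mask) <- FALSE
  dimnames(J) <- list(labels, labels)
  structure(list(J = J, labels = labels, union_empty_mask = mask),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  R <- length(x$labels)
  cat(sprintf("<connectome> %d regions, %d unique connections, mean J = %.4f\n",
              R, R * (R - 1) / 2, global_mean_connectivity(x)))
  invisible(x)
}

#' Unique connection values of a connectome
#'
#' @param c a `connectome` (or symmetric matrix).
#' @return data frame with `region_a`, `region_b`, `value` for all
#'   unordered off-diagonal pairs (lexicographic order).
#' @export
connection_table <- function(c) {
  J <- if (inherits(c, "connectome")) c$J else c
  labels <- if (inherits(c, "connectome")) c$labels else
    rownames(J) %||% sprintf("R%02d", seq_len(nrow(J)))
  ut <- which(upper.tri(J), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  data.frame(region_a = labels[ut[, 1]], region_b = labels[ut[, 2]],
             value = J[ut], stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strongest fraction of connections
#'
#' Returns the `floor(fraction * n_edges)` connections with the largest
#' values; ties at the cut are broken deterministically by lexicographic
#' label order.
#'
#' @param c a `connectome` or symmetric numeric matrix (e.g. a group
#'   difference matrix).
#' @param fraction fraction of edges to keep, in (0, 1].
#' @return data frame `region_a`, `region_b`, `value`, `rank`.
#' @export
top_fraction <- function(c, fraction) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  tab <- connection_table(c)
  if (nrow(tab) == 0) stop("empty connectivity matrix")
  ord <- order(-tab$value, tab$region_a, tab$region_b)
  n_keep <- floor(fraction * nrow(tab))
  out <- tab[ord[seq_len(n_keep)], , drop = FALSE]
  out$rank <- seq_len(n_keep)
  rownames(out) <- NULL
  out
}

#' Global mean connectivity
#'
#' Mean over all unique off-diagonal connections (the sum of the matrix
#' elements divided by the number of connections).
#'
#' @param c a `connectome` or symmetric matrix.
#' @return scalar.
#' @export
global_mean_connectivity <- function(c) {
  J <- if (inherits(c, "connectome")) c$J else c
  mean(J[upper.tri(J)])
}

#' Fraction of interhemispheric connections in an edge list
#'
#' Hemisphere is parsed from a trailing `_L`/`_R` (or `.L`/`.R`) label
#' suffix; edges whose endpoints are in different hemispheres count as
#' interhemispheric.  Labels without a recognised suffix yield `NA` and
#' are dropped from the fraction.
#'
#' @param edges data frame with `region_a`, `region_b`.
#' @return fraction in `[0, 1]`.
#' @export
interhemispheric_fraction <- function(edges) {
  hemi <- function(lab) {
    has <- grepl("[._][LR]$", lab)
    out <- rep(NA_character_, length(lab))
    out[has] <- sub(".*[._]([LR])$", "\\1", lab[has])
    out
  }
  ha <- hemi(edges$region_a); hb <- hemi(edges$region_b)
  ok <- !is.na(ha) & !is.na(hb)
  if (!any(ok)) return(NA_real_)
  mean(ha[ok] != hb[ok])
}
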
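# Ensemble comparison of models by element presence/absence: Hamming
# distances with directed decomposition, per-model average distances,
# heterogeneity degrees and core/unique statistics.

#' Binary presence matrix over an ensemble of element sets
#'
#' @param sets List of `element_sets` (from [element_sets()]) or plain
#'   lists carrying `model_id` and the relevant id vector.
#' @param element_class `"reaction"`, `"metabolite"` or `"gene"`.
#' @return 0/1 matrix, models x union of element ids.
#' @export
presence_matrix <- function(sets, element_class = c("reaction", "metabolite",
                                                    "gene")) {
  element_class <- match.arg(element_class)
  stopifnot(length(sets) >= 2)
  field <- paste0(element_class, "_ids")
  ids <- vapply(sets, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) {
    stop("duplicate model ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  elems <- sort(unique(unlist(lapply(sets, `[[`, field))))
  M <- matrix(0L, length(sets), length(elems), dimnames = list(ids, elems))
  for (i in seq_along(sets)) M[i, sets[[i]][[field]]] <- 1L
  M
}

#' Pairwise Hamming distances with directed decomposition
#'
#' The total distance between models A and B is the size of the symmetric
#' difference of their element sets — the number of element changes needed
#' to transform one model into the other. It decomposes into the directed
#' counts |A \\ B| (removals going A to B) and |B \\ A| (additions).
#'
#' @param matrix A presence matrix from [presence_matrix()].
#' @return A `distance_report`: `pairs` (data frame `model_a`, `model_b`,
#'   `a_minus_b`, `b_minus_a`, `total`) and `average` (named vector of each
#'   model's mean distance to all others).
#' @export
pairwise_distances <- function(matrix) {
  ids <- rownames(matrix)
  n <- length(ids)
  rows <- list()
  totals <- base::matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a_only <- sum(matrix[i, ] == 1L & matrix[j, ] == 0L)
      b_only <- sum(matrix[j, ] == 1L & matrix[i, ] == 0L)
      rows[[length(rows) + 1]] <- data.frame(
        model_a = ids[i], model_b = ids[j],
        a_minus_b = a_only, b_minus_a = b_only, total = a_only + b_only,
        stringsAsFactors = FALSE)
      totals[i, j] <- totals[j, i] <- a_only + b_only
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  average <- rowSums(totals) / (n - 1)
  structure(list(pairs = pairs, average = average, totals = totals),
            class = "distance_report")
}

#' Ensemble heterogeneity degree
#'
#' Mean over maximum pairwise Hamming distance: a dimensionless divergence
#' in \[0, 1\] that is 0 for identical models and 1 when all pairs are
#' equally distant (and by convention 0 when the maximum is 0).
#'
#' @param matrix A presence matrix.
#' @return List `mean_distance`, `max_distance`, `heterogeneity_degree`.
#' @export
heterogeneity <- function(matrix) {
  d <- pairwise_distances(matrix)$pairs$total
  mx <- max(d)
  list(mean_distance = mean(d), max_distance = mx,
       heterogeneity_degree = if (mx == 0) 0 else mean(d) / mx)
}

#' Core and unique element statistics
#'
#' @param matrix A presence matrix.
#' @return List `union_count`, `core_count` (elements in every model),
#'   `unique_count` (elements in exactly one), `core_percentage`
#'   (100 x core/union, one decimal).
#' @export
core_statistics <- function(matrix) {
  cs <- colSums(matrix)
  n <- nrow(matrix)
  union_count <- sum(cs >= 1L)
  core <- sum(cs == n)
  unique_count <- sum(cs == 1L)
  list(union_count = union_count, core_count = core,
       unique_count = unique_count,
       core_percentage = round(100 * core / union_count, 1))
}

#' Full ensemble comparison report
#'
#' Runs [pairwise_distances()], [heterogeneity()] and [core_statistics()]
#' for each element class present in the supplied sets.
#'
#' @param sets List of `element_sets` (>= 2).
#' @return Named list per element class with `distances`, `heterogeneity`,
#'   `core`.
#' @export
compare_ensemble <- function(sets) {
  out <- list()
  for (cl in c("reaction", "metabolite", "gene")) {
    field <- paste0(cl, "_ids")
    if (!any(vapply(sets, function(s) length(s[[field]]) > 0, logical(1)))) next
    M <- presence_matrix(sets, cl)
    out[[cl]] <- list(distances = pairwise_distances(M),
                      heterogeneity = heterogeneity(M),
                      core = core_statistics(M))
  }
  out
}
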
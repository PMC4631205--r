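# Gene-level statistics on the metabolic network (reporter metabolites with
# a greedy subnetwork expansion) and the two-group metabolite comparison
# statistics used for validation (Welch's t-test, Benjamini-Hochberg FDR).

P_CLAMP <- 1e-15

#' Reporter-metabolite scoring
#'
#' Aggregates gene-level p-values onto metabolites through the network
#' topology: the neighbour genes of a metabolite are the genes in the GPR
#' of any reaction that consumes or produces it. Each gene's p-value is
#' transformed to a standard-normal score z = qnorm(1 - p); a metabolite
#' with k scored neighbours gets z_raw = sum(z)/sqrt(k), corrected against
#' a background of random size-k gene draws: z_corrected =
#' (z_raw - mu_k)/sigma_k, with p_reporter = 1 - pnorm(z_corrected).
#' Metabolites with no scored neighbour gene are omitted.
#'
#' @param model A `metabolic_model`.
#' @param gene_pvalues Named numeric vector, gene id -> p-value; values are
#'   clamped into \[1e-15, 1 - 1e-15\] before the quantile transform.
#' @param n_background Random draws per distinct neighbourhood size
#'   (default 10000).
#' @param seed Integer seed for the background draws.
#' @return Data frame `metabolite`, `k`, `z_raw`, `z_corrected`,
#'   `p_reporter`, ordered by increasing `p_reporter`.
#' @export
reporter_metabolites <- function(model, gene_pvalues, n_background = 10000,
                                 seed = 1) {
  genes_in_model <- model_genes(model)
  scored <- intersect(names(gene_pvalues), genes_in_model)
  if (!length(scored)) stop("no overlap between scored genes and model genes")
  p <- pmin(pmax(gene_pvalues[scored], P_CLAMP), 1 - P_CLAMP)
  z <- stats::qnorm(1 - p)
  # metabolite -> neighbour genes via the reaction bipartite structure
  neighbours <- lapply(model$metabolites$id, function(mid) {
    touching <- model$reactions$id[vapply(model$stoichiometry, function(st)
      mid %in% names(st), logical(1))]
    gg <- unique(unlist(lapply(touching, function(rid)
      gpr_genes(model$reactions$gpr[match(rid, model$reactions$id)]))))
    intersect(gg, scored)
  })
  names(neighbours) <- model$metabolites$id
  ks <- lengths(neighbours)
  keep <- ks >= 1
  if (!any(keep)) stop("no metabolite has scored neighbour genes")
  rng <- local_rng(seed)
  bg <- list()
  for (k in sort(unique(ks[keep]))) {
    draws <- vapply(seq_len(n_background), function(i) {
      sum(z[rng$sample(length(z), k, replace = length(z) < k)]) / sqrt(k)
    }, numeric(1))
    bg[[as.character(k)]] <- c(mu = mean(draws), sigma = stats::sd(draws))
  }
  mets <- model$metabolites$id[keep]
  z_raw <- vapply(mets, function(m) sum(z[neighbours[[m]]]) /
                    sqrt(length(neighbours[[m]])), numeric(1))
  z_corr <- vapply(seq_along(mets), function(i) {
    b <- bg[[as.character(ks[keep][i])]]
    if (b[["sigma"]] < 1e-12) return(0)
    (z_raw[i] - b[["mu"]]) / b[["sigma"]]
  }, numeric(1))
  out <- data.frame(metabolite = mets, k = as.integer(ks[keep]),
                    z_raw = unname(z_raw), z_corrected = z_corr,
                    p_reporter = 1 - stats::pnorm(z_corr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_reporter, out$metabolite), ]
  rownames(out) <- NULL
  out
}

#' Greedy reporter subnetwork expansion
#'
#' Starting from the best-scoring metabolite, repeatedly adds the adjacent
#' metabolite (sharing a reaction with the current set) that maximises the
#' mean corrected score of the set, stopping at `size_limit` or when no
#' addition improves the mean. Ties are broken lexicographically by
#' metabolite id.
#'
#' @param model A `metabolic_model`.
#' @param reporter_scores Output of [reporter_metabolites()].
#' @param size_limit Maximum number of metabolites in the subnetwork.
#' @return List `metabolites`, `reactions` (all reactions touching the
#'   selected metabolites), `mean_z`.
#' @export
greedy_reporter_subnetwork <- function(model, reporter_scores, size_limit = 5) {
  sc <- stats::setNames(reporter_scores$z_corrected, reporter_scores$metabolite)
  mets_of <- function(rid) names(model$stoichiometry[[rid]])
  rxns_of <- function(mid) model$reactions$id[vapply(
    model$stoichiometry, function(st) mid %in% names(st), logical(1))]
  start <- names(sc)[order(-sc, names(sc))][1]
  current <- start
  repeat {
    if (length(current) >= size_limit) break
    frontier <- setdiff(
      unique(unlist(lapply(unique(unlist(lapply(current, rxns_of))), mets_of))),
      current)
    frontier <- intersect(frontier, names(sc))
    if (!length(frontier)) break
    gains <- vapply(frontier, function(m) mean(sc[c(current, m)]), numeric(1))
    best <- frontier[order(-gains, frontier)][1]
    # additions that keep the mean level are accepted so plateaus of
    # equally scored metabolites are traversed; only a strict drop stops
    if (gains[[best]] < mean(sc[current]) - 1e-9) break
    current <- c(current, best)
  }
  structure(list(metabolites = sort(current),
                 reactions = sort(unique(unlist(lapply(current, rxns_of)))),
                 mean_z = mean(sc[current])), class = "reporter_subnetwork")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (delegates to [stats::t.test()]).
#' When both groups are constant: equal means give p = 1; unequal means
#' are degenerate and raise an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) < 1e-300 && stats::var(group_b) < 1e-300) {
    if (abs(mean(group_a) - mean(group_b)) < 1e-12) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1, mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop("both groups constant with unequal means: t statistic undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Benjamini-Hochberg adjusted Q-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of Q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group comparison table for a metabolite panel
#'
#' Applies [welch_test()] per analyte of a long measurement table and
#' adjusts the p-values with [bh_fdr()].
#'
#' @param measurements Data frame `analyte`, `group` (exactly two levels),
#'   `value`.
#' @param log_transform Log-transform values first (the convention for
#'   metabolomics intensity data; default `TRUE`).
#' @return Data frame `analyte`, `mean_a`, `mean_b`, `t`, `df`, `p_value`,
#'   `q_value`.
#' @export
compare_groups <- function(measurements, log_transform = TRUE) {
  groups <- sort(unique(measurements$group))
  if (length(groups) != 2) stop("expected exactly two groups, got ",
                                length(groups))
  if (log_transform) measurements$value <- log(measurements$value)
  analytes <- unique(measurements$analyte)
  rows <- lapply(analytes, function(a) {
    d <- measurements[measurements$analyte == a, ]
    w <- welch_test(d$value[d$group == groups[1]],
                    d$value[d$group == groups[2]])
    data.frame(analyte = a, mean_a = w$mean_a, mean_b = w$mean_b,
               t = w$t, df = w$df, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Merge per-segment differential-expression tables
#'
#' Integrates DE tables from several tissue segments (e.g. duodenum,
#' jejunum, ileum): each gene keeps the entry with the lowest Q-value and
#' its fold change, except genes significantly changed (Q below
#' `q_threshold`) in opposite directions across segments, which are
#' excluded entirely.
#'
#' @param tables List of DE data frames (`gene_id`, `log2fc`, `q_value`).
#' @param q_threshold Significance cutoff for the conflict rule.
#' @return Merged DE data frame; attribute `dropped` lists the conflicting
#'   genes.
#' @export
merge_segment_de <- function(tables, q_threshold = 0.05) {
  stopifnot(length(tables) >= 1)
  all_de <- do.call(rbind, tables)
  sig <- all_de[all_de$q_value < q_threshold, ]
  dir <- ifelse(sig$log2fc > 0, "up", "down")
  ndir <- tapply(dir, sig$gene_id, function(d) length(unique(d)))
  conflicted <- names(ndir)[ndir > 1]
  keep <- all_de[!all_de$gene_id %in% conflicted, ]
  keep <- keep[order(keep$gene_id, keep$q_value), ]
  out <- keep[!duplicated(keep$gene_id), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- conflicted
  out
}
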
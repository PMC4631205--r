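# Seeded generators for every input class the pipeline consumes: toy
# flux-consistent GEMs with analytically known optima, differential-expression
# tables with controlled up/down fractions, log-normal two-group metabolomics,
# and a cross-feeding species pair with a four-class diet. All generators are
# pure functions of their arguments and seed.

#' Generate a toy genome-scale model
#'
#' Templates (all flux-consistent, with the analytic FBA optimum recorded in
#' `metadata$optimum`):
#' \describe{
#'   \item{chain}{uptake -> conversion -> sink; optimum = `uptake`.}
#'   \item{diamond}{two parallel routes of unequal length (2 vs 3 reactions)
#'     from substrate to product; optimum = `uptake`, the branch split is
#'     degenerate and parsimonious FBA picks the short route.}
#'   \item{futile_cycle}{chain plus a two-reaction cycle that can carry flux
#'     without touching the objective; parsimonious FBA zeroes it.}
#'   \item{epithelium}{small-intestine enterocyte caricature: diet uptakes
#'     (glucose, fat, and the amino acids glycine, cysteine, glutamate),
#'     a glutathione synthesis chain, and lipoprotein assembly secreting
#'     chylomicrons (primary product) and HDL, with GPR rules on the lipid
#'     assembly steps so expression integration has something to act on.}
#' }
#'
#' @param template One of `"chain"`, `"diamond"`, `"futile_cycle"`,
#'   `"epithelium"`.
#' @param uptake Maximum substrate uptake (mmol/gDW/h) for the simple
#'   templates.
#' @return A `metabolic_model`.
#' @export
make_toy_gem <- function(template = c("chain", "diamond", "futile_cycle",
                                      "epithelium"),
                         uptake = 10) {
  template <- match.arg(template)
  switch(template,
         chain = toy_chain(uptake),
         diamond = toy_diamond(uptake),
         futile_cycle = toy_futile(uptake),
         epithelium = toy_epithelium())
}

toy_from_rows <- function(id, rows, objective, optimum, gprs = NULL) {
  stoich <- list(); mets <- character()
  for (r in rows) {
    eq <- parse_equation(r$eq)
    stoich[[r$id]] <- eq$stoich
    mets <- union(mets, names(eq$stoich))
  }
  rxns <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    lb = vapply(rows, `[[`, numeric(1), "lb"),
    ub = vapply(rows, `[[`, numeric(1), "ub"),
    stringsAsFactors = FALSE)
  rxns$gpr <- if (is.null(gprs)) "" else
    unname(gprs[rxns$id]) |> (\(g) ifelse(is.na(g), "", g))()
  make_model(id, metabolites = data.frame(
    id = mets, name = vapply(mets, met_name, character(1)),
    compartment = vapply(mets, met_compartment, character(1)),
    stringsAsFactors = FALSE),
    reactions = rxns, stoichiometry = stoich, objective = objective,
    metadata = list(template = id, optimum = optimum))
}

toy_chain <- function(uptake) {
  toy_from_rows("chain", list(
    list(id = "EX_A", eq = "A[e] =>", lb = -uptake, ub = 0),
    list(id = "R_conv", eq = "A[e] => B[c]", lb = 0, ub = 1000),
    list(id = "EX_B", eq = "B[c] =>", lb = 0, ub = 1000)
  ), objective = "EX_B", optimum = uptake)
}

toy_diamond <- function(uptake) {
  # short route A->B->P (2 steps incl. join), long route A->C->D->P
  toy_from_rows("diamond", list(
    list(id = "EX_A", eq = "A[e] =>", lb = -uptake, ub = 0),
    list(id = "R_short", eq = "A[e] => P[c]", lb = 0, ub = 1000),
    list(id = "R_long1", eq = "A[e] => C[c]", lb = 0, ub = 1000),
    list(id = "R_long2", eq = "C[c] => P[c]", lb = 0, ub = 1000),
    list(id = "EX_P", eq = "P[c] =>", lb = 0, ub = 1000)
  ), objective = "EX_P", optimum = uptake)
}

toy_futile <- function(uptake) {
  toy_from_rows("futile_cycle", list(
    list(id = "EX_A", eq = "A[e] =>", lb = -uptake, ub = 0),
    list(id = "R_conv", eq = "A[e] => B[c]", lb = 0, ub = 1000),
    list(id = "R_cyc1", eq = "B[c] => C[c]", lb = 0, ub = 1000),
    list(id = "R_cyc2", eq = "C[c] => B[c]", lb = 0, ub = 1000),
    list(id = "EX_B", eq = "B[c] =>", lb = 0, ub = 1000)
  ), objective = "EX_B", optimum = uptake)
}

# Enterocyte caricature. Chylomicron assembly needs fat-derived lipid plus a
# glucose-derived precursor; HDL needs the same lipid at lower stoichiometry.
# Luminal uptakes are forced into narrow windows (the epithelium absorbs
# what the lumen delivers), so internal fluxes are tightly determined and
# bound scaling shifts them measurably. With glucose uptake G in [9, 10]
# and fat-derived lipid L in [4.5, 5], chylomicron flux is 2L - G, whose
# maximum is 2*5 - 9 = 1.
toy_epithelium <- function() {
  # every step carries genes, transporters included, so relative-expression
  # integration can act on the whole absorption-to-secretion route
  gprs <- c(EX_glc = "g_sglt1", EX_fat = "g_cd36", EX_gly = "g_slc6a9",
            EX_cys = "g_slc7a11", EX_glu = "g_slc1a1",
            R_glyc = "g_glyc", R_lipid = "g_fabp and g_mttp",
            R_chylo = "g_apob and (g_mttp or g_mttp2)",
            R_hdl = "g_apoa1", R_gsh = "g_gclc and g_gss",
            R_aa_pool = "g_slc", EX_gsh = "g_mrp2",
            EX_chylo = "g_sar1b", EX_hdl = "g_abca1")
  toy_from_rows("epithelium", list(
    list(id = "EX_glc", eq = "glc[e] =>", lb = -10, ub = -9),
    list(id = "EX_fat", eq = "fat[e] =>", lb = -5, ub = -4.5),
    list(id = "EX_gly", eq = "gly[e] =>", lb = -2, ub = -1.8),
    list(id = "EX_cys", eq = "cys[e] =>", lb = -2, ub = -1.8),
    list(id = "EX_glu", eq = "glu[e] =>", lb = -2, ub = -1.8),
    list(id = "R_glyc", eq = "glc[e] => prec[c]", lb = 0, ub = 1000),
    list(id = "R_lipid", eq = "fat[e] + prec[c] => lipid[c]", lb = 0, ub = 1000),
    list(id = "R_chylo", eq = "2 lipid[c] + prec[c] => chylo[c]", lb = 0, ub = 1000),
    list(id = "R_hdl", eq = "lipid[c] + prec[c] => hdl[c]", lb = 0, ub = 1000),
    list(id = "R_aa_pool", eq = "gly[e] + cys[e] + glu[e] => aa3[c]", lb = 0, ub = 1000),
    list(id = "R_gsh", eq = "aa3[c] => gsh[c]", lb = 0, ub = 1000),
    list(id = "EX_gsh", eq = "gsh[c] =>", lb = 0, ub = 1000),
    list(id = "EX_chylo", eq = "chylo[c] =>", lb = 0, ub = 1000),
    list(id = "EX_hdl", eq = "hdl[c] =>", lb = 0, ub = 1000)
  ), objective = "EX_chylo", optimum = 1, gprs = gprs)
}

#' Generate a differential-expression table mapped onto a model
#'
#' Assigns each model gene up, down or null status with the requested
#' fractions; significant genes get Q-values drawn below `q_signif`, null
#' genes above it. The true reaction direction labels implied by the
#' mapped-gene rule (up if all significant genes up, down if all down,
#' unchanged if mixed) are returned alongside for recovery tests.
#'
#' @param model A `metabolic_model` with GPR rules.
#' @param fraction_up,fraction_down Fractions of genes regulated in each
#'   direction (sum <= 1).
#' @param q_signif Significance threshold the Q-values straddle (default
#'   0.05).
#' @param n_extra_genes Off-model genes appended to emulate non-metabolic
#'   probes.
#' @param seed Integer seed.
#' @return List with `de` (data frame `gene_id`, `log2fc`, `q_value`) and
#'   `truth` (data frame `reaction`, `direction`).
#' @export
make_de_table <- function(model, fraction_up = 0.2, fraction_down = 0.2,
                          q_signif = 0.05, n_extra_genes = 0, seed = 1) {
  stopifnot(fraction_up + fraction_down <= 1)
  genes <- model_genes(model)
  if (!length(genes)) stop("model has no genes to perturb")
  rng <- local_rng(seed)
  n <- length(genes)
  n_up <- round(fraction_up * n); n_dn <- round(fraction_down * n)
  status <- rep("null", n)
  pick <- rng$sample(n, min(n, n_up + n_dn))
  status[pick[seq_len(n_up)]] <- "up"
  if (n_dn > 0) status[pick[n_up + seq_len(n_dn)]] <- "down"
  q <- ifelse(status == "null",
              q_signif + (1 - q_signif) * rng$runif(n),
              q_signif * rng$runif(n) * 0.9)
  lfc <- ifelse(status == "up", 1 + rng$runif(n),
                ifelse(status == "down", -1 - rng$runif(n),
                       0.2 * (rng$runif(n) - 0.5)))
  de <- data.frame(gene_id = genes, log2fc = lfc, q_value = q,
                   stringsAsFactors = FALSE)
  if (n_extra_genes > 0) {
    de <- rbind(de, data.frame(
      gene_id = sprintf("offmodel_%03d", seq_len(n_extra_genes)),
      log2fc = rng$runif(n_extra_genes, -2, 2),
      q_value = rng$runif(n_extra_genes), stringsAsFactors = FALSE))
  }
  sig <- stats::setNames(ifelse(q < q_signif, ifelse(lfc > 0, "up", "down"),
                                NA_character_)[seq_len(n)], genes)
  truth <- do.call(rbind, lapply(model$reactions$id, function(rid) {
    gg <- gpr_genes(model$reactions$gpr[match(rid, model$reactions$id)])
    dirs <- stats::na.omit(sig[gg])
    if (!length(dirs)) return(NULL)
    dir <- if (all(dirs == "up")) "up" else if (all(dirs == "down")) "down"
      else "unchanged"
    data.frame(reaction = rid, direction = dir, stringsAsFactors = FALSE)
  }))
  list(de = de, truth = truth)
}

#' Generate two-group log-normal metabolite measurements
#'
#' Emulates a portal-vein amino-acid panel: per analyte, both groups draw
#' log-normal values around a common base; analytes with a non-zero effect
#' have their second-group log-mean shifted by that many natural-log units.
#'
#' @param n_analytes Number of analytes.
#' @param n_per_group Samples per group (>= 3).
#' @param effect_sizes Numeric vector recycled over analytes, log-scale
#'   shifts of group B relative to group A; 0 = true null.
#' @param base_log_mean,noise_sd Location and scale of the log-normal.
#' @param seed Integer seed.
#' @return List with `data` (long data frame `analyte`, `group`, `value`)
#'   and `truth` (data frame `analyte`, `effect`).
#' @export
make_metabolomics <- function(n_analytes = 20, n_per_group = 6,
                              effect_sizes = 0, base_log_mean = 2,
                              noise_sd = 0.4, seed = 1) {
  stopifnot(n_per_group >= 3)
  rng <- local_rng(seed)
  effects <- rep_len(effect_sizes, n_analytes)
  analytes <- sprintf("analyte_%04d", seq_len(n_analytes))
  rows <- lapply(seq_len(n_analytes), function(i) {
    a <- exp(base_log_mean + rng$rnorm(n_per_group, 0, noise_sd))
    b <- exp(base_log_mean + effects[i] + rng$rnorm(n_per_group, 0, noise_sd))
    data.frame(analyte = analytes[i],
               group = rep(c("A", "B"), each = n_per_group),
               value = c(a, b), stringsAsFactors = FALSE)
  })
  list(data = do.call(rbind, rows),
       truth = data.frame(analyte = analytes, effect = effects,
                          stringsAsFactors = FALSE))
}

#' Generate a cross-feeding species pair and a four-class diet
#'
#' Producer: a glucose fermenter secreting acetate alongside biomass
#' (Bacteroides-like). Consumer: an acetate utiliser producing butyrate
#' (Eubacterium/Roseburia-like butyrogen); it grows only on acetate, so on a
#' sugar-only pool its growth is zero unless the producer feeds it. The diet
#' covers all four nutrient classes (protein with an amino-acid profile,
#' digestible and non-digestible carbohydrate, fat).
#'
#' @param glucose_uptake_cap Producer's maximum glucose uptake.
#' @return List with `producer` and `consumer` (each a `community_member`)
#'   and `diet` (a `diet_composition`).
#' @export
make_crossfeed_pair <- function(glucose_uptake_cap = 10) {
  producer <- toy_from_rows("producer", list(
    list(id = "EX_glc", eq = "glc[e] =>", lb = -glucose_uptake_cap, ub = 0),
    list(id = "EX_gly", eq = "gly[e] =>", lb = -1000, ub = 0),
    list(id = "R_ferm", eq = "glc[e] => 2 ac[e] + bio[c]", lb = 0, ub = 1000),
    list(id = "R_gly_bio", eq = "2 gly[e] => bio[c]", lb = 0, ub = 1000),
    list(id = "EX_ac", eq = "ac[e] =>", lb = -1000, ub = 1000),
    list(id = "EX_bio", eq = "bio[c] =>", lb = 0, ub = 1000)
  ), objective = "EX_bio", optimum = glucose_uptake_cap)
  consumer <- toy_from_rows("consumer", list(
    list(id = "EX_ac", eq = "ac[e] =>", lb = -1000, ub = 1000),
    list(id = "EX_gly", eq = "gly[e] =>", lb = -1000, ub = 0),
    list(id = "R_but", eq = "4 ac[e] => 2 but[e] + bio[c]", lb = 0, ub = 1000),
    list(id = "R_gly_bio", eq = "4 gly[e] => bio[c]", lb = 0, ub = 1000),
    list(id = "EX_but", eq = "but[e] =>", lb = 0, ub = 1000),
    list(id = "EX_bio", eq = "bio[c] =>", lb = 0, ub = 1000)
  ), objective = "EX_bio", optimum = 0)
  aa_profile <- data.frame(
    aa = c("gly", "ser", "thr", "leu"),
    weight_fraction = c(0.25, 0.25, 0.25, 0.25),
    molar_mass = c(0.075, 0.105, 0.119, 0.131),  # g/mmol
    stringsAsFactors = FALSE)
  diet <- diet_composition(data.frame(
    name = c("casein", "starch", "cellulose", "soy_oil"),
    class = c("protein", "digestible_carb", "non_digestible_carb", "fat"),
    grams_per_day = c(18, 36, 15, 6),
    molar_mass = c(NA, 0.18, 0.162, 0.88),
    stringsAsFactors = FALSE), aa_profile = aa_profile)
  list(
    producer = community_member(
      producer, biomass = "EX_bio",
      uptake_map = c(starch = "EX_glc", gly = "EX_gly"),
      scfa_map = c(acetate = "EX_ac")),
    consumer = community_member(
      consumer, biomass = "EX_bio",
      uptake_map = c(acetate = "EX_ac", gly = "EX_gly"),
      scfa_map = c(butyrate = "EX_but")),
    diet = diet)
}

# Self-contained RNG stream so generators never disturb (or depend on) the
# caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    f(...)
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample = with_state(base::sample))
}
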
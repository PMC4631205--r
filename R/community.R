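# Diet-partitioned two-member gut community simulation.
#
# The daily diet is split by nutrient class among bacteria, small-intestine
# host and colon; the bacterial pool then drives a round-robin scheme in
# which each member's uptake bounds are set from its allocated share, growth
# is maximised by FBA, fluxes fixed by parsimonious FBA, and secretions join
# the shared pool for later members and rounds. Amounts are mmol per
# simulated day for unit biomass; no dynamic biomass integration.

#' Construct a diet composition
#'
#' @param components Data frame with columns `name`,
#'   `class` (one of `protein`, `digestible_carb`, `non_digestible_carb`,
#'   `fat`), `grams_per_day`, `molar_mass` (g/mmol; may be `NA` for protein,
#'   which uses the amino-acid profile instead).
#' @param aa_profile Data frame `aa`, `weight_fraction`, `molar_mass`
#'   describing the amino-acid composition of dietary protein; fractions
#'   must sum to 1.
#' @return A `diet_composition` object.
#' @export
diet_composition <- function(components, aa_profile = NULL) {
  classes <- c("protein", "digestible_carb", "non_digestible_carb", "fat")
  bad <- setdiff(components$class, classes)
  if (length(bad)) stop("unknown nutrient classes: ", paste(bad, collapse = ", "))
  if (any(components$grams_per_day < 0)) stop("diet amounts must be >= 0")
  if (any(components$class == "protein")) {
    if (is.null(aa_profile)) stop("protein components require an aa_profile")
    if (abs(sum(aa_profile$weight_fraction) - 1) > 1e-6) {
      stop("amino-acid weight fractions must sum to 1")
    }
  }
  structure(list(components = components, aa_profile = aa_profile),
            class = "diet_composition")
}

#' Default diet partition fractions
#'
#' Per nutrient class, the fraction taken by bacteria and by the colon; the
#' small intestine receives the remainder. Defaults: bacteria take at most
#' 40% of protein and digestible carbohydrate and 5% of non-digestible
#' carbohydrate; 5% of protein and digestible carbohydrate passes to the
#' colon; fat is absorbed entirely by the small intestine.
#'
#' @param overrides Named list `class -> c(bacteria=, colon=)` replacing
#'   defaults.
#' @return A `partition_config`: data frame `class`, `bacteria`, `colon`,
#'   `small_intestine`.
#' @export
partition_config <- function(overrides = list()) {
  cfg <- data.frame(
    class = c("protein", "digestible_carb", "non_digestible_carb", "fat"),
    bacteria = c(0.40, 0.40, 0.05, 0),
    colon = c(0.05, 0.05, 0, 0),
    stringsAsFactors = FALSE)
  for (cl in names(overrides)) {
    i <- match(cl, cfg$class)
    if (is.na(i)) stop("unknown class in overrides: ", cl)
    ov <- overrides[[cl]]
    if ("bacteria" %in% names(ov)) cfg$bacteria[i] <- ov[["bacteria"]]
    if ("colon" %in% names(ov)) cfg$colon[i] <- ov[["colon"]]
  }
  if (any(cfg$bacteria + cfg$colon > 1 + 1e-9)) {
    stop("bacteria + colon fractions exceed 1 for some class")
  }
  cfg$small_intestine <- 1 - cfg$bacteria - cfg$colon
  structure(cfg, class = c("partition_config", "data.frame"))
}

#' Partition the diet among bacteria, small intestine and colon
#'
#' Splits each component's grams by its class fractions, expands protein
#' into amino acids via the weight profile, and converts grams to mmol via
#' the molar masses.
#'
#' @param diet A `diet_composition`.
#' @param config A `partition_config` (defaults used when omitted).
#' @return List of three named numeric vectors (`bacteria`,
#'   `small_intestine`, `colon`), metabolite name -> mmol/day, plus a
#'   `grams` attribute with the per-class gram split.
#' @export
partition_diet <- function(diet, config = partition_config()) {
  pools <- list(bacteria = numeric(), small_intestine = numeric(),
                colon = numeric())
  grams <- data.frame(class = config$class, bacteria = 0,
                      small_intestine = 0, colon = 0)
  add <- function(pool, met, mmol) {
    pool[met] <- (if (is.na(pool[met])) 0 else pool[met]) + mmol
    pool
  }
  for (i in seq_len(nrow(diet$components))) {
    comp <- diet$components[i, ]
    fr <- config[match(comp$class, config$class), ]
    gi <- match(comp$class, grams$class)
    for (consumer in c("bacteria", "small_intestine", "colon")) {
      g <- comp$grams_per_day * fr[[consumer]]
      grams[gi, consumer] <- grams[gi, consumer] + g
      if (g == 0) next
      if (comp$class == "protein") {
        prof <- diet$aa_profile
        for (j in seq_len(nrow(prof))) {
          pools[[consumer]] <- add(pools[[consumer]], prof$aa[j],
                                   g * prof$weight_fraction[j] / prof$molar_mass[j])
        }
      } else {
        if (is.na(comp$molar_mass)) {
          stop("component '", comp$name, "' has no molar mass")
        }
        pools[[consumer]] <- add(pools[[consumer]], comp$name,
                                 g / comp$molar_mass)
      }
    }
  }
  attr(pools, "grams") <- grams
  pools
}

#' Construct a community member
#'
#' @param model The member's `metabolic_model`.
#' @param biomass Reaction id whose flux is the member's growth.
#' @param uptake_map Named character vector, pool metabolite name ->
#'   exchange reaction id the member uses to take it up. The magnitude of
#'   the model's own exchange lower bound acts as the member's uptake
#'   capacity.
#' @param scfa_map Named character vector, product name (e.g. `acetate`,
#'   `butyrate`) -> secretion exchange id.
#' @return A `community_member`.
#' @export
community_member <- function(model, biomass, uptake_map, scfa_map = character()) {
  ids <- model$reactions$id
  missing_r <- setdiff(c(biomass, unname(uptake_map), unname(scfa_map)), ids)
  if (length(missing_r)) {
    stop("member '", model$id, "' lacks reactions: ",
         paste(missing_r, collapse = ", "))
  }
  structure(list(model = model, biomass = biomass, uptake_map = uptake_map,
                 scfa_map = scfa_map), class = "community_member")
}

# Maximum uptake the member could exert on `met` if offered `avail` mmol,
# with every other mapped exchange offered its own availability.
probe_demand <- function(member, met, avail, offers) {
  model <- member$model
  ex <- member$uptake_map[[met]]
  caps <- -model$reactions$lb[match(member$uptake_map, model$reactions$id)]
  names(caps) <- names(member$uptake_map)
  for (m2 in names(member$uptake_map)) {
    off <- if (m2 == met) avail else if (!is.na(offers[m2])) offers[m2] else 0
    model <- set_bounds(model, member$uptake_map[[m2]],
                        lb = -min(off, caps[[m2]]))
  }
  rng <- fva(model, ex)
  max(0, -rng$ranges$min)
}

#' Simulate a cross-feeding community on a shared nutrient pool
#'
#' Round-robin scheme: at the start of each round every member's demand for
#' each pool metabolite is probed (FVA maximum uptake with the full pool on
#' offer); contested metabolites are allocated proportionally to demand.
#' Each member then maximises its biomass by FBA with uptake bounds set to
#' its allocation, fluxes are fixed by parsimonious FBA, and its secretions
#' are added to the pool available in the next round. Iteration stops when
#' every growth value changes by less than `tolerance` between rounds.
#'
#' @param members List of `community_member`s; the round-robin order is the
#'   list order.
#' @param pool Named numeric vector, metabolite name -> mmol available to
#'   the community (the bacterial share from [partition_diet()]).
#' @param tolerance Convergence tolerance on growth values.
#' @param max_rounds Round cap; non-convergence is flagged, not an error.
#' @return A `community_result`: per-member `growth`, `uptake`, `secretion`;
#'   a `ledger` data frame per shared metabolite (`allocated`, `consumed`,
#'   `cross_fed`, `residual`); `rounds`; `converged`; `growth_trace`.
#' @export
simulate_community <- function(members, pool, tolerance = 1e-6,
                               max_rounds = 20) {
  stopifnot(length(members) >= 1)
  names(members) <- vapply(members, function(m) m$model$id, character(1))
  if (anyDuplicated(names(members))) stop("duplicate member model ids")
  pool <- pool[pool > 0]
  # close every unmapped uptake so nothing enters from outside the ledger
  members <- lapply(members, function(mb) {
    ex <- exchange_reactions(mb$model)
    free <- setdiff(ex[mb$model$reactions$lb[match(ex, mb$model$reactions$id)] < 0],
                    unname(mb$uptake_map))
    if (length(free)) mb$model <- set_bounds(mb$model, free, lb = 0)
    mb
  })
  growth_prev <- rep(0, length(members))
  trace <- list()
  secreted_prev <- numeric()   # pool gains from previous round
  result <- NULL
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    offer <- pool
    for (m in names(secreted_prev)) {
      offer[m] <- (if (is.na(offer[m])) 0 else offer[m]) + secreted_prev[m]
    }
    offer <- offer[offer > 1e-12]
    # simultaneous proportional allocation by probed demand
    demand <- matrix(0, length(members), length(offer),
                     dimnames = list(names(members), names(offer)))
    for (i in seq_along(members)) {
      mb <- members[[i]]
      for (met in intersect(names(offer), names(mb$uptake_map))) {
        demand[i, met] <- probe_demand(mb, met, offer[[met]], offer)
      }
    }
    alloc <- demand
    for (met in colnames(demand)) {
      tot <- sum(demand[, met])
      if (tot > offer[[met]] && tot > 0) {
        alloc[, met] <- offer[[met]] * demand[, met] / tot
      }
    }
    growth <- numeric(length(members))
    uptakes <- secretions <- vector("list", length(members))
    secreted_now <- numeric()
    for (i in seq_along(members)) {
      mb <- members[[i]]
      model <- mb$model
      caps <- -model$reactions$lb[match(mb$uptake_map, model$reactions$id)]
      names(caps) <- names(mb$uptake_map)
      for (met in names(mb$uptake_map)) {
        a <- if (met %in% colnames(alloc)) alloc[i, met] else 0
        model <- set_bounds(model, mb$uptake_map[[met]],
                            lb = -min(a, caps[[met]]))
      }
      sol <- pfba(model, objective = mb$biomass, sense = "max")
      if (sol$status != "optimal") {
        growth[i] <- 0
        uptakes[[i]] <- stats::setNames(numeric(length(mb$uptake_map)),
                                        names(mb$uptake_map))
        secretions[[i]] <- numeric()
        next
      }
      growth[i] <- sol$objective_value
      up <- vapply(names(mb$uptake_map), function(met) {
        max(0, -sol$fluxes[[mb$uptake_map[[met]]]])
      }, numeric(1))
      uptakes[[i]] <- up
      ex <- exchange_reactions(model)
      sec <- sol$fluxes[ex]
      sec <- sec[sec > 1e-9]
      # secretion names: invert the uptake/scfa maps where possible
      inv <- c(stats::setNames(names(mb$uptake_map), mb$uptake_map),
               stats::setNames(names(mb$scfa_map), mb$scfa_map))
      nm <- ifelse(names(sec) %in% names(inv), inv[names(sec)], names(sec))
      sec <- stats::setNames(as.numeric(sec), nm)
      sec <- sec[!nm %in% c("", NA) & !names(sec) %in% mb$biomass]
      sec <- sec[names(sec) != "bio"]
      secretions[[i]] <- sec
      for (m in names(sec)) {
        secreted_now[m] <- (if (is.na(secreted_now[m])) 0 else secreted_now[m]) + sec[[m]]
      }
    }
    trace[[round]] <- growth
    delta <- max(abs(growth - growth_prev))
    result <- list(round = round, offer = offer, alloc = alloc,
                   growth = growth, uptakes = uptakes,
                   secretions = secretions, secreted = secreted_now)
    if (delta < tolerance) { converged <- TRUE; break }
    growth_prev <- growth
    secreted_prev <- secreted_now
  }
  # ledger over all metabolites seen in pool, allocations or secretions
  mets <- sort(unique(c(names(pool), colnames(result$alloc),
                        names(result$secreted))))
  base <- vapply(mets, function(m) if (!is.na(pool[m])) pool[[m]] else 0,
                 numeric(1))
  allocated <- vapply(mets, function(m)
    if (m %in% colnames(result$alloc)) sum(result$alloc[, m]) else 0, numeric(1))
  consumed <- vapply(mets, function(m) {
    sum(vapply(seq_along(members), function(i) {
      u <- result$uptakes[[i]]
      if (!is.na(u[m])) u[[m]] else 0
    }, numeric(1)))
  }, numeric(1))
  cross_fed <- vapply(mets, function(m)
    if (!is.na(result$secreted[m])) result$secreted[[m]] else 0, numeric(1))
  ledger <- data.frame(metabolite = mets, pool = base, allocated = allocated,
                       consumed = consumed, cross_fed = cross_fed,
                       residual = base + cross_fed - consumed,
                       stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  structure(list(
    members = names(members),
    growth = stats::setNames(result$growth, names(members)),
    uptake = stats::setNames(result$uptakes, names(members)),
    secretion = stats::setNames(result$secretions, names(members)),
    ledger = ledger, rounds = result$round, converged = converged,
    growth_trace = trace), class = "community_result")
}

#' Per-member amino-acid consumption report
#'
#' @param result A `community_result`.
#' @param amino_acid_ids Pool metabolite names to report.
#' @return Data frame `amino_acid`, one consumption column per member,
#'   `total_consumed`, `residual`, `exhausted` (residual below 1e-6 of a
#'   positive pool).
#' @export
consumption_report <- function(result, amino_acid_ids) {
  unknown <- setdiff(amino_acid_ids, result$ledger$metabolite)
  if (length(unknown)) {
    stop("not in the simulation ledger: ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(amino_acid = amino_acid_ids, stringsAsFactors = FALSE)
  for (m in result$members) {
    out[[m]] <- vapply(amino_acid_ids, function(aa) {
      u <- result$uptake[[m]]
      if (!is.na(u[aa])) u[[aa]] else 0
    }, numeric(1))
  }
  led <- result$ledger[match(amino_acid_ids, result$ledger$metabolite), ]
  out$total_consumed <- led$consumed
  out$residual <- led$residual
  out$exhausted <- led$pool > 0 & led$residual < 1e-6
  rownames(out) <- NULL
  out
}
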
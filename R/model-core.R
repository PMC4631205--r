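# Data model for small constraint-based metabolic models.
#
# A model is a plain list of data frames plus a stoichiometry list; everything
# downstream (LP engine, sampling, community simulation) consumes this one
# structure. Exchange reactions follow the community sign convention:
# negative flux = uptake, positive flux = secretion.

#' Construct a metabolic model
#'
#' Builds a validated `metabolic_model` object from its parts. Reaction
#' stoichiometries are named numeric vectors (metabolite id -> signed
#' coefficient, negative = consumed). Gene-protein-reaction (GPR) rules are
#' boolean expressions over gene ids with `and` (enzyme complex) and `or`
#' (isoenzymes), e.g. `"g1 and (g2 or g3)"`.
#'
#' @param id Model identifier.
#' @param metabolites Data frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`.
#' @param reactions Data frame with columns `id`, `lb`, `ub` and optionally
#'   `gpr`, `subsystem`.
#' @param stoichiometry Named list (one entry per reaction id) of named
#'   numeric vectors keyed by metabolite id.
#' @param objective Reaction id of the objective, or `NA` for none.
#' @param sense `"max"` or `"min"`.
#' @param metadata Free-form list (generators record known optima here).
#' @return An object of class `metabolic_model`.
#' @export
make_model <- function(id, metabolites, reactions, stoichiometry,
                       objective = NA_character_, sense = "max",
                       metadata = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula))
    metabolites$formula <- rep(NA_character_, nrow(metabolites))
  if (is.null(reactions$gpr)) reactions$gpr <- rep("", nrow(reactions))
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem))
    reactions$subsystem <- rep(NA_character_, nrow(reactions))
  m <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry[reactions$id],
    objective = list(reaction = objective, sense = sense),
    metadata = metadata
  ), class = "metabolic_model")
  problems <- validate_model(m, stop_on_error = FALSE)
  if (length(problems)) {
    stop("invalid model '", id, "':\n  ", paste(problems, collapse = "\n  "))
  }
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, `lb <= ub`, stoichiometry
#' keys resolving to declared metabolites, GPR genes well formed, and the
#' objective reaction existing when set. Returns the violations as a
#' character vector (empty when valid), or raises an error.
#'
#' @param model A `metabolic_model`.
#' @param stop_on_error Raise an error on the first report instead of
#'   returning it.
#' @return Invisibly, a character vector of violation messages.
#' @export
validate_model <- function(model, stop_on_error = TRUE) {
  p <- character()
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids)) {
    p <- c(p, paste("duplicate metabolite ids:",
                    paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn_ids)) {
    p <- c(p, paste("duplicate reaction ids:",
                    paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  bad_bounds <- rxn_ids[model$reactions$lb > model$reactions$ub]
  if (length(bad_bounds)) {
    p <- c(p, paste("lb > ub for reactions:", paste(bad_bounds, collapse = ", ")))
  }
  for (rid in rxn_ids) {
    st <- model$stoichiometry[[rid]]
    if (is.null(st)) {
      p <- c(p, paste("reaction", rid, "has no stoichiometry entry"))
      next
    }
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown)) {
      p <- c(p, paste0("reaction ", rid, " references undeclared metabolites: ",
                       paste(unknown, collapse = ", ")))
    }
  }
  obj <- model$objective$reaction
  if (!is.na(obj) && !obj %in% rxn_ids) {
    p <- c(p, paste("objective reaction", obj, "not in model"))
  }
  if (length(p) && stop_on_error) {
    stop("invalid model '", model$id, "':\n  ", paste(p, collapse = "\n  "))
  }
  invisible(p)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ",
      nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ",
      length(model_genes(x)), " genes; objective: ",
      if (is.na(x$objective$reaction)) "none" else
        paste(x$objective$sense, x$objective$reaction), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a model's GPR rules
#'
#' @param model A `metabolic_model`.
#' @return Character vector of unique gene ids (sorted).
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
}

#' Extract the gene ids from a GPR expression
#'
#' @param gpr GPR string, e.g. `"g1 and (g2 or g3)"`; `""` and `NA` give an
#'   empty result.
#' @return Character vector of gene ids.
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(gpr)) return(character())
  toks <- strsplit(gsub("[()]", " ", gpr), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Evaluate a GPR expression under a gene on/off assignment
#'
#' @param gpr GPR string.
#' @param active Named logical vector, gene id -> expressed. Genes absent
#'   from `active` count as off.
#' @return Logical scalar; `TRUE` for an empty GPR (spontaneous reaction).
#' @export
gpr_eval <- function(gpr, active) {
  if (is.na(gpr) || !nzchar(gpr)) return(TRUE)
  genes <- gpr_genes(gpr)
  expr <- gpr
  # longest-first so gene ids that prefix one another substitute correctly
  for (g in genes[order(-nchar(genes))]) {
    val <- if (!is.na(active[g]) && isTRUE(active[[g]])) "TRUE" else "FALSE"
    expr <- gsub(paste0("(?<![A-Za-z0-9_.])", g, "(?![A-Za-z0-9_.])"),
                 val, expr, perl = TRUE)
  }
  expr <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  isTRUE(eval(parse(text = expr)))
}

#' Element id sets of a model
#'
#' The reaction, metabolite and gene id sets, the representation used by all
#' ensemble comparisons.
#'
#' @param model A `metabolic_model`.
#' @return A list of class `element_sets` with `reaction_ids`,
#'   `metabolite_ids`, `gene_ids`.
#' @export
element_sets <- function(model) {
  structure(list(
    model_id = model$id,
    reaction_ids = sort(model$reactions$id),
    metabolite_ids = sort(model$metabolites$id),
    gene_ids = model_genes(model)
  ), class = "element_sets")
}

#' Identify exchange reactions
#'
#' An exchange reaction touches exactly one metabolite (a boundary
#' pseudo-reaction); negative flux is uptake, positive is secretion.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  keep <- vapply(model$stoichiometry, function(st) sum(st != 0) == 1L, logical(1))
  model$reactions$id[keep]
}

#' Dense stoichiometric matrix
#'
#' @param model A `metabolic_model`.
#' @return Numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    S[names(st), rid] <- st
  }
  S
}

#' Update reaction flux bounds
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to change.
#' @param lb,ub Replacement bounds, recycled to length; `NA` leaves a bound
#'   untouched.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_ids, lb = NA, ub = NA) {
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reactions: ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  }
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  keep <- !is.na(lb); model$reactions$lb[idx[keep]] <- lb[keep]
  keep <- !is.na(ub); model$reactions$ub[idx[keep]] <- ub[keep]
  bad <- model$reactions$lb[idx] > model$reactions$ub[idx]
  if (any(bad)) {
    stop("lb > ub after update for: ",
         paste(reaction_ids[bad], collapse = ", "))
  }
  model
}

#' Apply diet uptake limits
#'
#' Sets the lower bound of each named exchange reaction to `-max_uptake`
#' (uptake is negative flux); exchanges not named are left untouched.
#'
#' @param model A `metabolic_model`.
#' @param diet_bounds Named numeric vector, exchange reaction id ->
#'   maximum uptake (non-negative, mmol/gDW/h).
#' @return The constrained model.
#' @export
apply_diet_bounds <- function(model, diet_bounds) {
  if (!length(diet_bounds)) return(model)
  if (any(diet_bounds < 0)) stop("diet uptake limits must be non-negative")
  set_bounds(model, names(diet_bounds), lb = -unname(diet_bounds))
}

# ---- reaction equation strings ----------------------------------------------

#' Parse a reaction equation
#'
#' Syntax: `2 A[c] + B[c] => C[e]` (irreversible) or `<=>` (reversible);
#' a missing side makes an exchange, e.g. `A[e] =>`. Metabolite tokens carry
#' their compartment in square brackets and are used verbatim as ids.
#'
#' @param equation Equation string.
#' @return List with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>" else if
    (grepl("=>", equation, fixed = TRUE)) "=>" else
    stop("equation has no '=>' or '<=>': ", equation)
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    out <- numeric()
    for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 2) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) stop("bad coefficient in term '", term, "'")
        met <- toks[2]
      } else if (length(toks) == 1) {
        coef <- 1; met <- toks[1]
      } else stop("cannot parse term '", term, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (is.na(st[m])) 0 else st[m]) + rhs[m]
  st <- st[st != 0]
  list(stoich = st, reversible = arrow == "<=>")
}

format_equation <- function(st, reversible) {
  side <- function(v, names) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names, paste(format(v, trim = TRUE), names)),
          collapse = " + ")
  }
  lhs <- -st[st < 0]; rhs <- st[st > 0]
  paste(side(lhs, names(lhs)), if (reversible) "<=>" else "=>",
        side(rhs, names(rhs)))
}

met_compartment <- function(met_id) {
  m <- regmatches(met_id, regexec("\\[([^]]*)\\]\\s*$", met_id))[[1]]
  if (length(m) == 2) m[2] else "c"
}

met_name <- function(met_id) sub("\\[[^]]*\\]\\s*$", "", met_id)

# ---- toy TSV format ---------------------------------------------------------

DEFAULT_BOUND <- 1000

read_toy_tsv <- function(path, id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("id", "equation", "lb", "ub")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("toy_tsv ", path, " lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$gpr)) tab$gpr <- ""
  tab$gpr[is.na(tab$gpr)] <- ""
  if (is.null(tab$objective)) tab$objective <- ""
  tab$objective[is.na(tab$objective)] <- ""
  stoich <- list(); mets <- character()
  for (i in seq_len(nrow(tab))) {
    eq <- parse_equation(tab$equation[i])
    stoich[[tab$id[i]]] <- eq$stoich
    mets <- union(mets, names(eq$stoich))
  }
  obj_rows <- which(nzchar(tab$objective))
  if (length(obj_rows) > 1) stop("toy_tsv declares more than one objective")
  objective <- if (length(obj_rows)) tab$id[obj_rows] else NA_character_
  sense <- if (length(obj_rows) && tolower(tab$objective[obj_rows]) == "min")
    "min" else "max"
  make_model(
    id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
    metabolites = data.frame(
      id = mets, name = vapply(mets, met_name, character(1)),
      compartment = vapply(mets, met_compartment, character(1)),
      stringsAsFactors = FALSE),
    reactions = data.frame(id = tab$id, lb = tab$lb, ub = tab$ub,
                           gpr = tab$gpr, stringsAsFactors = FALSE),
    stoichiometry = stoich, objective = objective, sense = sense)
}

write_toy_tsv <- function(model, path) {
  eqs <- vapply(model$reactions$id, function(rid) {
    format_equation(model$stoichiometry[[rid]], model$reactions$lb[
      match(rid, model$reactions$id)] < 0)
  }, character(1))
  obj <- ifelse(model$reactions$id == model$objective$reaction &
                  !is.na(model$objective$reaction),
                model$objective$sense, "")
  tab <- data.frame(id = model$reactions$id, equation = eqs,
                    lb = model$reactions$lb, ub = model$reactions$ub,
                    gpr = model$reactions$gpr, objective = obj,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- SBML L3V1 + fbc v2 -----------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds allow [A-Za-z_][A-Za-z0-9_]*; arbitrary ids (compartment suffixes
# in brackets etc.) are escaped reversibly as _xHH_ per offending byte.
encode_sid <- function(id, prefix) {
  chars <- strsplit(id, "")[[1]]
  esc <- vapply(chars, function(ch) {
    if (grepl("[A-Za-z0-9]", ch)) ch else sprintf("_x%02x_", utf8ToInt(ch))
  }, character(1))
  paste0(prefix, paste(esc, collapse = ""))
}

decode_sid <- function(sid, prefix) {
  body <- sub(paste0("^", prefix), "", sid)
  m <- gregexpr("_x[0-9a-f]{2}_", body)[[1]]
  if (m[1] == -1) return(body)
  out <- body
  for (tok in unique(regmatches(body, gregexpr("_x[0-9a-f]{2}_", body))[[1]])) {
    ch <- intToUtf8(strtoi(substr(tok, 3, 4), 16L))
    out <- gsub(tok, ch, out, fixed = TRUE)
  }
  out
}

gpr_to_fbc_nodes <- function(parent, gpr) {
  # parse "a and (b or c)" into nested fbc:and / fbc:or / fbc:geneProductRef
  node <- parse_gpr_ast(gpr)
  emit <- function(parent, ast) {
    if (ast$type == "gene") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = encode_sid(ast$gene, "G_"))
    } else {
      el <- xml2::xml_add_child(parent, paste0("fbc:", ast$type))
      for (ch in ast$args) emit(el, ch)
    }
  }
  emit(parent, node)
}

# Recursive-descent GPR parser: or-expr := and-expr ('or' and-expr)*;
# and-expr := atom ('and' atom)*; atom := gene | '(' or-expr ')'
parse_gpr_ast <- function(gpr) {
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
  pos <- 1
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(type = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else list(type = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (identical(t, "(")) {
      e <- parse_or()
      if (!identical(take(), ")")) stop("unbalanced parentheses in GPR: ", gpr)
      e
    } else list(type = "gene", gene = t)
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in GPR: ", gpr)
  out
}

fbc_nodes_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(decode_sid(xml2::xml_attr(node, "geneProduct"), "G_"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_nodes_to_gpr, character(1))
  joined <- paste(parts, collapse = paste0(" ", nm, " "))
  if (length(parts) > 1) paste0("(", joined, ")") else joined
}

write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = encode_sid(model$id, "MOD_"),
                             name = model$id, "fbc:strict" = "true")
  comps <- unique(model$metabolites$compartment)
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(loc, "compartment", id = encode_sid(cp, "C_"),
                        name = cp, constant = "true")
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    sp <- xml2::xml_add_child(
      los, "species",
      id = encode_sid(model$metabolites$id[i], "M_"),
      name = model$metabolites$name[i],
      compartment = encode_sid(model$metabolites$compartment[i], "C_"),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(model$metabolites$formula[i])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", model$metabolites$formula[i])
    }
  }
  # one parameter per distinct bound value
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  par_id <- function(v) encode_sid(format(v, trim = TRUE, digits = 17), "P_")
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(lop, "parameter", id = par_id(v),
                        value = format(v, trim = TRUE, digits = 17),
                        constant = "true", sboTerm = "SBO:0000626")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = encode_sid(rid, "R_"), name = rid,
      reversible = if (model$reactions$lb[i] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = par_id(model$reactions$lb[i]),
      "fbc:upperFluxBound" = par_id(model$reactions$ub[i]))
    st <- model$stoichiometry[[rid]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(reac)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = encode_sid(m, "M_"),
                            stoichiometry = format(-reac[[m]], trim = TRUE, digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = encode_sid(m, "M_"),
                            stoichiometry = format(prod[[m]], trim = TRUE, digits = 17),
                            constant = "true")
      }
    }
    gpr <- model$reactions$gpr[i]
    if (nzchar(gpr)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      gpr_to_fbc_nodes(gpa, gpr)
    }
  }
  genes <- model_genes(model)
  if (length(genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = encode_sid(g, "G_"),
                          "fbc:label" = g)
    }
  }
  if (!is.na(model$objective$reaction)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(
      loo, "fbc:objective", "fbc:id" = "obj",
      "fbc:type" = if (model$objective$sense == "max") "maximize" else "minimize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = encode_sid(model$objective$reaction, "R_"),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
}

read_sbml <- function(path, id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in ", path, ": ", conditionMessage(e))
  })
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  model_name <- xml2::xml_attr(mdl, "name")
  model_id <- if (!is.na(model_name)) model_name else
    decode_sid(xml2::xml_attr(mdl, "id"), "MOD_")
  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sids <- xml2::xml_attr(sp_nodes, "id")
  mets <- data.frame(
    id = vapply(sids, decode_sid, character(1), prefix = "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = vapply(xml2::xml_attr(sp_nodes, "compartment"),
                         decode_sid, character(1), prefix = "C_"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    stringsAsFactors = FALSE)
  rownames(mets) <- NULL
  sid_to_met <- stats::setNames(mets$id, sids)
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- data.frame(id = character(), lb = numeric(), ub = numeric(),
                     gpr = character(), stringsAsFactors = FALSE)
  stoich <- list()
  for (rx in rx_nodes) {
    rid <- decode_sid(xml2::xml_attr(rx, "id"), "R_")
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb <- if (!is.na(lb_ref)) par_val[[lb_ref]] else
      if (rev) -DEFAULT_BOUND else 0
    ub <- if (!is.na(ub_ref)) par_val[[ub_ref]] else DEFAULT_BOUND
    st <- numeric()
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      m <- sid_to_met[[xml2::xml_attr(sr, "species")]]
      if (is.null(m)) stop("reaction ", rid, " references undeclared species ",
                           xml2::xml_attr(sr, "species"))
      st[m] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      m <- sid_to_met[[xml2::xml_attr(sr, "species")]]
      if (is.null(m)) stop("reaction ", rid, " references undeclared species ",
                           xml2::xml_attr(sr, "species"))
      st[m] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else fbc_nodes_to_gpr(gpa)
    gpr <- gsub("^\\((.*)\\)$", "\\1", gpr)
    rxns <- rbind(rxns, data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                                   stringsAsFactors = FALSE))
    stoich[[rid]] <- st
  }
  obj_node <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- NA_character_; sense <- "max"
  if (!inherits(obj_node, "xml_missing")) {
    objective <- decode_sid(xml2::xml_attr(obj_node, "reaction"), "R_")
    parent_obj <- xml2::xml_parent(xml2::xml_parent(obj_node))
    sense <- if (identical(xml2::xml_attr(parent_obj, "type"), "minimize"))
      "min" else "max"
  }
  make_model(id = if (is.null(id)) model_id else id,
             metabolites = mets, reactions = rxns, stoichiometry = stoich,
             objective = objective, sense = sense)
}

#' Load a metabolic model from disk
#'
#' Reads SBML Level 3 Version 1 with the flux-balance-constraints (fbc v2)
#' annotations for bounds, objective and gene associations, or the plain
#' `toy_tsv` fixture format (tab-separated, columns
#' `id equation lb ub gpr objective`). SBML without fbc bounds gets the
#' family defaults: `[-1000, 1000]` when the reaction is flagged reversible,
#' `[0, 1000]` otherwise, and no objective.
#'
#' @param path File path.
#' @param format `"sbml"` or `"toy_tsv"`; guessed from the extension by
#'   default (`.xml`/`.sbml` vs anything else).
#' @param id Optional model id override.
#' @return A validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "sbml", "toy_tsv"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "toy_tsv"
  }
  switch(format, sbml = read_sbml(path, id), toy_tsv = read_toy_tsv(path, id))
}

#' Save a metabolic model to disk
#'
#' Writes SBML L3V1+fbc v2 or the `toy_tsv` fixture format. A
#' `load_model()` of the written file reproduces the element sets, bounds,
#' objective and GPR truth tables of the input.
#'
#' @param model A `metabolic_model`.
#' @param path Destination path.
#' @param format `"sbml"` or `"toy_tsv"`.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, format = c("sbml", "toy_tsv")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format, sbml = write_sbml(model, path),
         toy_tsv = write_toy_tsv(model, path))
  invisible(path)
}
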
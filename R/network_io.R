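#' Load a metabolic network from file
#'
#' Two formats are supported. The TSV dialect has one reaction per line with
#' fields `id`, equation, reversibility flag (`irrev`/`rev`), lower bound,
#' upper bound, separated by tabs or commas:
#'
#' ```
#' r1   2 A[c] + B[c] -> C[e]   irrev   0   1000
#' ```
#'
#' Coefficients are optional (default 1), the compartment is a square-bracket
#' suffix (`[c]` cytosolic, `[e]` extracellular), `->` marks irreversible and
#' `<=>` reversible reactions. Lines starting with `#` and blank lines are
#' ignored. SBML input is Level 3 with the `fbc` extension for flux bounds
#' and objectives.
#'
#' Because deposited networks use lab-specific metabolite naming, an
#' optional two-column `id_map` file (`from,to`, CSV) renames metabolites on
#' load instead of the loader guessing conventions.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"sbml"` (default guessed from the extension).
#' @param metabolite_file Optional CSV with columns `id`, `name`, `formula`
#'   attaching names/elemental formulas to metabolites (formula empty or NA
#'   flags a pseudo-species).
#' @param id_map Optional CSV path with columns `from`, `to` renaming
#'   metabolite ids on load.
#' @return A validated `metabolic_network`.
#' @export
load_network <- function(path, format = c("guess", "tsv", "sbml"),
                         metabolite_file = NULL, id_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "guess") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  net <- switch(format,
                tsv = read_network_tsv(path),
                sbml = read_network_sbml(path))
  if (!is.null(id_map)) {
    map <- utils::read.csv(id_map, stringsAsFactors = FALSE)
    hit <- match(net$metabolites$id, map$from)
    renamed <- !is.na(hit)
    net$metabolites$id[renamed] <- map$to[hit[renamed]]
    rownames(net$S) <- net$metabolites$id
  }
  if (!is.null(metabolite_file)) {
    info <- utils::read.csv(metabolite_file, stringsAsFactors = FALSE)
    hit <- match(net$metabolites$id, info$id)
    ok <- !is.na(hit)
    if (!is.null(info$name)) net$metabolites$name[ok] <- info$name[hit[ok]]
    if (!is.null(info$formula)) {
      f <- info$formula[hit[ok]]
      f[!nzchar(trimws(ifelse(is.na(f), "", f)))] <- NA_character_
      net$metabolites$formula[ok] <- f
    }
  }
  validate_network(net)
  net
}

parse_equation <- function(eq, line = NA) {
  ctx <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
           else if (grepl("->", eq, fixed = TRUE)) "->"
           else stop(sprintf("malformed equation%s: no '->' or '<=>' in '%s'", ctx, eq))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop(sprintf("malformed equation%s: '%s'", ctx, eq))
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    if (grepl("^\\+", side) || grepl("\\+$", side)) {
      stop(sprintf("malformed equation%s: dangling '+' in '%s'", ctx, eq))
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) stop(sprintf("malformed equation%s: empty term in '%s'", ctx, eq))
      m <- regmatches(tm, regexec(
        "^([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?[[:space:]]+)?([^][[:space:]]+)\\[([^]]+)\\]$", tm))[[1]]
      if (!length(m)) {
        stop(sprintf("malformed term%s: '%s' (expected '[coef] name[compartment]')", ctx, tm))
      }
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      comp <- m[5]
      if (!comp %in% c("c", "e")) {
        stop(sprintf("unknown compartment suffix '[%s]'%s in term '%s'", comp, ctx, tm))
      }
      id <- paste0(m[4], "[", comp, "]")
      out[id] <- (if (id %in% names(out)) out[[id]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- lhs
  for (id in names(rhs)) {
    stoich[id] <- (if (id %in% names(stoich)) stoich[[id]] else 0) + rhs[[id]]
  }
  stoich <- stoich[abs(stoich) > ZERO_COEF_TOL]
  if (!length(stoich)) {
    stop(sprintf("equation%s cancels to nothing: '%s'", ctx, eq))
  }
  list(stoich = stoich, reversible = arrow == "<=>")
}

read_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines))
  ids <- character(); stoichs <- list(); revs <- logical()
  lbs <- ubs <- numeric(); objective <- NULL
  for (k in keep) {
    ln <- lines[k]
    fields <- if (grepl("\t", ln)) strsplit(ln, "\t")[[1]] else strsplit(ln, ",")[[1]]
    fields <- trimws(fields)
    if (length(fields) < 2L) stop(sprintf("malformed reaction line %d: '%s'", k, ln))
    id <- fields[1]
    if (grepl("^@objective", id)) { objective <- fields[2]; next }
    pe <- parse_equation(fields[2], line = k)
    rev <- if (length(fields) >= 3 && nzchar(fields[3])) {
      if (!fields[3] %in% c("rev", "irrev")) {
        stop(sprintf("line %d: reversibility flag must be 'rev' or 'irrev', got '%s'", k, fields[3]))
      }
      fields[3] == "rev"
    } else pe$reversible
    if (rev != pe$reversible && length(fields) >= 3 && nzchar(fields[3])) {
      # explicit flag wins over the arrow, but keep them consistent here
      stop(sprintf("line %d: reversibility flag '%s' contradicts the equation arrow", k, fields[3]))
    }
    lb <- if (length(fields) >= 4 && nzchar(fields[4])) as.numeric(fields[4])
          else if (rev) -1000 else 0
    ub <- if (length(fields) >= 5 && nzchar(fields[5])) as.numeric(fields[5]) else 1000
    if (is.na(lb) || is.na(ub)) stop(sprintf("line %d: unparseable bounds", k))
    if (id %in% ids) stop(sprintf("duplicate reaction id '%s' (line %d)", id, k))
    ids <- c(ids, id); stoichs[[id]] <- pe$stoich
    revs <- c(revs, rev); lbs <- c(lbs, lb); ubs <- c(ubs, ub)
  }
  if (!length(ids)) stop(sprintf("no reactions found in %s", path))
  met_ids <- unique(unlist(lapply(stoichs, names)))
  S <- matrix(0, length(met_ids), length(ids), dimnames = list(met_ids, ids))
  for (id in ids) S[names(stoichs[[id]]), id] <- stoichs[[id]]
  comp <- sub("^.*\\[([^]]+)\\]$", "\\1", met_ids)
  mets <- data.frame(id = met_ids,
                     name = sub("\\[[^]]+\\]$", "", met_ids),
                     compartment = comp,
                     formula = NA_character_,
                     stringsAsFactors = FALSE)
  metabolic_network(mets,
                    data.frame(id = ids, reversible = revs, lb = lbs, ub = ubs,
                               stringsAsFactors = FALSE),
                    S, objective = objective)
}

format_equation <- function(net, j) {
  coef <- net$S[, j]
  neg <- which(coef < -ZERO_COEF_TOL); pos <- which(coef > ZERO_COEF_TOL)
  term <- function(i, s) {
    cf <- abs(coef[i])
    paste0(if (abs(cf - 1) < 1e-12) "" else paste0(format(cf, scientific = FALSE, trim = TRUE), " "),
           net$metabolites$id[i])
  }
  arrow <- if (net$reactions$reversible[j]) "<=>" else "->"
  paste(paste(vapply(neg, term, "", s = -1), collapse = " + "),
        arrow,
        paste(vapply(pos, term, "", s = 1), collapse = " + "))
}

#' Write a network in the TSV reaction dialect
#' @param net A `metabolic_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  lines <- vapply(seq_len(nrow(net$reactions)), function(j) {
    paste(net$reactions$id[j], format_equation(net, j),
          if (net$reactions$reversible[j]) "rev" else "irrev",
          format(net$reactions$lb[j], scientific = FALSE, trim = TRUE),
          format(net$reactions$ub[j], scientific = FALSE, trim = TRUE),
          sep = "\t")
  }, "")
  if (!is.null(net$objective)) lines <- c(lines, paste0("@objective\t", net$objective))
  writeLines(lines, path)
  invisible(path)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a network as SBML Level 3 with fbc flux bounds
#' @param net A `metabolic_network`.
#' @param path Output file.
#' @param model_id Model id attribute.
#' @return `path`, invisibly.
#' @export
write_network_sbml <- function(net, path, model_id = "model") {
  sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  mid <- sanitize(net$metabolites$id); rid <- sanitize(net$reactions$id)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = model_id, "fbc:strict" = "true")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in unique(net$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")
  }
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    attrs <- list(id = mid[i], name = net$metabolites$id[i],
                  compartment = net$metabolites$compartment[i],
                  hasOnlySubstanceUnits = "false", constant = "false",
                  boundaryCondition = if (net$metabolites$compartment[i] == "e") "true" else "false")
    f <- net$metabolites$formula[i]
    if (!is.na(f) && nzchar(f)) attrs[["fbc:chemicalFormula"]] <- f
    do.call(xml2::xml_add_child, c(list(sp, "species"), attrs))
  }
  pars <- xml2::xml_add_child(model, "listOfParameters")
  bound_par <- function(val, what, j) {
    id <- sprintf("%s_%s", what, rid[j])
    xml2::xml_add_child(pars, "parameter", id = id, constant = "true",
                        value = format(val, scientific = TRUE, digits = 12))
    id
  }
  rx <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(net$reactions))) {
    lbid <- bound_par(net$reactions$lb[j], "lb", j)
    ubid <- bound_par(net$reactions$ub[j], "ub", j)
    rnode <- xml2::xml_add_child(rx, "reaction", id = rid[j],
                                 name = net$reactions$id[j],
                                 reversible = tolower(as.character(net$reactions$reversible[j])),
                                 fast = "false",
                                 "fbc:lowerFluxBound" = lbid,
                                 "fbc:upperFluxBound" = ubid)
    coef <- net$S[, j]
    neg <- which(coef < -ZERO_COEF_TOL); pos <- which(coef > ZERO_COEF_TOL)
    if (length(neg)) {
      lr <- xml2::xml_add_child(rnode, "listOfReactants")
      for (i in neg) xml2::xml_add_child(lr, "speciesReference", species = mid[i],
                                         stoichiometry = format(-coef[i], digits = 15),
                                         constant = "true")
    }
    if (length(pos)) {
      lp <- xml2::xml_add_child(rnode, "listOfProducts")
      for (i in pos) xml2::xml_add_child(lp, "speciesReference", species = mid[i],
                                         stoichiometry = format(coef[i], digits = 15),
                                         constant = "true")
    }
  }
  if (!is.null(net$objective)) {
    lo <- xml2::xml_add_child(model, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = sanitize(net$objective),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spn <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(spn)) stop(sprintf("no species found in SBML file %s", path))
  sid <- xml2::xml_attr(spn, "id")
  sname <- xml2::xml_attr(spn, "name")
  sname[is.na(sname)] <- sid[is.na(sname)]
  comp <- xml2::xml_attr(spn, "compartment")
  formula <- xml2::xml_attr(spn, "chemicalFormula")
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rxn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxn)) stop(sprintf("no reactions found in SBML file %s", path))
  rid <- xml2::xml_attr(rxn, "id")
  rname <- xml2::xml_attr(rxn, "name"); rname[is.na(rname)] <- rid[is.na(rname)]
  rev <- xml2::xml_attr(rxn, "reversible") == "true"
  S <- matrix(0, length(sid), length(rxn), dimnames = list(sid, rname))
  lb <- ub <- numeric(length(rxn))
  for (j in seq_along(rxn)) {
    for (node in xml2::xml_find_all(rxn[[j]], "./listOfReactants/speciesReference")) {
      S[xml2::xml_attr(node, "species"), j] <-
        S[xml2::xml_attr(node, "species"), j] - as.numeric(xml2::xml_attr(node, "stoichiometry"))
    }
    for (node in xml2::xml_find_all(rxn[[j]], "./listOfProducts/speciesReference")) {
      S[xml2::xml_attr(node, "species"), j] <-
        S[xml2::xml_attr(node, "species"), j] + as.numeric(xml2::xml_attr(node, "stoichiometry"))
    }
    lbref <- xml2::xml_attr(rxn[[j]], "lowerFluxBound")
    ubref <- xml2::xml_attr(rxn[[j]], "upperFluxBound")
    lb[j] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
             else if (rev[j]) -1000 else 0
    ub[j] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
  }
  objnode <- xml2::xml_find_first(doc, ".//fluxObjective")
  objective <- NULL
  if (!inherits(objnode, "xml_missing")) {
    objective <- rname[match(xml2::xml_attr(objnode, "reaction"), rid)]
  }
  mets <- data.frame(id = sname, name = sub("\\[[^]]+\\]$", "", sname),
                     compartment = comp, formula = formula,
                     stringsAsFactors = FALSE)
  rownames(S) <- sname
  metabolic_network(mets,
                    data.frame(id = rname, reversible = rev, lb = lb, ub = ub,
                               stringsAsFactors = FALSE),
                    S, objective = objective)
}
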
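#' Create an empty metabolic + regulatory network
#'
#' A `metreg_network` holds five tables describing a pathway/genome-database
#' style knowledge structure: entities (genes, proteins, complexes, modified
#' forms, metabolites), reactions (with direction, catalysts and transport /
#' protein-binding flags), regulatory interactions, transcription units, and
#' metadata. Networks are built incrementally with the `add_*()` verbs, read
#' from JSON with [read_network()], or generated with [generate_network()].
#'
#' @return A `metreg_network` object (a list of tibbles).
#' @examples
#' net <- network() |>
#'   add_metabolite("M0") |>
#'   add_metabolite("M1") |>
#'   add_gene_product("E1") |>
#'   add_reaction("R1", reactants = "M0", products = "M1", enzymes = "E1")
#' net
#' @export
network <- function() {
  structure(
    list(
      entities = tibble::tibble(
        id = character(), kind = character(), name = character(),
        ubiquitous = logical(), base_entity = character(),
        gene = character(), components = list()
      ),
      reactions = tibble::tibble(
        id = character(), direction = character(),
        is_transport = logical(), is_protein_binding = logical(),
        reactants = list(), products = list(), enzymes = list(),
        transported = list()
      ),
      regulations = tibble::tibble(
        id = character(), regulator = character(), regulatee = character(),
        mode = character(), sign = character()
      ),
      transcription_units = tibble::tibble(id = character(), genes = list()),
      meta = list(schema_version = "1.0")
    ),
    class = "metreg_network"
  )
}

entity_kinds <- c("gene", "protein", "complex", "metabolite", "modified-form")
reaction_directions <- c("left-to-right", "right-to-left", "reversible")
regulation_modes <- c("transcriptional", "translational", "sigma-factor",
                      "enzyme-modulation", "cofactor")

#' Default ubiquitous-compound names
#'
#' Compounds that take part in very large numbers of reactions (water, ATP and
#' the like) are excluded from substrate-role influence edges. Whether a
#' compound is ubiquitous is data (the `ubiquitous` entity flag); when the flag
#' is absent this default name list is applied, matched case-insensitively
#' against entity id and display name. The set is user-overridable because no
#' canonical enumeration exists.
#'
#' @return A character vector of compound names.
#' @export
default_ubiquitous_compounds <- function() {
  c("water", "ATP", "ADP", "AMP", "phosphate", "diphosphate", "H+",
    "NAD", "NADH", "NADP", "NADPH", "CO2", "O2")
}

add_entity_row <- function(net, id, kind, name = id, ubiquitous = NA,
                           base_entity = NA_character_, gene = NA_character_,
                           components = NULL) {
  stopifnot(inherits(net, "metreg_network"))
  net$entities <- dplyr::bind_rows(net$entities, tibble::tibble(
    id = id, kind = kind, name = name, ubiquitous = as.logical(ubiquitous),
    base_entity = base_entity, gene = gene,
    components = list(components %||% numeric())
  ))
  net
}

#' Add records to a network
#'
#' Pipe-friendly builder verbs. `add_gene_product()` adds a gene and a linked
#' protein product in one step (the protein's `gene` field records the
#' association used by logical-entity coalescing). Complex components are given
#' as a named numeric vector of copy counts, e.g. `c(P1 = 2)` for a homodimer.
#'
#' @param net A `metreg_network`.
#' @param id Record id (unique within its category).
#' @param name Display name; defaults to the id.
#' @param ubiquitous Logical flag marking a compound excluded from
#'   substrate-role edges; `NA` means "decide from the default name list".
#' @param gene,protein Gene and protein ids for `add_gene_product()`.
#' @param base Base entity id for a modified form.
#' @param components Named numeric vector of component copy counts.
#' @param reactants,products Character vectors of substrate entity ids.
#' @param direction One of `"left-to-right"`, `"right-to-left"`,
#'   `"reversible"`.
#' @param enzymes Character vector of catalyst entity ids.
#' @param is_transport,is_protein_binding Reaction flags.
#' @param transported Transported substrates (subset of the substrates).
#' @param regulator,regulatee Entity ids of a regulatory interaction.
#' @param mode One of `"transcriptional"`, `"translational"`,
#'   `"sigma-factor"`, `"enzyme-modulation"`, `"cofactor"`.
#' @param sign `"+"` or `"-"` (sigma-factor and cofactor records are fixed
#'   to `"+"`).
#' @param genes Ordered gene ids of a transcription unit.
#' @return The extended network, invisibly pipeable.
#' @name network-builders
NULL

#' @rdname network-builders
#' @export
add_metabolite <- function(net, id, name = id, ubiquitous = NA) {
  add_entity_row(net, id, "metabolite", name, ubiquitous)
}

#' @rdname network-builders
#' @export
add_gene <- function(net, id, name = id) add_entity_row(net, id, "gene", name)

#' @rdname network-builders
#' @export
add_protein <- function(net, id, name = id, gene = NA_character_) {
  add_entity_row(net, id, "protein", name, gene = gene)
}

#' @rdname network-builders
#' @export
add_gene_product <- function(net, gene, protein = paste0(gene, "_p")) {
  net |> add_gene(gene) |> add_protein(protein, gene = gene)
}

#' @rdname network-builders
#' @export
add_complex <- function(net, id, components, name = id) {
  add_entity_row(net, id, "complex", name, components = components)
}

#' @rdname network-builders
#' @export
add_modified_form <- function(net, id, base, name = id) {
  add_entity_row(net, id, "modified-form", name, base_entity = base)
}

#' @rdname network-builders
#' @export
add_reaction <- function(net, id, reactants, products,
                         direction = "left-to-right", enzymes = character(),
                         is_transport = FALSE, transported = character(),
                         is_protein_binding = FALSE) {
  stopifnot(inherits(net, "metreg_network"))
  net$reactions <- dplyr::bind_rows(net$reactions, tibble::tibble(
    id = id, direction = direction, is_transport = is_transport,
    is_protein_binding = is_protein_binding,
    reactants = list(as.character(reactants)),
    products = list(as.character(products)),
    enzymes = list(as.character(enzymes)),
    transported = list(as.character(transported))
  ))
  net
}

#' @rdname network-builders
#' @export
add_regulation <- function(net, id, regulator, regulatee, mode, sign = "+") {
  stopifnot(inherits(net, "metreg_network"))
  if (mode %in% c("sigma-factor", "cofactor")) sign <- "+"
  net$regulations <- dplyr::bind_rows(net$regulations, tibble::tibble(
    id = id, regulator = regulator, regulatee = regulatee,
    mode = mode, sign = sign
  ))
  net
}

#' @rdname network-builders
#' @export
add_transcription_unit <- function(net, id, genes) {
  stopifnot(inherits(net, "metreg_network"))
  net$transcription_units <- dplyr::bind_rows(
    net$transcription_units,
    tibble::tibble(id = id, genes = list(as.character(genes)))
  )
  net
}

#' @export
print.metreg_network <- function(x, ...) {
  cat("<metreg_network> schema", x$meta$schema_version, "\n")
  cat("  entities:           ", nrow(x$entities), "\n")
  cat("  reactions:          ", nrow(x$reactions), "\n")
  cat("  regulations:        ", nrow(x$regulations), "\n")
  cat("  transcription units:", nrow(x$transcription_units), "\n")
  invisible(x)
}

#' @method glance metreg_network
#' @export
glance.metreg_network <- function(x, ...) {
  tibble::tibble(
    n_entities = nrow(x$entities),
    n_reactions = nrow(x$reactions),
    n_regulations = nrow(x$regulations),
    n_transcription_units = nrow(x$transcription_units),
    n_logical_nodes = length(unique(logical_node_map(x)))
  )
}

resolve_ubiquitous <- function(entities,
                               defaults = default_ubiquitous_compounds()) {
  flag <- entities$ubiquitous
  miss <- is.na(flag)
  if (any(miss)) {
    dl <- tolower(defaults)
    flag[miss] <- tolower(entities$id[miss]) %in% dl |
      tolower(entities$name[miss]) %in% dl
  }
  flag & entities$kind == "metabolite"
}

#' Validate a network
#'
#' Checks id uniqueness per category, cross-reference resolution, and the
#' structural invariants of each record type: complexes (and only complexes)
#' have components and the composition relation is acyclic; modified forms
#' (and only they) carry a base entity; reactant and product sets are disjoint
#' and non-empty; transported species are substrates; enzyme-modulation and
#' cofactor regulatees catalyse at least one reaction; transcription units
#' list genes only.
#'
#' @param net A `metreg_network`.
#' @return `net`, invisibly, on success; otherwise an error naming the
#'   offending record.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metreg_network"))
  ent <- net$entities
  fail <- function(..., .envir = parent.frame()) {
    rlang::abort(glue::glue(..., .envir = .envir),
                 class = "metregr_invalid_network")
  }
  for (tab in c("entities", "reactions", "regulations", "transcription_units")) {
    ids <- net[[tab]]$id
    if (anyDuplicated(ids))
      fail("duplicate id in {tab}: {ids[duplicated(ids)][1]}")
  }
  bad_kind <- setdiff(unique(ent$kind), entity_kinds)
  if (length(bad_kind)) fail("unknown entity kind: {bad_kind[1]}")
  known <- ent$id
  ref_ok <- function(ids, where) {
    missing <- setdiff(ids, known)
    if (length(missing))
      fail("dangling reference in {where}: unknown entity \"{missing[1]}\"")
  }
  # entity-level invariants
  for (i in seq_len(nrow(ent))) {
    e <- ent[i, ]
    comp <- e$components[[1]]
    if (e$kind == "complex") {
      if (length(comp) == 0)
        fail("complex \"{e$id}\" has no components")
      ref_ok(names(comp), glue::glue("complex \"{e$id}\""))
      if (any(comp <= 0)) fail("complex \"{e$id}\" has non-positive copy count")
    } else if (length(comp) > 0) {
      fail("non-complex entity \"{e$id}\" has components")
    }
    if (e$kind == "modified-form") {
      if (is.na(e$base_entity)) fail("modified form \"{e$id}\" lacks base_entity")
      ref_ok(e$base_entity, glue::glue("modified form \"{e$id}\""))
    } else if (!is.na(e$base_entity)) {
      fail("non-modified entity \"{e$id}\" has base_entity")
    }
    if (!is.na(e$gene)) {
      ref_ok(e$gene, glue::glue("protein \"{e$id}\""))
      if (ent$kind[match(e$gene, ent$id)] != "gene")
        fail("gene field of \"{e$id}\" does not reference a gene")
    }
  }
  # composition acyclicity (complex -> component)
  if (nrow(ent) > 0) {
    comp_edges <- purrr::map2_dfr(ent$id, ent$components, function(id, comp) {
      if (length(comp) == 0) return(NULL)
      tibble::tibble(from = id, to = names(comp))
    })
    if (nrow(comp_edges) > 0) {
      g <- igraph::graph_from_data_frame(comp_edges, directed = TRUE)
      if (!igraph::is_dag(g)) fail("cycle in the complex composition relation")
    }
  }
  rx <- net$reactions
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    re <- r$reactants[[1]]; pr <- r$products[[1]]
    if (length(re) == 0 || length(pr) == 0)
      fail("reaction \"{r$id}\" needs at least one substrate on each side")
    if (length(intersect(re, pr)))
      fail("reaction \"{r$id}\" has overlapping reactant and product sets")
    ref_ok(c(re, pr, r$enzymes[[1]]), glue::glue("reaction \"{r$id}\""))
    if (!r$direction %in% reaction_directions)
      fail("reaction \"{r$id}\" has unknown direction \"{r$direction}\"")
    tr <- r$transported[[1]]
    if (length(tr) && !all(tr %in% c(re, pr)))
      fail("reaction \"{r$id}\" transports a non-substrate")
    if (length(tr) && !r$is_transport)
      fail("reaction \"{r$id}\" lists transported species but is not transport")
  }
  rg <- net$regulations
  enzyme_ids <- unique(unlist(rx$enzymes))
  lmap <- if (nrow(ent)) logical_node_map(net) else character()
  enzyme_lnodes <- unique(unname(lmap[enzyme_ids]))
  for (i in seq_len(nrow(rg))) {
    g <- rg[i, ]
    ref_ok(c(g$regulator, g$regulatee), glue::glue("regulation \"{g$id}\""))
    if (!g$mode %in% regulation_modes)
      fail("regulation \"{g$id}\" has unknown mode \"{g$mode}\"")
    if (!g$sign %in% c("+", "-"))
      fail("regulation \"{g$id}\" has unknown sign \"{g$sign}\"")
    if (g$mode %in% c("enzyme-modulation", "cofactor") &&
        !(lmap[[g$regulatee]] %in% enzyme_lnodes))
      fail("regulation \"{g$id}\": regulatee \"{g$regulatee}\" catalyses no reaction")
  }
  tu <- net$transcription_units
  for (i in seq_len(nrow(tu))) {
    u <- tu[i, ]
    gs <- u$genes[[1]]
    if (length(gs) == 0) fail("transcription unit \"{u$id}\" lists no genes")
    ref_ok(gs, glue::glue("transcription unit \"{u$id}\""))
    kinds <- ent$kind[match(gs, ent$id)]
    if (any(kinds != "gene"))
      fail("transcription unit \"{u$id}\" lists a non-gene member")
  }
  invisible(net)
}

# ---- logical-entity coalescing -----------------------------------------

#' Map every entity to its logical node
#'
#' A gene, its protein product, and any homomultimeric complexes of that
#' product are one logical entity and share a single node id; chemically
#' modified forms and heteromultimeric complexes are distinct logical nodes.
#' The canonical id of a coalesced group prefers gene over monomer protein
#' over complex, with lexicographic tie-breaking, so displayed node names are
#' gene-centric and deterministic.
#'
#' @param net A `metreg_network`.
#' @return A named character vector: entity id -> canonical logical node id.
#' @export
logical_node_map <- function(net) {
  ent <- net$entities
  n <- nrow(ent)
  if (n == 0) return(stats::setNames(character(), character()))
  parent <- stats::setNames(seq_len(n), ent$id)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  idx <- stats::setNames(seq_len(n), ent$id)
  # gene -- product
  for (i in seq_len(n)) {
    if (!is.na(ent$gene[i])) union_(i, idx[[ent$gene[i]]])
  }
  # homomultimer -- its single distinct component (repeat to settle
  # homomultimers of homomultimers regardless of record order)
  homo <- which(ent$kind == "complex" &
                  purrr::map_int(ent$components, ~ length(unique(names(.x)))) == 1L)
  for (pass in 1:2) {
    for (i in homo) union_(i, idx[[names(ent$components[[i]])[1]]])
  }
  group <- vapply(seq_len(n), find, integer(1))
  canon <- character(max(group))
  for (g in unique(group)) {
    members <- which(group == g)
    rank <- match(ent$kind[members], c("gene", "protein", "complex")) |>
      (\(r) ifelse(is.na(r), 4L, r))()
    ord <- order(rank, ent$id[members])
    canon[g] <- ent$id[members[ord[1]]]
  }
  stats::setNames(canon[group], ent$id)
}

#' Logical node of an entity
#'
#' @param entity An entity id.
#' @param net A `metreg_network`.
#' @return The canonical logical node id (see [logical_node_map()]).
#' @export
logical_node_of <- function(entity, net) {
  lmap <- logical_node_map(net)
  if (!entity %in% names(lmap))
    rlang::abort(glue::glue("unknown entity id \"{entity}\""))
  unname(lmap[[entity]])
}

# ---- internal index used by pricing and traversal ----------------------

# Precomputes, over logical nodes: substrate participation (with the
# small-molecule protein-binding exclusion and ubiquitous zeroing), catalysis
# and transport counts, regulation tables, TU membership, and node kinds.
net_index <- function(net) {
  ent <- net$entities
  lmap <- logical_node_map(net)
  ubi_ent <- resolve_ubiquitous(ent)
  lnodes <- unique(unname(lmap))
  grp_kind <- function(l) ent$kind[lmap == l]
  kind <- vapply(lnodes, function(l) {
    k <- grp_kind(l)
    if (all(k == "metabolite")) "metabolite"
    else if (any(k == "modified-form")) "modified-form"
    else "gene-product"
  }, character(1))
  ubiquitous <- vapply(lnodes, function(l) any(ubi_ent[lmap == l]), logical(1))
  names(kind) <- names(ubiquitous) <- lnodes

  rx <- net$reactions
  to_l <- function(ids) unique(unname(lmap[ids]))
  rxl <- purrr::pmap(rx, function(id, direction, is_transport,
                                  is_protein_binding, reactants, products,
                                  enzymes, transported) {
    list(id = id, direction = direction, is_transport = is_transport,
         is_protein_binding = is_protein_binding,
         reactants = to_l(reactants), products = to_l(products),
         enzymes = to_l(enzymes), transported = to_l(transported))
  })
  names(rxl) <- rx$id

  # substrate participation: reactions in which a logical node is a reactant
  # or product, dropping protein-binding reactions for small molecules, and
  # everything for ubiquitous compounds
  sub_rxns <- stats::setNames(vector("list", length(lnodes)), lnodes)
  enz_rxns <- stats::setNames(vector("list", length(lnodes)), lnodes)
  trans_rxns <- stats::setNames(vector("list", length(lnodes)), lnodes)
  for (r in rxl) {
    for (s in unique(c(r$reactants, r$products))) {
      if (ubiquitous[[s]]) next
      if (kind[[s]] == "metabolite" && r$is_protein_binding) next
      sub_rxns[[s]] <- c(sub_rxns[[s]], r$id)
    }
    for (e in r$enzymes) {
      enz_rxns[[e]] <- c(enz_rxns[[e]], r$id)
      if (r$is_transport) trans_rxns[[e]] <- c(trans_rxns[[e]], r$id)
    }
  }

  rg <- net$regulations
  rgl <- tibble::tibble(
    id = rg$id,
    regulator = unname(lmap[rg$regulator]),
    regulatee = unname(lmap[rg$regulatee]),
    mode = rg$mode, sign = rg$sign
  )

  tus <- net$transcription_units
  tu_of_gene <- list()
  for (i in seq_len(nrow(tus))) {
    for (g in unique(unname(lmap[tus$genes[[i]]]))) {
      tu_of_gene[[g]] <- c(tu_of_gene[[g]], tus$id[i])
    }
  }

  # heteromultimeric complexes, keyed by logical node
  hetero <- ent[ent$kind == "complex" &
                  purrr::map_int(ent$components, ~ length(unique(names(.x)))) > 1L, ]
  hetero_of <- list()
  for (i in seq_len(nrow(hetero))) {
    l <- lmap[[hetero$id[i]]]
    hetero_of[[l]] <- c(hetero_of[[l]], list(list(
      id = hetero$id[i],
      components = unique(unname(lmap[names(hetero$components[[i]])]))
    )))
  }

  list(net = net, lmap = lmap, lnodes = lnodes, kind = kind,
       ubiquitous = ubiquitous, reactions = rxl,
       sub_rxns = sub_rxns, enz_rxns = enz_rxns, trans_rxns = trans_rxns,
       regulations = rgl, tu_of_gene = tu_of_gene, hetero_of = hetero_of,
       tus = tus)
}

count_excluding <- function(set, excluding) {
  length(setdiff(set, excluding))
}

# ---- specificity-count queries -----------------------------------------

#' Specificity counts used by the edge-cost formulas
#'
#' Each count is taken over logical nodes (see [logical_node_map()]):
#' `substrate_reaction_count()` is the number of *other* reactions (excluding
#' `excluding`) in which the entity is a reactant or product — zero by
#' convention for ubiquitous compounds, and not counting protein-binding
#' reactions when the entity is a small molecule; `enzyme_reaction_count()`
#' counts catalysed reactions; `transporter_reaction_count()` counts catalysed
#' transport reactions; `modulated_enzyme_count()` and
#' `cofactor_enzyme_count()` count distinct enzymes the entity modulates or
#' serves as cofactor for; `regulated_gene_count()` counts distinct
#' regulatees across transcriptional, translational and sigma-factor records;
#' `regulator_count()` counts the entity's distinct (regulator, mode)
#' transcriptional/translational/sigma-factor regulators.
#'
#' @param entity An entity id (any member of the logical node may be given).
#' @param net A `metreg_network`.
#' @param excluding A reaction id to leave out ("number of other reactions").
#' @return A non-negative integer.
#' @name specificity-counts
NULL

resolve_lnode <- function(entity, idx) {
  if (entity %in% names(idx$lmap)) return(unname(idx$lmap[[entity]]))
  if (entity %in% idx$lnodes) return(entity)
  rlang::abort(glue::glue("unknown entity id \"{entity}\""))
}

#' @rdname specificity-counts
#' @export
substrate_reaction_count <- function(entity, net, excluding = character()) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  l <- resolve_lnode(entity, idx)
  count_excluding(idx$sub_rxns[[l]], excluding)
}

#' @rdname specificity-counts
#' @export
enzyme_reaction_count <- function(entity, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  length(idx$enz_rxns[[resolve_lnode(entity, idx)]])
}

#' @rdname specificity-counts
#' @export
transporter_reaction_count <- function(entity, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  length(idx$trans_rxns[[resolve_lnode(entity, idx)]])
}

#' @rdname specificity-counts
#' @export
modulated_enzyme_count <- function(entity, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  l <- resolve_lnode(entity, idx)
  rg <- idx$regulations
  length(unique(rg$regulatee[rg$regulator == l & rg$mode == "enzyme-modulation"]))
}

#' @rdname specificity-counts
#' @export
cofactor_enzyme_count <- function(entity, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  l <- resolve_lnode(entity, idx)
  rg <- idx$regulations
  length(unique(rg$regulatee[rg$regulator == l & rg$mode == "cofactor"]))
}

#' @rdname specificity-counts
#' @export
regulated_gene_count <- function(entity, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  l <- resolve_lnode(entity, idx)
  rg <- idx$regulations
  keep <- rg$regulator == l &
    rg$mode %in% c("transcriptional", "translational", "sigma-factor")
  length(unique(rg$regulatee[keep]))
}

#' @rdname specificity-counts
#' @export
regulator_count <- function(entity, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  l <- resolve_lnode(entity, idx)
  rg <- idx$regulations
  keep <- rg$regulatee == l &
    rg$mode %in% c("transcriptional", "translational", "sigma-factor")
  nrow(dplyr::distinct(rg[keep, c("regulator", "mode")]))
}
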
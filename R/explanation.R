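substrate_edge_types <- c("reactant-of-producing", "reactant-of-consuming",
                          "product-of-consuming", "enzyme-of-producing",
                          "enzyme-of-consuming", "transporter")

reaction_of_via <- function(via, type) {
  ifelse(type %in% substrate_edge_types, sub(":(fwd|rev)$", "", via),
         NA_character_)
}

#' Partition a filtered graph into metabolic and regulatory components
#'
#' Phase 3 starts by splitting the filtered graph's nodes into two groups:
#' those directly associated with a metabolic reaction underlying one of its
#' edges (as reactant, product or enzyme), and all others. Each group is then
#' split into connected components under the filtered edges restricted to the
#' group; edges crossing the groups are kept as inter-component links. A node
#' that is both reaction-associated and regulated is assigned to the
#' metabolic group.
#'
#' @param g2 A `filtered_graph`.
#' @param net The `metreg_network` it was derived from.
#' @return A list with `metabolic` and `regulatory` (each a list of
#'   components: `nodes`, `edges`, `reactions`), and `inter_edges`.
#' @export
partition_components <- function(g2, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  empty <- list(metabolic = list(), regulatory = list(),
                inter_edges = g2$edges[0, , drop = FALSE])
  if (!nrow(g2$nodes)) return(empty)
  rxn_ids <- unique(stats::na.omit(reaction_of_via(g2$edges$via,
                                                   g2$edges$type)))
  rxn_nodes <- character()
  for (rid in rxn_ids) {
    r <- idx$reactions[[rid]]
    rxn_nodes <- c(rxn_nodes, r$reactants, r$products, r$enzymes)
  }
  met_ids <- intersect(g2$nodes$id, unique(rxn_nodes))
  reg_ids <- setdiff(g2$nodes$id, met_ids)

  split_components <- function(ids) {
    if (!length(ids)) return(list())
    ed <- g2$edges[g2$edges$from %in% ids & g2$edges$to %in% ids, ,
                   drop = FALSE]
    g <- igraph::graph_from_data_frame(
      ed[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = ids))
    memb <- igraph::components(g)$membership
    purrr::map(sort(unique(memb)), function(m) {
      nd <- sort(names(memb)[memb == m])
      ce <- ed[ed$from %in% nd & ed$to %in% nd, , drop = FALSE]
      list(nodes = nd, edges = ce,
           reactions = sort(unique(stats::na.omit(
             reaction_of_via(ce$via, ce$type)))))
    })
  }
  inter <- g2$edges[(g2$edges$from %in% met_ids) !=
                      (g2$edges$to %in% met_ids), , drop = FALSE]
  list(metabolic = split_components(met_ids),
       regulatory = split_components(reg_ids),
       inter_edges = inter)
}

#' Assemble a metabolic component into a temporary pathway
#'
#' Collects the reactions underlying a metabolic component and orders them
#' into a chain by shared substrates. Drawing a reaction requires its main
#' reactant and product even when they were filtered out, so a primary
#' substrate is forced into the display set for any reaction side with no
#' member in the filtered graph (the lexicographically first non-ubiquitous
#' substrate); enzymes and side metabolites outside the filtered graph are
#' suppressed rather than drawn.
#'
#' @param component One metabolic component from [partition_components()].
#' @param g2 The `filtered_graph`.
#' @param net The `metreg_network`.
#' @return A `temp_pathway`: `reactions` (ordered ids), `display_nodes`,
#'   `suppressed`, `forced_in`.
#' @export
assemble_temp_pathway <- function(component, g2, net) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  rids <- component$reactions
  in_g2 <- function(ids) ids[ids %in% g2$nodes$id]
  display <- component$nodes
  forced <- character()
  suppressed <- character()
  for (rid in rids) {
    r <- idx$reactions[[rid]]
    for (side in list(r$reactants, r$products)) {
      present <- in_g2(side)
      if (!length(present)) {
        cand <- sort(side[!vapply(side, function(s)
          isTRUE(idx$ubiquitous[[s]]), logical(1))])
        if (length(cand)) forced <- c(forced, cand[1])
      }
    }
    side_subs <- setdiff(c(r$reactants, r$products),
                         c(display, forced))
    suppressed <- c(suppressed, side_subs,
                    setdiff(r$enzymes, c(display, forced)))
  }
  forced <- setdiff(unique(forced), display)
  # reaction order: chain by shared primary substrates
  order_rids <- rids
  if (length(rids) > 1) {
    prim <- function(rid) {
      r <- idx$reactions[[rid]]
      union(in_g2(c(r$reactants, r$products)),
            intersect(c(r$reactants, r$products), forced))
    }
    adj <- purrr::map(rids, prim)
    names(adj) <- rids
    pairs <- purrr::map_dfr(utils::combn(rids, 2, simplify = FALSE),
                            function(p) {
      if (length(intersect(adj[[p[1]]], adj[[p[2]]])))
        tibble::tibble(from = p[1], to = p[2]) else NULL
    })
    if (nrow(pairs)) {
      g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                         vertices = data.frame(name = rids))
      order_rids <- names(igraph::dfs(g, root = sort(rids)[1],
                                      unreachable = TRUE)$order)
    } else {
      order_rids <- sort(rids)
    }
  }
  structure(
    list(reactions = order_rids,
         display_nodes = sort(unique(c(display, forced))),
         suppressed = sort(unique(setdiff(suppressed, c(display, forced)))),
         forced_in = sort(forced)),
    class = "temp_pathway")
}

arrowhead_map <- c(
  "reactant-of-producing" = "normal", "reactant-of-consuming" = "normal",
  "product-of-consuming" = "normal", "enzyme-of-producing" = "vee",
  "enzyme-of-consuming" = "vee", "transporter" = "diamond",
  "enzyme-activator" = "odot", "enzyme-inhibitor" = "tee",
  "cofactor" = "odiamond", "transcriptional-regulator" = "empty",
  "translational-regulator" = "empty", "sigma-factor" = "empty",
  "complex-component" = "dot", "transcription-unit" = "none")

sign_color_map <- c("+" = "forestgreen", "-" = "red3",
                    "ambiguous" = "gray40")

#' Build the styled explanation graph
#'
#' Phase 3 output: the filtered graph partitioned into metabolic temporary
#' pathways and regulatory components, with display styles resolved. Target
#' entities and covering-set influencers are highlighted; when directions of
#' change were supplied, increased entities are coloured green and decreased
#' entities red. Every edge receives exactly one arrowhead class (by
#' influence type) and one colour class (by sign: activation green,
#' inhibition red, ambiguous grey).
#'
#' @param g2 A `filtered_graph`.
#' @param net The `metreg_network`.
#' @param target_specs Target tibble ([target_spec()]); used for highlight
#'   and direction colouring.
#' @param cover Character vector of covering-set influencer ids (undirected
#'   runs); highlighted like targets.
#' @return An `explanation_graph`: `components` (tibble: `component`,
#'   `kind`, `n_nodes`, `nodes`, `reactions`), `pathways` (temp_pathway list),
#'   `nodes` (id, kind, component, highlight, direction, fillcolor),
#'   `edges` (with `arrowhead`, `color`, `component`), `inter_edges`.
#' @export
build_explanation_graph <- function(g2, net, target_specs = NULL,
                                    cover = character()) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  part <- partition_components(g2, idx)
  target_specs <- target_specs %||% target_spec(character())

  comp_tbl <- list()
  node_rows <- list()
  edge_rows <- list()
  pathways <- list()
  ci <- 0
  add_component <- function(comp, kind) {
    ci <<- ci + 1
    cid <- sprintf("%s-%d", kind, ci)
    pw <- NULL
    nodes <- comp$nodes
    if (kind == "metabolic") {
      pw <- assemble_temp_pathway(comp, g2, idx)
      pathways[[cid]] <<- pw
      nodes <- pw$display_nodes
    }
    comp_tbl[[length(comp_tbl) + 1]] <<- tibble::tibble(
      component = cid, kind = kind, n_nodes = length(nodes),
      nodes = list(nodes), reactions = list(comp$reactions))
    node_rows[[length(node_rows) + 1]] <<- tibble::tibble(
      id = nodes, component = cid)
    if (nrow(comp$edges))
      edge_rows[[length(edge_rows) + 1]] <<-
        dplyr::mutate(comp$edges, component = cid)
  }
  for (comp in part$metabolic) add_component(comp, "metabolic")
  for (comp in part$regulatory) add_component(comp, "regulatory")

  nodes <- dplyr::bind_rows(node_rows)
  if (!nrow(nodes)) nodes <- tibble::tibble(id = character(),
                                            component = character())
  nodes <- dplyr::distinct(nodes, .data$id, .keep_all = TRUE)
  hl <- function(id) {
    dplyr::case_when(
      id %in% target_specs$entity[target_specs$role == "condition"] ~ "condition",
      id %in% target_specs$entity[target_specs$role == "effect"] ~ "effect",
      id %in% cover ~ "influencer",
      TRUE ~ "none")
  }
  dirs <- stats::setNames(target_specs$direction, target_specs$entity)
  nodes <- nodes |>
    dplyr::mutate(
      kind = purrr::map_chr(.data$id, function(n)
        if (n %in% idx$lnodes) idx$kind[[n]] else "transcription-unit"),
      highlight = hl(.data$id),
      direction = dplyr::coalesce(dirs[.data$id], "unspecified"),
      fillcolor = dplyr::case_when(
        .data$direction == "up" ~ "palegreen",
        .data$direction == "down" ~ "lightcoral",
        .data$highlight != "none" ~ "khaki",
        TRUE ~ "white")) |>
    dplyr::arrange(.data$component, .data$id)

  style_edges <- function(ed, component = NA_character_) {
    if (!nrow(ed)) {
      return(tibble::tibble(from = character(), to = character(),
                            type = character(), sign = character(),
                            via = character(), cost = numeric(),
                            arrowhead = character(), color = character(),
                            component = character()))
    }
    dplyr::mutate(ed,
                  arrowhead = unname(arrowhead_map[.data$type]),
                  color = unname(sign_color_map[.data$sign]))
  }
  edges <- dplyr::bind_rows(edge_rows)
  edges <- if (nrow(edges)) style_edges(edges) else
    style_edges(g2$edges[0, , drop = FALSE])
  inter <- style_edges(dplyr::mutate(part$inter_edges,
                                     component = "inter"))

  structure(
    list(components = dplyr::bind_rows(comp_tbl) %||% tibble::tibble(),
         pathways = pathways, nodes = nodes, edges = edges,
         inter_edges = inter, targets = target_specs, cover = cover),
    class = "explanation_graph")
}

#' @export
print.explanation_graph <- function(x, ...) {
  nm <- sum(x$components$kind == "metabolic")
  nr <- sum(x$components$kind == "regulatory")
  cat("<explanation_graph>", nrow(x$nodes), "nodes,",
      nrow(x$edges) + nrow(x$inter_edges), "edges;",
      nm, "metabolic +", nr, "regulatory components\n")
  invisible(x)
}

#' @method glance explanation_graph
#' @export
glance.explanation_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges) + nrow(x$inter_edges),
    n_metabolic = sum(x$components$kind == "metabolic"),
    n_regulatory = sum(x$components$kind == "regulatory"),
    n_highlighted = sum(x$nodes$highlight != "none"))
}

#' Re-run filtering and display for a subset of the original targets
#'
#' The expensive influence graph is cached and reused: only the filtering
#' and display phases are recomputed for the selected targets. Selecting the
#' full original set reproduces the original result.
#'
#' @param g1 The cached `metreg_graph`.
#' @param net The `metreg_network`.
#' @param selected Target tibble (subset of the original targets).
#' @param offset,max_paths,parity_filter,C_max See [filter_directed()] /
#'   [filter_undirected()].
#' @return A list with `g2` and `g3` (plus `scores`/`cover` in undirected
#'   mode).
#' @export
reselect_subset <- function(g1, net, selected, offset = 2, max_paths = 25,
                            parity_filter = TRUE, C_max = g1$C_max) {
  if (!nrow(selected)) rlang::abort("selection is empty")
  if (g1$mode == "directed") {
    conds <- selected[selected$role == "condition", , drop = FALSE]
    effs <- selected[selected$role == "effect", , drop = FALSE]
    g2 <- filter_directed(g1, conds, effs, offset, max_paths, parity_filter)
    g3 <- build_explanation_graph(g2, net, selected)
    list(g2 = g2, g3 = g3)
  } else {
    res <- filter_undirected(g1, selected, offset, max_paths, parity_filter,
                             C_max)
    g3 <- build_explanation_graph(res$g2, net, selected, res$cover$entity)
    c(res, list(g3 = g3))
  }
}
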
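#' The fourteen influence-edge types
#'
#' Influence edges run from the influenced entity to its influencer, the
#' direction in which the graph is grown outward from the effect entities.
#' Substrate-role types apply when the influenced entity is a reaction
#' substrate (including proteins in ligand-binding reactions); the regulatory
#' types apply to genes, gene products and complexes. The activator/inhibitor
#' pricing row is split into two codes by sign; transcription-unit links are
#' correlational dead-ends used only in undirected mode.
#'
#' @return Character vector of the 14 type codes, in fixed display order.
#' @export
influence_types <- function() {
  c("reactant-of-producing", "reactant-of-consuming", "product-of-consuming",
    "enzyme-of-producing", "enzyme-of-consuming", "transporter",
    "enzyme-activator", "enzyme-inhibitor", "cofactor",
    "transcriptional-regulator", "translational-regulator", "sigma-factor",
    "complex-component", "transcription-unit")
}

#' Default edge-sign policy
#'
#' Maps each influence type to the sign of the influencer's effect on the
#' influenced entity (`+`, `-`, or `ambiguous`). Transcriptional and
#' translational edges take the sign of the underlying regulation record
#' (entry `"regulation"`); any edge derived from a reversible reaction is
#' overridden to `ambiguous`, since such reactions can support either parity.
#' The policy is a plain named vector so it can be replaced wholesale or
#' loaded from a JSON override file with [read_sign_policy()].
#'
#' @return A named character vector keyed by influence type.
#' @export
default_sign_policy <- function() {
  c("reactant-of-producing" = "+", "reactant-of-consuming" = "-",
    "product-of-consuming" = "ambiguous",
    "enzyme-of-producing" = "+", "enzyme-of-consuming" = "-",
    "transporter" = "+",
    "enzyme-activator" = "+", "enzyme-inhibitor" = "-", "cofactor" = "+",
    "transcriptional-regulator" = "regulation",
    "translational-regulator" = "regulation",
    "sigma-factor" = "+", "complex-component" = "+",
    "transcription-unit" = "ambiguous")
}

#' Read a sign-policy override file
#'
#' @param path JSON file mapping influence-type codes to `"+"`, `"-"`,
#'   `"ambiguous"` or `"regulation"`; unlisted types keep their defaults.
#' @return A complete named sign-policy vector.
#' @export
read_sign_policy <- function(path) {
  pol <- default_sign_policy()
  over <- unlist(jsonlite::fromJSON(path, simplifyVector = TRUE))
  bad <- setdiff(names(over), names(pol))
  if (length(bad))
    rlang::abort(glue::glue("unknown influence type in sign policy: {bad[1]}"))
  pol[names(over)] <- over
  pol
}

edge_tbl <- function(from = character(), to = character(), type = character(),
                     sign = character(), via = character(),
                     reversible = logical()) {
  tibble::tibble(from = from, to = to, type = type, sign = sign, via = via,
                 reversible = reversible)
}

#' Enumerate the influencers of a logical node
#'
#' Returns every licensed influence edge from `node` to its influencers:
#' substrate-role edges (reactants/products/enzymes/transporters of reactions
#' producing or consuming the node) when the node is a non-ubiquitous reaction
#' substrate — protein-binding reactions are skipped for small-molecule
#' nodes; regulator, sigma-factor, cofactor, enzyme-modulation and
#' complex-component edges for gene/protein/complex nodes; and, in undirected
#' mode only, cost-free transcription-unit links. Reversible reactions license
#' both the producing and the consuming reading of each substrate role (with
#' distinct provenance) and force the sign to `ambiguous`. Each edge carries
#' the id of the reaction, regulation, complex or transcription unit it was
#' drawn from.
#'
#' @param node A logical node id (or any entity id; it is coalesced first).
#' @param net A `metreg_network`.
#' @param mode `"directed"` or `"undirected"`.
#' @param sign_policy Named sign vector, see [default_sign_policy()].
#' @return A tibble with columns `from`, `to`, `type`, `sign`, `via`,
#'   `reversible`, ordered by (type, provenance, influencer).
#' @export
influencers_of <- function(node, net, mode = c("directed", "undirected"),
                           sign_policy = default_sign_policy()) {
  mode <- match.arg(mode)
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  x <- resolve_lnode(node, idx)
  out <- list(edge_tbl())
  add <- function(to, type, via, sign, reversible = FALSE) {
    if (length(to) == 0) return()
    out[[length(out) + 1]] <<- edge_tbl(rep(x, length(to)), to, type,
                                        rep(sign, length.out = length(to)),
                                        via, reversible)
  }
  pol <- function(type) unname(sign_policy[[type]])

  # -- substrate-role edges ---------------------------------------------
  if (!isTRUE(idx$ubiquitous[[x]])) {
    small <- idx$kind[[x]] == "metabolite"
    for (r in idx$reactions) {
      if (small && r$is_protein_binding) next
      in_react <- x %in% r$reactants
      in_prod <- x %in% r$products
      if (!in_react && !in_prod) next
      rev <- r$direction == "reversible"
      # the substrate sides that produce / consume x under the direction
      producing <- consuming <- list()
      if (r$direction %in% c("left-to-right", "reversible")) {
        if (in_prod) producing <- c(producing, list(list(side = r$reactants,
                                                         tag = "fwd")))
        if (in_react) consuming <- c(consuming, list(list(side = r$reactants,
                                                          opp = r$products,
                                                          tag = "fwd")))
      }
      if (r$direction %in% c("right-to-left", "reversible")) {
        if (in_react) producing <- c(producing, list(list(side = r$products,
                                                          tag = "rev")))
        if (in_prod) consuming <- c(consuming, list(list(side = r$products,
                                                         opp = r$reactants,
                                                         tag = "rev")))
      }
      via_tag <- function(tag) if (rev) paste0(r$id, ":", tag) else r$id
      keep <- function(ids) {
        ids <- setdiff(ids, x)
        ids[!vapply(ids, function(i) isTRUE(idx$ubiquitous[[i]]), logical(1))]
      }
      transported_here <- r$is_transport && x %in% r$transported
      esign <- function(type) if (rev) "ambiguous" else pol(type)
      for (p in producing) {
        add(keep(p$side), "reactant-of-producing", via_tag(p$tag),
            esign("reactant-of-producing"), rev)
        if (!transported_here)
          add(r$enzymes, "enzyme-of-producing", via_tag(p$tag),
              esign("enzyme-of-producing"), rev)
      }
      for (cns in consuming) {
        add(keep(cns$side), "reactant-of-consuming", via_tag(cns$tag),
            esign("reactant-of-consuming"), rev)
        add(keep(cns$opp), "product-of-consuming", via_tag(cns$tag),
            esign("product-of-consuming"), rev)
        if (!transported_here)
          add(r$enzymes, "enzyme-of-consuming", via_tag(cns$tag),
              esign("enzyme-of-consuming"), rev)
      }
      if (transported_here)
        add(r$enzymes, "transporter", r$id,
            if (rev) "ambiguous" else pol("transporter"), rev)
    }
  }

  # -- gene / protein / complex edges -----------------------------------
  if (idx$kind[[x]] != "metabolite") {
    rg <- idx$regulations
    tgt <- rg[rg$regulatee == x, , drop = FALSE]
    for (i in seq_len(nrow(tgt))) {
      g <- tgt[i, ]
      type <- switch(g$mode,
        "transcriptional" = "transcriptional-regulator",
        "translational"   = "translational-regulator",
        "sigma-factor"    = "sigma-factor",
        "cofactor"        = "cofactor",
        "enzyme-modulation" =
          if (g$sign == "+") "enzyme-activator" else "enzyme-inhibitor")
      sgn <- pol(type)
      if (identical(sgn, "regulation")) sgn <- g$sign
      add(g$regulator, type, g$id, sgn)
    }
    for (cx in idx$hetero_of[[x]] %||% list()) {
      add(setdiff(cx$components, x), "complex-component", cx$id,
          pol("complex-component"))
    }
    if (mode == "undirected") {
      for (tu in idx$tu_of_gene[[x]] %||% character()) {
        add(tu, "transcription-unit", tu, pol("transcription-unit"))
      }
    }
  }

  edges <- dplyr::bind_rows(out)
  ord <- order(match(edges$type, influence_types()), edges$via, edges$to)
  edges[ord, , drop = FALSE]
}

#' Price influence edges
#'
#' Applies the specificity-weighted cost formula for each edge type. Costs
#' are 1 (producing side, regulators, modulators) or 2 (consuming side) plus
#' a hub penalty proportional to how many reactions or genes the entities
#' involved touch, so lightest-weight paths avoid common metabolites and
#' global regulators when a more specific route exists:
#'
#' * reactant of producing reaction: `1 + (|Rx_sub| + |Ri_sub|)/20`
#' * reactant of consuming reaction: `1 + (|Rx_sub| + |Ri_sub|)/10`
#' * product of consuming reaction: `2 + (|Rx_sub| + |Ri_sub|)/10`
#' * enzyme of producing / consuming reaction: `1 + |Ri_enz|/20` /
#'   `2 + |Ri_enz|/20`
#' * transporter: `1 + |Ri_transport|/20`
#' * enzyme activator / inhibitor: `1 + |Enzs_i_modulated|/20`
#' * cofactor: `1 + |Enzs_i_cofactor|/20`
#' * transcriptional / translational regulator:
#'   `1 + (|Regs_x| + |Genes_i_regulated|)/20`
#' * sigma factor: `1 + |Genes_i_regulated|/20`
#' * complex component: `0.1`; transcription unit: `0`
#'
#' where substrate counts exclude the edge's own reaction. If the influencer
#' is one of the user-supplied input entities (condition or effect) the cost
#' is 0.1 regardless of the formula, biasing the search toward the entities of
#' interest; transcription-unit links stay at 0.
#'
#' @param edges A tibble from [influencers_of()].
#' @param net A `metreg_network`.
#' @param input_entities Logical node ids of the condition and effect
#'   entities.
#' @return `edges` with a `cost` column appended.
#' @export
edge_cost <- function(edges, net, input_entities = character()) {
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  nsub <- function(l, excl) count_excluding(idx$sub_rxns[[l]], excl)
  cost1 <- function(from, to, type, via) {
    rxn <- sub(":(fwd|rev)$", "", via)
    switch(type,
      "reactant-of-producing" = 1 + (nsub(from, rxn) + nsub(to, rxn)) / 20,
      "reactant-of-consuming" = 1 + (nsub(from, rxn) + nsub(to, rxn)) / 10,
      "product-of-consuming"  = 2 + (nsub(from, rxn) + nsub(to, rxn)) / 10,
      "enzyme-of-producing"   = 1 + length(idx$enz_rxns[[to]]) / 20,
      "enzyme-of-consuming"   = 2 + length(idx$enz_rxns[[to]]) / 20,
      "transporter"           = 1 + length(idx$trans_rxns[[to]]) / 20,
      "enzyme-activator"      = 1 + n_modulated(to) / 20,
      "enzyme-inhibitor"      = 1 + n_modulated(to) / 20,
      "cofactor"              = 1 + n_cofactored(to) / 20,
      "transcriptional-regulator" = 1 + (n_regs(from) + n_genes(to)) / 20,
      "translational-regulator"   = 1 + (n_regs(from) + n_genes(to)) / 20,
      "sigma-factor"          = 1 + n_genes(to) / 20,
      "complex-component"     = 0.1,
      "transcription-unit"    = 0,
      rlang::abort(glue::glue("unknown influence type \"{type}\""))
    )
  }
  rg <- idx$regulations
  n_modulated <- function(l)
    length(unique(rg$regulatee[rg$regulator == l & rg$mode == "enzyme-modulation"]))
  n_cofactored <- function(l)
    length(unique(rg$regulatee[rg$regulator == l & rg$mode == "cofactor"]))
  n_genes <- function(l)
    length(unique(rg$regulatee[rg$regulator == l &
      rg$mode %in% c("transcriptional", "translational", "sigma-factor")]))
  n_regs <- function(l)
    nrow(dplyr::distinct(rg[rg$regulatee == l &
      rg$mode %in% c("transcriptional", "translational", "sigma-factor"),
      c("regulator", "mode")]))

  cost <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (edges$type[i] == "transcription-unit") {
      cost[i] <- 0
    } else if (edges$to[i] %in% input_entities) {
      cost[i] <- 0.1
    } else {
      cost[i] <- cost1(edges$from[i], edges$to[i], edges$type[i], edges$via[i])
    }
  }
  dplyr::mutate(edges, cost = cost)
}

#' Sign of an influence edge
#'
#' Looks the edge type up in a sign policy; the sign describes the effect of
#' the influencer on the influenced entity (the reverse of the stored edge
#' direction). Edges derived from reversible reactions are `ambiguous`
#' regardless of policy, and transcriptional/translational edges take the
#' sign of their regulation record (already resolved by [influencers_of()]).
#'
#' @param edges A tibble of influence edges.
#' @param sign_policy Named sign vector.
#' @return `edges` with the `sign` column recomputed.
#' @export
edge_sign <- function(edges, sign_policy = default_sign_policy()) {
  sgn <- unname(sign_policy[edges$type])
  keep <- sgn == "regulation" | edges$reversible
  sgn[keep] <- edges$sign[keep]
  sgn[edges$reversible] <- "ambiguous"
  dplyr::mutate(edges, sign = sgn)
}
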
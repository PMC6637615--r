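# Independent oracles and fixture builders shared across tests.

# ---- hand-coded edge-cost expressions (kept independent of edge_cost) ----
oracle_cost_formulas <- list(
  "reactant-of-producing" = function(nx, ni) 1 + (nx + ni) / 20,
  "reactant-of-consuming" = function(nx, ni) 1 + (nx + ni) / 10,
  "product-of-consuming"  = function(nx, ni) 2 + (nx + ni) / 10,
  "enzyme-of-producing"   = function(ni)     1 + ni / 20,
  "enzyme-of-consuming"   = function(ni)     2 + ni / 20,
  "transporter"           = function(ni)     1 + ni / 20,
  "enzyme-activator"      = function(ni)     1 + ni / 20,
  "enzyme-inhibitor"      = function(ni)     1 + ni / 20,
  "cofactor"              = function(ni)     1 + ni / 20,
  "transcriptional-regulator" = function(nx, ni) 1 + (nx + ni) / 20,
  "translational-regulator"   = function(nx, ni) 1 + (nx + ni) / 20,
  "sigma-factor"          = function(ni)     1 + ni / 20,
  "complex-component"     = function()       0.1,
  "transcription-unit"    = function()       0
)

# Network in which metabolite X takes part in `nx` reactions besides the
# probe reaction and metabolite I in `ni` besides it; the probe reaction
# realises the requested substrate role of I relative to X.
make_substrate_fixture <- function(role = c("reactant-of-producing",
                                            "reactant-of-consuming",
                                            "product-of-consuming"),
                                   nx = 0, ni = 0) {
  role <- match.arg(role)
  net <- network() |> add_metabolite("X") |> add_metabolite("I")
  net <- switch(role,
    "reactant-of-producing" = add_reaction(net, "PROBE", "I", "X"),
    "reactant-of-consuming" = {
      net |> add_metabolite("Wp") |> add_reaction("PROBE", c("X", "I"), "Wp")
    },
    "product-of-consuming" = add_reaction(net, "PROBE", "X", "I"))
  for (k in seq_len(nx)) {
    f <- paste0("FX", k)
    net <- net |> add_metabolite(f) |>
      add_reaction(paste0("RX", k), "X", f)
  }
  for (k in seq_len(ni)) {
    f <- paste0("FI", k)
    net <- net |> add_metabolite(f) |>
      add_reaction(paste0("RI", k), "I", f)
  }
  validate_network(net)
}

# Enzyme/transporter E catalysing the probe plus `n_extra` further reactions.
make_enzyme_fixture <- function(consuming = FALSE, n_extra = 0,
                                transport = FALSE) {
  net <- network() |> add_metabolite("X") |> add_metabolite("S") |>
    add_gene_product("E")
  net <- if (transport) {
    add_reaction(net, "PROBE", "S", "X", enzymes = "E_p",
                 is_transport = TRUE, transported = "X")
  } else if (consuming) {
    add_reaction(net, "PROBE", "X", "S", enzymes = "E_p")
  } else {
    add_reaction(net, "PROBE", "S", "X", enzymes = "E_p")
  }
  for (k in seq_len(n_extra)) {
    a <- paste0("A", k); b <- paste0("B", k)
    net <- net |> add_metabolite(a) |> add_metabolite(b) |>
      add_reaction(paste0("RE", k), a, b, enzymes = "E_p",
                   is_transport = transport,
                   transported = if (transport) b else character())
  }
  validate_network(net)
}

# Regulator I modulating / cofactoring / regulating the probe target X plus
# n_extra other enzymes or genes; X additionally has nx_regs other regulators.
make_regulation_fixture <- function(mode, n_extra = 0, nx_regs = 0,
                                    sign = "+") {
  net <- network() |> add_gene_product("X") |> add_gene_product("I") |>
    add_metabolite("S0") |> add_metabolite("P0") |>
    add_reaction("RX", "S0", "P0", enzymes = "X_p")
  reg_mode <- switch(mode, "enzyme-activator" = , "enzyme-inhibitor" =
                       "enzyme-modulation", "cofactor" = "cofactor",
                     "transcriptional-regulator" = "transcriptional",
                     "translational-regulator" = "translational",
                     "sigma-factor" = "sigma-factor")
  tgt <- if (reg_mode %in% c("enzyme-modulation", "cofactor")) "X_p" else "X"
  net <- add_regulation(net, "PROBE", "I_p", tgt, reg_mode, sign)
  for (k in seq_len(n_extra)) {
    g <- paste0("G", k)
    net <- net |> add_gene_product(g)
    if (reg_mode %in% c("enzyme-modulation", "cofactor")) {
      a <- paste0("MA", k); b <- paste0("MB", k)
      net <- net |> add_metabolite(a) |> add_metabolite(b) |>
        add_reaction(paste0("RG", k), a, b, enzymes = paste0(g, "_p")) |>
        add_regulation(paste0("EXI", k), "I_p", paste0(g, "_p"), reg_mode,
                       sign)
    } else {
      net <- add_regulation(net, paste0("EXI", k), "I_p", g, "transcriptional")
    }
  }
  for (k in seq_len(nx_regs)) {
    t <- paste0("T", k)
    net <- net |> add_gene_product(t) |>
      add_regulation(paste0("EXX", k), paste0(t, "_p"), "X", "transcriptional")
  }
  validate_network(net)
}

# probe-edge cost: the cost of the unique PROBE-derived edge of `type`
# among the influencers of X
probe_cost <- function(net, type, inputs = character()) {
  e <- influencers_of("X", net, mode = "undirected")
  e <- edge_cost(e, net, inputs)
  hit <- e[e$type == type & grepl("^PROBE", e$via) |
             e$type == type & e$via == "PROBE", , drop = FALSE]
  stopifnot(nrow(hit) == 1)
  hit$cost
}

# ---- brute-force G1 construction (independent of build_metreg_graph) ----
# Iterative fixpoint: edges are enumerated with the shared pricing layer but
# the graph algorithm is plain repeated Bellman-Ford relaxation plus a
# node-creation sweep, with no priority queue and no recursion.
oracle_g1 <- function(net, effects, inputs = effects, C_max = 20,
                      mode = "directed") {
  lmap <- logical_node_map(net)
  roots <- unique(unname(lmap[effects]))
  inputs <- unique(unname(lmap[inputs]))
  influencer_edges <- function(n) {
    if (!n %in% names(lmap) && !n %in% unname(lmap)) return(NULL)  # TU node
    e <- influencers_of(n, net, mode)
    e <- e[e$to != e$from, , drop = FALSE]
    edge_cost(e, net, inputs)
  }
  bellman <- function(edges, sources) {
    dist <- stats::setNames(rep(Inf, length(sources)), sources)
    repeat {
      changed <- FALSE
      for (s in sources) dist[s] <- 0
      if (is.null(edges) || nrow(edges) == 0) break
      nodes_all <- unique(c(edges$from, edges$to, sources))
      miss <- setdiff(nodes_all, names(dist))
      if (length(miss)) dist[miss] <- Inf
      for (i in seq_len(nrow(edges))) {
        cand <- dist[edges$from[i]] + edges$cost[i]
        if (cand < dist[edges$to[i]] - 1e-12) {
          dist[edges$to[i]] <- cand
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    dist
  }
  nodes <- roots
  cache <- list()
  repeat {
    # candidate edges emanating from current nodes (TU nodes never expand)
    for (n in setdiff(nodes, names(cache))) {
      cache[[n]] <- influencer_edges(n)
    }
    all_edges <- dplyr::bind_rows(cache[nodes])
    internal <- all_edges[all_edges$to %in% nodes, , drop = FALSE]
    dist <- bellman(internal, roots)
    dist[setdiff(nodes, names(dist))] <- Inf
    reach <- dist[all_edges$from] + all_edges$cost
    grow <- unique(all_edges$to[reach < C_max & !all_edges$to %in% nodes])
    if (!length(grow)) break
    nodes <- c(nodes, grow)
  }
  for (n in setdiff(nodes, names(cache))) cache[[n]] <- influencer_edges(n)
  all_edges <- dplyr::bind_rows(cache[nodes])
  edges <- all_edges[all_edges$to %in% nodes, , drop = FALSE]
  C <- bellman(edges, roots)[nodes]
  PC <- lapply(stats::setNames(roots, roots),
               function(r) bellman(edges, r)[nodes])
  list(nodes = sort(nodes), C = C, PC = PC, edges = edges)
}

# ---- exhaustive simple-path enumeration (independent of enumerate_paths) --
oracle_paths <- function(g1, root, terminus, offset) {
  if (!terminus %in% g1$nodes$id) return(list())
  by_from <- split(seq_len(nrow(g1$edges)), g1$edges$from)
  found <- list()
  rec <- function(node, visited, idx, cost) {
    if (node == terminus) {
      if (length(idx)) found[[length(found) + 1]] <<- list(idx = idx,
                                                           cost = cost)
      return()
    }
    for (ei in by_from[[node]]) {
      v <- g1$edges$to[ei]
      if (v %in% visited) next
      rec(v, c(visited, v), c(idx, ei), cost + g1$edges$cost[ei])
    }
  }
  if (root != terminus) rec(root, root, integer(), 0)
  if (!length(found)) return(list())
  costs <- vapply(found, `[[`, numeric(1), "cost")
  keep <- costs <= min(costs) + offset + 1e-9
  found[keep]
}

path_edge_key <- function(steps) {
  paste(steps$from, steps$to, steps$type, steps$via, sep = "\r",
        collapse = "\n")
}

expect_sets_equal <- function(a, b) {
  expect_true(setequal(a, b),
              info = paste0("only in first: ",
                            paste(setdiff(a, b), collapse = ", "),
                            "; only in second: ",
                            paste(setdiff(b, a), collapse = ", ")))
}
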
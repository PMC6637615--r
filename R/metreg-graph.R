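#' Build the weighted influence graph around the effect entities
#'
#' Phase 1 of the explanation pipeline. Starting from the effect entities
#' (the roots), the combined metabolic + regulatory influence graph is grown
#' outward in best-first order with a priority queue: the cheapest unexpanded
#' node is removed, its influencers are enumerated ([influencers_of()]) and
#' priced ([edge_cost()]), a new node is created only when the path cost to
#' it stays below `C_max`, and each node tracks both its minimum cost to any
#' root (`C`) and its minimum path cost to every individual root (`PC`).
#' Path-cost improvements are propagated recursively to already-expanded
#' descendants, and a node whose minimum cost drops is re-inserted into the
#' queue so the final costs equal true shortest-path distances even with
#' near-zero edge weights. Edges between two existing nodes are always
#' recorded; only node *creation* is cutoff-guarded. Transcription-unit nodes
#' are dead-ends: they receive path costs but are never expanded.
#'
#' @param effects Character vector of effect entity ids (coalesced to logical
#'   nodes; these become the roots).
#' @param net A `metreg_network`.
#' @param input_entities Entity ids whose incoming edges get the 0.1
#'   input-entity override; defaults to the effects, and should include the
#'   condition entities in directed mode.
#' @param C_max Maximum path cost; nodes are only created below it.
#'   Defaults to 20, an approximate upper bound on the number of unit-cost
#'   steps linking condition and effect.
#' @param mode `"directed"` or `"undirected"`; undirected mode adds
#'   transcription-unit links.
#' @param sign_policy Edge-sign policy, see [default_sign_policy()].
#' @return A `metreg_graph`: list with `roots`, `nodes` (tibble `id`, `kind`,
#'   `C`), `pc` (tibble `root`, `node`, `cost`), `edges` (tibble `from`,
#'   `to`, `type`, `sign`, `via`, `cost`), plus `C_max`, `mode` and the
#'   coalesced `input_entities`.
#' @examples
#' g1 <- build_metreg_graph("M0", toy_network(),
#'                          input_entities = c("M0", "TF0"))
#' tidy(g1)
#' @export
build_metreg_graph <- function(effects, net, input_entities = effects,
                               C_max = 20, mode = c("directed", "undirected"),
                               sign_policy = default_sign_policy()) {
  mode <- match.arg(mode)
  if (length(effects) == 0) rlang::abort("effects must be non-empty")
  if (!is.numeric(C_max) || C_max <= 0) rlang::abort("C_max must be positive")
  idx <- if (inherits(net, "metreg_network")) net_index(net) else net
  roots <- unique(vapply(effects, resolve_lnode, character(1), idx = idx))
  inputs <- unique(vapply(input_entities, resolve_lnode, character(1),
                          idx = idx))

  C <- new.env(parent = emptyenv())      # node -> min cost to any root
  PC <- new.env(parent = emptyenv())     # node -> named vector root -> cost
  OUT <- new.env(parent = emptyenv())    # node -> integer edge indices out
  node_kind <- new.env(parent = emptyenv())
  edges <- list()
  edge_keys <- new.env(parent = emptyenv())
  inf_cache <- new.env(parent = emptyenv())

  qcost <- numeric(0)                    # priority queue: named cost vector

  enqueue <- function(n, cost) {
    cur <- qcost[n]
    if (is.na(cur) || cost < cur) qcost[n] <<- cost
  }

  node_exists <- function(n) !is.null(C[[n]])

  kind_of <- function(n) {
    if (n %in% idx$lnodes) idx$kind[[n]] else "transcription-unit"
  }

  # propagate improved per-root path costs along stored out-edges; strict
  # improvement guards termination on cycles
  propagate <- function(start, roots_touched) {
    stack <- list(list(node = start, roots = roots_touched))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (ei in OUT[[cur$node]] %||% integer()) {
        e <- edges[[ei]]
        child <- e$to
        improved <- character()
        pc_child <- PC[[child]]
        pc_par <- PC[[cur$node]]
        for (r in cur$roots) {
          cand <- pc_par[[r]] + e$cost
          old <- pc_child[r]
          if (is.na(old) || cand < old) {
            pc_child[r] <- cand
            improved <- c(improved, r)
          }
        }
        if (length(improved)) {
          PC[[child]] <- pc_child
          newC <- min(pc_child)
          if (newC < C[[child]]) {
            C[[child]] <- newC
            if (kind_of(child) != "transcription-unit") enqueue(child, newC)
          }
          stack[[length(stack) + 1]] <- list(node = child, roots = improved)
        }
      }
    }
  }

  for (r in roots) {
    C[[r]] <- 0
    PC[[r]] <- stats::setNames(0, r)
    node_kind[[r]] <- kind_of(r)
    enqueue(r, 0)
  }
  # a root reachable from another root still needs its self path cost of 0
  for (r in roots) {
    pc <- PC[[r]]
    pc[r] <- 0
    PC[[r]] <- pc
  }

  while (length(qcost)) {
    ord <- order(qcost, names(qcost))
    n <- names(qcost)[ord[1]]
    qcost <- qcost[names(qcost) != n]
    if (is.null(inf_cache[[n]])) {
      inf <- influencers_of(n, idx, mode, sign_policy)
      inf <- inf[inf$to != inf$from, , drop = FALSE]
      inf_cache[[n]] <- edge_cost(inf, idx, inputs)
    }
    inf <- inf_cache[[n]]
    Cn <- C[[n]]
    for (i in seq_len(nrow(inf))) {
      np <- inf$to[i]
      ecost <- inf$cost[i]
      created <- FALSE
      if (!node_exists(np)) {
        if (Cn + ecost < C_max) {
          C[[np]] <- Cn + ecost
          PC[[np]] <- stats::setNames(numeric(), character())
          node_kind[[np]] <- kind_of(np)
          if (node_kind[[np]] != "transcription-unit")
            enqueue(np, C[[np]])
          created <- TRUE
        } else {
          next
        }
      }
      key <- paste(n, np, inf$type[i], inf$via[i], sep = "\r")
      if (is.null(edge_keys[[key]])) {
        edge_keys[[key]] <- TRUE
        edges[[length(edges) + 1]] <- list(
          from = n, to = np, type = inf$type[i], sign = inf$sign[i],
          via = inf$via[i], cost = ecost)
        OUT[[n]] <- c(OUT[[n]] %||% integer(), length(edges))
      }
      if (!created && Cn + ecost < C[[np]]) {
        C[[np]] <- Cn + ecost
        if (node_kind[[np]] != "transcription-unit")
          enqueue(np, C[[np]])
      }
      # per-root path-cost updates, then recursive propagation
      improved <- character()
      pc_np <- PC[[np]]
      pc_n <- PC[[n]]
      for (r in names(pc_n)) {
        cand <- pc_n[[r]] + ecost
        old <- pc_np[r]
        if (is.na(old) || cand < old) {
          pc_np[r] <- cand
          improved <- c(improved, r)
        }
      }
      if (length(improved)) {
        PC[[np]] <- pc_np
        propagate(np, improved)
      }
    }
  }

  node_ids <- sort(ls(C))
  nodes <- tibble::tibble(
    id = node_ids,
    kind = unname(vapply(node_ids, function(n) node_kind[[n]], character(1))),
    C = unname(vapply(node_ids, function(n) C[[n]], numeric(1)))
  )
  pc <- purrr::map_dfr(node_ids, function(n) {
    v <- PC[[n]]
    if (length(v) == 0) return(NULL)
    tibble::tibble(root = names(v), node = n, cost = unname(v))
  }) |> dplyr::arrange(.data$root, .data$node)
  etbl <- dplyr::bind_rows(purrr::map(edges, tibble::as_tibble)) |>
    (\(d) if (nrow(d)) dplyr::arrange(d, .data$from, .data$to, .data$type,
                                      .data$via) else
      tibble::tibble(from = character(), to = character(), type = character(),
                     sign = character(), via = character(), cost = numeric()))()
  structure(
    list(roots = sort(roots), nodes = nodes, pc = pc, edges = etbl,
         C_max = C_max, mode = mode, input_entities = sort(inputs),
         sign_policy = sign_policy),
    class = "metreg_graph")
}

#' Minimum path cost from a root to a node
#'
#' @param g1 A `metreg_graph`.
#' @param root,node Logical node ids.
#' @return The stored path cost, or `NA` when the node has no path from that
#'   root.
#' @export
path_cost <- function(g1, root, node) {
  hit <- g1$pc$cost[g1$pc$root == root & g1$pc$node == node]
  if (length(hit)) hit[1] else NA_real_
}

#' @export
print.metreg_graph <- function(x, ...) {
  cat("<metreg_graph>", x$mode, "mode, C_max =", x$C_max, "\n")
  cat("  roots:", paste(x$roots, collapse = ", "), "\n")
  cat("  nodes:", nrow(x$nodes), " edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Tidy a MetReg graph into its node table
#'
#' @param x A `metreg_graph`.
#' @param ... Unused.
#' @return A tibble with one row per node (`id`, `kind`, `C`) and one
#'   `pc_<root>` column per root.
#' @method tidy metreg_graph
#' @export
tidy.metreg_graph <- function(x, ...) {
  wide <- x$pc |>
    dplyr::mutate(root = paste0("pc_", .data$root)) |>
    tidyr::pivot_wider(names_from = "root", values_from = "cost",
                       names_sort = TRUE)
  dplyr::left_join(x$nodes, wide, by = c(id = "node")) |>
    dplyr::arrange(.data$C, .data$id)
}

#' @method glance metreg_graph
#' @export
glance.metreg_graph <- function(x, ...) {
  tibble::tibble(mode = x$mode, C_max = x$C_max, n_roots = length(x$roots),
                 n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 max_C = if (nrow(x$nodes)) max(x$nodes$C) else NA_real_)
}

#' Dump a MetReg graph as TSV
#'
#' Writes `nodes.tsv` (id, kind, C, one path-cost column per root) and
#' `edges.tsv` (from, to, type, sign, via, cost).
#'
#' @param g1 A `metreg_graph`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_metreg_tsv <- function(g1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(g1), file.path(dir, "nodes.tsv"))
  readr::write_tsv(g1$edges, file.path(dir, "edges.tsv"))
  invisible(dir)
}
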
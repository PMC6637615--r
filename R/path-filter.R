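#' Target specifications
#'
#' Builds the tidy table of condition/effect targets used by the filtering
#' phase. Directed mode requires at least one condition and one effect;
#' undirected mode takes effects only. Directions (`up`/`down`) are optional
#' and enable parity filtering and display colouring.
#'
#' @param entity Entity ids.
#' @param role `"condition"` or `"effect"` (recycled).
#' @param direction `"up"`, `"down"` or `"unspecified"` (recycled).
#' @return A tibble with columns `entity`, `role`, `direction`.
#' @export
target_spec <- function(entity, role = "effect", direction = "unspecified") {
  stopifnot(all(role %in% c("condition", "effect")),
            all(direction %in% c("up", "down", "unspecified")))
  tibble::tibble(entity = entity, role = role, direction = direction)
}

#' Read a targets TSV file
#'
#' Expects columns `entity`, `role` and optionally `direction`.
#'
#' @param path TSV file path.
#' @return A target tibble as from [target_spec()].
#' @export
read_targets <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("entity", "role") %in% names(d)))
    rlang::abort("targets file needs columns `entity` and `role`")
  if (!"direction" %in% names(d)) d$direction <- "unspecified"
  d$direction[is.na(d$direction)] <- "unspecified"
  target_spec(d$entity, d$role, d$direction)
}

path_parity <- function(signs) {
  if (any(signs == "ambiguous")) return("ambiguous")
  if (sum(signs == "-") %% 2 == 0) "+" else "-"
}

reverse_distances <- function(g1, terminus) {
  # exact distance node -> terminus over the stored edges (reverse Dijkstra);
  # used as an admissible pruning bound during path enumeration
  dist <- stats::setNames(rep(Inf, nrow(g1$nodes)), g1$nodes$id)
  if (!terminus %in% names(dist)) return(dist)
  dist[terminus] <- 0
  by_to <- split(seq_len(nrow(g1$edges)), g1$edges$to)
  todo <- stats::setNames(0, terminus)
  while (length(todo)) {
    ord <- order(todo, names(todo))
    v <- names(todo)[ord[1]]
    dv <- todo[[v]]
    todo <- todo[names(todo) != v]
    if (dv > dist[v]) next
    for (ei in by_to[[v]] %||% integer()) {
      u <- g1$edges$from[ei]
      cand <- dv + g1$edges$cost[ei]
      if (cand < dist[u]) {
        dist[u] <- cand
        todo[u] <- cand
      }
    }
  }
  dist
}

#' Enumerate bounded-cost simple paths from a root to a terminus
#'
#' Finds every simple path from an effect root to `terminus` in the influence
#' graph whose total cost is at most the minimum path cost for the pair plus
#' `offset`. The offset admits slightly longer alternatives because the edge
#' weighting is deliberately blunt: the absolute lightest path is not always
#' the most biologically meaningful one. Enumeration is a depth-first
#' traversal pruned with exact remaining-distance lower bounds (a reverse
#' shortest-path pass from the terminus), so only branches that can still
#' finish within the bound are explored.
#'
#' @param g1 A `metreg_graph`.
#' @param root One of `g1$roots`.
#' @param terminus Target logical node (absence yields an empty result).
#' @param offset Cost slack above the per-pair minimum (default 2).
#' @param max_paths Truncation limit; when exceeded the result keeps the
#'   cheapest `max_paths` paths and gains attribute `truncated = TRUE`.
#' @return A tibble of path records: `root`, `terminus`, `total_cost`,
#'   `parity`, `n_edges`, and a list-column `steps` of edge tibbles.
#' @export
enumerate_paths <- function(g1, root, terminus, offset = 2, max_paths = 25) {
  stopifnot(inherits(g1, "metreg_graph"))
  if (!root %in% g1$roots)
    rlang::abort(glue::glue("\"{root}\" is not a root of the graph"))
  empty <- tibble::tibble(root = character(), terminus = character(),
                          total_cost = numeric(), parity = character(),
                          n_edges = integer(), steps = list())
  if (!terminus %in% g1$nodes$id) return(empty)
  min_cost <- path_cost(g1, root, terminus)
  if (is.na(min_cost)) return(empty)
  bound <- min_cost + offset + 1e-9
  h <- reverse_distances(g1, terminus)
  by_from <- split(seq_len(nrow(g1$edges)), g1$edges$from)

  found <- list()
  walk <- function(node, cost, edge_idx, on_path) {
    if (node == terminus && length(edge_idx)) {
      found[[length(found) + 1]] <<- edge_idx
      return()
    }
    for (ei in by_from[[node]] %||% integer()) {
      v <- g1$edges$to[ei]
      if (on_path[v] %||% FALSE) next
      c2 <- cost + g1$edges$cost[ei]
      if (c2 + h[v] > bound) next
      on_path[v] <- TRUE
      walk(v, c2, c(edge_idx, ei), on_path)
      on_path[v] <- FALSE
    }
  }
  seen <- stats::setNames(rep(FALSE, nrow(g1$nodes)), g1$nodes$id)
  seen[root] <- TRUE
  if (root == terminus) {
    # a root can be its own terminus only via the trivial empty path
    found <- list(integer())
  } else {
    walk(root, 0, integer(), seen)
  }

  if (!length(found)) return(empty)
  recs <- purrr::map(found, function(ix) {
    steps <- g1$edges[ix, , drop = FALSE]
    tibble::tibble(
      root = root, terminus = terminus,
      total_cost = sum(steps$cost),
      parity = path_parity(steps$sign),
      n_edges = nrow(steps), steps = list(steps)
    )
  }) |> dplyr::bind_rows()
  key <- purrr::map_chr(recs$steps, ~ paste(.x$from, .x$to, .x$type, .x$via,
                                            collapse = "|"))
  recs <- recs[order(recs$total_cost, key), , drop = FALSE]
  truncated <- nrow(recs) > max_paths
  if (truncated) recs <- recs[seq_len(max_paths), , drop = FALSE]
  attr(recs, "truncated") <- truncated
  recs
}

#' Is a path's parity consistent with the observed directions of change?
#'
#' An all-activating chain explains co-directional changes only; a net
#' inhibitory chain explains opposite changes; a path through any ambiguous
#' edge (e.g. a reversible reaction) can support either parity and is always
#' considered consistent.
#'
#' @param parity `"+"`, `"-"` or `"ambiguous"` (a path's sign product).
#' @param condition_dir,effect_dir `"up"` or `"down"`.
#' @return Logical.
#' @export
parity_consistent <- function(parity, condition_dir, effect_dir) {
  if (!all(c(condition_dir, effect_dir) %in% c("up", "down")))
    rlang::abort(paste("both directions must be specified as up/down;",
                       "skip parity filtering otherwise"))
  parity == "ambiguous" |
    (parity == "+" & condition_dir == effect_dir) |
    (parity == "-" & condition_dir != effect_dir)
}

#' Filter the influence graph to condition/effect paths (directed mode)
#'
#' Phase 2. For every (effect root, condition) pair present in the graph,
#' enumerates all simple paths within `offset` of the pair's minimum cost.
#' When a pair yields more than `max_paths` paths, parity filtering is
#' applied first (if directions were supplied for both ends), then the offset
#' is repeatedly halved, and finally the cheapest `max_paths` survive. The
#' union of all surviving paths' nodes and edges is the filtered graph G2;
#' conditions with no node or no path are reported as unconnected.
#'
#' @param g1 A `metreg_graph` built from the effect entities.
#' @param conditions Target tibble (see [target_spec()]) or character vector
#'   of condition entity ids.
#' @param effects Optional target tibble carrying effect directions; default
#'   uses the graph's roots with unspecified direction.
#' @param offset,max_paths See [enumerate_paths()].
#' @param parity_filter Apply parity filtering during path-count reduction
#'   (default `TRUE`; it only ever triggers when both directions are known).
#' @return A `filtered_graph`: `nodes`, `edges`, `paths` (one row per kept
#'   path with `pair`, consistency flag), `pairs` summary,
#'   `consistent_pairs`, `unconnected`.
#' @export
filter_directed <- function(g1, conditions, effects = NULL, offset = 2,
                            max_paths = 25, parity_filter = TRUE) {
  stopifnot(inherits(g1, "metreg_graph"))
  if (is.character(conditions)) conditions <- target_spec(conditions, "condition")
  if (is.null(effects)) effects <- target_spec(g1$roots, "effect")
  net_nodes <- g1$nodes$id
  all_paths <- list()
  pair_rows <- list()
  unconnected <- character()

  for (ci in seq_len(nrow(conditions))) {
    cnd <- conditions$entity[ci]
    cdir <- conditions$direction[ci]
    reached_any <- FALSE
    for (ri in seq_len(nrow(effects))) {
      rt <- effects$entity[ri]
      edir <- effects$direction[ri]
      if (!rt %in% g1$roots) next
      if (rt == cnd) next
      paths <- enumerate_paths(g1, rt, cnd, offset, max_paths = .Machine$integer.max)
      if (!nrow(paths)) next
      reached_any <- TRUE
      dirs_known <- all(c(cdir, edir) %in% c("up", "down"))
      if (dirs_known) {
        paths$consistent <- parity_consistent(paths$parity, cdir, edir)
      } else {
        paths$consistent <- NA
      }
      # reduction schedule: parity filter first, then halve the offset
      if (nrow(paths) > max_paths && parity_filter && dirs_known) {
        paths <- paths[paths$consistent, , drop = FALSE]
      }
      if (!nrow(paths)) next
      off <- offset
      min_cost <- min(paths$total_cost)
      while (nrow(paths) > max_paths && off > 1e-9) {
        off <- off / 2
        paths <- paths[paths$total_cost <= min_cost + off + 1e-9, ,
                       drop = FALSE]
      }
      if (nrow(paths) > max_paths)
        paths <- paths[seq_len(max_paths), , drop = FALSE]
      paths$pair <- paste(rt, cnd, sep = " -> ")
      paths$condition <- cnd
      all_paths[[length(all_paths) + 1]] <- paths
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        effect = rt, condition = cnd, n_paths = nrow(paths),
        min_cost = min(paths$total_cost),
        any_consistent = if (dirs_known) any(paths$consistent) else NA
      )
    }
    if (!reached_any) unconnected <- c(unconnected, cnd)
  }

  paths <- dplyr::bind_rows(all_paths)
  pairs <- dplyr::bind_rows(pair_rows)
  if (nrow(paths)) {
    step_tbl <- dplyr::bind_rows(paths$steps) |>
      dplyr::distinct(.data$from, .data$to, .data$type, .data$via,
                      .keep_all = TRUE) |>
      dplyr::arrange(.data$from, .data$to, .data$type, .data$via)
    node_ids <- sort(unique(c(
      unlist(purrr::map(paths$steps, ~ c(.x$from, .x$to))),
      paths$root, paths$terminus)))
  } else {
    step_tbl <- g1$edges[0, , drop = FALSE]
    node_ids <- character()
  }
  structure(
    list(
      nodes = g1$nodes[g1$nodes$id %in% node_ids, , drop = FALSE],
      edges = step_tbl,
      paths = paths,
      pairs = pairs,
      consistent_pairs = if (nrow(pairs))
        pairs[which(pairs$any_consistent %in% TRUE),
              c("effect", "condition")] else
        tibble::tibble(effect = character(), condition = character()),
      unconnected = unconnected,
      conditions = conditions, effects = effects,
      offset = offset, max_paths = max_paths
    ),
    class = "filtered_graph")
}

#' @export
print.filtered_graph <- function(x, ...) {
  cat("<filtered_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$paths), "paths over", nrow(x$pairs), "pairs\n")
  if (length(x$unconnected))
    cat("  unconnected:", paste(x$unconnected, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy filtered_graph
#' @export
tidy.filtered_graph <- function(x, ...) {
  if (!nrow(x$paths)) return(x$paths)
  dplyr::select(x$paths, "pair", "root", "terminus", "total_cost", "parity",
                "consistent", "n_edges", "steps")
}

#' @method glance filtered_graph
#' @export
glance.filtered_graph <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_paths = nrow(x$paths), n_pairs = nrow(x$pairs),
                 n_consistent_pairs = nrow(x$consistent_pairs),
                 n_unconnected = length(x$unconnected))
}

#' Score candidate common influencers (undirected mode)
#'
#' Every node with paths to two or more targets is scored as the sum of its
#' minimum path costs to each reached target plus a penalty of 1.5 times the
#' maximum-cost cutoff for every target it does not reach; lower scores mean
#' greater influence, and the penalty makes broad influencers beat narrow
#' ones all else being equal. Nodes are returned in increasing score order
#' (ties: more targets reached first, then id).
#'
#' @param g1 A `metreg_graph` built in undirected mode with the targets as
#'   roots.
#' @param targets Target logical node ids; default the graph's roots.
#' @param C_max The cutoff used in the penalty; default the graph's.
#' @return An `influencer_scores` tibble: `entity`, `score`, `n_reached`,
#'   `reached` (list), `per_target_cost` (list); attribute `top_ten`.
#' @export
score_influencers <- function(g1, targets = g1$roots, C_max = g1$C_max) {
  stopifnot(inherits(g1, "metreg_graph"))
  targets <- unique(targets)
  if (length(targets) < 2)
    rlang::abort("undirected influence scoring needs at least two targets")
  penalty_mult <- 1.5
  pc <- g1$pc[g1$pc$root %in% targets, , drop = FALSE]
  by_node <- split(pc, pc$node)
  rows <- purrr::map(by_node, function(d) {
    if (nrow(d) < 2) return(NULL)
    tibble::tibble(
      entity = d$node[1],
      score = sum(d$cost) + penalty_mult * C_max * (length(targets) - nrow(d)),
      n_reached = nrow(d),
      reached = list(sort(d$root)),
      per_target_cost = list(stats::setNames(d$cost, d$root))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(entity = character(), score = numeric(),
                          n_reached = integer(), reached = list(),
                          per_target_cost = list())
  } else {
    out <- out[order(out$score, -out$n_reached, out$entity), , drop = FALSE]
  }
  attr(out, "top_ten") <- utils::head(out, 10)
  attr(out, "targets") <- sort(targets)
  class(out) <- c("influencer_scores", class(out))
  out
}

#' Greedy covering set of influencers
#'
#' Walks the ranking in order of increasing score; an influencer that adds at
#' least one uncovered target to the covered set is kept. Stops when all
#' targets are covered or the ranking is exhausted. The result favours
#' well-scoring influencers over minimality and may include members of the
#' target set itself.
#'
#' @param ranked An `influencer_scores` tibble (ascending score order).
#' @param targets The target set to cover; default the ranking's.
#' @return A list with `cover` (tibble slice of `ranked`, in addition
#'   order), `covered` and `uncovered` (character vectors).
#' @export
covering_set <- function(ranked, targets = attr(ranked, "targets")) {
  covered <- character()
  keep <- integer()
  for (i in seq_len(nrow(ranked))) {
    gain <- setdiff(intersect(ranked$reached[[i]], targets), covered)
    if (length(gain)) {
      keep <- c(keep, i)
      covered <- union(covered, gain)
      if (setequal(covered, targets)) break
    }
  }
  list(cover = ranked[keep, , drop = FALSE],
       covered = sort(covered),
       uncovered = sort(setdiff(targets, covered)))
}

#' Undirected-mode filtering
#'
#' Reduces the undirected problem to the directed one: influencers are scored
#' over the target-rooted graph, a greedy covering set is formed, and the
#' cover members are posited as conditions for [filter_directed()]. A
#' specific influencer can be substituted for the automatic cover to explore
#' alternatives (mirroring an interactive influencer list).
#'
#' @param g1 A `metreg_graph` built in undirected mode (targets as roots).
#' @param targets Target tibble or ids; default the graph's roots.
#' @param offset,max_paths,parity_filter Passed to [filter_directed()].
#' @param C_max Penalty cutoff for scoring; default the graph's.
#' @param use_influencers Optional character vector overriding the cover
#'   members used as conditions.
#' @return A list with `scores`, `cover`, `covered`, `uncovered`, and `g2`
#'   (the `filtered_graph`).
#' @export
filter_undirected <- function(g1, targets = NULL, offset = 2, max_paths = 25,
                              parity_filter = TRUE, C_max = g1$C_max,
                              use_influencers = NULL) {
  if (is.null(targets)) targets <- target_spec(g1$roots, "effect")
  if (is.character(targets)) targets <- target_spec(targets, "effect")
  scores <- score_influencers(g1, targets$entity, C_max)
  cov <- covering_set(scores, unique(targets$entity))
  cond_ids <- use_influencers %||% cov$cover$entity
  g2 <- filter_directed(g1, target_spec(cond_ids, "condition"),
                        effects = targets, offset = offset,
                        max_paths = max_paths, parity_filter = parity_filter)
  # targets never reached by any cover member
  reached <- if (nrow(g2$paths)) unique(g2$paths$root) else character()
  g2$unconnected <- union(g2$unconnected,
                          setdiff(unique(targets$entity),
                                  c(reached, cov$covered)))
  list(scores = scores, cover = cov$cover, covered = cov$covered,
       uncovered = cov$uncovered, g2 = g2)
}

#' Render kept paths as a text report
#'
#' One block per condition/effect pair, each path printed as
#' `A -[type,sign]-> B -...` with its total cost and (when directions were
#' supplied) its parity-consistency flag.
#'
#' @param g2 A `filtered_graph`.
#' @return A character vector of report lines.
#' @export
path_report <- function(g2) {
  if (!nrow(g2$paths)) return("no paths found")
  lines <- character()
  for (p in split(g2$paths, g2$paths$pair)) {
    lines <- c(lines, paste0("== ", p$pair[1], " (", nrow(p), " path",
                             if (nrow(p) > 1) "s", ") =="))
    for (i in seq_len(nrow(p))) {
      st <- p$steps[[i]]
      chain <- paste0(st$from[1], paste0(" -[", st$type, ",", st$sign, "]-> ",
                                         st$to, collapse = ""))
      flag <- if (isTRUE(p$consistent[i])) " [consistent]"
        else if (isFALSE(p$consistent[i])) " [inconsistent]" else ""
      lines <- c(lines, sprintf("  cost %.3f parity %s%s: %s",
                                p$total_cost[i], p$parity[i], flag, chain))
    }
  }
  lines
}

#' Write an influencer ranking as TSV
#'
#' @param scores An `influencer_scores` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_influencers_tsv <- function(scores, path) {
  flat <- scores |>
    dplyr::mutate(targets = purrr::map_chr(.data$reached, paste,
                                           collapse = ";")) |>
    dplyr::select("entity", "score", "n_reached", "targets")
  readr::write_tsv(flat, path)
  invisible(path)
}
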
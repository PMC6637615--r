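dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

explanation_igraph <- function(g3) {
  edges <- dplyr::bind_rows(g3$edges, g3$inter_edges)
  verts <- as.data.frame(g3$nodes[, c("id", "kind", "component", "highlight",
                                      "direction", "fillcolor")])
  names(verts)[1] <- "name"
  extra <- setdiff(unique(c(edges$from, edges$to)), verts$name)
  if (length(extra)) {
    verts <- rbind(verts, data.frame(name = extra, kind = "unknown",
                                     component = "inter", highlight = "none",
                                     direction = "unspecified",
                                     fillcolor = "white"))
  }
  verts <- verts[order(verts$name), , drop = FALSE]
  igraph::graph_from_data_frame(
    as.data.frame(edges[, c("from", "to", "type", "sign", "via", "cost",
                            "arrowhead", "color", "component")]),
    directed = TRUE, vertices = verts)
}

write_dot <- function(g3, path) {
  lines <- c("digraph explanation {",
             "  rankdir=LR;",
             "  node [style=filled, fontname=\"Helvetica\"];")
  for (ci in seq_len(nrow(g3$components))) {
    comp <- g3$components[ci, ]
    nd <- g3$nodes[g3$nodes$component == comp$component, , drop = FALSE]
    lines <- c(lines,
               sprintf("  subgraph cluster_%s {", gsub("-", "_", comp$component)),
               sprintf("    label=%s;", dot_quote(comp$component)))
    for (i in seq_len(nrow(nd))) {
      shape <- switch(nd$kind[i], metabolite = "ellipse",
                      "transcription-unit" = "note", "box")
      pw <- if (nd$highlight[i] != "none") ", penwidth=2" else ""
      lines <- c(lines, sprintf(
        "    %s [shape=%s, fillcolor=%s%s];",
        dot_quote(nd$id[i]), shape, dot_quote(nd$fillcolor[i]), pw))
    }
    lines <- c(lines, "  }")
  }
  all_edges <- dplyr::bind_rows(g3$edges, g3$inter_edges)
  if (nrow(all_edges)) {
    all_edges <- dplyr::arrange(all_edges, .data$from, .data$to, .data$type,
                                .data$via)
    for (i in seq_len(nrow(all_edges))) {
      e <- all_edges[i, ]
      # drawn influencer -> influenced: the direction influence acts in
      lines <- c(lines, sprintf(
        "  %s -> %s [arrowhead=%s, color=%s, label=%s];",
        dot_quote(e$to), dot_quote(e$from), e$arrowhead,
        dot_quote(e$color), dot_quote(e$type)))
    }
  }
  lines <- c(lines, "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
}

#' Export an explanation graph
#'
#' Writes the styled explanation graph in one of three standard formats:
#' Graphviz DOT (components as clusters, arrowheads by influence type,
#' colours by sign, influence drawn influencer to influenced), GraphML (via
#' igraph, all style attributes as node/edge attributes), or a documented
#' JSON form carrying components, temporary pathways, nodes, edges and
#' styles. Re-exporting the same graph yields identical bytes.
#'
#' @param g3 An `explanation_graph`.
#' @param path Output file.
#' @param format `"dot"`, `"graphml"` or `"json"`; default guessed from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g3, path, format = c("auto", "dot", "graphml",
                                              "json")) {
  stopifnot(inherits(g3, "explanation_graph"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("dot", "graphml", "json"))
      rlang::abort(glue::glue("cannot guess export format from \"{path}\""))
  }
  if (format == "dot") {
    write_dot(g3, path)
  } else if (format == "graphml") {
    igraph::write_graph(explanation_igraph(g3), path, format = "graphml")
  } else {
    doc <- list(
      components = purrr::pmap(g3$components, function(component, kind,
                                                       n_nodes, nodes,
                                                       reactions) {
        list(id = component, kind = kind, nodes = as.list(nodes),
             reactions = as.list(reactions))
      }),
      pathways = purrr::imap(g3$pathways, function(pw, id) {
        list(component = id, reactions = as.list(pw$reactions),
             display_nodes = as.list(pw$display_nodes),
             suppressed = as.list(pw$suppressed),
             forced_in = as.list(pw$forced_in))
      }),
      nodes = purrr::pmap(g3$nodes, function(id, component, kind, highlight,
                                             direction, fillcolor) {
        list(id = id, kind = kind, component = component,
             highlight = highlight, direction = direction,
             fillcolor = fillcolor)
      }),
      edges = purrr::pmap(dplyr::bind_rows(g3$edges, g3$inter_edges),
                          function(from, to, type, sign, via, cost, arrowhead,
                                   color, component) {
        list(influenced = from, influencer = to, type = type, sign = sign,
             via = via, cost = cost, arrowhead = arrowhead, color = color,
             component = component)
      })
    )
    json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
    con <- file(path, open = "wb")
    writeLines(json, con, useBytes = TRUE)
    close(con)
  }
  invisible(path)
}

#' Plot methods
#'
#' `autoplot.metreg_graph()` shows the node-cost landscape (cost to the
#' nearest root per node, by kind); `autoplot.explanation_graph()` draws the
#' styled graph with a deterministic layered layout (ggplot2);
#' `plot_influencers()` shows the influence-score ranking.
#'
#' @param object,scores The object to plot.
#' @param top_n How many influencers to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot metreg_graph
#' @export
autoplot.metreg_graph <- function(object, ...) {
  d <- object$nodes |> dplyr::mutate(is_root = .data$id %in% object$roots)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$C, y = stats::reorder(.data$id, -.data$C),
                                  colour = .data$kind, shape = .data$is_root)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$C_max, linetype = "dashed") +
    ggplot2::labs(x = "minimum cost to any root", y = NULL,
                  colour = "node kind", shape = "root",
                  title = "Influence-graph node costs") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot explanation_graph
#' @export
autoplot.explanation_graph <- function(object, ...) {
  edges <- dplyr::bind_rows(object$edges, object$inter_edges)
  g <- explanation_igraph(object)
  set.seed(1)   # deterministic layout
  xy <- igraph::layout_with_fr(g)
  nd <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                       fillcolor = igraph::V(g)$fillcolor,
                       highlight = igraph::V(g)$highlight)
  ed <- edges |>
    dplyr::left_join(nd[, c("id", "x", "y")], by = c(to = "id")) |>
    dplyr::left_join(nd[, c("id", "x", "y")], by = c(from = "id"),
                     suffix = c("", "end"))
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
  }
  p +
    ggplot2::geom_label(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$id,
                                     fill = .data$fillcolor), size = 3) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_colour_manual(values = c("+" = "forestgreen",
                                            "-" = "red3",
                                            "ambiguous" = "gray40")) +
    ggplot2::labs(colour = "influence sign", title = "Explanation graph") +
    ggplot2::theme_void()
}

#' @rdname plots
#' @export
plot_influencers <- function(scores, top_n = 10) {
  d <- utils::head(scores, top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = stats::reorder(.data$entity, -.data$score),
                                  fill = factor(.data$n_reached))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "influence score (lower = more influential)", y = NULL,
                  fill = "targets reached",
                  title = "Top candidate common influencers") +
    ggplot2::theme_minimal()
}
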
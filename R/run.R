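#' Run the full explanation pipeline
#'
#' Orchestrates the three phases end to end: loads (or accepts) a network
#' and a target table, builds the influence graph around the effect
#' entities, filters it to condition/effect paths (directed mode) or scores
#' influencers and posits a covering set (undirected mode), assembles the
#' styled explanation graph, and writes all outputs plus a run manifest to
#' `out_dir`. Outputs: `explanation.<fmt>` per requested format,
#' `paths.txt`, `influencers.tsv` (undirected), `unconnected.txt`,
#' `manifest.json`. A run is fully reproducible from its manifest.
#'
#' @param network A `metreg_network` or path to a network JSON file.
#' @param targets A target tibble ([target_spec()]) or path to a targets TSV.
#' @param mode `"directed"` (conditions and effects) or `"undirected"`
#'   (effects only).
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param C_max Maximum path cost (default 20).
#' @param offset Path-cost slack above the per-pair minimum (default 2).
#' @param max_paths Per-pair path budget (default 25).
#' @param parity_filter Use parity filtering when reducing path counts.
#' @param formats Export formats, subset of `c("dot", "graphml", "json")`.
#' @param sign_policy Edge-sign policy or path to an override file.
#' @return (Invisibly) a list with `g1`, `g2`, `g3`, `paths`, `unconnected`,
#'   and in undirected mode `scores` and `cover`.
#' @export
run_explain <- function(network, targets, mode = c("directed", "undirected"),
                        out_dir = NULL, C_max = 20, offset = 2,
                        max_paths = 25, parity_filter = TRUE,
                        formats = "dot",
                        sign_policy = default_sign_policy()) {
  mode <- match.arg(mode)
  net <- if (inherits(network, "metreg_network")) network else
    read_network(network)
  specs <- if (is.data.frame(targets)) targets else read_targets(targets)
  if (is.character(sign_policy) && length(sign_policy) == 1 &&
      file.exists(sign_policy))
    sign_policy <- read_sign_policy(sign_policy)

  lmap <- logical_node_map(net)
  unknown <- setdiff(specs$entity, names(lmap))
  if (length(unknown)) {
    sugg <- purrr::map_chr(unknown, function(u) {
      d <- utils::adist(u, names(lmap), ignore.case = TRUE)
      names(lmap)[which.min(d)]
    })
    rlang::abort(paste0(
      "unknown target entities: ",
      paste(sprintf("\"%s\" (did you mean \"%s\"?)", unknown, sugg),
            collapse = ", ")))
  }
  specs$entity <- unname(lmap[specs$entity])
  specs <- dplyr::distinct(specs)
  conds <- specs[specs$role == "condition", , drop = FALSE]
  effs <- specs[specs$role == "effect", , drop = FALSE]
  if (!nrow(effs)) rlang::abort("at least one effect entity is required")
  if (mode == "directed" && !nrow(conds))
    rlang::abort("directed mode requires at least one condition entity")
  if (mode == "undirected" && nrow(conds))
    rlang::abort("undirected mode takes effect entities only")

  g1 <- build_metreg_graph(effs$entity, net,
                           input_entities = specs$entity, C_max = C_max,
                           mode = mode, sign_policy = sign_policy)
  scores <- NULL; cover <- NULL
  if (mode == "directed") {
    g2 <- filter_directed(g1, conds, effs, offset, max_paths, parity_filter)
    g3 <- build_explanation_graph(g2, net, specs)
  } else {
    res <- filter_undirected(g1, effs, offset, max_paths, parity_filter,
                             C_max)
    g2 <- res$g2
    scores <- res$scores
    cover <- res$cover
    g3 <- build_explanation_graph(g2, net, specs, cover$entity)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (fmt in formats) {
      export_graph(g3, file.path(out_dir, paste0("explanation.", fmt)), fmt)
    }
    writeLines(path_report(g2), file.path(out_dir, "paths.txt"))
    writeLines(g2$unconnected, file.path(out_dir, "unconnected.txt"))
    if (!is.null(scores)) {
      write_influencers_tsv(scores, file.path(out_dir, "influencers.tsv"))
      writeLines(c("# top ten influencers",
                   utils::capture.output(print.data.frame(
                     as.data.frame(attr(scores, "top_ten")[,
                       c("entity", "score", "n_reached")])))),
                 file.path(out_dir, "top_influencers.txt"))
    }
    manifest <- list(
      mode = mode, C_max = C_max, offset = offset, max_paths = max_paths,
      parity_filter = parity_filter, formats = as.list(formats),
      targets = purrr::pmap(specs, \(entity, role, direction)
        list(entity = entity, role = role, direction = direction)),
      n_g1_nodes = nrow(g1$nodes), n_g2_nodes = nrow(g2$nodes),
      n_paths = nrow(g2$paths),
      unconnected = as.list(g2$unconnected),
      cover = as.list(cover$entity %||% character()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(g1 = g1, g2 = g2, g3 = g3, paths = g2$paths,
                 unconnected = g2$unconnected, scores = scores,
                 cover = cover))
}

#' Generate a synthetic network file
#'
#' Wraps [generate_network()]: writes the network JSON plus a small manifest
#' recording the parameters, so the file can be regenerated byte-for-byte.
#'
#' @param path Output network JSON path.
#' @param params A `synth_params` list.
#' @return `path`, invisibly.
#' @export
run_generate <- function(path, params = synth_params()) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  net <- generate_network(params)
  write_network(net, path)
  jsonlite::write_json(unclass(params),
                       paste0(tools::file_path_sans_ext(path),
                              "_params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
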